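#' Run the desk-scale SIR telomere-spreading study
#'
#' Generates the 100-kb SIR demo genome, runs both model variants for the
#' demo's replicate design (30 replicates of 50 cycles by default), sums
#' `sir3_bound` coverage across replicates and averages it over the
#' telomere windows and the interior.  Model 1 (single-motif seeding)
#' spreads marks across the whole chromosome; model 2 (gapped double-motif
#' seeding) confines them to the telomere windows.
#'
#' @param seed integer seed; the genome uses `seed`, model 1 replicates use
#'   seeds `seed + 1 ...` and model 2 replicates `seed + 1000 + 1 ...`.
#' @param n_replicates,n_cycles override the demo design (defaults 30 and
#'   50).
#' @return list with `genome`, `tracks` (per-model `gl_coverage`), and
#'   `summary`: a tibble of mean per-base replicate coverage by model and
#'   region (`telomere` / `interior`).
#' @export
run_sir_demo <- function(seed = 1L, n_replicates = NULL, n_cycles = NULL) {
  demo <- build_scaled_demo("sir")
  n_replicates <- n_replicates %||% demo$n_replicates
  n_cycles <- n_cycles %||% demo$n_cycles
  gen <- generate_genome(demo$spec, seed = seed)
  run_model <- function(bundle, base_seed) {
    cfg <- model_config(bundle, gen$genome, n_cycles = n_cycles,
                        snapshot_every = NULL, seed = base_seed)
    reps <- run_replicates(cfg, n_replicates, base_seed = base_seed)
    sum_coverage(replicate_layer_ranges(reps, "sir3_bound"), gen$genome)
  }
  tracks <- list(model_1 = run_model(demo$bundle_m1, as.integer(seed)),
                 model_2 = run_model(demo$bundle_m2, as.integer(seed + 1000L)))
  len <- demo$spec$chrom_length
  tel <- demo$telomere_window
  region_mean <- function(track, from, to) {
    v <- as.integer(S4Vectors::decode(track$runs[[1]]))
    mean(v[from:to])
  }
  summary <- dplyr::bind_rows(lapply(names(tracks), function(m) {
    tr <- tracks[[m]]
    tibble(model = m,
           region = c("telomere", "interior"),
           mean_coverage = c(
             mean(c(as.integer(S4Vectors::decode(tr$runs[[1]]))[1:tel],
                    as.integer(S4Vectors::decode(tr$runs[[1]]))[(len - tel + 1L):len])),
             region_mean(tr, tel + 1L, len - tel)))
  }))
  list(genome = gen$genome, tracks = tracks, summary = summary,
       telomere_window = tel, n_replicates = n_replicates,
       n_cycles = n_cycles)
}

#' Run the desk-scale OSKM activation-versus-repression study
#'
#' Generates the 200-kb OSKM demo genome (60 synthetic TSS, CpG islands on
#' two-thirds of them) and runs the seven-factor model once per activator
#' statewidth in the demo sweep, tracking the proportion of TSS marked
#' active or repressed at every snapshot.
#'
#' @param seed integer seed; the genome uses `seed` and the run at the
#'   `i`-th statewidth uses `seed + i`.
#' @param statewidths activator statewidths (bp) to sweep.
#' @param n_cycles cycles per run (default 100).
#' @return list with `genome`, `tss`, and `proportions`: a tibble of
#'   (`statewidth`, `cycle`, `gene_list`, `state`, `proportion`, `n_tss`)
#'   including an `all` gene list pooling every TSS.
#' @export
run_oskm_demo <- function(seed = 1L, statewidths = NULL, n_cycles = NULL) {
  demo <- build_scaled_demo("oskm")
  statewidths <- statewidths %||% demo$statewidths
  n_cycles <- n_cycles %||% demo$n_cycles
  gen <- generate_genome(demo$spec, seed = seed)
  rows <- lapply(seq_along(statewidths), function(i) {
    sw <- statewidths[i]
    m <- build_oskm_model(statewidth = sw,
                          abundances = demo$bundle$abundances)
    cfg <- model_config(m, gen$genome, n_cycles = n_cycles,
                        snapshot_every = max(1L, n_cycles %/% 10L),
                        seed = as.integer(seed + i))
    res <- run_simulation(cfg)
    tbl <- tss_state_proportions(res, demo$tss, demo$gene_lists,
                                 states = c("active", "repressed"),
                                 other_name = "no_island")
    pooled <- tbl |>
      dplyr::group_by(.data$cycle, .data$state) |>
      dplyr::summarise(
        proportion = sum(.data$proportion * .data$n_tss) / sum(.data$n_tss),
        n_tss = sum(.data$n_tss), .groups = "drop") |>
      dplyr::mutate(gene_list = "all")
    dplyr::bind_rows(tbl, pooled) |>
      dplyr::mutate(statewidth = sw)
  })
  list(genome = gen$genome, tss = demo$tss,
       proportions = dplyr::bind_rows(rows) |>
         dplyr::select("statewidth", "cycle", "gene_list", "state",
                       "proportion", "n_tss"))
}
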