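#' Ready-built model bundles
#'
#' A model bundle collects the layer names, the ordered binding factors,
#' a constant abundance schedule and default cycle/snapshot settings of a
#' model, ready to drop into [simulation_config()].
#'
#' @name gl_model
NULL

new_model <- function(name, layers, factors, abundances, n_cycles,
                      snapshot_every) {
  fnames <- vapply(factors, `[[`, character(1), "name")
  if (!setequal(fnames, names(abundances))) {
    abort("Abundances must name exactly the bundle's factors.")
  }
  used <- unique(unlist(lapply(factors, function(f) {
    c(f$predicate$present, f$predicate$absent, names(f$mods))
  })))
  if (!all(used %in% layers)) {
    abort(paste0("Bundle references undeclared layer(s): ",
                 paste(setdiff(used, layers), collapse = ", ")))
  }
  structure(list(name = name, layers = layers, factors = factors,
                 abundances = abundances, n_cycles = as.integer(n_cycles),
                 snapshot_every = snapshot_every),
            class = "gl_model")
}

#' @export
print.gl_model <- function(x, ...) {
  cat("<gl_model> ", x$name, ": ", length(x$factors), " factor(s) on layers ",
      paste(x$layers, collapse = ", "), "; ", x$n_cycles,
      " cycle(s) by default\n", sep = "")
  for (f in x$factors) print(f)
  invisible(x)
}

#' Yeast SIR telomeric-silencing models
#'
#' Two variants of a recruitment-and-spreading model of SIR heterochromatin
#' in budding yeast.  RAP1 recognises the telomeric-repeat motif `GGTGT`
#' and marks a `sir3_potential` layer; in variant 1 any single motif
#' suffices, in variant 2 RAP1 is only recruited to double motifs gapped by
#' 0-3 bp (`GGTGT.{0,3}GGTGT`).  Sir3p (the SIR complex) binds wherever
#' `sir3_potential` is marked but `sir3_bound` is not, marking
#' `sir3_bound`; Sir3.spreader then extends `sir3_bound` around existing
#' marks, displacing each placement by a normally distributed distance
#' (default mean 147 bp, sd 30 bp — about one nucleosome) in a random
#' direction.
#'
#' Defaults follow the full-genome study conditions: 200 cycles with
#' snapshots every 10.  Abundances are package defaults (500 per factor at
#' a ~12 Mbp genome scale) exposed as parameters.
#'
#' @param variant 1 (single-motif seeding) or 2 (gapped double motifs).
#' @param spread_mean,spread_sd spreading distance distribution in bp.
#' @param abundances named abundances for `RAP1`, `Sir3p`, `Sir3.spreader`.
#' @param rap1_statewidth,sir3_statewidth mark widths in bp.
#' @return a `gl_model` bundle.
#' @export
build_sir_model <- function(variant = 1, spread_mean = 147, spread_sd = 30,
                            abundances = c(RAP1 = 500, Sir3p = 500,
                                           Sir3.spreader = 500),
                            rap1_statewidth = 10L, sir3_statewidth = 147L) {
  if (!variant %in% c(1, 2)) abort("`variant` must be 1 or 2.")
  rap1_profile <- if (variant == 1) {
    seq_profile("consensus", "GGTGT")
  } else {
    seq_profile("regex", "GGTGT.{0,3}GGTGT")
  }
  factors <- list(
    binding_factor("RAP1", rap1_profile,
                   mods = c(sir3_potential = "present"),
                   statewidth = rap1_statewidth, cacheable = TRUE),
    binding_factor("Sir3p", seq_profile("none"),
                   layer_predicate(present = "sir3_potential",
                                   absent = "sir3_bound"),
                   mods = c(sir3_bound = "present"),
                   statewidth = sir3_statewidth),
    binding_factor("Sir3.spreader", seq_profile("none"),
                   layer_predicate(present = "sir3_bound"),
                   mods = c(sir3_bound = "present"),
                   statewidth = sir3_statewidth,
                   offset = offset_normal(spread_mean, spread_sd)))
  new_model(paste0("sir_model_", variant),
            layers = c("sir3_potential", "sir3_bound"),
            factors = factors, abundances = abundances,
            n_cycles = 200L, snapshot_every = 10L)
}

#' Human OSKM-activation versus CpG-island-repression model
#'
#' Seven binding factors on layers `active` and `repressed`: the four
#' pluripotency (OSKM) activators OCT4 (`ATGCAAAT`), SOX2 (`WTTGT`), KLF4
#' (`GCCAMGCCTC`) and MYC (`CACGTG`) mark `active` around their consensus
#' matches, sharing one `statewidth` and ignoring repression entirely; a
#' generic repressor recognises CpG-island-like sequence
#' (`(CG.{0,20}){4}CG`) and marks `repressed`, but only where no `active`
#' mark overlaps; `bf.RepSpread` extends `repressed` around existing
#' repressed marks (again blocked by `active`); and `bf.cleaner` resolves
#' conflicts by erasing both marks wherever they overlap (its abundance is
#' effectively unlimited).  Default abundances are the full-genome values:
#' 5000 per activator, 20000 for repressor and spreader, 1e10 for the
#' cleaner; default 100 cycles.
#'
#' @param statewidth shared activator mark width in bp (the swept
#'   parameter).
#' @param abundances named per-factor abundances.
#' @param repressor_statewidth repressed mark width at island matches (bp).
#' @param repspread_statewidth repressed spreading width (bp); spreading
#'   placements are displaced by a uniform 1..`repspread_statewidth`
#'   magnitude with random sign.
#' @param cleaner `"intersection"` erases only the overlap of the two
#'   marks (the default conflict-resolver reading); `"footprint"` erases
#'   whole conflicted intervals (the literal reading).
#' @return a `gl_model` bundle.
#' @export
build_oskm_model <- function(statewidth = 200L,
                             abundances = c(bf_OCT4 = 5000, bf_SOX2 = 5000,
                                            bf_KLF4 = 5000, bf_MYC = 5000,
                                            bf_repressor = 20000,
                                            bf.RepSpread = 20000,
                                            bf.cleaner = 1e10),
                             repressor_statewidth = 500L,
                             repspread_statewidth = 1000L,
                             cleaner = c("intersection", "footprint")) {
  cleaner <- match.arg(cleaner)
  if (!is_count(statewidth)) abort("`statewidth` must be a positive integer.")
  activator <- function(name, pattern) {
    binding_factor(name, seq_profile("consensus", pattern),
                   mods = c(active = "present"), statewidth = statewidth,
                   cacheable = TRUE)
  }
  factors <- list(
    activator("bf_OCT4", "ATGCAAAT"),
    activator("bf_SOX2", "WTTGT"),
    activator("bf_KLF4", "GCCAMGCCTC"),
    activator("bf_MYC", "CACGTG"),
    binding_factor("bf_repressor", seq_profile("regex", "(CG.{0,20}){4}CG"),
                   layer_predicate(absent = "active"),
                   mods = c(repressed = "present"),
                   statewidth = repressor_statewidth, cacheable = TRUE),
    binding_factor("bf.RepSpread", seq_profile("none"),
                   layer_predicate(present = "repressed", absent = "active"),
                   mods = c(repressed = "present"),
                   statewidth = repspread_statewidth,
                   offset = offset_uniform(1L, repspread_statewidth)),
    binding_factor("bf.cleaner", seq_profile("none"),
                   layer_predicate(present = c("active", "repressed")),
                   mods = c(active = "absent", repressed = "absent"),
                   placement = if (cleaner == "intersection") "intersection"
                               else "footprint"))
  new_model("oskm_model", layers = c("active", "repressed"),
            factors = factors, abundances = abundances,
            n_cycles = 100L, snapshot_every = 10L)
}

#' Turn a model bundle into a simulation configuration
#'
#' @param model a `gl_model`.
#' @param genome a [gl_genome].
#' @param n_cycles,snapshot_every,seed,abundances,initial,snapshot_dir
#'   overrides of the bundle defaults (see [simulation_config()]).
#' @return a `gl_config`.
#' @export
model_config <- function(model, genome, n_cycles = model$n_cycles,
                         snapshot_every = model$snapshot_every, seed = 1L,
                         abundances = model$abundances, initial = NULL,
                         snapshot_dir = NULL) {
  stopifnot(inherits(model, "gl_model"))
  simulation_config(genome, model$layers, model$factors, abundances,
                    n_cycles = n_cycles, snapshot_every = snapshot_every,
                    seed = seed, initial = initial,
                    snapshot_dir = snapshot_dir)
}

#' Desk-scale demonstration models on synthetic genomes
#'
#' Constructs a synthetic-genome specification plus matched model bundles,
#' scaled so the full study design runs in minutes on one CPU.
#'
#' `model = "sir"`: one 100-kb chromosome with `GGTGT` clusters planted in
#' 2-kb telomere windows (3 gapped double motifs and 4 singles per end)
#' and 20 isolated single motifs in the interior, plus both SIR model
#' variants with abundances rescaled by genome size (500 at ~12 Mbp scales
#' to 4 at 100 kb, rounding up); 50 cycles, 30 replicates.
#'
#' `model = "oskm"`: one 200-kb chromosome carrying 60 synthetic TSS, a
#' 500-bp CpG island centred on two-thirds of them (40/60), and an OCT4
#' motif planted 0.6-1.2 kb from every TSS; Table-scale abundances rescale
#' to 1 per activator and 4 for repressor and spreader (floor of 1,
#' preserving the 4:1 repressor-to-single-activator ratio), cleaner 1e9;
#' 100 cycles.  The returned `statewidths` give the demo's sweep
#' (200, 1000, 5000 bp).  `tss` and `gene_lists` tibbles carry the
#' annotation truth (gene ids, island status, a `cpg_island` gene list).
#'
#' @param model `"sir"` or `"oskm"`.
#' @return a list with `spec` (a [synth_genome_spec()]), model bundles
#'   (`bundle_m1`/`bundle_m2` for sir, `bundle` for oskm), run settings
#'   (`n_cycles`, and `n_replicates` or `statewidths`), `telomere_window`
#'   (sir) and annotation tibbles (`tss`, `gene_lists` for oskm).
#' @export
build_scaled_demo <- function(model = c("sir", "oskm")) {
  model <- match.arg(model)
  if (model == "sir") {
    spec <- synth_genome_spec(
      n_chroms = 1L, chrom_length = 100000L,
      motifs = list(
        planted_motif("GGTGT", 6L, placement = "telomeric",
                      form = "double_gapped", gap_range = c(0L, 3L)),
        planted_motif("GGTGT", 8L, placement = "telomeric"),
        planted_motif("GGTGT", 20L, placement = "interior")),
      telomere_window = 2000L)
    demo_ab <- c(RAP1 = 4, Sir3p = 4, Sir3.spreader = 4)
    list(spec = spec,
         bundle_m1 = build_sir_model(1, abundances = demo_ab),
         bundle_m2 = build_sir_model(2, abundances = demo_ab),
         telomere_window = 2000L, n_cycles = 50L, n_replicates = 30L)
  } else {
    n_tss <- 60L
    tss_pos <- as.integer(round(seq(5000, 195000, length.out = n_tss)))
    has_island <- seq_len(n_tss) %% 3L != 0L   # exactly 2/3 of TSS
    island_starts <- tss_pos[has_island] - 249L
    oct4_offsets <- rep(c(-1200L, -900L, -600L, 600L, 900L, 1200L),
                        length.out = n_tss)
    spec <- synth_genome_spec(
      n_chroms = 1L, chrom_length = 200000L,
      base_composition = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
      motifs = list(
        planted_motif("ATGCAAAT", n_tss, positions = tss_pos + oct4_offsets)),
      islands = list(
        planted_island(sum(has_island), 500L, density = 0.12,
                       positions = island_starts)),
      telomere_window = 2000L)
    tss <- tibble(chrom = "chrS1", pos = tss_pos,
                  gene_id = sprintf("gene_%03d", seq_len(n_tss)),
                  has_island = has_island)
    gene_lists <- tibble(gene_id = tss$gene_id[tss$has_island],
                         list_name = "cpg_island")
    demo_ab <- c(bf_OCT4 = 1, bf_SOX2 = 1, bf_KLF4 = 1, bf_MYC = 1,
                 bf_repressor = 4, bf.RepSpread = 4, bf.cleaner = 1e9)
    list(spec = spec,
         bundle = build_oskm_model(statewidth = 200L, abundances = demo_ab),
         statewidths = c(200L, 1000L, 5000L),
         n_cycles = 100L, tss = tss, gene_lists = gene_lists)
  }
}
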