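#' Stochastic cycle engine
#'
#' One simulation cycle matches every binding factor, in declared order,
#' against the current layer-set state; each factor applies up to its
#' abundance of modifications and immediately hands the updated state to
#' the next factor.  A simulation runs a configured number of cycles from a
#' single seeded RNG stream; replicates run the same configuration under
#' derived seeds.
#'
#' @name sim_engine
NULL

#' Sample hits under an abundance cap
#'
#' If `n` is at least the number of hits, all hits are kept; otherwise a
#' uniform random subset of size `n` is drawn without replacement.  Output
#' is sorted by chromosome and start.  Uses the current RNG stream, so the
#' draw is deterministic under a fixed seed.
#'
#' @param hits a hit tibble.
#' @param n non-negative cap.
#' @param genome optional [gl_genome] fixing the chromosome sort order.
#' @return a hit tibble with `min(n, nrow(hits))` rows.
#' @export
sample_hits <- function(hits, n, genome = NULL) {
  if (!is_count(n, positive = FALSE)) abort("`n` must be a non-negative integer.")
  if (n < nrow(hits)) {
    hits <- hits[sort(sample.int(nrow(hits), n)), , drop = FALSE]
  }
  if (!is.null(genome)) hits <- sort_hits(hits, genome)
  hits
}

#' Place a modification region around a hit
#'
#' The placement centre is the hit midpoint, displaced by a sampled offset
#' magnitude with a uniformly random sign (unless the offset sampler is
#' `NULL`).  The region spans `statewidth` bases starting at
#' `centre - floor(statewidth / 2)` and is clipped to the chromosome; a
#' placement falling entirely off the chromosome yields no region.
#'
#' @param start,end the hit footprint (1-based inclusive).
#' @param statewidth positive integer or sampler; samplers yielding a value
#'   < 1 are redrawn up to 100 times before erroring.
#' @param offset offset sampler or `NULL`.
#' @param chrom_length chromosome length in bp.
#' @return an integer vector `c(start, end)` or `NULL` for an off-chromosome
#'   placement.
#' @export
place_modification <- function(start, end, statewidth, offset = NULL,
                               chrom_length) {
  sw <- draw_sampler(statewidth, 1L)
  tries <- 0L
  while (sw < 1L && tries < 100L) {
    sw <- draw_sampler(statewidth, 1L)
    tries <- tries + 1L
  }
  if (sw < 1L) abort("statewidth sampler kept returning values < 1.")
  centre <- (start + end) %/% 2L
  if (!is.null(offset)) {
    d <- draw_sampler(offset, 1L)
    sgn <- if (stats::runif(1) < 0.5) -1L else 1L
    centre <- centre + sgn * d
  }
  s <- centre - sw %/% 2L
  e <- s + sw - 1L
  if (e < 1L || s > chrom_length) return(NULL)
  c(max(1L, s), min(chrom_length, e))
}

factor_placements <- function(x, bf, hit_chrom, hit_start, hit_end) {
  len <- chrom_lengths(x$genome)[[hit_chrom]]
  switch(bf$placement,
    statewidth = {
      p <- place_modification(hit_start, hit_end, bf$statewidth, bf$offset, len)
      if (is.null(p)) NULL else tibble(chrom = hit_chrom, start = p[1], end = p[2])
    },
    footprint = tibble(chrom = hit_chrom, start = hit_start, end = hit_end),
    intersection = {
      others <- bf$predicate$present[-1]
      ir <- IRanges::IRanges(hit_start, hit_end)
      for (nm in others) {
        ir <- IRanges::intersect(ir, x$layers[[nm]][[hit_chrom]])
      }
      if (length(ir) == 0L) NULL else
        tibble(chrom = hit_chrom, start = IRanges::start(ir),
               end = IRanges::end(ir))
    })
}

#' Apply one binding factor to a layer set
#'
#' Matches the factor, samples at most `abundance` hits, places one
#' modification region per chosen hit and applies every modification of the
#' factor to it.  A modification that re-marks an already matching region
#' is a no-op by interval algebra, but still consumes abundance.
#'
#' @param x a [gl_layerset].
#' @param bf a [binding_factor()].
#' @param abundance non-negative per-cycle cap on modifications.
#' @return list with `layerset` (updated), `n_hits` (candidate matches) and
#'   `n_applied` (hits acted on, always `<= abundance`).
#' @export
apply_binding_factor <- function(x, bf, abundance) {
  hits <- match_binding_factor(x, bf)
  chosen <- sample_hits(hits, abundance, x$genome)
  if (nrow(chosen)) {
    for (i in seq_len(nrow(chosen))) {
      pl <- factor_placements(x, bf, chosen$chrom[i], chosen$start[i],
                              chosen$end[i])
      if (is.null(pl) || nrow(pl) == 0L) next
      for (m in seq_along(bf$mods)) {
        x <- set_state(x, names(bf$mods)[m], pl$chrom, pl$start, pl$end,
                       unname(bf$mods[m]))
      }
    }
  }
  list(layerset = x, n_hits = nrow(hits), n_applied = nrow(chosen))
}

#' Run one simulation cycle
#'
#' Factors are applied sequentially in list order; each factor matches
#' against the state left by its predecessors within the same cycle.  A
#' per-layer history record (interval count, covered bp) is appended at the
#' cycle end.
#'
#' @param x a [gl_layerset].
#' @param factors ordered list of [binding_factor()]s.
#' @param abundances named numeric vector of per-factor abundances for this
#'   cycle (must cover every factor).
#' @param cycle_index 1-based cycle number recorded in the history.
#' @return list with `layerset` and `applications`, a tibble of
#'   (`cycle`, `factor`, `n_hits`, `n_applied`).
#' @export
run_cycle <- function(x, factors, abundances, cycle_index = x$cycle + 1L) {
  nms <- vapply(factors, `[[`, character(1), "name")
  if (!all(nms %in% names(abundances))) {
    abort(paste0("No abundance for factor(s): ",
                 paste(setdiff(nms, names(abundances)), collapse = ", ")))
  }
  apps <- vector("list", length(factors))
  for (i in seq_along(factors)) {
    res <- apply_binding_factor(x, factors[[i]],
                                as.numeric(abundances[[nms[i]]]))
    x <- res$layerset
    apps[[i]] <- tibble(cycle = as.integer(cycle_index), factor = nms[i],
                        n_hits = res$n_hits, n_applied = res$n_applied)
  }
  x$cycle <- as.integer(cycle_index)
  rec <- dplyr::bind_rows(lapply(names(x$layers), function(nm) {
    tibble(cycle = as.integer(cycle_index), layer = nm,
           n_ranges = layer_n_ranges(x, nm),
           covered_bp = as.integer(covered_bp(x, nm)))
  }))
  x$history <- dplyr::bind_rows(x$history, rec)
  list(layerset = x, applications = dplyr::bind_rows(apps))
}

#' Simulation configuration
#'
#' @param genome a [gl_genome] (or path to a FASTA file, loaded lazily).
#' @param layers layer names.
#' @param factors ordered list of [binding_factor()]s.
#' @param abundances named numeric vector (constant schedule) or a function
#'   `function(cycle)` returning one; every factor must be covered at every
#'   cycle.
#' @param n_cycles number of cycles (>= 1).
#' @param snapshot_every keep a copy of all layers every this many cycles
#'   (`NULL` to disable); snapshots happen exactly at multiples of
#'   `snapshot_every` up to `n_cycles`.
#' @param seed integer seed for the simulation's RNG stream
#'   (Mersenne-Twister; recorded in run manifests).
#' @param initial optional initial intervals per layer (see [layer_set()]).
#' @param snapshot_dir optional directory: snapshots are also persisted to
#'   `snapshot_dir/cycle_NNNN/` via [snapshot_layers()].
#' @return a `gl_config`.
#' @export
simulation_config <- function(genome, layers, factors, abundances,
                              n_cycles, snapshot_every = NULL, seed = 1L,
                              initial = NULL, snapshot_dir = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  stopifnot(inherits(genome, "gl_genome"))
  if (!is_count(n_cycles)) abort("`n_cycles` must be a positive integer.")
  if (!is.null(snapshot_every) && !is_count(snapshot_every)) {
    abort("`snapshot_every` must be a positive integer or NULL.")
  }
  if (!all(vapply(factors, inherits, logical(1), "gl_factor"))) {
    abort("`factors` must be a list of binding_factor() objects.")
  }
  fnames <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(fnames)) abort("Factor names must be unique.")
  used <- unique(unlist(lapply(factors, function(f) {
    c(f$predicate$present, f$predicate$absent, names(f$mods))
  })))
  dangling <- setdiff(used, layers)
  if (length(dangling)) {
    abort(paste0("Factor(s) reference undeclared layer(s): ",
                 paste(dangling, collapse = ", ")))
  }
  structure(list(genome = genome, layers = layers, factors = factors,
                 abundances = abundances, n_cycles = as.integer(n_cycles),
                 snapshot_every = snapshot_every, seed = as.integer(seed),
                 initial = initial, snapshot_dir = snapshot_dir),
            class = "gl_config")
}

abundances_at <- function(config, cycle) {
  ab <- config$abundances
  if (is.function(ab)) ab <- ab(cycle)
  if (any(ab < 0)) abort("Abundances must be >= 0.")
  ab
}

#' Run a simulation
#'
#' Runs `n_cycles` sequential cycles from the initialised layer set under a
#' single RNG stream seeded from `config$seed`; identical configurations
#' and seeds give identical results (including byte-identical persisted
#' snapshots).
#'
#' @param config a [simulation_config()].
#' @return a `gl_sim` result: `layerset` (final state), `snapshots` (named
#'   list, cycle number to per-layer interval lists), `history` (per-layer
#'   per-cycle tibble), `applications` (per-factor per-cycle tibble) and
#'   `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "gl_config"))
  x <- layer_set(config$genome, config$layers, config$initial)
  snapshots <- list()
  apps <- vector("list", config$n_cycles)
  with_seed(config$seed, {
    for (cyc in seq_len(config$n_cycles)) {
      res <- run_cycle(x, config$factors, abundances_at(config, cyc), cyc)
      x <- res$layerset
      apps[[cyc]] <- res$applications
      if (!is.null(config$snapshot_every) &&
          cyc %% config$snapshot_every == 0L) {
        snapshots[[as.character(cyc)]] <- x$layers
        if (!is.null(config$snapshot_dir)) {
          dir <- file.path(config$snapshot_dir, sprintf("cycle_%04d", cyc))
          ok <- tryCatch({ snapshot_layers(x, dir); TRUE },
                         error = function(e) e)
          if (!isTRUE(ok)) {
            unlink(dir, recursive = TRUE)
            abort(paste0("Snapshot at cycle ", cyc, " failed: ",
                         conditionMessage(ok)))
          }
        }
      }
    }
  })
  structure(list(layerset = x, snapshots = snapshots,
                 history = x$history,
                 applications = dplyr::bind_rows(apps), config = config),
            class = "gl_sim")
}

#' @export
print.gl_sim <- function(x, ...) {
  cat("<gl_sim> ", x$config$n_cycles, " cycle(s), ",
      length(x$config$factors), " factor(s), ",
      length(x$snapshots), " snapshot(s)\n", sep = "")
  print(x$layerset)
  invisible(x)
}

run_manifest <- function(config, seed, path) {
  manifest <- list(
    package = "layersim",
    version = as.character(utils::packageVersion("layersim")),
    seed = seed,
    rng = list(kind = "Mersenne-Twister", normal = "Inversion",
               sample = "Rejection"),
    n_cycles = config$n_cycles,
    layers = config$layers,
    factors = vapply(config$factors, `[[`, character(1), "name"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run seeded replicate simulations
#'
#' Replicate `r` runs the configuration under seed `base_seed + r`, so each
#' replicate owns its RNG stream and can be reproduced in isolation.  A
#' failing replicate is reported by index with a warning and returned as
#' `NULL` without aborting the rest.
#'
#' @param config a [simulation_config()].
#' @param n_replicates number of replicates (>= 1).
#' @param base_seed integer; replicate `r` uses `base_seed + r`.
#' @param out_dir optional directory: each replicate's final layers are
#'   persisted to `out_dir/replicate_NNN/` together with a small manifest.
#' @return list of `gl_sim` results (or `NULL` for failed replicates).
#' @export
run_replicates <- function(config, n_replicates, base_seed = config$seed,
                           out_dir = NULL) {
  if (!is_count(n_replicates)) abort("`n_replicates` must be >= 1.")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    res <- tryCatch(run_simulation(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("Replicate %d failed: %s", r, conditionMessage(res)))
      return(NULL)
    }
    if (!is.null(out_dir)) {
      rdir <- file.path(out_dir, sprintf("replicate_%03d", r))
      snapshot_layers(res$layerset, rdir)
      run_manifest(cfg, cfg$seed, file.path(rdir, "run_manifest.json"))
    }
    res
  })
}

#' Collect one layer's final intervals across replicates
#'
#' @param results list of `gl_sim` results (as from [run_replicates()]).
#' @param layer layer name.
#' @return list of per-chromosome interval lists, ready for
#'   [sum_coverage()].
#' @export
replicate_layer_ranges <- function(results, layer) {
  results <- results[!vapply(results, is.null, logical(1))]
  lapply(results, function(res) res$layerset$layers[[layer]])
}
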