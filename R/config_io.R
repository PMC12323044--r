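#' Read and write simulation configurations
#'
#' Configurations serialize to YAML (or JSON) with these top-level keys:
#' `genome` (a FASTA path) or `synthetic` (a synthetic-genome spec with an
#' optional `seed`), `layers`, `factors`, `abundances`, `n_cycles`,
#' `snapshot_every`, `seed`.  Each factor entry carries `name`, `profile`
#' (`kind`, `pattern`/`pwm`+`threshold`, `strand`), `predicate`
#' (`present`, `absent`, `mode`), `mods` (layer to state map),
#' `statewidth`, `offset` (`dist` plus parameters), `placement` and
#' `cacheable`.  Samplers given as R functions cannot be serialized; use
#' the declarative [offset_normal()]/[offset_uniform()] forms in configs.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @param base_dir directory against which relative genome paths resolve.
#' @return [read_sim_config()]: a `gl_config`.
#' @export
read_sim_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  genome <- if (!is.null(cfg$genome)) {
    gpath <- cfg$genome
    if (!file.exists(gpath)) gpath <- file.path(base_dir, cfg$genome)
    read_genome(gpath)
  } else if (!is.null(cfg$synthetic)) {
    spec <- spec_from_list(cfg$synthetic)
    generate_genome(spec, seed = cfg$synthetic$seed %||% 1L)$genome
  } else {
    abort("Config needs a `genome` path or a `synthetic` genome spec.")
  }
  factors <- lapply(cfg$factors, factor_from_list)
  ab <- unlist(cfg$abundances)
  simulation_config(genome, layers = unlist(cfg$layers), factors = factors,
                    abundances = ab, n_cycles = cfg$n_cycles,
                    snapshot_every = cfg$snapshot_every,
                    seed = cfg$seed %||% 1L)
}

spec_from_list <- function(sl) {
  motifs <- lapply(sl$motifs %||% list(), function(m) {
    planted_motif(m$motif, m$count, placement = m$placement %||% "uniform",
                  form = m$form %||% "single",
                  gap_range = unlist(m$gap_range %||% c(0L, 3L)),
                  positions = unlist(m$positions))
  })
  islands <- lapply(sl$islands %||% list(), function(i) {
    planted_island(i$count, i$length, i$density,
                   positions = unlist(i$positions))
  })
  comp <- unlist(sl$base_composition %||%
                   c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  synth_genome_spec(n_chroms = sl$n_chroms %||% 1L,
                    chrom_length = sl$chrom_length,
                    base_composition = comp, motifs = motifs,
                    islands = islands,
                    telomere_window = sl$telomere_window %||% 1000L)
}

sampler_from_list <- function(sl) {
  if (is.null(sl) || length(sl) == 0L) return(NULL)
  if (is.numeric(sl)) return(as.integer(sl))
  switch(sl$dist,
    normal = offset_normal(sl$mean, sl$sd),
    uniform = offset_uniform(sl$min, sl$max),
    fixed = statewidth_fixed(sl$width),
    abort(paste0("Unknown sampler distribution: ", sl$dist)))
}

factor_from_list <- function(fl) {
  pr <- fl$profile
  profile <- switch(pr$kind,
    none = seq_profile("none"),
    pwm = seq_profile("pwm", pwm = matrix(unlist(pr$pwm), nrow = 4L,
                                          byrow = TRUE,
                                          dimnames = list(c("A","C","G","T"),
                                                          NULL)),
                      threshold = pr$threshold %||% 0.90,
                      strand = pr$strand),
    seq_profile(pr$kind, pattern = pr$pattern, strand = pr$strand))
  pd <- fl$predicate %||% list()
  predicate <- layer_predicate(present = unlist(pd$present) %||% character(),
                               absent = unlist(pd$absent) %||% character(),
                               mode = pd$mode %||% "any")
  binding_factor(fl$name, profile, predicate,
                 mods = unlist(fl$mods),
                 statewidth = sampler_from_list(fl$statewidth),
                 offset = sampler_from_list(fl$offset),
                 placement = fl$placement %||% "statewidth",
                 cacheable = fl$cacheable)
}

sampler_to_list <- function(s) {
  if (is.null(s)) return(NULL)
  if (is.function(s)) {
    abort("Function-valued samplers cannot be serialized; use offset_normal()/offset_uniform()/statewidth_fixed().")
  }
  if (is.numeric(s)) return(as.integer(s))
  unclass(s)[setdiff(names(unclass(s)), "what")]
}

factor_to_list <- function(f) {
  pr <- f$profile
  profile <- switch(pr$kind,
    none = list(kind = "none"),
    pwm = list(kind = "pwm", pwm = apply(pr$pwm, 1L, identity,
                                         simplify = FALSE),
               threshold = pr$threshold, strand = pr$strand),
    list(kind = pr$kind, pattern = pr$pattern, strand = pr$strand))
  if (pr$kind == "pwm") {
    profile$pwm <- lapply(seq_len(nrow(pr$pwm)),
                          function(i) unname(pr$pwm[i, ]))
  }
  out <- list(name = f$name, profile = profile,
              predicate = list(present = as.list(f$predicate$present),
                               absent = as.list(f$predicate$absent),
                               mode = f$predicate$mode),
              mods = as.list(f$mods),
              statewidth = sampler_to_list(f$statewidth),
              offset = sampler_to_list(f$offset),
              placement = f$placement, cacheable = f$cacheable)
  out[!vapply(out, is.null, logical(1))]
}

#' @rdname read_sim_config
#' @param config a `gl_config` or `gl_model` bundle to serialize.
#' @param genome_path FASTA path recorded in the file (the genome itself is
#'   not embedded); for bundles this may be `NULL` and filled in later.
#' @export
write_sim_config <- function(config, path, genome_path = NULL) {
  if (inherits(config, "gl_model")) {
    out <- list(genome = genome_path, layers = as.list(config$layers),
                factors = lapply(config$factors, factor_to_list),
                abundances = as.list(config$abundances),
                n_cycles = config$n_cycles,
                snapshot_every = config$snapshot_every, seed = 1L)
  } else {
    stopifnot(inherits(config, "gl_config"))
    if (is.function(config$abundances)) {
      abort("Function-valued abundance schedules cannot be serialized.")
    }
    out <- list(genome = genome_path, layers = as.list(config$layers),
                factors = lapply(config$factors, factor_to_list),
                abundances = as.list(config$abundances),
                n_cycles = config$n_cycles,
                snapshot_every = config$snapshot_every, seed = config$seed)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
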