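#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a simulation result
#'
#' `tidy()` returns the per-cycle per-layer history (interval count and
#' covered bp, plus the covered genome fraction); `glance()` returns a
#' one-row summary of the run.
#'
#' @param x a `gl_sim` from [run_simulation()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.gl_sim <- function(x, ...) {
  total <- sum(chrom_lengths(x$layerset$genome))
  dplyr::mutate(x$history, fraction = .data$covered_bp / total)
}

#' @rdname tidy.gl_sim
#' @export
glance.gl_sim <- function(x, ...) {
  final <- dplyr::filter(x$history, .data$cycle == max(.data$cycle))
  tibble(
    n_cycles = x$config$n_cycles,
    n_factors = length(x$config$factors),
    n_layers = length(x$config$layers),
    n_snapshots = length(x$snapshots),
    seed = x$config$seed,
    total_covered_bp = sum(final$covered_bp),
    max_layer_fraction = max(final$covered_bp) /
      sum(chrom_lengths(x$layerset$genome)))
}
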