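#' Plot a replicate coverage track
#'
#' Step plot of per-base replicate counts along each chromosome, the usual
#' way to display how many replicate simulations marked each base.
#'
#' @param track a `gl_coverage` from [sum_coverage()] or a tibble from
#'   [coverage_tbl()].
#' @return a ggplot.
#' @export
plot_coverage <- function(track) {
  tb <- if (inherits(track, "gl_coverage")) coverage_tbl(track) else
    as_tibble(track)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$start, y = .data$count)) +
    ggplot2::geom_step(colour = "steelblue4") +
    ggplot2::facet_wrap(~chrom, ncol = 1L, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "replicates covering base") +
    ggplot2::theme_minimal()
}

#' Plot per-layer state accumulation over cycles
#'
#' @param x a `gl_sim` (its history is used) or a history tibble.
#' @return a ggplot of covered bp per layer against cycle.
#' @export
plot_history <- function(x) {
  h <- if (inherits(x, "gl_sim")) x$history else as_tibble(x)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$cycle, y = .data$covered_bp,
                                  colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "covered bp", colour = "layer") +
    ggplot2::theme_minimal()
}

#' Plot TSS state proportions over cycles
#'
#' @param tbl output of [tss_state_proportions()].
#' @return a ggplot, faceted by state, coloured by gene list.
#' @export
plot_tss_proportions <- function(tbl) {
  ggplot2::ggplot(as_tibble(tbl),
                  ggplot2::aes(x = .data$cycle, y = .data$proportion,
                               colour = .data$gene_list)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~state) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "cycle", y = "proportion of TSS covered",
                  colour = "gene list") +
    ggplot2::theme_minimal()
}
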