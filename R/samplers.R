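#' Displacement and statewidth samplers
#'
#' Samplers are small declarative objects so they can round-trip through
#' configuration files; plain R functions `function(n)` are also accepted
#' wherever a sampler is, for fully custom distributions.
#'
#' Offset samplers draw displacement *magnitudes* in bp; the placement step
#' assigns each magnitude a uniformly random sign, so spreading is
#' bidirectional.
#'
#' @param mean,sd mean and standard deviation in bp of the normal
#'   magnitude distribution (draws are rounded to integers).
#' @return a `gl_sampler`.
#' @export
offset_normal <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
  structure(list(what = "offset", dist = "normal", mean = mean, sd = sd),
            class = "gl_sampler")
}

#' @rdname offset_normal
#' @param min,max inclusive integer bounds of the uniform magnitude
#'   distribution.
#' @export
offset_uniform <- function(min, max) {
  stopifnot(min <= max)
  structure(list(what = "offset", dist = "uniform", min = as.integer(min),
                 max = as.integer(max)),
            class = "gl_sampler")
}

#' @rdname offset_normal
#' @param width fixed statewidth in bp.
#' @export
statewidth_fixed <- function(width) {
  stopifnot(is_count(width))
  structure(list(what = "statewidth", dist = "fixed",
                 width = as.integer(width)),
            class = "gl_sampler")
}

#' Draw integer values from a sampler
#'
#' @param sampler a `gl_sampler`, a plain `function(n)`, or a single number
#'   (returned unchanged, replicated).
#' @param n number of draws.
#' @return integer vector of length `n` (magnitudes for offset samplers).
#' @export
draw_sampler <- function(sampler, n) {
  if (is.null(sampler)) return(rep(0L, n))
  if (is.function(sampler)) return(as.integer(round(sampler(n))))
  if (is.numeric(sampler)) return(rep(as.integer(sampler), n))
  stopifnot(inherits(sampler, "gl_sampler"))
  switch(sampler$dist,
    normal = as.integer(round(stats::rnorm(n, sampler$mean, sampler$sd))),
    uniform = if (n == 0L) integer(0) else
      as.integer(sampler$min +
                 floor(stats::runif(n) * (sampler$max - sampler$min + 1L))),
    fixed = rep(sampler$width, n))
}
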