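#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
#' @import dplyr
NULL

# package-local state: sequence-scan counter (used to verify the hit cache)
.gl_state <- new.env(parent = emptyenv())
.gl_state$scan_count <- 0L

#' Number of genome sequence scans performed so far
#'
#' Every fresh sequence scan (consensus, PWM or regex) increments a
#' process-wide counter.  Cached binding factors should not increment it
#' after their first match; the counter makes that contract observable.
#'
#' @param reset if `TRUE`, reset the counter to zero after reading it.
#' @return integer count of scans since load (or last reset).
#' @export
scan_count <- function(reset = FALSE) {
  n <- .gl_state$scan_count
  if (isTRUE(reset)) .gl_state$scan_count <- 0L
  n
}

bump_scan_count <- function() {
  .gl_state$scan_count <- .gl_state$scan_count + 1L
  invisible(NULL)
}

# Evaluate `code` under a fixed, fully specified RNG state, restoring the
# caller's RNG afterwards.  All stochastic behaviour in the package funnels
# through this so that seeds mean the same thing on every platform.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (if (positive) x >= 1 else x >= 0)
}

`%s|%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x
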