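# Independent brute-force oracles used to validate the package's scanning
# and interval algebra.  These deliberately share no code with the
# implementation: per-window character comparison, per-base boolean arrays.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"), R = c("A", "G"), Y = c("C", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))

rc_chr <- function(p) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", W = "W", S = "S",
            R = "Y", Y = "R", K = "M", M = "K", B = "V", V = "B", D = "H",
            H = "D")
  paste(rev(comp[strsplit(toupper(p), "")[[1]]]), collapse = "")
}

naive_consensus_starts <- function(seq, pattern) {
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  n <- length(s); L <- length(p)
  if (L > n) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    ok <- ok & s[j:(n - L + j)] %in% iupac_sets[[p[j]]]
  }
  which(ok)
}

naive_consensus_hits <- function(seq, pattern, strand = "both") {
  starts <- naive_consensus_starts(seq, pattern)
  if (strand == "both") {
    starts <- sort(unique(c(starts, naive_consensus_starts(seq, rc_chr(pattern)))))
  }
  data.frame(start = starts, end = starts + nchar(pattern) - 1L)
}

naive_pwm_scores <- function(seq, pwm) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s); L <- ncol(pwm)
  if (L > n) return(numeric(0))
  sc <- rep(0, n - L + 1L)
  for (j in seq_len(L)) {
    w <- pwm[, j][match(s[j:(n - L + j)], c("A", "C", "G", "T"))]
    w[is.na(w)] <- 0    # N and friends weigh nothing
    sc <- sc + w
  }
  sc
}

naive_pwm_hits <- function(seq, pwm, threshold, strand = "both") {
  min_score <- threshold * sum(apply(pwm, 2, max))
  fwd <- naive_pwm_scores(seq, pwm)
  starts <- which(fwd >= min_score)
  if (strand == "both") {
    rc <- pwm[4:1, ncol(pwm):1, drop = FALSE]
    rownames(rc) <- c("A", "C", "G", "T")
    starts <- sort(unique(c(starts, which(naive_pwm_scores(seq, rc) >= min_score))))
  }
  data.frame(start = starts, end = starts + ncol(pwm) - 1L)
}

# per-base boolean-array oracle of a single-chromosome layer
bool_track <- function(x, layer, chrom) {
  len <- chrom_lengths(x$genome)[[chrom]]
  v <- rep(FALSE, len)
  tbl <- layer_tbl(x, layer)
  tbl <- tbl[tbl$chrom == chrom, ]
  for (i in seq_len(nrow(tbl))) v[tbl$start[i]:tbl$end[i]] <- TRUE
  v
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

toy_genome <- function(...) {
  layersim:::new_genome(c(...))
}

# every-base count oracle for coverage summation
naive_coverage_counts <- function(tbls, len) {
  v <- rep(0L, len)
  for (tbl in tbls) {
    for (i in seq_len(nrow(tbl))) {
      v[tbl$start[i]:tbl$end[i]] <- v[tbl$start[i]:tbl$end[i]] + 1L
    }
  }
  v
}

coverage_counts_vec <- function(track, chrom) {
  as.integer(S4Vectors::decode(track$runs[[chrom]]))
}
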