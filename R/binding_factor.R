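#' Sequence-matching profiles
#'
#' A profile describes how a binding factor recognises the genome sequence:
#' an IUPAC consensus, a position weight matrix, a regular expression, or
#' nothing at all (`"none"`, for factors recruited purely by layer state).
#'
#' Scanning conventions: consensus and PWM scans report every matching
#' window, overlapping occurrences included, on the forward strand and — by
#' default — also on the reverse strand via the reverse-complemented
#' pattern, with palindromic double-counts collapsed to one hit per
#' position.  Regular expressions follow the usual regex-engine contract:
#' non-overlapping, leftmost matches, forward strand only by default.
#' `N` in the genome matches only a literal `N` in a consensus (or regex
#' wildcards); PWM columns give `N` weight 0.
#'
#' @param kind `"consensus"`, `"pwm"`, `"regex"` or `"none"`.
#' @param pattern consensus (IUPAC alphabet) or regular-expression string.
#' @param pwm for `kind = "pwm"`: a 4-row numeric matrix (rows `A`,`C`,`G`,
#'   `T`).  Non-negative integer matrices are treated as JASPAR-style counts
#'   and converted to log-odds with a +0.25 pseudocount per cell against a
#'   uniform background; other matrices are used as score matrices directly.
#' @param threshold for `kind = "pwm"`: minimum score as a fraction of the
#'   maximum attainable score, in (0, 1]; default 0.90.
#' @param strand `"forward"` or `"both"`; defaults to `"both"` for consensus
#'   and PWM profiles and `"forward"` for regex profiles.
#' @return a `gl_profile`.
#' @export
seq_profile <- function(kind = c("consensus", "pwm", "regex", "none"),
                        pattern = NULL, pwm = NULL, threshold = 0.90,
                        strand = NULL) {
  kind <- match.arg(kind)
  if (kind == "none") {
    return(structure(list(kind = "none"), class = "gl_profile"))
  }
  strand <- strand %||% if (kind == "regex") "forward" else "both"
  if (!strand %in% c("forward", "both")) {
    abort('`strand` must be "forward" or "both".')
  }
  if (kind == "pwm") {
    if (is.null(pwm) || !is.matrix(pwm) || nrow(pwm) != 4L) {
      abort("`pwm` must be a 4-row matrix with rows A, C, G, T.")
    }
    rownames(pwm) <- rownames(pwm) %||% c("A", "C", "G", "T")
    pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
    if (all(pwm >= 0) && all(pwm == floor(pwm))) {
      counts <- pwm + 0.25
      pwm <- log2(sweep(counts, 2L, colSums(counts), "/") / 0.25)
    }
    if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
      abort("`threshold` must lie in (0, 1].")
    }
    return(structure(list(kind = "pwm", pwm = pwm, threshold = threshold,
                          strand = strand),
                     class = "gl_profile"))
  }
  if (is.null(pattern) || !nzchar(pattern)) {
    abort(paste0("A ", kind, " profile needs a non-empty `pattern`."))
  }
  if (kind == "consensus") {
    pattern <- toupper(pattern)
    if (grepl("[^ACGTNWSRYKMBVDH]", pattern)) {
      abort("Consensus patterns must use the IUPAC DNA alphabet.")
    }
  } else {
    ok <- tryCatch({ suppressWarnings(regexpr(pattern, "ACGT", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) abort(paste0("Invalid regular expression: ", pattern))
  }
  structure(list(kind = kind, pattern = pattern, strand = strand),
            class = "gl_profile")
}

profile_fingerprint <- function(profile) {
  switch(profile$kind,
    none = "none",
    pwm = paste("pwm", paste(signif(profile$pwm, 10), collapse = ","),
                profile$threshold, profile$strand, sep = "|"),
    paste(profile$kind, profile$pattern, profile$strand, sep = "|"))
}

#' Layer-state predicates
#'
#' A conjunction of per-layer requirements: each `present` layer must
#' overlap the candidate footprint and each `absent` layer must not.  The
#' empty predicate is always true.  `mode = "any"` (default) counts a
#' `present` term satisfied by >= 1 bp of overlap; `mode = "contain"`
#' requires the footprint to lie entirely within a single layer interval.
#'
#' @param present,absent character vectors of layer names.
#' @param mode `"any"` or `"contain"` overlap semantics for `present` terms.
#' @return a `gl_predicate`.
#' @export
layer_predicate <- function(present = character(), absent = character(),
                            mode = c("any", "contain")) {
  mode <- match.arg(mode)
  if (anyDuplicated(c(present, absent))) {
    abort("A layer may appear only once in a predicate.")
  }
  structure(list(present = as.character(present),
                 absent = as.character(absent), mode = mode),
            class = "gl_predicate")
}

predicate_is_empty <- function(p) {
  length(p$present) == 0L && length(p$absent) == 0L
}

#' Binding factors
#'
#' A binding factor matches a combination of genome sequence (its profile)
#' and layer states (its predicate), and where it matches it sets one or
#' more layers present or absent over a placement region.
#'
#' @param name factor name.
#' @param profile a [seq_profile()].
#' @param predicate a [layer_predicate()]; factors with a `"none"` profile
#'   draw their candidate positions from the first `present` layer of the
#'   predicate.
#' @param mods named character vector of modifications, e.g.
#'   `c(active = "present", repressed = "absent")`; at least one required.
#' @param statewidth width in bp of the modified region — either a positive
#'   integer or a sampler (a function `function(n)` returning `n` positive
#'   integers, or [statewidth_fixed()]).  Independent of the match width.
#' @param offset optional displacement sampler for the placement centre
#'   ([offset_normal()], [offset_uniform()] or a `function(n)`); sampled
#'   magnitudes get a uniformly random sign.  Default: no displacement.
#' @param placement `"statewidth"` (default: a `statewidth`-wide region
#'   centred on the match midpoint plus offset), `"footprint"` (modify the
#'   matched interval itself) or `"intersection"` (modify the intersection
#'   of the matched interval with the other `present` layers of the
#'   predicate — the conflict-resolver placement).
#' @param cacheable should sequence hits be cached across cycles?  Defaults
#'   to `TRUE` for sequence-bearing profiles (the genome never changes).
#' @return a `gl_factor`.
#' @export
binding_factor <- function(name, profile, predicate = layer_predicate(),
                           mods, statewidth = NULL, offset = NULL,
                           placement = c("statewidth", "footprint",
                                         "intersection"),
                           cacheable = NULL) {
  placement <- match.arg(placement)
  stopifnot(inherits(profile, "gl_profile"), inherits(predicate, "gl_predicate"))
  if (profile$kind == "none" && predicate_is_empty(predicate)) {
    abort("A factor needs a sequence profile and/or a layer predicate.")
  }
  if (length(mods) == 0L || is.null(names(mods)) || any(!nzchar(names(mods)))) {
    abort("`mods` must be a named vector like c(layer = \"present\").")
  }
  if (!all(mods %in% c("present", "absent"))) {
    abort('Modification states must be "present" or "absent".')
  }
  if (placement == "statewidth") {
    if (is.null(statewidth)) {
      abort("`statewidth` is required for placement = \"statewidth\".")
    }
    if (!is.function(statewidth) && !is_count(statewidth)) {
      abort("`statewidth` must be a positive integer or a sampler function.")
    }
  }
  if (placement == "intersection" && length(predicate$present) < 2L) {
    abort("placement = \"intersection\" needs >= 2 present layers in the predicate.")
  }
  cacheable <- cacheable %||% (profile$kind != "none")
  structure(list(name = name, profile = profile, predicate = predicate,
                 mods = mods, statewidth = statewidth, offset = offset,
                 placement = placement, cacheable = isTRUE(cacheable)),
            class = "gl_factor")
}

#' @export
print.gl_factor <- function(x, ...) {
  pat <- switch(x$profile$kind, none = "<none>",
                pwm = sprintf("PWM[%d] >= %.0f%%", ncol(x$profile$pwm),
                              100 * x$profile$threshold),
                x$profile$pattern)
  cat(sprintf("<gl_factor> %s: %s %s; mods: %s\n", x$name, x$profile$kind,
              pat, paste(names(x$mods), x$mods, sep = "->", collapse = ", ")))
  invisible(x)
}

empty_hits <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), score = numeric())
}

sort_hits <- function(hits, genome) {
  hits$chrom <- factor(hits$chrom, levels = chrom_names(genome))
  hits <- dplyr::arrange(hits, .data$chrom, .data$start, .data$end)
  hits$chrom <- as.character(hits$chrom)
  hits
}

#' Scan a genome for sequence matches
#'
#' @param genome a [gl_genome].
#' @param profile a [seq_profile()] with a sequence-bearing kind.
#' @return tibble of hits: `chrom`, `start`, `end` (1-based inclusive
#'   matched footprint), `strand` (`"+"`, `"-"`, or `"."` for strandless
#'   regex hits) and `score` (PWM score, or 1 for exact kinds), sorted by
#'   chromosome and start.
#' @export
find_sequence_hits <- function(genome, profile) {
  stopifnot(inherits(genome, "gl_genome"), inherits(profile, "gl_profile"))
  if (profile$kind == "none") {
    abort("A \"none\" profile has no sequence matches to find.")
  }
  bump_scan_count()
  parts <- lapply(chrom_names(genome), function(ch) {
    subject <- genome$seqs[[ch]]
    switch(profile$kind,
      consensus = scan_consensus(subject, ch, profile),
      pwm = scan_pwm(subject, ch, profile),
      regex = scan_regex(as.character(subject), ch, profile))
  })
  hits <- dplyr::bind_rows(parts) %s|% empty_hits()
  sort_hits(hits, genome)
}

scan_consensus <- function(subject, ch, profile) {
  pat <- Biostrings::DNAString(profile$pattern)
  out <- list()
  if (length(pat) <= length(subject)) {
    m <- Biostrings::matchPattern(pat, subject, fixed = "subject")
    out$fwd <- tibble(chrom = ch, start = Biostrings::start(m),
                      end = Biostrings::end(m), strand = "+", score = 1)
    if (profile$strand == "both") {
      rc <- Biostrings::reverseComplement(pat)
      m2 <- Biostrings::matchPattern(rc, subject, fixed = "subject")
      out$rev <- tibble(chrom = ch, start = Biostrings::start(m2),
                        end = Biostrings::end(m2), strand = "-", score = 1)
    }
  }
  hits <- dplyr::bind_rows(out) %s|% empty_hits()
  # palindromes: one hit per position
  dplyr::distinct(hits, .data$chrom, .data$start, .data$end,
                  .keep_all = TRUE)
}

scan_pwm <- function(subject, ch, profile) {
  pwm <- profile$pwm
  min_score <- profile$threshold * Biostrings::maxScore(pwm)
  out <- list()
  if (ncol(pwm) <= length(subject)) {
    m <- suppressWarnings(
      Biostrings::matchPWM(pwm, subject, min.score = min_score,
                           with.score = TRUE))
    out$fwd <- tibble(chrom = ch, start = Biostrings::start(m),
                      end = Biostrings::end(m), strand = "+",
                      score = as.numeric(S4Vectors::mcols(m)$score))
    if (profile$strand == "both") {
      m2 <- suppressWarnings(
        Biostrings::matchPWM(Biostrings::reverseComplement(pwm), subject,
                             min.score = min_score, with.score = TRUE))
      out$rev <- tibble(chrom = ch, start = Biostrings::start(m2),
                        end = Biostrings::end(m2), strand = "-",
                        score = as.numeric(S4Vectors::mcols(m2)$score))
    }
  }
  hits <- dplyr::bind_rows(out) %s|% empty_hits()
  hits <- dplyr::arrange(hits, .data$start, dplyr::desc(.data$score))
  dplyr::distinct(hits, .data$chrom, .data$start, .data$end,
                  .keep_all = TRUE)
}

scan_regex <- function(seq_chr, ch, profile) {
  m <- gregexpr(profile$pattern, seq_chr, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_hits())
  tibble(chrom = ch, start = as.integer(m),
         end = as.integer(m) + attr(m, "match.length") - 1L,
         strand = ".", score = 1)
}

#' Count sequence matches under explicit conventions
#'
#' Exposes both strand conventions (via `strand`) and both overlap
#' conventions: `"allow"` counts every matching window; `"disjoint"` counts
#' a greedy left-to-right non-overlapping subset, the convention a
#' non-overlapping scanner would report.
#'
#' @inheritParams find_sequence_hits
#' @param overlap `"allow"` or `"disjoint"`.
#' @param strand optionally override the profile's strand policy.
#' @return integer hit count.
#' @export
count_sequence_hits <- function(genome, profile,
                                overlap = c("allow", "disjoint"),
                                strand = NULL) {
  overlap <- match.arg(overlap)
  if (!is.null(strand)) profile$strand <- match.arg(strand, c("forward", "both"))
  hits <- find_sequence_hits(genome, profile)
  if (overlap == "allow" || nrow(hits) == 0L) return(nrow(hits))
  n <- 0L
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, ]
    last_end <- 0L
    for (i in seq_len(nrow(h))) {
      if (h$start[i] > last_end) {
        n <- n + 1L
        last_end <- h$end[i]
      }
    }
  }
  n
}

#' Evaluate a layer predicate over a footprint
#'
#' A `present` term holds iff the footprint overlaps that layer by at least
#' one base (or is contained in one of its intervals under
#' `mode = "contain"`); an `absent` term holds iff the overlap is zero.
#'
#' @param x a [gl_layerset].
#' @param chrom,start,end the candidate footprint (1-based inclusive).
#' @param predicate a [layer_predicate()].
#' @return logical scalar.
#' @export
evaluate_predicate <- function(x, chrom, start, end, predicate) {
  hits <- tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end))
  filter_hits_by_predicate(x, hits, predicate)$keep[1]
}

filter_hits_by_predicate <- function(x, hits, predicate) {
  keep <- rep(TRUE, nrow(hits))
  if (nrow(hits) == 0L || predicate_is_empty(predicate)) {
    hits$keep <- keep
    return(hits)
  }
  for (nm in c(predicate$present, predicate$absent)) check_layer(x, nm)
  for (ch in unique(hits$chrom)) {
    rows <- which(hits$chrom == ch)
    ir <- IRanges::IRanges(hits$start[rows], hits$end[rows])
    ok <- rep(TRUE, length(rows))
    for (nm in predicate$present) {
      lyr <- x$layers[[nm]][[ch]]
      ov <- if (predicate$mode == "contain") {
        IRanges::countOverlaps(ir, lyr, type = "within")
      } else {
        IRanges::countOverlaps(ir, lyr)
      }
      ok <- ok & ov > 0L
    }
    for (nm in predicate$absent) {
      ok <- ok & IRanges::countOverlaps(ir, x$layers[[nm]][[ch]]) == 0L
    }
    keep[rows] <- ok
  }
  hits$keep <- keep
  hits
}

get_cached_hits <- function(x, profile) {
  key <- profile_fingerprint(profile)
  if (!exists(key, envir = x$cache, inherits = FALSE)) {
    assign(key, find_sequence_hits(x$genome, profile), envir = x$cache)
  }
  get(key, envir = x$cache, inherits = FALSE)
}

#' Match a binding factor against the current layer-set state
#'
#' Sequence-bearing factors take their candidate hits from the layer set's
#' hit cache (populated on first use) when `cacheable`, otherwise from a
#' fresh scan, and filter them through the layer predicate.  Factors with a
#' `"none"` profile take one candidate per maximal interval of the first
#' `present` layer of their predicate, filtered by the remaining terms.
#'
#' @param x a [gl_layerset].
#' @param bf a [binding_factor()].
#' @return a hit tibble (`chrom`, `start`, `end`, `strand`, `score`) sorted
#'   by chromosome and start.
#' @export
match_binding_factor <- function(x, bf) {
  stopifnot(inherits(x, "gl_layerset"), inherits(bf, "gl_factor"))
  if (bf$profile$kind == "none") {
    if (length(bf$predicate$present) == 0L) {
      abort(paste0("Factor '", bf$name,
                   "' has no sequence profile and no present-layer term; ",
                   "it has no candidate source."))
    }
    src <- bf$predicate$present[1]
    check_layer(x, src)
    cand <- layer_tbl(x, src)
    cand$strand <- rep(".", nrow(cand))
    cand$score <- rep(1, nrow(cand))
    rest <- layer_predicate(present = bf$predicate$present[-1],
                            absent = bf$predicate$absent,
                            mode = bf$predicate$mode)
    out <- filter_hits_by_predicate(x, cand, rest)
  } else {
    hits <- if (bf$cacheable) get_cached_hits(x, bf$profile)
            else find_sequence_hits(x$genome, bf$profile)
    out <- filter_hits_by_predicate(x, hits, bf$predicate)
  }
  out <- out[out$keep, c("chrom", "start", "end", "strand", "score")]
  sort_hits(as_tibble(out), x$genome)
}
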