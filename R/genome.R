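#' Genome objects
#'
#' A `gl_genome` is an immutable, ordered set of named chromosome sequences
#' over the alphabet `A`, `C`, `G`, `T`, `N`.  It is the fixed sequence
#' component of a [layer_set()]: simulations read it but can never modify it.
#'
#' @name gl_genome
NULL

new_genome <- function(seqs) {
  if (!is.character(seqs) || length(seqs) == 0L) {
    abort("A genome needs at least one chromosome sequence.")
  }
  nms <- names(seqs)
  if (is.null(nms) || any(!nzchar(nms))) {
    abort("Every chromosome must have a non-empty name.")
  }
  if (anyDuplicated(nms)) {
    abort(paste0("Duplicate chromosome name(s): ",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  bad <- gsub("[ACGTN]", "", seqs)
  n_bad <- sum(nchar(bad))
  if (n_bad > 0) {
    warn(sprintf("%d non-ACGTN base(s) replaced with N.", n_bad))
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (any(nchar(seqs) == 0L)) abort("Zero-length chromosome sequence.")
  structure(
    list(seqs = Biostrings::DNAStringSet(seqs)),
    class = "gl_genome"
  )
}

#' @export
print.gl_genome <- function(x, ...) {
  cat("<gl_genome> ", length(x$seqs), " chromosome(s), ",
      format(sum(chrom_lengths(x)), big.mark = ","), " bp total\n", sep = "")
  ln <- chrom_lengths(x)
  for (i in seq_len(min(10L, length(ln)))) {
    cat("  ", names(ln)[i], ": ", format(ln[i], big.mark = ","), " bp\n",
        sep = "")
  }
  if (length(ln) > 10L) cat("  ...\n")
  invisible(x)
}

#' @rdname gl_genome
#' @param x a `gl_genome`.
#' @return `chrom_names()`: character vector of chromosome names in genome
#'   order; `chrom_lengths()`: named integer vector of lengths in bp;
#'   `chrom_seq()`: the sequence of one chromosome as a character scalar.
#' @export
chrom_names <- function(x) names(x$seqs)

#' @rdname gl_genome
#' @export
chrom_lengths <- function(x) {
  stats::setNames(Biostrings::width(x$seqs), names(x$seqs))
}

#' @rdname gl_genome
#' @param chrom chromosome name.
#' @export
chrom_seq <- function(x, chrom) {
  if (!chrom %in% chrom_names(x)) abort(paste0("Unknown chromosome: ", chrom))
  as.character(x$seqs[[chrom]])
}

#' Read a genome from a FASTA file
#'
#' Records are kept in file order; sequences are upper-cased (soft-masking is
#' ignored) and any IUPAC-ambiguity or other non-`ACGTN` character is
#' replaced by `N` with a warning giving the count.
#'
#' @param path path to a plain or gzipped FASTA file.
#' @return a [gl_genome] object.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) abort(paste0("No FASTA records in ", path))
  nms <- sub("\\s.*$", "", names(dss))
  new_genome(stats::setNames(as.character(dss), nms))
}

#' Write a genome to a FASTA file
#'
#' Sequence lines are wrapped at 60 columns; [read_genome()] on the written
#' file reproduces the genome exactly.
#'
#' @param genome a [gl_genome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "gl_genome"))
  Biostrings::writeXStringSet(genome$seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' Supports the full IUPAC alphabet (`W`/`S` self-complementary, `R`/`Y`,
#' `K`/`M`, `B`/`V`, `D`/`H` swapped, `N` fixed).
#'
#' @param seq a single DNA string.
#' @return the reverse complement, upper-case.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTNWSRYKMBVDHU]", seq)) {
    abort("Sequence contains characters outside the IUPAC DNA alphabet.")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# ---- synthetic genomes -----------------------------------------------------

#' Declare a motif to plant in a synthetic genome
#'
#' @param motif motif string over `ACGT`.
#' @param count number of copies to plant.
#' @param placement `"uniform"` (anywhere), `"telomeric"` (entirely within
#'   `telomere_window` bp of a chromosome end, alternating ends so clusters
#'   stay balanced) or `"interior"` (entirely outside the telomere windows).
#' @param form `"single"` plants the motif itself; `"double_gapped"` plants
#'   two copies separated by a gap drawn uniformly from `gap_range`.
#' @param gap_range integer range (inclusive) for `double_gapped` gaps.
#' @param positions optional explicit start positions (single-chromosome
#'   specs only); overrides random placement but is still collision-checked.
#' @return a `gl_plant` description used by [synth_genome_spec()].
#' @export
planted_motif <- function(motif, count,
                          placement = c("uniform", "telomeric", "interior"),
                          form = c("single", "double_gapped"),
                          gap_range = c(0L, 3L), positions = NULL) {
  placement <- match.arg(placement)
  form <- match.arg(form)
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  if (grepl("[^ACGT]", toupper(motif))) {
    abort("Planted motifs must be plain ACGT strings.")
  }
  if (!is_count(count)) abort("`count` must be a positive integer.")
  stopifnot(length(gap_range) == 2L, gap_range[1] >= 0,
            gap_range[2] >= gap_range[1])
  structure(list(kind = if (form == "single") "motif" else "double_motif",
                 motif = toupper(motif), count = as.integer(count),
                 placement = placement, gap_range = as.integer(gap_range),
                 positions = positions),
            class = "gl_plant")
}

#' Declare CpG-island-like segments to plant in a synthetic genome
#'
#' Island sequence is built by emitting a `CG` dinucleotide with probability
#' `p = density / (1 - density)` per step and a background base otherwise,
#' so the expected CG-dinucleotide density (CG count / island length) is
#' `density`.
#'
#' @param count number of islands.
#' @param length island length in bp.
#' @param density expected CG dinucleotides per bp, in (0, 0.5].
#' @param positions optional explicit start positions (single-chromosome
#'   specs only).
#' @return a `gl_plant` description used by [synth_genome_spec()].
#' @export
planted_island <- function(count, length, density, positions = NULL) {
  if (!is_count(count) || !is_count(length)) {
    abort("`count` and `length` must be positive integers.")
  }
  if (!is.numeric(density) || density <= 0 || density > 0.5) {
    abort("`density` must lie in (0, 0.5].")
  }
  structure(list(kind = "cpg_island", count = as.integer(count),
                 length = as.integer(length), density = density,
                 placement = "uniform", positions = positions),
            class = "gl_plant")
}

#' Specification of a synthetic genome
#'
#' Describes background composition plus planted features (motifs, gapped
#' double motifs, CpG-island-like segments) with a machine-readable ground
#' truth, as a stand-in for reference assemblies in tests and demos.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param base_composition named probabilities over `A`,`C`,`G`,`T`
#'   (must sum to 1).
#' @param motifs list of [planted_motif()] descriptions.
#' @param islands list of [planted_island()] descriptions.
#' @param telomere_window bp from each chromosome end counted as telomeric;
#'   must be at most `chrom_length / 2`.
#' @param chrom_prefix prefix for generated chromosome names.
#' @return a `gl_genome_spec`.
#' @export
synth_genome_spec <- function(n_chroms = 1L, chrom_length = 10000L,
                              base_composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                              motifs = list(), islands = list(),
                              telomere_window = 1000L,
                              chrom_prefix = "chrS") {
  if (!is_count(n_chroms) || !is_count(chrom_length)) {
    abort("`n_chroms` and `chrom_length` must be positive integers.")
  }
  comp <- base_composition[c("A", "C", "G", "T")]
  if (anyNA(comp) || abs(sum(comp) - 1) > 1e-9 || any(comp < 0)) {
    abort("`base_composition` must be named A/C/G/T probabilities summing to 1.")
  }
  if (!is_count(telomere_window) || telomere_window > chrom_length / 2) {
    abort("`telomere_window` must be a positive integer <= chrom_length / 2.")
  }
  plants <- c(motifs, islands)
  if (!all(vapply(plants, inherits, logical(1), "gl_plant"))) {
    abort("`motifs`/`islands` must be lists of planted_motif()/planted_island().")
  }
  if (n_chroms > 1L &&
      any(vapply(plants, function(p) !is.null(p$positions), logical(1)))) {
    abort("Explicit `positions` are only supported for single-chromosome specs.")
  }
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 base_composition = comp, plants = plants,
                 telomere_window = as.integer(telomere_window),
                 chrom_prefix = chrom_prefix),
            class = "gl_genome_spec")
}

plant_length <- function(plant, gap = NULL) {
  switch(plant$kind,
         motif = nchar(plant$motif),
         double_motif = 2L * nchar(plant$motif) + gap,
         cpg_island = plant$length)
}

build_island_seq <- function(len, density, comp) {
  p <- density / (1 - density)
  out <- character(0)
  n <- 0L
  while (n < len) {
    if (stats::runif(1) < p) {
      out <- c(out, "CG"); n <- n + 2L
    } else {
      out <- c(out, sample(c("A", "C", "G", "T"), 1L, prob = comp))
      n <- n + 1L
    }
  }
  substr(paste0(out, collapse = ""), 1L, len)
}

#' Generate a synthetic genome with planted ground truth
#'
#' Background bases are drawn i.i.d. from the spec's base composition, then
#' planted features overwrite the background at collision-free positions
#' (rejection sampling, at most 1000 retries per feature).  Every feature is
#' present verbatim at its recorded coordinates, and the same seed always
#' reproduces the same genome and truth table.
#'
#' @param spec a [synth_genome_spec()].
#' @param seed integer seed.
#' @return a list with `genome` (a [gl_genome]) and `features`, a tibble of
#'   planted features (`chrom`, `start`, `end` 1-based inclusive, `kind`,
#'   `payload`).
#' @export
generate_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "gl_genome_spec"))
  with_seed(seed, {
    len <- spec$chrom_length
    nms <- paste0(spec$chrom_prefix, seq_len(spec$n_chroms))
    seqs <- vapply(nms, function(nm) {
      paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = spec$base_composition), collapse = "")
    }, character(1))
    occupied <- stats::setNames(
      rep(list(IRanges::IRanges()), spec$n_chroms), nms)
    feats <- list()
    tel <- spec$telomere_window
    tel_side <- 0L
    for (plant in spec$plants) {
      for (i in seq_len(plant$count)) {
        gap <- if (plant$kind == "double_motif") {
          sample(seq(plant$gap_range[1], plant$gap_range[2]), 1L)
        } else NULL
        flen <- plant_length(plant, gap)
        payload <- switch(plant$kind,
          motif = plant$motif,
          double_motif = paste0(plant$motif,
            paste0(sample(c("A", "C", "G", "T"), gap, replace = TRUE,
                          prob = spec$base_composition), collapse = ""),
            plant$motif),
          cpg_island = build_island_seq(plant$length, plant$density,
                                        spec$base_composition))
        if (!is.null(plant$positions)) {
          chrom <- nms[1]
          start <- as.integer(plant$positions[i])
          if (is.na(start) || start < 1L || start + flen - 1L > len) {
            abort(sprintf("Explicit position %d for %s is out of bounds.",
                          start, plant$kind))
          }
          cand <- IRanges::IRanges(start, start + flen - 1L)
          if (sum(IRanges::countOverlaps(cand, occupied[[chrom]])) > 0) {
            abort(sprintf(
              "Explicit %s position %d collides with an earlier feature.",
              plant$kind, start))
          }
        } else {
          placed <- FALSE
          for (try in seq_len(1000L)) {
            chrom <- nms[sample.int(spec$n_chroms, 1L)]
            start <- switch(plant$placement,
              uniform = sample.int(len - flen + 1L, 1L),
              telomeric = {
                side <- tel_side %% 2L
                lo <- if (side == 0L) 1L else len - tel + 1L
                hi <- if (side == 0L) tel - flen + 1L else len - flen + 1L
                if (hi < lo) abort("telomere_window too small for feature.")
                sample(seq(lo, hi), 1L)
              },
              interior = {
                lo <- tel + 1L
                hi <- len - tel - flen + 1L
                if (hi < lo) abort("Chromosome too small for interior feature.")
                sample(seq(lo, hi), 1L)
              })
            cand <- IRanges::IRanges(start, start + flen - 1L)
            if (sum(IRanges::countOverlaps(cand, occupied[[chrom]])) == 0) {
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            abort(sprintf(
              "Could not place %s feature %d ('%s') without overlap after 1000 tries.",
              plant$placement, i, plant$kind))
          }
          if (plant$placement == "telomeric") tel_side <- tel_side + 1L
        }
        occupied[[chrom]] <- c(occupied[[chrom]], cand)
        substr(seqs[[chrom]], start, start + flen - 1L) <- payload
        feats[[length(feats) + 1L]] <- tibble(
          chrom = chrom, start = start, end = start + flen - 1L,
          kind = plant$kind, payload = payload)
      }
    }
    features <- if (length(feats)) {
      dplyr::arrange(dplyr::bind_rows(feats), chrom, start)
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             kind = character(), payload = character())
    }
    list(genome = new_genome(seqs), features = features)
  })
}

#' Write a planted-feature truth table as BED6+1
#'
#' Coordinates are converted to BED's 0-based half-open convention; the
#' `name` column holds the feature kind and a seventh column the planted
#' sequence payload.
#'
#' @param features the `features` tibble from [generate_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(features, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s",
                   features$chrom, features$start - 1L, features$end,
                   features$kind, features$payload)
  writeLines(lines, path)
  invisible(path)
}
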