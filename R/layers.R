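#' Layer sets
#'
#' A `gl_layerset` couples an immutable [gl_genome] with any number of named
#' binary state layers.  Each layer is a per-chromosome set of sorted,
#' merged, non-adjacent intervals (1-based, inclusive): a base is either in
#' the layer ("present") or not.  The object also carries a hit cache for
#' cacheable binding factors and a history table of per-cycle layer
#' statistics.
#'
#' @name gl_layerset
NULL

empty_layer <- function(genome) {
  stats::setNames(rep(list(IRanges::IRanges()), length(chrom_names(genome))),
                  chrom_names(genome))
}

normalize_ranges <- function(ir) IRanges::reduce(ir, min.gapwidth = 1L)

check_intervals <- function(genome, chrom, start, end, what = "interval") {
  lens <- chrom_lengths(genome)
  bad_chrom <- !chrom %in% names(lens)
  if (any(bad_chrom)) {
    abort(paste0("Unknown chromosome in ", what, ": ",
                 paste(unique(chrom[bad_chrom]), collapse = ", ")))
  }
  ok <- start >= 1L & end >= start & end <= lens[chrom]
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf("Out-of-bounds %s: %s:[%d,%d] (1-based, chromosome length %d).",
                  what, chrom[i], start[i], end[i], lens[[chrom[i]]]))
  }
  invisible(TRUE)
}

ranges_from_tbl <- function(genome, tbl, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(tbl)))
  check_intervals(genome, tbl$chrom, tbl$start, tbl$end, what)
  out <- empty_layer(genome)
  for (ch in unique(tbl$chrom)) {
    rows <- tbl$chrom == ch
    out[[ch]] <- normalize_ranges(
      IRanges::IRanges(tbl$start[rows], tbl$end[rows]))
  }
  out
}

empty_history <- function() {
  tibble(cycle = integer(), layer = character(),
         n_ranges = integer(), covered_bp = integer())
}

#' Create a layer set
#'
#' @param genome a [gl_genome].
#' @param layers character vector of (unique) layer names.
#' @param initial optional named list of initial intervals per layer, each a
#'   data frame with `chrom`, `start`, `end` (1-based inclusive).  Initial
#'   intervals are normalized (sorted, overlapping/adjacent runs merged).
#' @return a `gl_layerset` with empty history and hit cache.
#' @export
layer_set <- function(genome, layers, initial = NULL) {
  stopifnot(inherits(genome, "gl_genome"))
  if (!is.character(layers) || length(layers) == 0L ||
      anyDuplicated(layers) || any(!nzchar(layers))) {
    abort("`layers` must be unique, non-empty layer names.")
  }
  lyr <- stats::setNames(rep(list(empty_layer(genome)), length(layers)),
                         layers)
  for (nm in names(initial %||% list())) {
    if (!nm %in% layers) abort(paste0("Initial ranges for unknown layer: ", nm))
    lyr[[nm]] <- ranges_from_tbl(genome, as_tibble(initial[[nm]]),
                                 paste0("initial interval of layer '", nm, "'"))
  }
  structure(list(genome = genome, layers = lyr,
                 cache = new.env(parent = emptyenv()),
                 history = empty_history(), cycle = 0L),
            class = "gl_layerset")
}

#' @export
print.gl_layerset <- function(x, ...) {
  cat("<gl_layerset> ", length(chrom_names(x$genome)), " chromosome(s), ",
      length(x$layers), " layer(s), cycle ", x$cycle, "\n", sep = "")
  for (nm in names(x$layers)) {
    cat(sprintf("  %s: %d range(s), %s bp\n", nm,
                layer_n_ranges(x, nm),
                format(covered_bp(x, nm), big.mark = ",")))
  }
  invisible(x)
}

check_layer <- function(x, layer) {
  if (!layer %in% names(x$layers)) {
    abort(paste0("Unknown layer: '", layer, "'. Layers: ",
                 paste(names(x$layers), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Set a layer's state over intervals
#'
#' Marks intervals present (union) or absent (subtraction) in one layer;
#' the result is always kept normalized and the genome is never touched.
#' Vectorised over `chrom`, `start`, `end`.
#'
#' @param x a [gl_layerset].
#' @param layer layer name.
#' @param chrom,start,end interval(s), 1-based inclusive.
#' @param state `"present"` or `"absent"`.
#' @return the modified `gl_layerset`.
#' @export
set_state <- function(x, layer, chrom, start, end,
                      state = c("present", "absent")) {
  state <- match.arg(state)
  check_layer(x, layer)
  check_intervals(x$genome, chrom, start, end)
  for (ch in unique(chrom)) {
    rows <- chrom == ch
    ir <- IRanges::IRanges(start[rows], end[rows])
    cur <- x$layers[[layer]][[ch]]
    x$layers[[layer]][[ch]] <- if (state == "present") {
      normalize_ranges(c(cur, ir))
    } else {
      IRanges::setdiff(cur, IRanges::reduce(ir))
    }
  }
  x
}

#' @rdname covered_bp
#' @export
layer_n_ranges <- function(x, layer) {
  check_layer(x, layer)
  sum(vapply(x$layers[[layer]], length, integer(1)))
}

#' Bases covered by a layer
#'
#' @param x a [gl_layerset].
#' @param layer layer name.
#' @return `covered_bp()`: total interval width in bp; `layer_n_ranges()`:
#'   number of (merged) intervals; `layer_tbl()`: the intervals as a tibble.
#' @export
covered_bp <- function(x, layer) {
  check_layer(x, layer)
  sum(vapply(x$layers[[layer]], function(ir) sum(IRanges::width(ir)),
             numeric(1)))
}

#' @rdname covered_bp
#' @export
layer_tbl <- function(x, layer) {
  check_layer(x, layer)
  ranges_tbl(x$layers[[layer]])
}

ranges_tbl <- function(rl) {
  parts <- lapply(names(rl), function(ch) {
    ir <- rl[[ch]]
    tibble(chrom = rep(ch, length(ir)),
           start = IRanges::start(ir), end = IRanges::end(ir))
  })
  dplyr::bind_rows(parts) %s|%
    tibble(chrom = character(), start = integer(), end = integer())
}

# ---- BED -------------------------------------------------------------------

#' Read intervals from a BED file
#'
#' Only the first three columns are used.  BED's 0-based half-open
#' coordinates are converted to the package's 1-based inclusive convention.
#' Malformed lines raise an error naming the line number; when a genome is
#' given, intervals are validated against its chromosome bounds.
#'
#' @param path BED file path.
#' @param genome optional [gl_genome] for bounds validation.
#' @return a tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  out <- tibble(chrom = character(), start = integer(), end = integer())
  if (any(keep)) {
    idx <- which(keep)
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    for (k in seq_along(fields)) {
      f <- fields[[k]]
      if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2]))) ||
          is.na(suppressWarnings(as.integer(f[3])))) {
        abort(sprintf("Malformed BED line %d in %s.", idx[k], path))
      }
    }
    out <- tibble(
      chrom = vapply(fields, `[`, character(1), 1L),
      start = vapply(fields, function(f) as.integer(f[2]), integer(1)) + 1L,
      end = vapply(fields, function(f) as.integer(f[3]), integer(1)))
    bad <- out$start > out$end
    if (any(bad)) {
      abort(sprintf("Empty or inverted BED interval at line %d in %s.",
                    idx[which(bad)[1]], path))
    }
    if (!is.null(genome)) check_intervals(genome, out$chrom, out$start, out$end)
  }
  out
}

#' Write one layer (or an interval tibble) as BED3
#'
#' @param x a [gl_layerset] or a tibble with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param layer layer name (ignored when `x` is a tibble).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, layer = NULL, path) {
  tbl <- if (inherits(x, "gl_layerset")) layer_tbl(x, layer) else as_tibble(x)
  writeLines(sprintf("%s\t%d\t%d", tbl$chrom, tbl$start - 1L, tbl$end), path)
  invisible(path)
}

# ---- snapshots -------------------------------------------------------------

safe_file_name <- function(nm) gsub("[^A-Za-z0-9._-]", "_", nm)

#' Persist and restore layer-set snapshots
#'
#' A snapshot is a directory holding one BED file per layer, a JSON manifest
#' (genome chromosome names and lengths, cycle index, layer-to-file map) and
#' the history table as TSV.  Restoring validates the manifest's genome
#' identifiers against the genome supplied at restore time.
#'
#' @param x a [gl_layerset].
#' @param dir snapshot directory (created if needed).
#' @return `snapshot_layers()`: `dir`, invisibly; `restore_layers()`: a
#'   `gl_layerset` equivalent to the snapshotted one.
#' @export
snapshot_layers <- function(x, dir) {
  stopifnot(inherits(x, "gl_layerset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- stats::setNames(
    paste0("layer_", safe_file_name(names(x$layers)), ".bed"),
    names(x$layers))
  if (anyDuplicated(files)) {
    files[] <- paste0("layer_", seq_along(files), ".bed")
  }
  for (nm in names(x$layers)) {
    write_bed(x, nm, file.path(dir, files[[nm]]))
  }
  manifest <- list(
    format = "layersim-snapshot-1",
    cycle = x$cycle,
    genome = list(chrom = chrom_names(x$genome),
                  length = unname(chrom_lengths(x$genome))),
    layers = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.table(x$history, file.path(dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname snapshot_layers
#' @param genome the [gl_genome] to restore against; chromosome names and
#'   lengths must match the manifest.
#' @export
restore_layers <- function(dir, genome) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort(paste0("No snapshot manifest in ", dir))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(as.character(manifest$genome$chrom), chrom_names(genome)) ||
      !identical(as.integer(manifest$genome$length),
                 as.integer(unname(chrom_lengths(genome))))) {
    abort("Snapshot genome (chromosome names/lengths) does not match `genome`.")
  }
  layer_files <- manifest$layers
  x <- layer_set(genome, names(layer_files))
  for (nm in names(layer_files)) {
    tbl <- read_bed(file.path(dir, layer_files[[nm]]), genome)
    if (nrow(tbl)) {
      x <- set_state(x, nm, tbl$chrom, tbl$start, tbl$end, "present")
    }
  }
  hpath <- file.path(dir, "history.tsv")
  if (file.exists(hpath)) {
    h <- utils::read.delim(hpath, sep = "\t", stringsAsFactors = FALSE)
    if (nrow(h)) x$history <- as_tibble(h)
  }
  x$cycle <- as.integer(manifest$cycle)
  x
}

# ---- coverage --------------------------------------------------------------

#' Sum per-base coverage across replicate interval sets
#'
#' Counts, for every base of the genome, how many of the input interval sets
#' contain it — the per-base replicate coverage used to aggregate repeated
#' simulations into a single track.
#'
#' @param rangesets a list where each element is one replicate's intervals
#'   for a layer: either a tibble (`chrom`, `start`, `end`) or the
#'   per-chromosome range list from a `gl_layerset` (`x$layers[[layer]]`).
#' @param genome the [gl_genome] the intervals live on.
#' @return a `gl_coverage` object (per-chromosome run-length encoded
#'   counts).
#' @export
sum_coverage <- function(rangesets, genome) {
  if (!is.list(rangesets) || length(rangesets) == 0L) {
    abort("`rangesets` must be a non-empty list of interval sets.")
  }
  lens <- chrom_lengths(genome)
  as_rl <- function(rs) {
    if (is.data.frame(rs)) ranges_from_tbl(genome, as_tibble(rs)) else rs
  }
  rls <- lapply(rangesets, as_rl)
  runs <- lapply(names(lens), function(ch) {
    covs <- lapply(rls, function(rl) {
      ir <- rl[[ch]] %||% IRanges::IRanges()
      if (length(ir) && max(IRanges::end(ir)) > lens[[ch]]) {
        abort(paste0("Interval beyond end of ", ch, " in sum_coverage()."))
      }
      IRanges::coverage(ir, width = lens[[ch]])
    })
    Reduce(`+`, covs)
  })
  structure(list(runs = stats::setNames(runs, names(lens)),
                 n_inputs = length(rls)),
            class = "gl_coverage")
}

#' @export
print.gl_coverage <- function(x, ...) {
  cat("<gl_coverage> over", length(x$runs), "chromosome(s), summed from",
      x$n_inputs, "input set(s)\n")
  invisible(x)
}

#' Coverage track as a tibble of constant-count runs
#'
#' @param track a `gl_coverage` from [sum_coverage()].
#' @param drop_zero drop zero-count runs?
#' @return tibble with `chrom`, `start`, `end` (1-based inclusive), `count`.
#' @export
coverage_tbl <- function(track, drop_zero = FALSE) {
  parts <- lapply(names(track$runs), function(ch) {
    r <- track$runs[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    tb <- tibble(chrom = rep(ch, length(ends)),
                 start = c(1L, utils::head(ends, -1L) + 1L),
                 end = as.integer(ends),
                 count = as.integer(S4Vectors::runValue(r)))
    if (drop_zero) dplyr::filter(tb, .data$count > 0L) else tb
  })
  dplyr::bind_rows(parts)
}

#' Write a coverage track as bedGraph
#'
#' Zero-count runs are omitted; adjacent equal-count runs are merged (the
#' run-length encoding guarantees this).  Coordinates follow bedGraph's
#' 0-based half-open convention.
#'
#' @param track a `gl_coverage`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  tb <- coverage_tbl(track, drop_zero = TRUE)
  writeLines(sprintf("%s\t%d\t%d\t%d", tb$chrom, tb$start - 1L, tb$end,
                     tb$count), path)
  invisible(path)
}

#' Read a bedGraph file back into a coverage track
#'
#' @param path bedGraph path.
#' @param genome [gl_genome] providing chromosome lengths (bases not listed
#'   in the file get count 0).
#' @return a `gl_coverage`.
#' @export
read_bedgraph <- function(path, genome) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lens <- chrom_lengths(genome)
  vals <- stats::setNames(lapply(lens, function(l) numeric(l)), names(lens))
  for (k in which(keep)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) abort(sprintf("Malformed bedGraph line %d.", k))
    ch <- f[1]
    if (!ch %in% names(vals)) abort(paste0("Unknown chromosome: ", ch))
    vals[[ch]][(as.integer(f[2]) + 1L):as.integer(f[3])] <- as.numeric(f[4])
  }
  structure(list(runs = lapply(vals, function(v) S4Vectors::Rle(as.integer(v))),
                 n_inputs = NA_integer_),
            class = "gl_coverage")
}
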