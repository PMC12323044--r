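#' Proportion of TSS covered by state layers over simulation snapshots
#'
#' For every snapshot cycle, gene list and state layer, computes the
#' proportion of transcription start sites whose (single-base) position
#' lies within the state layer.  Genes not assigned to any provided list
#' are pooled into an automatic "all other genes" list.
#'
#' @param snapshots a `gl_sim` result (its in-memory snapshots are used), a
#'   [gl_layerset] (one row set at its current cycle) or a named list
#'   mapping cycle numbers to per-layer interval lists.
#' @param tss tibble with `chrom`, `pos` (1-based TSS base) and `gene_id`;
#'   [read_tss_bed()] builds one from a BED file.
#' @param gene_lists optional tibble with `gene_id`, `list_name`; ids
#'   absent from `tss` are dropped with a warning.
#' @param states character vector of layer names to evaluate.
#' @param window half-width in bp by which to widen each TSS symmetrically
#'   (0 keeps the 1-bp point convention).
#' @param other_name name for the automatic remainder list.
#' @return tibble with `cycle`, `gene_list`, `state`, `proportion`, `n_tss`.
#' @export
tss_state_proportions <- function(snapshots, tss, gene_lists = NULL,
                                  states, window = 0L,
                                  other_name = "all_other") {
  if (inherits(snapshots, "gl_sim")) {
    snaps <- snapshots$snapshots
  } else if (inherits(snapshots, "gl_layerset")) {
    snaps <- stats::setNames(list(snapshots$layers[states]),
                             as.character(snapshots$cycle))
    snaps[[1]] <- snapshots$layers
  } else {
    snaps <- snapshots
  }
  tss <- as_tibble(tss)
  if (nrow(tss) == 0L) abort("Empty TSS table.")
  stopifnot(all(c("chrom", "pos", "gene_id") %in% names(tss)))
  lists <- list()
  if (!is.null(gene_lists) && nrow(gene_lists)) {
    gene_lists <- as_tibble(gene_lists)
    missing <- setdiff(gene_lists$gene_id, tss$gene_id)
    if (length(missing)) {
      warn(sprintf("%d gene id(s) in lists are absent from the TSS table and were dropped.",
                   length(missing)))
      gene_lists <- gene_lists[gene_lists$gene_id %in% tss$gene_id, ]
    }
    lists <- split(gene_lists$gene_id, gene_lists$list_name)
  }
  assigned <- unique(unlist(lists, use.names = FALSE))
  others <- setdiff(tss$gene_id, assigned)
  if (length(others)) lists[[other_name]] <- others
  rows <- list()
  for (cyc in names(snaps)) {
    layers <- snaps[[cyc]]
    for (state in states) {
      rl <- layers[[state]]
      if (is.null(rl)) abort(paste0("Snapshot has no layer '", state, "'."))
      covered <- vapply(seq_len(nrow(tss)), function(i) {
        ir <- IRanges::IRanges(tss$pos[i] - window, tss$pos[i] + window)
        lyr <- rl[[tss$chrom[i]]]
        !is.null(lyr) && sum(IRanges::countOverlaps(ir, lyr)) > 0L
      }, logical(1))
      for (ln in names(lists)) {
        sel <- tss$gene_id %in% lists[[ln]]
        rows[[length(rows) + 1L]] <- tibble(
          cycle = as.integer(cyc), gene_list = ln, state = state,
          proportion = mean(covered[sel]), n_tss = sum(sel))
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$cycle, .data$gene_list,
                 .data$state)
}

#' Fraction of the genome in a state
#'
#' @param x a [gl_layerset] (or a `gl_sim`, whose final state is used).
#' @param layer layer name.
#' @return covered bp divided by total genome bp.
#' @export
genome_fraction_in_state <- function(x, layer) {
  if (inherits(x, "gl_sim")) x <- x$layerset
  stopifnot(inherits(x, "gl_layerset"))
  covered_bp(x, layer) / sum(chrom_lengths(x$genome))
}

#' Read 1-bp TSS sites from a BED file
#'
#' Each record's start base becomes the TSS position; the BED name column
#' (4th) supplies `gene_id` when present.
#'
#' @param path BED path.
#' @param genome optional [gl_genome] for bounds validation.
#' @return tibble with `chrom`, `pos`, `gene_id`.
#' @export
read_tss_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("TSS BED not found: ", path))
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) abort(paste0("Empty TSS BED: ", path))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  out <- tibble(
    chrom = vapply(fields, `[`, character(1), 1L),
    pos = vapply(fields, function(f) as.integer(f[2]), integer(1)) + 1L,
    gene_id = vapply(seq_along(fields), function(k) {
      f <- fields[[k]]
      if (length(f) >= 4L && nzchar(f[4])) f[4] else paste0("tss_", k)
    }, character(1)))
  if (!is.null(genome)) check_intervals(genome, out$chrom, out$pos, out$pos,
                                        "TSS")
  out
}

#' Read a two-column gene-list TSV
#'
#' @param path TSV with columns `gene_id`, `list_name` (header optional).
#' @return tibble with `gene_id`, `list_name`.
#' @export
read_gene_lists <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("Gene-list TSV needs two columns: gene_id, list_name.")
  df <- df[, 1:2]
  names(df) <- c("gene_id", "list_name")
  if (identical(tolower(df$gene_id[1]), "gene_id")) df <- df[-1, ]
  as_tibble(df)
}

#' Sum one layer's coverage across persisted replicate run directories
#'
#' @param run_dirs snapshot directories written by [run_replicates()] (or
#'   [snapshot_layers()]).
#' @param layer layer name.
#' @param genome the [gl_genome] the runs were made on.
#' @return a `gl_coverage` track.
#' @export
coverage_from_runs <- function(run_dirs, layer, genome) {
  if (length(run_dirs) == 0L) abort("No run directories given.")
  sets <- lapply(run_dirs, function(d) {
    x <- restore_layers(d, genome)
    check_layer(x, layer)
    x$layers[[layer]]
  })
  sum_coverage(sets, genome)
}
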