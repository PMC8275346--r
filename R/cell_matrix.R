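#' Cell-by-bin accessibility matrix with per-cell metadata
#'
#' The central data container: a sparse cells x bins matrix of fragment
#' counts (or, after [binarize()], presence/absence calls) together with the
#' per-cell metadata the model needs. Depths are the *raw* fragment totals of
#' each cell; they are carried as metadata because sequencing depth is treated
#' as a technical confounder of the cell, not a property of the (possibly
#' filtered, binarized) matrix.
#'
#' @param counts sparse or dense cells x bins matrix of non-negative counts.
#' @param cell_ids character barcodes, one per row.
#' @param bin_coords data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), one row per column of `counts`. May be `NULL`,
#'   in which case dummy single-chromosome coordinates are generated.
#' @param depths raw fragment count per cell; defaults to row sums of
#'   `counts`.
#' @param batch_ids factor or character batch label per cell; defaults to a
#'   single batch `"batch1"`.
#' @param promoter_ratio optional numeric per-cell promoter fraction.
#' @param labels optional per-cell ground-truth labels.
#' @return an object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_ids = NULL, bin_coords = NULL,
                        depths = NULL, batch_ids = NULL,
                        promoter_ratio = NULL, labels = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  n <- nrow(counts); p <- ncol(counts)
  if (any(counts@x < 0)) stop("count matrix has negative entries", call. = FALSE)
  cell_ids <- cell_ids %||% sprintf("cell_%06d", seq_len(n))
  stop_if_not(length(cell_ids) == n, "cell_ids length (", length(cell_ids),
              ") does not match number of rows (", n, ")")
  if (is.null(bin_coords)) {
    bin_coords <- data.frame(chrom = "chrS",
                             start = (seq_len(p) - 1L) * 500L,
                             end = seq_len(p) * 500L)
  }
  stop_if_not(nrow(bin_coords) == p, "bin_coords rows (", nrow(bin_coords),
              ") do not match number of columns (", p, ")")
  depths <- depths %||% Matrix::rowSums(counts)
  stop_if_not(length(depths) == n, "depths length does not match cell count")
  batch_ids <- batch_ids %||% rep("batch1", n)
  stop_if_not(length(batch_ids) == n, "batch_ids length does not match cell count")
  if (!is.null(promoter_ratio))
    stop_if_not(length(promoter_ratio) == n, "promoter_ratio length mismatch")
  if (!is.null(labels))
    stop_if_not(length(labels) == n, "labels length mismatch")
  structure(list(counts = counts, cell_ids = as.character(cell_ids),
                 bin_coords = bin_coords, depths = as.numeric(depths),
                 batch_ids = as.character(batch_ids),
                 promoter_ratio = promoter_ratio, labels = labels,
                 binarized = FALSE),
            class = "cell_matrix")
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d bins (%s), %d batch(es)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$binarized) "binary" else "counts",
              length(unique(x$batch_ids))))
  invisible(x)
}

#' Subset a cell_matrix by cells and/or bins
#'
#' @param x a `cell_matrix`.
#' @param cells integer or logical index over cells (rows).
#' @param bins integer or logical index over bins (columns).
#' @return the subset `cell_matrix`; depths and other per-cell metadata follow
#'   the cell index, bin coordinates follow the bin index. Depths are *not*
#'   recomputed when bins are dropped (they are raw fragment totals).
#' @export
subset_cells <- function(x, cells = NULL, bins = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  if (!is.null(cells)) {
    x$counts <- x$counts[cells, , drop = FALSE]
    x$cell_ids <- x$cell_ids[cells]
    x$depths <- x$depths[cells]
    x$batch_ids <- x$batch_ids[cells]
    if (!is.null(x$promoter_ratio)) x$promoter_ratio <- x$promoter_ratio[cells]
    if (!is.null(x$labels)) x$labels <- x$labels[cells]
  }
  if (!is.null(bins)) {
    x$counts <- x$counts[, bins, drop = FALSE]
    x$bin_coords <- x$bin_coords[bins, , drop = FALSE]
    rownames(x$bin_coords) <- NULL
  }
  x
}
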