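# Preprocessing: binarization, bin-prevalence filtering, cell QC, and the
# per-cell confounder vector (one-hot batch + standardized log depth).

#' Binarize an accessibility count matrix
#'
#' Sets every positive count to 1. Per-cell depths are *not* recomputed: the
#' raw fragment total is an experimental property of the cell and is kept as
#' the depth confounder.
#'
#' @param matrix a [cell_matrix()] with non-negative counts.
#' @return the binarized `cell_matrix` (idempotent).
#' @export
binarize <- function(matrix) {
  stopifnot(inherits(matrix, "cell_matrix"))
  if (any(matrix$counts@x < 0))
    stop("cannot binarize: matrix has negative entries", call. = FALSE)
  matrix$counts@x[matrix$counts@x > 0] <- 1
  matrix$binarized <- TRUE
  matrix
}

#' Filter bins by cell prevalence
#'
#' Keeps bin `j` iff the fraction of cells open in `j` lies in
#' `[min_cell_frac, max_cell_frac]` (boundaries inclusive: the targets are
#' bins open in *over* 90% or in *less than* 1% of cells). Removing
#' always-closed bins strips uninformative background; removing
#' almost-always-open bins strips saturated, non-discriminative signal.
#'
#' @param matrix a binarized [cell_matrix()].
#' @param min_cell_frac lower prevalence bound (default 0.01).
#' @param max_cell_frac upper prevalence bound (default 0.90).
#' @return list with `matrix` (the filtered `cell_matrix`) and `kept`
#'   (integer indices of retained bins in the input column order).
#' @export
filter_bins <- function(matrix, min_cell_frac = 0.01, max_cell_frac = 0.90) {
  stopifnot(inherits(matrix, "cell_matrix"))
  stop_if_not(isTRUE(matrix$binarized),
              "filter_bins expects a binarized matrix; call binarize() first")
  prevalence <- Matrix::colSums(matrix$counts) / nrow(matrix$counts)
  keep <- which(prevalence >= min_cell_frac & prevalence <= max_cell_frac)
  if (length(keep) == 0)
    stop("bin filter removed all bins; check thresholds", call. = FALSE)
  list(matrix = subset_cells(matrix, bins = keep), kept = keep)
}

#' Quality-control filter for cells
#'
#' Keeps cells whose promoter ratio lies in `[promoter_lo, promoter_hi]`,
#' whose `log10` fragment count lies in `[log_umi_lo, log_umi_hi]`, and whose
#' depth is at least `min_fragments` (all bounds inclusive). The promoter
#' filter is skipped with a warning when no promoter ratios are attached.
#'
#' @param matrix a [cell_matrix()].
#' @param promoter_lo,promoter_hi promoter-ratio interval (default 0.2–0.6).
#' @param log_umi_lo,log_umi_hi `log10(UMI)` interval (default 3–5).
#' @param min_fragments minimum raw fragment count (default 1000).
#' @return integer indices of retained cells.
#' @export
qc_cells <- function(matrix, promoter_lo = 0.2, promoter_hi = 0.6,
                     log_umi_lo = 3, log_umi_hi = 5, min_fragments = 1000) {
  stopifnot(inherits(matrix, "cell_matrix"))
  keep <- rep(TRUE, length(matrix$depths))
  if (is.null(matrix$promoter_ratio)) {
    warning("no promoter_ratio attached; skipping promoter-ratio filter")
  } else {
    keep <- keep & matrix$promoter_ratio >= promoter_lo &
      matrix$promoter_ratio <= promoter_hi
  }
  lu <- log10(matrix$depths)
  keep <- keep & lu >= log_umi_lo & lu <= log_umi_hi &
    matrix$depths >= min_fragments
  if (!any(keep)) stop("cell QC retained zero cells", call. = FALSE)
  which(keep)
}

#' Build the per-cell confounder table
#'
#' The confounder vector fed to the conditional decoder is the concatenation
#' of a one-hot batch embedding and the standardized natural-log depth
#' (z-scored across all retained cells with the population-SD convention, so
#' two cells give exactly -1/+1). A zero-spread depth vector yields zeros
#' rather than a division by zero.
#'
#' @param depths positive raw fragment counts.
#' @param batch_ids per-cell batch labels.
#' @param batch_levels optional fixed batch vocabulary (training-time order);
#'   unseen labels raise an error.
#' @return object of class `confounder_table` with `batch_onehot`,
#'   `depth_norm`, `combined` (cells x (n_batches + 1) matrix), the batch
#'   vocabulary and the depth-normalization statistics.
#' @export
build_confounders <- function(depths, batch_ids, batch_levels = NULL) {
  stop_if_not(all(depths > 0), "depths must be positive")
  stop_if_not(length(depths) == length(batch_ids),
              "depths and batch_ids must align")
  batch_levels <- batch_levels %||% sort(unique(as.character(batch_ids)))
  bi <- match(as.character(batch_ids), batch_levels)
  if (any(is.na(bi)))
    stop("unseen batch label(s): ",
         paste(setdiff(unique(batch_ids), batch_levels), collapse = ", "),
         call. = FALSE)
  n <- length(depths)
  onehot <- matrix(0, n, length(batch_levels),
                   dimnames = list(NULL, batch_levels))
  onehot[cbind(seq_len(n), bi)] <- 1
  ld <- log(depths)
  mu <- mean(ld)
  sd_pop <- sqrt(mean((ld - mu)^2))
  depth_norm <- if (sd_pop < 1e-12) rep(0, n) else (ld - mu) / sd_pop
  structure(list(batch_onehot = onehot, depth_norm = depth_norm,
                 combined = cbind(onehot, depth_norm = depth_norm),
                 batch_levels = batch_levels,
                 depth_log_mean = mu, depth_log_sd = sd_pop),
            class = "confounder_table")
}

#' @export
print.confounder_table <- function(x, ...) {
  cat(sprintf("confounder_table: %d cells, batches [%s] + depth_norm\n",
              nrow(x$combined), paste(x$batch_levels, collapse = ", ")))
  invisible(x)
}
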