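# Readers and writers for the matrix-market triplet layout (matrix.mtx +
# barcodes.tsv + bins as BED/TSV) and per-cell metadata tables. All writers
# emit files their paired readers round-trip losslessly.

find_first <- function(path, names) {
  for (nm in names) {
    f <- file.path(path, nm)
    if (file.exists(f)) return(f)
  }
  NULL
}

read_bins_file <- function(f) {
  first <- readLines(f, n = 1L)
  has_header <- grepl("chrom|start", first, ignore.case = TRUE)
  df <- utils::read.table(f, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  stop_if_not(ncol(df) >= 3, "bin file ", f, " needs >= 3 columns (chrom, start, end)")
  stats::setNames(df[, 1:3], c("chrom", "start", "end"))
}

#' Read a matrix-market triplet directory
#'
#' Expects `matrix.mtx` (optionally gzipped), `barcodes.tsv` and bin
#' coordinates as `bins.bed`/`peaks.bed` (or `.tsv`). Orientation
#' (cells x bins vs bins x cells) is auto-detected from the sidecar lengths;
#' a square matrix with equal-length sidecars is ambiguous and raises an
#' error. Counts are preserved; binarization is a separate explicit step.
#'
#' @param path directory containing the triplet.
#' @return a [cell_matrix()] with raw counts and depths = row sums.
#' @export
read_matrix_dir <- function(path) {
  mtx <- find_first(path, c("matrix.mtx", "matrix.mtx.gz"))
  if (is.null(mtx)) stop("no matrix.mtx(.gz) in ", path, call. = FALSE)
  bc_file <- find_first(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(bc_file)) stop("no barcodes.tsv in ", path, call. = FALSE)
  bins_file <- find_first(path, c("bins.bed", "peaks.bed", "bins.tsv", "peaks.tsv"))
  if (is.null(bins_file))
    stop("no bins.bed/peaks.bed/bins.tsv/peaks.tsv in ", path, call. = FALSE)
  m <- Matrix::readMM(mtx)
  barcodes <- readLines(bc_file)
  bins <- read_bins_file(bins_file)
  nb <- length(barcodes); np <- nrow(bins)
  if (nrow(m) == ncol(m) && nb == np && nb == nrow(m)) {
    stop("square matrix with equal sidecar lengths in ", path,
         ": orientation is ambiguous", call. = FALSE)
  } else if (nrow(m) == nb && ncol(m) == np) {
    # cells x bins as stored
  } else if (nrow(m) == np && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(paste0("dimension mismatch in %s: matrix is %d x %d but ",
                        "barcodes.tsv has %d rows and %s has %d rows"),
                 path, nrow(m), ncol(m), nb, basename(bins_file), np),
         call. = FALSE)
  }
  cell_matrix(m, cell_ids = barcodes, bin_coords = bins)
}

#' Read and attach per-cell metadata
#'
#' Reads a tab-separated table with a header; a `barcode` column is
#' required, and `depth`, `batch`, `promoter_ratio` and `label` columns are
#' attached when present. When `matrix` is supplied the table is joined to it
#' by barcode: metadata must cover every cell (missing barcodes raise an
#' error naming them), and extra metadata rows produce a warning with their
#' count.
#'
#' @param path TSV file path.
#' @param matrix optional [cell_matrix()] to join onto.
#' @return the metadata data frame, or the updated `cell_matrix` when
#'   `matrix` is given.
#' @export
read_metadata <- function(path, matrix = NULL) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  stop_if_not("barcode" %in% names(meta),
              "metadata file ", path, " has no 'barcode' column")
  if (anyDuplicated(meta$barcode))
    stop("duplicate barcodes in metadata: ",
         paste(utils::head(unique(meta$barcode[duplicated(meta$barcode)]), 5),
               collapse = ", "), call. = FALSE)
  if (is.null(matrix)) return(meta)
  stopifnot(inherits(matrix, "cell_matrix"))
  hit <- match(matrix$cell_ids, meta$barcode)
  if (anyNA(hit))
    stop("metadata missing for ", sum(is.na(hit)), " barcode(s), e.g. ",
         paste(utils::head(matrix$cell_ids[is.na(hit)], 5), collapse = ", "),
         call. = FALSE)
  extra <- nrow(meta) - length(unique(hit))
  if (extra > 0)
    warning(extra, " metadata row(s) without a matching cell in the matrix")
  meta <- meta[hit, , drop = FALSE]
  if ("depth" %in% names(meta)) matrix$depths <- as.numeric(meta$depth)
  if ("batch" %in% names(meta)) matrix$batch_ids <- as.character(meta$batch)
  if ("promoter_ratio" %in% names(meta))
    matrix$promoter_ratio <- as.numeric(meta$promoter_ratio)
  if ("label" %in% names(meta)) matrix$labels <- meta$label
  matrix
}

#' Write a cell matrix (or simulated dataset) as a matrix-market triplet
#'
#' Emits `matrix.mtx`, `barcodes.tsv`, `bins.bed` (0-based half-open
#' coordinates) and `metadata.tsv` (barcode, depth, batch, label when
#' available). For a [simulate_experiment()] result, ground truth is written
#' too: `labels.tsv` (cell, type, batch) and `bulk_profiles.tsv` (long
#' format: type, bin index of each truly accessible bin).
#'
#' @param x a [cell_matrix()] or `sim_dataset`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_matrix_dir <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cm <- if (inherits(x, "sim_dataset")) x$matrix else x
  stopifnot(inherits(cm, "cell_matrix"))
  Matrix::writeMM(cm$counts, file.path(path, "matrix.mtx"))
  writeLines(cm$cell_ids, file.path(path, "barcodes.tsv"))
  utils::write.table(cm$bin_coords, file.path(path, "bins.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  meta <- data.frame(barcode = cm$cell_ids, depth = cm$depths,
                     batch = cm$batch_ids)
  if (!is.null(cm$promoter_ratio)) meta$promoter_ratio <- cm$promoter_ratio
  if (!is.null(cm$labels)) meta$label <- cm$labels
  utils::write.table(meta, file.path(path, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (inherits(x, "sim_dataset")) {
    utils::write.table(
      data.frame(cell = cm$cell_ids, type = x$labels, batch = x$batch_ids),
      file.path(path, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(type = rep(names(x$peak_sets), lengths(x$peak_sets)),
                 bin = unlist(x$peak_sets)),
      file.path(path, "bulk_profiles.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}
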