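# Confounder-free imputation: decode each cell's latent mean with the
# confounder vector pinned to a fixed reference (mean depth, one reference
# batch), so reconstructed landscapes vary only with the invariant component.

#' Impute a denoised, confounder-free accessibility landscape
#'
#' Every cell is encoded to its latent mean and decoded with the confounders
#' fixed: depth at the dataset mean (which is `depth_norm = 0` on the
#' z-scored scale the decoder was trained on) and a single reference batch
#' for all cells. The default reference batch is the one with the highest
#' median per-cell fragment count — a reproducible proxy for the
#' highest-quality batch — recorded in the model at training time.
#'
#' @param model a trained `invae_model`.
#' @param matrix a [cell_matrix()] preprocessed with the model's bin map.
#' @param fixed_batch reference batch name; default the model's `best_batch`.
#'   Must belong to the model's batch vocabulary.
#' @param fixed_depth_norm value of the standardized log-depth confounder
#'   (default 0 = mean depth).
#' @param chunk cells per decoding chunk.
#' @return dense cells x bins matrix of probabilities in (0, 1), with cell
#'   ids as row names.
#' @export
impute <- function(model, matrix, fixed_batch = NULL, fixed_depth_norm = 0,
                   chunk = 1024L) {
  stopifnot(inherits(model, "invae_model"))
  fixed_batch <- fixed_batch %||% model$best_batch
  bi <- match(fixed_batch, model$batch_levels)
  if (is.na(bi))
    stop("fixed batch '", fixed_batch, "' is not in the model vocabulary [",
         paste(model$batch_levels, collapse = ", "), "]", call. = FALSE)
  z <- encode(model, matrix, chunk = chunk)$mean
  onehot <- rep(0, length(model$batch_levels)); onehot[bi] <- 1
  cvec <- c(onehot, fixed_depth_norm)
  n <- nrow(z)
  out <- matrix(0, n, model$params$n_input)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    C <- matrix(cvec, length(idx), length(cvec), byrow = TRUE)
    out[idx, ] <- decode(model, z[idx, , drop = FALSE], C)
  }
  rownames(out) <- rownames(z)
  out
}

#' Threshold an imputed probability matrix to binary calls
#'
#' @param imputed probability matrix from [impute()].
#' @param threshold call a bin open when probability >= `threshold`
#'   (default 0.5).
#' @return binary matrix of the same shape.
#' @export
binarize_imputed <- function(imputed, threshold = 0.5) {
  (imputed >= threshold) * 1
}
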