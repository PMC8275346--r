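# Synthetic scATAC-seq generator: log-normal per-cell fragment counts, reads
# split between a cell type's peak set and genomic background at a
# signal-to-noise ratio rho, multiple batches with batch-specific mu/rho,
# optional rare cell types, and ground-truth bulk profiles.

#' Simulation configuration
#'
#' Describes a multi-batch simulated scATAC-seq experiment. Each batch has its
#' own log-normal depth law (`mu`, `sigma`), signal-to-noise ratio `rho` and
#' cell-type composition; all batches share one genome (bin universe) and one
#' set of per-type peak archetypes.
#'
#' The depth law is parameterized in log space:
#' `log(count) ~ Normal(ln mu, (ln sigma)^2)`, so `mu` is the median fragment
#' count and `sigma` is a multiplicative spread factor (must exceed 1).
#'
#' @param n_cells_per_type integer vector, cells per type (single-batch form);
#'   ignored when `batches` is supplied.
#' @param n_bins total number of genomic bins.
#' @param peaks_per_type number of peak bins per cell type.
#' @param peak_overlap_fraction fraction in \[0,1\] of each type's peaks drawn
#'   from a common shared set (housekeeping-like accessibility).
#' @param mu,sigma,rho single-batch depth/noise parameters (`mu` > 0 median
#'   fragments, `sigma` > 1 spread, `rho` in (0,1\] the expected fraction of a
#'   cell's fragments landing in its own peak set).
#' @param batches optional list of per-batch lists with elements
#'   `n_cells_per_type` (length = number of types; zeros mark types absent
#'   from the batch), `mu`, `sigma`, `rho`.
#' @param type_names optional character names for the cell types.
#' @param seed master seed driving every random sub-stream.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_type = NULL, n_bins, peaks_per_type,
                       peak_overlap_fraction = 0.2, mu = NULL, sigma = NULL,
                       rho = NULL, batches = NULL, type_names = NULL,
                       seed = 1L) {
  if (is.null(batches)) {
    stop_if_not(!is.null(n_cells_per_type) && !is.null(mu) &&
                  !is.null(sigma) && !is.null(rho),
                "either `batches` or (n_cells_per_type, mu, sigma, rho) required")
    batches <- list(list(n_cells_per_type = n_cells_per_type,
                         mu = mu, sigma = sigma, rho = rho))
  }
  n_types <- length(batches[[1]]$n_cells_per_type)
  for (b in batches) {
    stop_if_not(length(b$n_cells_per_type) == n_types,
                "all batches must list cell counts for the same types")
    stop_if_not(is_scalar_number(b$mu) && b$mu > 0, "mu must be > 0")
    stop_if_not(is_scalar_number(b$sigma) && b$sigma > 1,
                "sigma must be > 1 (multiplicative log-normal spread)")
    stop_if_not(is_scalar_number(b$rho) && b$rho > 0 && b$rho <= 1,
                "rho must lie in (0, 1]")
    stop_if_not(all(b$n_cells_per_type >= 0) && sum(b$n_cells_per_type) > 0,
                "per-batch cell counts must be non-negative with a positive sum")
  }
  stop_if_not(peak_overlap_fraction >= 0 && peak_overlap_fraction <= 1,
              "peak_overlap_fraction must lie in [0, 1]")
  stop_if_not(n_bins >= peaks_per_type, "n_bins must be >= peaks_per_type")
  type_names <- type_names %||% sprintf("type%d", seq_len(n_types))
  stop_if_not(length(type_names) == n_types, "type_names length mismatch")
  structure(list(n_bins = as.integer(n_bins),
                 peaks_per_type = as.integer(peaks_per_type),
                 peak_overlap_fraction = peak_overlap_fraction,
                 batches = batches, type_names = type_names,
                 n_types = n_types, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw per-type peak archetypes
#'
#' Places `peaks_per_type` peak bins for each cell type: a fraction
#' `peak_overlap_fraction` is taken from one shared pool common to all types,
#' the rest are type-exclusive. Exclusive peaks never collide across types,
#' so rare types are separable in principle.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to a sub-stream of `config$seed`).
#' @return named list of sorted integer bin-index vectors, one per type, with
#'   attribute `shared` holding the shared peak bins.
#' @export
make_archetypes <- function(config, seed = child_seed(config$seed, 1L)) {
  P <- config$peaks_per_type
  n_shared <- as.integer(round(config$peak_overlap_fraction * P))
  n_excl <- P - n_shared
  need <- n_shared + config$n_types * n_excl
  if (need > config$n_bins)
    stop(sprintf(paste0("infeasible archetypes: %d shared + %d types x %d ",
                        "exclusive peaks need %d bins but only %d available"),
                 n_shared, config$n_types, n_excl, need, config$n_bins),
         call. = FALSE)
  with_seed(seed, {
    pool <- sample.int(config$n_bins, need)
    shared <- if (n_shared > 0) pool[seq_len(n_shared)] else integer(0)
    rest <- pool[-seq_len(n_shared)]
    if (n_shared == 0) rest <- pool
    sets <- vector("list", config$n_types)
    for (t in seq_len(config$n_types)) {
      excl <- rest[seq.int((t - 1L) * n_excl + 1L, length.out = n_excl)]
      sets[[t]] <- sort(c(shared, excl))
    }
    names(sets) <- config$type_names
    attr(sets, "shared") <- sort(shared)
    sets
  })
}

#' Sample per-cell fragment counts from a log-normal law
#'
#' `log(count) ~ Normal(ln mu, (ln sigma)^2)`, rounded to the nearest integer
#' with a floor of 1, so `mu` is the median fragment count per cell.
#'
#' @param mu median fragment count (> 0).
#' @param sigma multiplicative spread (> 1).
#' @param n number of cells.
#' @param seed integer seed.
#' @return integer vector of `n` positive fragment counts.
#' @export
sample_cell_depths <- function(mu, sigma, n, seed = 1L) {
  stop_if_not(is_scalar_number(mu) && mu > 0, "mu must be > 0")
  stop_if_not(is_scalar_number(sigma) && sigma > 1,
              "sigma must be > 1 (degenerate or invalid spread)")
  stop_if_not(n >= 1, "n must be >= 1")
  with_seed(seed, {
    pmax(1L, as.integer(round(exp(stats::rnorm(n, log(mu), log(sigma))))))
  })
}

# Map uniform draws over the background (all bins minus an excluded sorted
# peak set) back to absolute bin indices.
sample_background_bins <- function(n_draw, n_bins, excluded_sorted) {
  if (n_draw == 0L) return(integer(0))
  u <- sample.int(n_bins - length(excluded_sorted), n_draw, replace = TRUE)
  v <- u
  repeat {
    v2 <- u + findInterval(v, excluded_sorted)
    if (all(v2 == v)) break
    v <- v2
  }
  v
}

#' Place reads for each cell into peak and background bins
#'
#' Each of a cell's fragments independently lands in a uniformly chosen bin of
#' its type's peak set with probability `rho`, otherwise in a uniformly chosen
#' background bin (any bin outside the cell's own peak set, including other
#' types' peaks, which creates realistic cross-type noise). Sampling is with
#' replacement, so a bin can collect several fragments; row sums of the
#' returned count matrix equal the supplied depths exactly.
#'
#' @param peak_sets named list of per-type peak bin indices.
#' @param depths fragment count per cell.
#' @param rho signal-to-noise ratio in (0, 1].
#' @param n_bins total bins.
#' @param labels per-cell type label (name or index into `peak_sets`).
#' @param seed integer seed.
#' @return sparse cells x bins count matrix (`dgCMatrix`).
#' @export
simulate_cells <- function(peak_sets, depths, rho, n_bins, labels, seed = 1L) {
  stop_if_not(length(depths) == length(labels),
              "one depth and one label per cell required")
  idx <- if (is.numeric(labels)) as.integer(labels)
         else match(as.character(labels), names(peak_sets))
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(peak_sets)))
    stop("label without a matching peak set", call. = FALSE)
  n_cells <- length(depths)
  with_seed(seed, {
    ii <- vector("list", n_cells); jj <- vector("list", n_cells)
    xx <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      ps <- peak_sets[[idx[i]]]
      d <- depths[i]
      n_peak <- stats::rbinom(1L, d, rho)
      bins <- c(if (n_peak > 0) ps[sample.int(length(ps), n_peak, replace = TRUE)],
                sample_background_bins(d - n_peak, n_bins, ps))
      tab <- tabulate(bins, nbins = n_bins)
      nz <- which(tab > 0L)
      ii[[i]] <- rep.int(i, length(nz)); jj[[i]] <- nz; xx[[i]] <- tab[nz]
    }
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = c(n_cells, n_bins))
  })
}

#' Run a full multi-batch simulation
#'
#' Concatenates per-batch simulations over one shared genome and archetype
#' set, and returns the count matrix together with complete ground truth.
#'
#' @param config a [sim_config()], e.g. from [sim_preset()].
#' @return an object of class `sim_dataset`: a list with elements `matrix`
#'   (a [cell_matrix()] of raw counts), `labels`, `batch_ids`, `depths`,
#'   `bulk_profiles` (types x bins binary sparse matrix; entry 1 iff the bin
#'   belongs to that type's peak set), `peak_sets` and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  peak_sets <- make_archetypes(config)
  mats <- list(); labels <- character(0); batch_ids <- character(0)
  depths <- numeric(0)
  for (b in seq_along(config$batches)) {
    bb <- config$batches[[b]]
    npt <- bb$n_cells_per_type
    lab_b <- rep(config$type_names, times = npt)
    dep_b <- sample_cell_depths(bb$mu, bb$sigma, length(lab_b),
                                seed = child_seed(config$seed, 10L + b))
    mats[[b]] <- simulate_cells(peak_sets, dep_b, bb$rho, config$n_bins,
                                lab_b, seed = child_seed(config$seed, 100L + b))
    labels <- c(labels, lab_b)
    batch_ids <- c(batch_ids, rep(sprintf("batch%d", b), length(lab_b)))
    depths <- c(depths, dep_b)
  }
  counts <- do.call(rbind, mats)
  cell_ids <- sprintf("%s_cell%05d", batch_ids, seq_along(labels))
  cm <- cell_matrix(counts, cell_ids = cell_ids, depths = depths,
                    batch_ids = batch_ids, labels = labels)
  bulk <- Matrix::sparseMatrix(
    i = rep(seq_along(peak_sets), lengths(peak_sets)),
    j = unlist(peak_sets), x = 1,
    dims = c(config$n_types, config$n_bins))
  rownames(bulk) <- config$type_names
  structure(list(matrix = cm, labels = labels, batch_ids = batch_ids,
                 depths = depths, bulk_profiles = bulk,
                 peak_sets = peak_sets, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d cells x %d bins, %d type(s), %d batch(es)\n",
              length(x$labels), x$config$n_bins, x$config$n_types,
              length(x$config$batches)))
  invisible(x)
}

#' Preset simulation scenarios
#'
#' Three study designs: `sim1`, a deeply sequenced single sample (5 cell
#' types, `mu = 5000`, `sigma = 1.5`, `rho = 0.4`, one rare type at 1% of the
#' population); `sim2`, a shallowly sequenced single sample with nine cell
#' types (`mu = 3000`, `sigma = 1.5`, `rho = 0.4`); and `sim3`, a two-batch
#' design with mismatched rare types (batch 1: `mu = 2500`, `rho = 0.4`;
#' batch 2: `mu = 5000`, `rho = 0.5`; four shared major types plus one
#' batch-exclusive rare type per batch at 2% of its batch).
#'
#' Peak-set geometry is derived from the depth parameters: each type receives
#' `round(mean(rho * mu) / 1.5)` peak bins (a median in-peak read rate of 1.5
#' per peak bin, i.e. ~78% per-cell peak detection — the dropout regime), and
#' the background is sized to `mean((1 - rho) * mu) / 0.005` bins (background
#' read rate 0.005 per bin, so the 1% prevalence filter removes most pure
#' background, as it does at full scale).
#'
#' For desk-scale runs, `cells` shrinks the population and `genome_scale`
#' shrinks the genome *and* the per-cell depth by the same factor, which keeps
#' all per-bin read rates — and therefore sparsity, filter behaviour and
#' overlap statistics — at their full-scale values.
#'
#' @param name `"sim1"`, `"sim2"` or `"sim3"`.
#' @param cells total number of cells (default: the full-scale 10000).
#' @param genome_scale joint scale factor on genome size and depth (default 1).
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("sim1", "sim2", "sim3"), cells = 10000L,
                       genome_scale = 1, seed = 1L) {
  name <- match.arg(name)
  stop_if_not(genome_scale > 0 && genome_scale <= 1,
              "genome_scale must lie in (0, 1]")
  if (name == "sim1") {
    n_rare <- max(10L, round(0.01 * cells))
    n_major <- floor((cells - n_rare) / 4)
    batches <- list(list(
      n_cells_per_type = c(rep(n_major, 4L), n_rare),
      mu = 5000 * genome_scale, sigma = 1.5, rho = 0.4))
    type_names <- c(sprintf("type%d", 1:4), "rare1")
  } else if (name == "sim2") {
    n_each <- floor(cells / 9)
    npt <- rep(n_each, 9L); npt[1] <- npt[1] + cells - sum(npt)
    batches <- list(list(n_cells_per_type = npt,
                         mu = 3000 * genome_scale, sigma = 1.5, rho = 0.4))
    type_names <- sprintf("type%d", 1:9)
  } else {
    per_batch <- floor(cells / 2)
    n_rare <- max(10L, round(0.02 * per_batch))
    n_major <- floor((per_batch - n_rare) / 4)
    batches <- list(
      list(n_cells_per_type = c(rep(n_major, 4L), n_rare, 0L),
           mu = 2500 * genome_scale, sigma = 1.5, rho = 0.4),
      list(n_cells_per_type = c(rep(n_major, 4L), 0L, n_rare),
           mu = 5000 * genome_scale, sigma = 1.5, rho = 0.5))
    type_names <- c(sprintf("type%d", 1:4), "rareA", "rareB")
  }
  w <- vapply(batches, function(b) sum(b$n_cells_per_type), numeric(1))
  w <- w / sum(w)
  mean_signal <- sum(w * vapply(batches, function(b) b$rho * b$mu, numeric(1)))
  mean_bg <- sum(w * vapply(batches, function(b) (1 - b$rho) * b$mu, numeric(1)))
  peaks_per_type <- max(20L, as.integer(round(mean_signal / 1.5)))
  n_shared <- as.integer(round(0.2 * peaks_per_type))
  n_peak_bins <- n_shared + length(type_names) * (peaks_per_type - n_shared)
  n_bins <- n_peak_bins + as.integer(round(mean_bg / 0.005))
  sim_config(n_bins = n_bins, peaks_per_type = peaks_per_type,
             peak_overlap_fraction = 0.2, batches = batches,
             type_names = type_names, seed = seed)
}
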