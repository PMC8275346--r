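# Evaluation suite: Dice similarity against bulk truth, nonparametric
# k-nearest-neighbor mutual-information estimation between latent dimensions
# and confounders, and clustering agreement (ARI / NMI).

#' Dice similarity coefficient against a bulk profile
#'
#' `DSC = 2 <x_bulk, x_hat> / (|x_bulk| + |x_hat|)`. For binary `x_hat` this
#' equals `2TP / (2TP + FP + FN)` (the F1 score of open-bin recovery); the
#' formula is equally well-defined for probabilistic `x_hat`, which is how
#' imputed landscapes are scored by default.
#'
#' @param x_bulk binary ground-truth accessibility vector.
#' @param x_hat predicted vector in `[0, 1]` of the same length.
#' @return value in `[0, 1]`. Two all-zero vectors return 1 with a warning
#'   (vacuous perfect agreement).
#' @export
dice_coefficient <- function(x_bulk, x_hat) {
  stop_if_not(length(x_bulk) == length(x_hat),
              "x_bulk and x_hat must have equal lengths")
  stop_if_not(all(x_bulk %in% c(0, 1)), "x_bulk must be binary")
  stop_if_not(all(x_hat >= 0 & x_hat <= 1), "x_hat must lie in [0, 1]")
  denom <- sum(x_bulk) + sum(x_hat)
  if (denom == 0) {
    warning("both vectors are all-zero; Dice defined as 1 (vacuous agreement)")
    return(1)
  }
  2 * sum(x_bulk * x_hat) / denom
}

# kth smallest entry per row of a distance block (self-distances already Inf)
row_kth <- function(D, k) {
  apply(D, 1L, function(r) sort.int(r, partial = k)[k])
}

# Tiny deterministic jitter breaking exact ties; k-NN radii degenerate to
# zero on heavily tied data otherwise. Fixed internal seed keeps the
# estimator deterministic given its inputs.
break_ties <- function(x, stream = 1L) {
  scale <- 1e-10 * max(1, mean(abs(x)))
  x + with_seed(child_seed(285713L, stream), stats::rnorm(length(x), 0, scale))
}

# Kraskov (KSG, variant 1) estimator for two continuous 1-D variables:
# eps_i = distance to the kth joint neighbor under the max-norm; n_x, n_y =
# points strictly within eps_i along each marginal.
ksg_mi <- function(x, y, k, block = 512L) {
  n <- length(x)
  nx <- integer(n); ny <- integer(n)
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(s + block - 1L, n)
    dx <- abs(outer(x[idx], x, "-"))
    dy <- abs(outer(y[idx], y, "-"))
    dj <- pmax(dx, dy)
    dj[cbind(seq_along(idx), idx)] <- Inf
    eps <- row_kth(dj, k)
    nx[idx] <- rowSums(dx < eps) - 1L # exclude self
    ny[idx] <- rowSums(dy < eps) - 1L
  }
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

# Ross estimator for one continuous and one discrete variable: the kth
# neighbor radius is found within the point's own class, then m_i counts all
# points (any class) strictly inside that radius.
ross_mi <- function(x, g, k) {
  g <- as.factor(g)
  n <- length(x)
  xs <- sort(x)
  kvec <- integer(n); mvec <- integer(n); ng <- integer(n)
  keep <- rep(TRUE, n)
  for (lev in levels(g)) {
    idx <- which(g == lev)
    n_l <- length(idx)
    ng[idx] <- n_l
    if (n_l < 2L) { keep[idx] <- FALSE; next } # singleton class: no radius
    k_l <- min(k, n_l - 1L)
    xi <- x[idx]
    o <- order(xi); xo <- xi[o]
    # kth within-class neighbor distance via a sliding window on sorted values
    eps_o <- vapply(seq_len(n_l), function(i) {
      lo <- max(1L, i - k_l); hi <- min(n_l, i + k_l)
      sort.int(abs(xo[lo:hi] - xo[i]), partial = k_l + 1L)[k_l + 1L]
    }, numeric(1))
    eps <- numeric(n_l); eps[o] <- eps_o
    # points of any class strictly within eps (sorted full sample + binary search)
    hi <- findInterval(xi + eps, xs, left.open = TRUE)
    lo <- findInterval(xi - eps, xs)
    mvec[idx] <- hi - lo - 1L # open interval count, excluding self
    kvec[idx] <- k_l
  }
  if (!any(keep)) return(0)
  # +1: the count includes the query point itself (radius just below the
  # kth within-class neighbor distance); singleton-class points are dropped
  digamma(sum(keep)) - mean(digamma(ng[keep])) + mean(digamma(kvec[keep])) -
    mean(digamma(mvec[keep] + 1))
}

#' Nonparametric mutual information between a latent dimension and a confounder
#'
#' k-nearest-neighbor MI estimation in nats: the Kraskov estimator for a
#' continuous confounder (e.g. standardized log depth) and the Ross variant
#' for a discrete one (e.g. batch id, passed as factor/character). The
#' estimate is deterministic given the inputs and `k`; small negative values
#' are possible (estimator noise) and are not clamped here.
#'
#' @param z numeric per-cell values of one latent dimension.
#' @param c per-cell confounder: numeric = continuous, factor/character/
#'   logical = discrete.
#' @param k neighbor count (default 3).
#' @return MI estimate in nats (possibly slightly negative); exactly 0 when
#'   either input is constant.
#' @export
estimate_mi <- function(z, c, k = 3L) {
  stop_if_not(length(z) == length(c), "z and c must have equal lengths")
  stop_if_not(k >= 1, "k must be >= 1")
  z <- as.numeric(z)
  discrete <- is.factor(c) || is.character(c) || is.logical(c)
  if (stats::var(z) == 0) return(0)
  if (discrete) {
    if (length(unique(c)) < 2L) return(0)
    ross_mi(break_ties(z, 1L), c, k)
  } else {
    c <- as.numeric(c)
    if (stats::var(c) == 0) return(0)
    ksg_mi(break_ties(z, 1L), break_ties(c, 2L), k)
  }
}

#' Mutual information profile of an embedding against a confounder
#'
#' Estimates MI separately between each latent dimension and the confounder,
#' then averages across dimensions — the per-dimension-then-mean protocol
#' used for the reported `I(z, c)`. Negative per-dimension estimates are
#' clamped to 0 and counted in `n_clamped`.
#'
#' @param embedding cells x d matrix of latent means.
#' @param confounder per-cell confounder (continuous or discrete, see
#'   [estimate_mi()]).
#' @param k neighbor count (default 3).
#' @return object of class `mi_estimate`: `per_dim` (clamped per-dimension
#'   values), `mean`, `k`, `n_clamped`.
#' @export
mi_profile <- function(embedding, confounder, k = 3L) {
  embedding <- as.matrix(embedding)
  stop_if_not(nrow(embedding) == length(confounder),
              "embedding and confounder must align")
  raw <- apply(embedding, 2L, estimate_mi, c = confounder, k = k)
  clamped <- pmax(raw, 0)
  structure(list(per_dim = clamped, mean = mean(clamped), k = as.integer(k),
                 n_clamped = sum(raw < 0)),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("mi_estimate: mean %.4f nats over %d dimension(s) (k = %d%s)\n",
              x$mean, length(x$per_dim), x$k,
              if (x$n_clamped > 0)
                sprintf(", %d negative value(s) clamped", x$n_clamped) else ""))
  invisible(x)
}

#' Clustering agreement scores
#'
#' Adjusted Rand index and normalized mutual information (arithmetic-mean
#' entropy normalization) between a predicted and a reference partition.
#'
#' @param predicted,truth per-cell cluster labels (any label type).
#' @return named numeric vector `c(ari = ..., nmi = ...)`.
#' @export
cluster_agreement <- function(predicted, truth) {
  stop_if_not(length(predicted) == length(truth),
              "predicted and truth labels must have equal lengths")
  tab <- table(predicted, truth)
  n <- sum(tab)
  # adjusted Rand index from the contingency table
  sum_comb <- function(x) sum(choose(x, 2))
  a <- sum_comb(tab); b <- sum_comb(rowSums(tab)); c2 <- sum_comb(colSums(tab))
  expected <- b * c2 / choose(n, 2)
  maxidx <- (b + c2) / 2
  ari <- if (maxidx == expected) 1 else (a - expected) / (maxidx - expected)
  # NMI with arithmetic-mean entropy normalization
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  nmi <- if (hx + hy == 0) 1 else 2 * mi / (hx + hy)
  c(ari = ari, nmi = nmi)
}
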