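# Representation extraction and clustering: latent means as embeddings, a
# symmetrized Euclidean KNN graph, and Louvain community detection.

#' Extract invariant cell embeddings
#'
#' The per-cell latent representation is the posterior mean of `q(z|x)` — no
#' sampling, so repeated calls are identical.
#'
#' @param model a trained `invae_model`.
#' @param matrix a [cell_matrix()] preprocessed with the model's bin map.
#' @return numeric cells x d matrix with cell ids as row names.
#' @export
embed <- function(model, matrix) {
  encode(model, matrix)$mean
}

#' Build a k-nearest-neighbor graph from an embedding
#'
#' Euclidean KNN with edges symmetrized by union (an edge exists if either
#' endpoint lists the other among its k nearest); self-edges excluded.
#' Distances are computed blockwise so memory stays bounded for large cell
#' counts.
#'
#' @param embedding numeric cells x d matrix.
#' @param k neighbors per cell (`1 <= k < n_cells`).
#' @param block rows per distance block.
#' @return an undirected `igraph` graph with one vertex per cell.
#' @export
knn_graph <- function(embedding, k = 16L, block = 512L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  stop_if_not(k >= 1, "k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  sq <- rowSums(embedding^2)
  nbrs <- matrix(0L, n, k)
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(s + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * embedding[idx, , drop = FALSE] %*% t(embedding)
    d2[cbind(seq_along(idx), idx)] <- Inf # exclude self
    nbrs[idx, ] <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
  }
  edges <- cbind(rep(seq_len(n), each = k), as.integer(t(nbrs)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g) # union symmetrization; drops duplicates
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Louvain clustering of a cell graph
#'
#' Modularity-maximizing community detection with seed-controlled
#' tie-breaking. Labels are re-indexed to contiguous `0..K-1`.
#'
#' @param graph an undirected `igraph` graph (e.g. from [knn_graph()]).
#' @param resolution modularity resolution (default 1; smaller merges).
#' @param seed integer seed.
#' @return object of class `cluster_assignment`: list with `labels`
#'   (0-based integer per cell), `k` (number of clusters) and `modularity`.
#' @export
louvain_cluster <- function(graph, resolution = 1, seed = 1L) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  cl <- with_seed(seed, igraph::cluster_louvain(graph, resolution = resolution))
  labels <- as.integer(igraph::membership(cl)) - 1L
  structure(list(labels = labels, k = length(unique(labels)),
                 modularity = max(igraph::modularity(cl))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells in %d clusters (modularity %.3f)\n",
              length(x$labels), x$k, x$modularity))
  invisible(x)
}

#' PCA coordinates for 2D visualization export
#'
#' A linear 2D projection of an embedding (or imputed matrix) for quick
#' plotting and export. Nonlinear 2D layouts (t-SNE, UMAP) are deliberately
#' left to external tools operating on the exported embedding.
#'
#' @param x numeric matrix (cells x features).
#' @param n_comp number of components (default 2).
#' @return cells x `n_comp` matrix of principal-component coordinates.
#' @export
project_2d <- function(x, n_comp = 2L) {
  p <- stats::prcomp(as.matrix(x), center = TRUE, scale. = FALSE, rank. = n_comp)
  coords <- p$x
  rownames(coords) <- rownames(x)
  coords
}
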