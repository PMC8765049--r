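#' Graph-based clustering of cells
#'
#' Z-scales the selected genes, computes a PCA over cells, builds a
#' k-nearest-neighbor graph in PC space (Euclidean metric) and partitions it
#' by modularity optimization (Louvain) at the given resolution.
#' Deterministic given `seed`.
#'
#' @param norm Normalized genes-by-cells matrix with dimnames.
#' @param hvgs Character vector of genes to cluster on (e.g. from
#'   [select_hvg()]).
#' @param n_pcs Number of principal components (>= 2). Default 20.
#' @param resolution Modularity resolution parameter. Default 0.6.
#' @param k Neighbors per cell in the kNN graph. Default 15.
#' @param seed Integer seed for the partition optimizer.
#' @return Factor of cluster labels (`"1"`, `"2"`, ...) named by cell
#'   barcode, ordered by decreasing cluster size.
#' @export
cluster_cells <- function(norm, hvgs, n_pcs = 20L, resolution = 0.6,
                          k = 15L, seed = 0L) {
  stopifnot(n_pcs >= 2L)
  n_cells <- ncol(norm)
  if (n_cells <= n_pcs) stop("fewer cells (", n_cells, ") than n_pcs + 1")
  hvgs <- intersect(hvgs, rownames(norm))
  if (length(hvgs) < 2L) stop("need at least 2 genes present in norm")

  x <- as.matrix(norm[hvgs, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) {
    # no variable gene: all cells indistinguishable
    return(factor(stats::setNames(rep(1L, n_cells), colnames(norm))))
  }
  x <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]

  n_pcs <- min(n_pcs, nrow(x) - 1L, n_cells - 1L)
  pcs <- stats::prcomp(t(x), center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x

  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  k_use <- min(k, n_cells - 1L)
  nn <- apply(d, 1, function(row) order(row)[seq_len(k_use)])
  edges <- cbind(rep(seq_len(n_cells), each = k_use), as.vector(nn))
  edges <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)

  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- igraph::membership(comm)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- factor(relabel[as.character(mem)])
  names(labels) <- colnames(norm)
  labels
}
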