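#' Cluster composition by side and sample
#'
#' Tabulates cells by cluster against side of origin and against sample, and
#' derives (i) side-of-origin fractions within each cluster and (ii) the
#' cluster mixture within each side.
#'
#' @param cell_meta `data.frame` with columns `cluster`, `side`, `sample_id`
#'   (rownames or a `barcode` column identify cells in error messages).
#' @return A `composition_table` list: `counts_side`, `counts_sample`,
#'   `side_of_origin` (cluster x side fractions), `cluster_mixture` (side x
#'   cluster fractions).
#' @export
composition_by_side <- function(cell_meta) {
  cell_meta <- as.data.frame(cell_meta)
  stopifnot(all(c("cluster", "side", "sample_id") %in% names(cell_meta)))
  ids <- if (!is.null(cell_meta$barcode)) cell_meta$barcode else rownames(cell_meta)
  bad <- is.na(cell_meta$cluster) | is.na(cell_meta$side) | is.na(cell_meta$sample_id)
  if (any(bad)) {
    stop("unlabeled cell(s): ", paste(utils::head(ids[bad], 10), collapse = ", "),
         if (sum(bad) > 10) sprintf(" (+%d more)", sum(bad) - 10))
  }
  unknown <- setdiff(unique(as.character(cell_meta$side)), c("left", "right"))
  if (length(unknown)) stop("unknown side label: ", paste(unknown, collapse = ", "))

  counts_side <- table(cluster = cell_meta$cluster, side = cell_meta$side)
  counts_sample <- table(cluster = cell_meta$cluster, sample_id = cell_meta$sample_id)
  side_of_origin <- proportions(counts_side, margin = 1)
  cluster_mixture <- proportions(t(counts_side), margin = 1)
  structure(
    list(counts_side = counts_side, counts_sample = counts_sample,
         side_of_origin = side_of_origin, cluster_mixture = cluster_mixture),
    class = "composition_table"
  )
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Cluster composition (", sum(x$counts_side), " cells, ",
      nrow(x$counts_side), " clusters)\n", sep = "")
  cat("Side-of-origin fractions:\n")
  print(round(x$side_of_origin, 3))
  invisible(x)
}

#' Fold ratio of two counts
#'
#' @param count_a,count_b Non-negative counts.
#' @return `count_a / count_b`, or `NA` when `count_b` is 0 (undefined, not
#'   an error).
#' @export
fold_ratio <- function(count_a, count_b) {
  stopifnot(count_a >= 0, count_b >= 0)
  if (count_b == 0) return(NA_real_)
  count_a / count_b
}

#' Left-versus-right ratio of within-side preexhausted:exhausted ratios
#'
#' Computes `(pre_left / exh_left) / (pre_right / exh_right)`. Because each
#' cluster's total size cancels between numerator and denominator, the same
#' value is obtained from side-of-origin *fractions* of the two clusters:
#' `(fL_pre * fR_exh) / (fR_pre * fL_exh)`, so printed percentages can be
#' used directly in place of raw counts.
#'
#' @param pre_left,pre_right Preexhausted-cluster cell counts (or
#'   side-of-origin fractions) from left- and right-sided samples.
#' @param exh_left,exh_right The same for the exhausted cluster.
#' @return Positive scalar fold ratio.
#' @export
exhaustion_ratio_of_ratios <- function(pre_left, pre_right, exh_left, exh_right) {
  vals <- c(pre_left = pre_left, pre_right = pre_right,
            exh_left = exh_left, exh_right = exh_right)
  zero <- vals <= 0
  if (any(zero)) {
    stop("non-positive count for: ", paste(names(vals)[zero], collapse = ", "))
  }
  (pre_left / exh_left) / (pre_right / exh_right)
}

#' Centroid correlation network between cell types
#'
#' Computes each type's centroid (mean normalized expression over its cells,
#' restricted to `genes`) and the pairwise Pearson correlation of centroids
#' over genes — the edge weights of the similarity network.
#'
#' @param norm Normalized genes-by-cells matrix.
#' @param labels Cell-type labels per cell.
#' @param genes Gene space (>= 3 genes present); defaults to all rows, but
#'   the HVG set used for clustering is the conventional choice.
#' @return A `similarity_network` list: `nodes`, `centroids` (genes x
#'   types), `weights` (symmetric correlation matrix, unit diagonal).
#' @export
centroid_correlation_network <- function(norm, labels, genes = rownames(norm)) {
  types <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(norm))
  genes <- intersect(genes, rownames(norm))
  if (length(genes) < 3L) stop("need at least 3 genes in the gene space")
  empty <- types[!types %in% labels]
  if (length(empty)) {
    warning("dropping empty type(s): ", paste(empty, collapse = ", "))
    types <- setdiff(types, empty)
  }
  if (length(types) < 2L) stop("need at least 2 non-empty types")
  x <- as.matrix(norm[genes, , drop = FALSE])
  centroids <- vapply(types, function(tp) {
    rowMeans(x[, labels == tp, drop = FALSE])
  }, numeric(length(genes)))
  weights <- stats::cor(centroids)
  structure(list(nodes = types, centroids = centroids, weights = weights),
            class = "similarity_network")
}

#' Average-linkage dendrogram of cell-type centroids
#'
#' Agglomerative clustering of centroid profiles with correlation distance
#' (1 - Pearson) and average (UPGMA) linkage. Input columns are ordered
#' lexicographically by label first, which fixes the tie-break and makes the
#' tree invariant to input order.
#'
#' @param centroids Genes-by-types numeric matrix with type colnames (e.g.
#'   from [centroid_correlation_network()]).
#' @return An [stats::hclust] object.
#' @export
hclust_centroids <- function(centroids) {
  stopifnot(!is.null(colnames(centroids)), ncol(centroids) >= 2L)
  centroids <- centroids[, order(colnames(centroids)), drop = FALSE]
  sdv <- apply(centroids, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("constant centroid (correlation undefined) for: ",
         paste(colnames(centroids)[sdv == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(centroids))
  stats::hclust(d, method = "average")
}

#' Export a centroid dendrogram as Newick
#'
#' @param hc An [stats::hclust] object (e.g. from [hclust_centroids()]).
#' @param path Optional file to write to.
#' @return Newick string, invisibly when `path` is given.
#' @export
centroid_tree_newick <- function(hc, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Hypergeometric over-representation of a gene list in gene sets
#'
#' Upper-tail hypergeometric test P(X >= overlap) of the hit list against
#' each gene set, with Benjamini-Hochberg adjustment across the supplied
#' collection.
#'
#' @param hits Character vector of hit genes (subset of `universe`).
#' @param sets Named list of gene sets (each a subset of `universe`).
#' @param universe Character vector of all testable genes.
#' @return `data.frame` with columns `set`, `overlap`, `set_size`, `n_hits`,
#'   `universe_size`, `p`, `p_adj`.
#' @export
ora_hypergeometric <- function(hits, sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- unique(universe)
  hits <- unique(hits)
  if (!all(hits %in% universe)) {
    stop("hit genes outside the universe: ",
         paste(utils::head(setdiff(hits, universe), 5), collapse = ", "))
  }
  n_u <- length(universe)
  n_h <- length(hits)
  res <- lapply(names(sets), function(nm) {
    s <- unique(sets[[nm]])
    if (!all(s %in% universe)) {
      stop("gene set '", nm, "' not contained in the universe")
    }
    k <- length(intersect(hits, s))
    if (k > length(s)) stop("overlap exceeds set size for '", nm, "'")
    p <- stats::phyper(k - 1, length(s), n_u - length(s), n_h,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s), n_hits = n_h,
               universe_size = n_u, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
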