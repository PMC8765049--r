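#' Two-sided Wilcoxon rank-sum p-value
#'
#' For combined group sizes of at most `exact_max` the null distribution is
#' enumerated exactly over all assignments of observations to groups
#' (midranks handle ties), and the p-value is the probability of a rank sum
#' at least as far from its expectation as observed. For larger groups the
#' normal approximation with tie correction is used (no continuity
#' correction).
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_max Total sample size at or below which the exact
#'   enumeration is used. Default 10.
#' @return Two-sided p-value in (0, 1].
#' @export
wilcox_p <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  s_obs <- sum(r[seq_len(n1)])
  e_s <- n1 * (n1 + n2 + 1) / 2
  if (n1 + n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    mean(abs(sums - e_s) >= abs(s_obs - e_s) - 1e-9)
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    p <- 2 * stats::pnorm(-abs(s_obs - e_s) / sqrt(sigma2))
    min(1, p)
  }
}

# vectorized over the rows of a matrix: two-sided Wilcoxon of cols in `idx1`
# vs cols in `idx2`, plus natural-log fold change of group means
wilcox_rows <- function(mat, idx1, idx2, exact_max = 10L) {
  mat <- as.matrix(mat)
  n1 <- length(idx1); n2 <- length(idx2)
  sub <- mat[, c(idx1, idx2), drop = FALSE]
  p <- apply(sub, 1, function(v) {
    wilcox_p(v[seq_len(n1)], v[n1 + seq_len(n2)], exact_max)
  })
  lfc <- rowMeans(mat[, idx1, drop = FALSE]) - rowMeans(mat[, idx2, drop = FALSE])
  data.frame(gene = rownames(mat), lfc = unname(lfc), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Per-cluster marker genes by Wilcoxon rank-sum
#'
#' For each cluster, tests every gene cluster-vs-rest with a two-sided
#' Wilcoxon rank-sum test, adjusts p-values by Benjamini-Hochberg across
#' genes within the comparison, and retains genes with
#' `|log fold change| > lfc_cut` and `p_adj < alpha`. The log fold change is
#' the difference of group means of log-normalized expression (natural log);
#' `log2fc` is the same quantity in log2 units.
#'
#' @param norm Normalized genes-by-cells matrix with rownames.
#' @param labels Cluster labels per cell (factor or character).
#' @param lfc_cut Retention threshold on `|lfc|`. Default 0.5.
#' @param alpha Retention threshold on the BH-adjusted p. Default 0.05.
#' @return `data.frame` with columns `gene`, `group`, `lfc`, `log2fc`, `p`,
#'   `p_adj`, `direction` (`"up"`/`"down"` in the cluster vs rest).
#' @export
find_cluster_markers <- function(norm, labels, lfc_cut = 0.5, alpha = 0.05) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(norm))
  tabs <- table(labels)
  if (length(tabs) < 2L) stop("need at least 2 clusters")
  out <- list()
  for (cl in names(tabs)) {
    idx1 <- which(labels == cl)
    idx2 <- which(labels != cl)
    if (length(idx1) < 2L || length(idx2) < 2L) {
      warning("cluster '", cl, "' has fewer than 2 cells on one side; skipped")
      next
    }
    res <- wilcox_rows(norm, idx1, idx2)
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    res$group <- cl
    res <- res[abs(res$lfc) > lfc_cut & res$p_adj < alpha, , drop = FALSE]
    out[[cl]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(gene = character(0), group = character(0),
                      lfc = numeric(0), log2fc = numeric(0), p = numeric(0),
                      p_adj = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  res$log2fc <- res$lfc / log(2)
  res$direction <- ifelse(res$lfc > 0, "up", "down")
  rownames(res) <- NULL
  res[, c("gene", "group", "lfc", "log2fc", "p", "p_adj", "direction")]
}

#' Left-versus-right differential expression counts per cluster
#'
#' Within each cluster, tests every gene left vs right cells (two-sided
#' Wilcoxon), applies BH across genes, and counts genes passing
#' `|lfc| > lfc_cut` and `p_adj < alpha`. Clusters represented by fewer than
#' `min_cells` cells on either side get `NA` (flagged, not counted).
#'
#' @param norm Normalized genes-by-cells matrix.
#' @param labels Cluster labels per cell.
#' @param side Per-cell side labels (`"left"`/`"right"`).
#' @param lfc_cut,alpha Retention thresholds, defaults 0.5 and 0.05.
#' @param min_cells Minimum cells per side within a cluster. Default 2.
#' @return Named integer vector of DEG counts per cluster (`NA` where a side
#'   is missing).
#' @export
side_degs_per_cluster <- function(norm, labels, side, lfc_cut = 0.5,
                                  alpha = 0.05, min_cells = 2L) {
  labels <- as.character(labels)
  side <- as.character(side)
  stopifnot(length(labels) == ncol(norm), length(side) == ncol(norm))
  bad <- setdiff(unique(side), c("left", "right"))
  if (length(bad)) stop("unknown side label: ", paste(bad, collapse = ", "))
  clusters <- sort(unique(labels))
  counts <- stats::setNames(rep(NA_integer_, length(clusters)), clusters)
  for (cl in clusters) {
    in_cl <- labels == cl
    idx_l <- which(in_cl & side == "left")
    idx_r <- which(in_cl & side == "right")
    if (length(idx_l) < min_cells || length(idx_r) < min_cells) next
    res <- wilcox_rows(norm, idx_l, idx_r)
    p_adj <- stats::p.adjust(res$p, method = "BH")
    counts[cl] <- sum(abs(res$lfc) > lfc_cut & p_adj < alpha)
  }
  counts
}

#' Filter a DEG table for pathway over-representation input
#'
#' Retains genes with BH-adjusted p below `alpha` and absolute log2 fold
#' change strictly larger than `lfc2_cut` (so `log2fc = 1.0` exactly is
#' dropped).
#'
#' @param deg `data.frame` with columns `gene`, `log2fc`, `p_adj` (as
#'   returned by [find_cluster_markers()]).
#' @param lfc2_cut log2 fold-change threshold (strict). Default 1.
#' @param alpha Adjusted-p threshold (strict). Default 0.01.
#' @return Character vector of retained gene names (unique).
#' @export
filter_degs_for_enrichment <- function(deg, lfc2_cut = 1, alpha = 0.01) {
  if (nrow(deg) == 0L) return(character(0))
  stopifnot(all(c("gene", "log2fc", "p_adj") %in% names(deg)))
  keep <- deg$p_adj < alpha & abs(deg$log2fc) > lfc2_cut
  unique(deg$gene[keep])
}
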