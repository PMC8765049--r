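#' Read a ligand-receptor pair database
#'
#' TSV with columns `pair_id`, `ligand`, `receptor`, and optionally
#' `annotation`; multi-subunit complexes are `;`-joined gene lists (e.g.
#' `ITGA1;ITGB1` for an a1b1-style integrin complex).
#'
#' @param path TSV path.
#' @return A `lr_pair_db` data.frame with list-columns `ligand_genes` and
#'   `receptor_genes`.
#' @export
lr_pair_db <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pair_id", "ligand", "receptor") %in% names(df)))
  if (anyDuplicated(df$pair_id)) stop("duplicated pair ids")
  split_sub <- function(x) lapply(strsplit(x, ";", fixed = TRUE), trimws)
  df$ligand_genes <- split_sub(df$ligand)
  df$receptor_genes <- split_sub(df$receptor)
  empty <- vapply(c(df$ligand_genes, df$receptor_genes),
                  function(g) any(!nzchar(g)) || length(g) == 0L, logical(1))
  if (any(empty)) stop("empty subunit gene name in pair database")
  if (is.null(df$annotation)) df$annotation <- ""
  class(df) <- c("lr_pair_db", class(df))
  df
}

#' Packaged ligand-receptor pair list
#'
#' A small curated list (~30 pairs) of well-known ligand-receptor couples
#' relevant to tumor-microenvironment signaling — TNF/TRAIL/TGF-beta axes,
#' chemokines, checkpoint couples, and collagen-to-integrin (a1b1 complex)
#' entries — standing in for a full external interaction database.
#'
#' @return A `lr_pair_db` data.frame.
#' @export
builtin_lr_pairs <- function() {
  lr_pair_db(system.file("extdata", "lr_pairs.tsv", package = "tmeside"))
}

#' Per-cluster mean expression with an expressed-fraction mask
#'
#' Mean normalized expression of every gene in every cluster; a gene
#' detected (count > 0) in fewer than `min_expr_frac` of a cluster's cells
#' has its mean masked to 0 for that cluster.
#'
#' @param norm Normalized genes-by-cells matrix.
#' @param labels Cluster labels covering all cells.
#' @param min_expr_frac Minimum expressed fraction. Default 0.1.
#' @return List with genes-by-clusters matrices `mean`, `frac`, and
#'   `masked_mean`.
#' @export
cluster_mean_expression <- function(norm, labels, min_expr_frac = 0.1) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(norm))
  x <- as.matrix(norm)
  clusters <- sort(unique(labels))
  n_per <- table(labels)[clusters]
  mean_m <- vapply(clusters, function(cl) {
    rowMeans(x[, labels == cl, drop = FALSE])
  }, numeric(nrow(x)))
  frac_m <- vapply(clusters, function(cl) {
    rowMeans(x[, labels == cl, drop = FALSE] > 0)
  }, numeric(nrow(x)))
  masked <- mean_m
  masked[frac_m < min_expr_frac] <- 0
  list(mean = mean_m, frac = frac_m, masked_mean = masked,
       n_cells = as.integer(n_per))
}

# complex expression: minimum over subunit masked means for one cluster
entity_mean <- function(masked_mean, genes, cluster) {
  missing <- setdiff(genes, rownames(masked_mean))
  if (length(missing)) {
    stop("gene(s) absent from the matrix: ", paste(missing, collapse = ", "))
  }
  min(masked_mean[genes, cluster])
}

#' Ligand-receptor statistic for one pair and one ordered cluster pair
#'
#' The statistic is the average of the ligand-entity mean in the sender
#' cluster and the receptor-entity mean in the receiver cluster, where an
#' entity mean is the minimum masked subunit mean (complex rule); it is 0
#' whenever either entity is masked to 0.
#'
#' @param ligand_genes,receptor_genes Character vectors of subunit genes.
#' @param sender,receiver Cluster labels (columns of `masked_mean`).
#' @param masked_mean Genes-by-clusters masked mean matrix from
#'   [cluster_mean_expression()].
#' @return Non-negative scalar.
#' @export
lr_statistic <- function(ligand_genes, receptor_genes, sender, receiver,
                         masked_mean) {
  l <- entity_mean(masked_mean, ligand_genes, sender)
  r <- entity_mean(masked_mean, receptor_genes, receiver)
  if (l == 0 || r == 0) return(0)
  (l + r) / 2
}

# all (pair, sender, receiver) statistics as a pairs x (k*k) matrix
all_lr_statistics <- function(pairdb, masked_mean) {
  clusters <- colnames(masked_mean)
  combos <- expand.grid(sender = clusters, receiver = clusters,
                        stringsAsFactors = FALSE)
  stat <- matrix(0, nrow(pairdb), nrow(combos))
  for (i in seq_len(nrow(pairdb))) {
    lg <- pairdb$ligand_genes[[i]]
    rg <- pairdb$receptor_genes[[i]]
    lmin <- apply(masked_mean[lg, , drop = FALSE], 2, min)
    rmin <- apply(masked_mean[rg, , drop = FALSE], 2, min)
    s <- (lmin[combos$sender] + rmin[combos$receiver]) / 2
    s[lmin[combos$sender] == 0 | rmin[combos$receiver] == 0] <- 0
    stat[i, ] <- s
  }
  list(stat = stat, combos = combos)
}

#' Permutation test for ligand-receptor interactions between clusters
#'
#' For every pair in the database and every ordered (sender, receiver)
#' cluster combination, compares the observed statistic ([lr_statistic()])
#' with a null distribution obtained by shuffling cluster labels over cells
#' `n_perm` times. The add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` never returns 0. Pairs
#' whose observed statistic is 0 (masked or unexpressed) are reported with
#' `p = 1` and flagged. Deterministic given `seed`.
#'
#' @param norm Normalized genes-by-cells matrix.
#' @param labels Cluster labels per cell (>= 2 clusters).
#' @param pairdb A `lr_pair_db` (see [lr_pair_db()], [builtin_lr_pairs()]).
#'   Pairs with genes absent from `norm` are dropped with a warning.
#' @param n_perm Number of label permutations (>= 100). Default 1000.
#' @param seed Integer seed.
#' @param min_expr_frac Expressed-fraction mask threshold. Default 0.1.
#' @return `data.frame` with columns `pair_id`, `sender`, `receiver`,
#'   `statistic`, `p`, `significant` (`p <= 0.05`), `masked`.
#' @export
permutation_test_lr <- function(norm, labels, pairdb, n_perm = 1000L,
                                seed = 1L, min_expr_frac = 0.1) {
  stopifnot(n_perm >= 100L)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")

  present <- vapply(seq_len(nrow(pairdb)), function(i) {
    all(c(pairdb$ligand_genes[[i]], pairdb$receptor_genes[[i]]) %in% rownames(norm))
  }, logical(1))
  if (!all(present)) {
    warning(sum(!present), " pair(s) dropped: gene(s) absent from the matrix")
    pairdb <- pairdb[present, , drop = FALSE]
  }
  if (nrow(pairdb) == 0L) stop("no testable pairs")

  genes <- unique(unlist(c(pairdb$ligand_genes, pairdb$receptor_genes)))
  sub <- as.matrix(norm[genes, , drop = FALSE])

  cm <- cluster_mean_expression(sub, labels, min_expr_frac)
  obs <- all_lr_statistics(pairdb, cm$masked_mean)

  set.seed(seed)
  exceed <- matrix(0L, nrow(obs$stat), ncol(obs$stat))
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    cm_b <- cluster_mean_expression(sub, perm, min_expr_frac)
    null_b <- all_lr_statistics(pairdb, cm_b$masked_mean)$stat
    exceed <- exceed + (null_b >= obs$stat)
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[obs$stat == 0] <- 1

  out <- data.frame(
    pair_id = rep(pairdb$pair_id, times = ncol(obs$stat)),
    sender = rep(obs$combos$sender, each = nrow(pairdb)),
    receiver = rep(obs$combos$receiver, each = nrow(pairdb)),
    statistic = as.vector(obs$stat),
    p = as.vector(p),
    stringsAsFactors = FALSE
  )
  out$significant <- out$p <= 0.05
  out$masked <- out$statistic == 0
  out
}

#' Retain significant ligand-receptor results
#'
#' Keeps rows with `p <= 0.05`; pairs with `p > 0.05` are filtered out.
#'
#' @param result Output of [permutation_test_lr()].
#' @return The retained rows.
#' @export
filter_significant_pairs <- function(result) {
  result[result$p <= 0.05, , drop = FALSE]
}

#' Run the ligand-receptor test separately per side
#'
#' Reproduces the left/right contrast structure: the permutation test is run
#' independently on left- and right-sided cells.
#'
#' @param norm Normalized genes-by-cells matrix.
#' @param labels Cluster labels per cell.
#' @param side Per-cell side labels (`"left"`/`"right"`).
#' @param ... Forwarded to [permutation_test_lr()].
#' @return Named list with elements `left` and `right`.
#' @export
permutation_test_lr_by_side <- function(norm, labels, side, ...) {
  side <- as.character(side)
  stopifnot(length(side) == ncol(norm))
  lapply(stats::setNames(c("left", "right"), c("left", "right")), function(s) {
    idx <- side == s
    permutation_test_lr(norm[, idx, drop = FALSE], labels[idx], ...)
  })
}
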