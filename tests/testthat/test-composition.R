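make_meta <- function(cluster, side, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- ifelse(side == "left", "L1", "R1")
  data.frame(cluster = cluster, side = side, sample_id = sample_id,
             barcode = sprintf("bc%03d", seq_along(cluster)))
}

test_that("side-of-origin fractions are exact integer arithmetic", {
  meta <- make_meta(rep(c("m", "t"), c(40, 20)),
                    rep(c("right", "left", "left"), c(30, 10, 20)))
  comp <- composition_by_side(meta)
  expect_equal(comp$side_of_origin["m", "right"], 0.75)
  expect_equal(comp$side_of_origin["m", "left"], 0.25)
  # a fully one-sided cluster
  expect_equal(unname(comp$side_of_origin["t", c("left", "right")]), c(1, 0))
  # per-side cluster mixtures sum to one
  expect_equal(unname(rowSums(comp$cluster_mixture)), c(1, 1))
})

test_that("unlabeled cells and unknown sides are rejected", {
  meta <- make_meta(c("a", NA), c("left", "left"))
  expect_error(composition_by_side(meta), "bc002")
  meta2 <- make_meta(c("a", "b"), c("left", "up"))
  expect_error(composition_by_side(meta2), "unknown side")
})

test_that("fold ratios divide counts and guard the zero denominator", {
  expect_equal(fold_ratio(90, 10), 9.0)
  expect_equal(fold_ratio(10, 10), 1.0)
  expect_true(is.na(fold_ratio(5, 0)))
  f <- fold_ratio(7, 3)
  expect_equal(f * fold_ratio(3, 7), 1.0, tolerance = 1e-15)
})

test_that("the ratio-of-ratios works on counts and on fractions alike", {
  # counts consistent with side-of-origin fractions 86.8% / 67.9%
  expect_equal(exhaustion_ratio_of_ratios(868, 132, 321, 679),
               (868 / 321) / (132 / 679), tolerance = 1e-12)
  expect_equal(round(exhaustion_ratio_of_ratios(868, 132, 321, 679), 1), 13.9)
  # equal composition on both sides
  expect_equal(exhaustion_ratio_of_ratios(50, 50, 30, 30), 1.0)
  expect_error(exhaustion_ratio_of_ratios(10, 0, 5, 5), "pre_right")
})

test_that("the ratio-of-ratios is invariant to cluster-total rescaling", {
  set.seed(7)
  for (i in 1:25) {
    v <- sample(1:500, 4, replace = TRUE)
    base <- exhaustion_ratio_of_ratios(v[1], v[2], v[3], v[4])
    s_pre <- runif(1, 0.1, 10); s_exh <- runif(1, 0.1, 10)
    scaled <- exhaustion_ratio_of_ratios(v[1] * s_pre, v[2] * s_pre,
                                         v[3] * s_exh, v[4] * s_exh)
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("centroid network weights equal hand-computed Pearson values", {
  norm <- rbind(
    g1 = c(1, 1, 3, 3, 1, 1),
    g2 = c(2, 2, 2, 2, 2, 2.5),
    g3 = c(3, 3, 1, 1, 4, 3.5)
  )
  colnames(norm) <- paste0("c", 1:6)
  labels <- c("A", "A", "B", "B", "C", "C")
  net <- centroid_correlation_network(norm, labels)
  expect_equal(unname(diag(net$weights)), c(1, 1, 1))
  expect_equal(net$weights, t(net$weights))
  # A centroid [1,2,3], B centroid [3,2,1]: exact anti-correlation
  expect_equal(net$weights["A", "B"], -1.0, tolerance = 1e-12)
  # hand Pearson for [1,2,3] vs [1,2.25,3.75]
  expect_equal(net$weights["A", "C"],
               oracle_pearson(c(1, 2, 3), c(1, 2.25, 3.75)), tolerance = 1e-12)
})

test_that("centroids [1,2,3] and [1,2,4] correlate at 0.9820", {
  norm <- cbind(a = c(1, 2, 3), b = c(1, 2, 4))
  rownames(norm) <- paste0("g", 1:3)
  net <- centroid_correlation_network(norm, c("A", "B"))
  expect_equal(round(net$weights["A", "B"], 4), 0.9820)
})

test_that("network weights match the brute-force oracle on random data", {
  set.seed(8)
  norm <- matrix(rexp(20 * 40), 20, 40,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:40)))
  labels <- sample(paste0("t", 1:5), 40, replace = TRUE)
  net <- centroid_correlation_network(norm, labels)
  for (a in net$nodes) {
    for (b in net$nodes) {
      expect_equal(net$weights[a, b],
                   oracle_pearson(net$centroids[, a], net$centroids[, b]),
                   tolerance = 1e-12)
    }
  }
})

test_that("empty types are dropped with a warning", {
  norm <- matrix(rexp(30), 5, 6,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  labels <- factor(rep(c("A", "B"), 3), levels = c("A", "B", "ghost"))
  expect_warning(net <- centroid_correlation_network(norm, labels), "ghost")
  expect_setequal(net$nodes, c("A", "B"))
})

test_that("UPGMA on centroids reproduces hand-computed merges", {
  # build three centroids with exact pairwise correlations .9, .5, .5
  target <- rbind(c(1, 0.9, 0.5), c(0.9, 1, 0.5), c(0.5, 0.5, 1))
  set.seed(9)
  raw <- matrix(rnorm(3 * 60), 3, 60)
  raw <- raw - rowMeans(raw)
  e <- qr.Q(qr(t(raw)))[, 1:3]          # centered orthonormal basis? ensure centering
  e <- e - matrix(colMeans(e), 60, 3, byrow = TRUE)
  e <- qr.Q(qr(e))
  y <- t(chol(target)) %*% t(e)         # 3 x 60 with cor(y_i, y_j) = target
  centroids <- t(y)
  colnames(centroids) <- c("A", "B", "C")
  expect_equal(stats::cor(centroids), target, tolerance = 1e-9,
               ignore_attr = TRUE)

  hc <- hclust_centroids(centroids)
  expect_equal(hc$height, c(0.1, 0.5), tolerance = 1e-9)
  # first merge joins A and B (both leaves), second adds C
  expect_true(all(hc$merge[1, ] < 0))
  labs <- hc$labels[-hc$merge[1, ]]
  expect_setequal(labs, c("A", "B"))
})

test_that("identical centroids merge first at height zero", {
  set.seed(10)
  base <- rnorm(20)
  centroids <- cbind(A = base, B = base, C = rnorm(20), D = rnorm(20))
  hc <- hclust_centroids(centroids)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("A", "B"))
})

test_that("the dendrogram is invariant to input column order", {
  set.seed(11)
  centroids <- matrix(rnorm(20 * 5), 20, 5,
                      dimnames = list(NULL, c("e", "b", "d", "a", "c")))
  h1 <- hclust_centroids(centroids)
  h2 <- hclust_centroids(centroids[, sample(5)])
  expect_equal(h1$height, h2$height, tolerance = 1e-12)
  expect_equal(stats::cophenetic(h1), stats::cophenetic(h2), tolerance = 1e-12)
})

test_that("constant centroids are rejected by name", {
  centroids <- cbind(A = rnorm(10), Flat = rep(1, 10))
  expect_error(hclust_centroids(centroids), "Flat")
})

test_that("dendrograms export to parseable Newick", {
  set.seed(12)
  centroids <- matrix(rnorm(15 * 4), 15, 4,
                      dimnames = list(NULL, c("Tcell", "Bcell", "Mast", "DC")))
  nwk <- centroid_tree_newick(hclust_centroids(centroids))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("Tcell", "Bcell", "Mast", "DC"))
})

test_that("hypergeometric over-representation matches exact combinatorics", {
  res <- ora_hypergeometric(
    hits = paste0("g", 1:5),
    sets = list(s = paste0("g", 1:5)),
    universe = paste0("g", 1:20)
  )
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(signif(res$p, 4), 6.45e-05)

  # universe 10, set 2, hits 2, overlap 1 -> 17/45
  res2 <- ora_hypergeometric(
    hits = c("g1", "g9"),
    sets = list(s = c("g1", "g2")),
    universe = paste0("g", 1:10)
  )
  expect_equal(res2$p, 17 / 45, tolerance = 1e-12)

  # zero overlap -> P(X >= 0) = 1
  res3 <- ora_hypergeometric(
    hits = c("g9", "g10"),
    sets = list(s = c("g1", "g2")),
    universe = paste0("g", 1:10)
  )
  expect_equal(res3$p, 1)
})

test_that("over-representation p matches exhaustive enumeration (universe <= 15)", {
  set.seed(13)
  for (i in 1:10) {
    n_u <- sample(6:15, 1)
    set_size <- sample(2:(n_u - 2), 1)
    n_hits <- sample(2:(n_u - 1), 1)
    universe <- paste0("g", seq_len(n_u))
    hits <- sample(universe, n_hits)
    s <- universe[seq_len(set_size)]
    res <- ora_hypergeometric(hits, list(s = s), universe)
    expect_equal(res$p,
                 oracle_ora_p(n_u, set_size, n_hits, res$overlap),
                 tolerance = 1e-12)
  }
})

test_that("over-representation validates its inputs and adjusts across sets", {
  expect_error(
    ora_hypergeometric("x", list(s = c("g1")), paste0("g", 1:5)),
    "outside the universe"
  )
  expect_error(
    ora_hypergeometric("g1", list(s = "zz"), paste0("g", 1:5)),
    "not contained"
  )
  res <- ora_hypergeometric(
    paste0("g", 1:4),
    list(a = paste0("g", 1:4), b = paste0("g", 5:8), c = paste0("g", c(1, 9))),
    paste0("g", 1:12)
  )
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  expect_true(all(res$p_adj >= res$p))
})

test_that("the reference composition config realizes the printed fractions", {
  cfg <- reference_composition_config(n_cells_per_sample = 400, n_genes = 200,
                                      seed = 23)
  sce <- generate_counts(cfg)
  comp <- composition_by_side(data.frame(
    cluster = sce$cell_type, side = sce$side, sample_id = sce$sample_id
  ))
  # mast-cell cluster right fraction within the exact binomial 99% interval
  n_mast <- sum(comp$counts_side["Mast", ])
  ci <- qbinom(c(0.005, 0.995), n_mast, 0.715) / n_mast
  frac <- comp$side_of_origin["Mast", "right"]
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})
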