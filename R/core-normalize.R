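#' Log counts-per-10,000 normalization
#'
#' Scales each cell to a total of 10,000 counts and applies `log1p`, the
#' de-facto convention of the standard single-cell toolchains. All-zero
#' cells cannot be normalized and are excluded with a warning.
#'
#' @param x A genes-by-cells count matrix (dense, sparse, or a
#'   `SingleCellExperiment` with a `counts` assay).
#' @param scale_factor Per-cell target total. Default 1e4.
#' @return For a matrix input, the normalized matrix (same storage class,
#'   all-zero cells removed, with attribute `dropped_cells` listing excluded
#'   barcodes). For a `SingleCellExperiment`, the object with zero cells
#'   dropped and a `logcounts` assay added.
#' @export
normalize_log_cp10k <- function(x, scale_factor = 1e4) {
  if (methods::is(x, "SingleCellExperiment")) {
    norm <- normalize_log_cp10k(SummarizedExperiment::assay(x, "counts"),
                                scale_factor)
    kept <- colnames(norm)
    x <- x[, kept]
    SummarizedExperiment::assay(x, "logcounts") <- norm
    return(x)
  }
  totals <- Matrix::colSums(x)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s) excluded from normalization")
    x <- x[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  if (methods::is(x, "sparseMatrix")) {
    norm <- methods::as(x, "CsparseMatrix")
    norm@x <- log1p(norm@x / rep.int(totals, diff(norm@p)) * scale_factor)
  } else {
    norm <- log1p(sweep(as.matrix(x), 2, totals, "/") * scale_factor)
  }
  if (any(zero)) attr(norm, "dropped_cells") <- names(zero)[zero]
  norm
}

#' Linear counts-per-10,000 normalization
#'
#' Depth normalization without the log transform. Plain fold changes of mean
#' expression (e.g. [panel_fold_change()]) are ratios of linear-scale means,
#' so they should be computed on this scale, not on log-normalized values.
#'
#' @inheritParams normalize_log_cp10k
#' @return Matrix of the same shape with each cell scaled to `scale_factor`
#'   total counts (all-zero cells removed with a warning).
#' @export
normalize_cp10k <- function(x, scale_factor = 1e4) {
  if (methods::is(x, "SingleCellExperiment")) {
    x <- SummarizedExperiment::assay(x, "counts")
  }
  totals <- Matrix::colSums(x)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s) excluded from normalization")
    x <- x[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  if (methods::is(x, "sparseMatrix")) {
    out <- methods::as(x, "CsparseMatrix")
    out@x <- out@x / rep.int(totals, diff(out@p)) * scale_factor
    out
  } else {
    sweep(as.matrix(x), 2, totals, "/") * scale_factor
  }
}

#' Basic per-cell filtering
#'
#' Removes cells expressing fewer than `min_genes` features. The motivating
#' study design does not print per-cell thresholds; this conservative default
#' is configurable and applied before normalization.
#'
#' @param x Count matrix or `SingleCellExperiment`.
#' @param min_genes Minimum number of detected genes per cell. Default 200.
#' @return The filtered object.
#' @export
filter_cells <- function(x, min_genes = 200L) {
  counts <- if (methods::is(x, "SingleCellExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else x
  detected <- Matrix::colSums(counts > 0)
  x[, detected >= min_genes, drop = FALSE]
}

#' Select highly variable genes
#'
#' Ranks genes by a binned dispersion statistic: dispersion =
#' variance / mean of the normalized expression, standardized (z-scored)
#' within bins of comparable mean expression so that highly expressed genes
#' do not dominate. Ties are broken lexicographically by gene name, making
#' the selection deterministic.
#'
#' @param norm Normalized genes-by-cells matrix with rownames.
#' @param n_top Number of genes to return (`0 < n_top <=` number of genes).
#' @param n_bins Number of equal-frequency mean-expression bins. Default 20.
#' @return Character vector of `n_top` gene names, highest dispersion first.
#' @export
select_hvg <- function(norm, n_top, n_bins = 20L) {
  stopifnot(n_top >= 1L, n_top <= nrow(norm))
  if (is.null(rownames(norm))) stop("norm must have gene rownames")
  means <- Matrix::rowMeans(norm)
  sq <- Matrix::rowMeans(norm^2)
  n <- ncol(norm)
  vars <- (sq - means^2) * n / (n - 1)
  disp <- ifelse(means > 0, vars / means, 0)

  brk <- unique(stats::quantile(means, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(means, breaks = brk, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  # z first, then raw dispersion (bins too sparse to standardize), then name
  ord <- order(-z, -disp, rownames(norm))
  rownames(norm)[ord][seq_len(n_top)]
}
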