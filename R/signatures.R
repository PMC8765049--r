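#' Construct a gene signature
#'
#' @param name Signature label.
#' @param genes Non-empty character vector of unique gene names.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(genes) == 0L) stop("signature '", name, "': empty gene list")
  if (anyDuplicated(genes)) stop("signature '", name, "': duplicated genes")
  structure(list(name = name, genes = as.character(genes)),
            class = "gene_signature")
}

#' Gene-wise Z-score transformation
#'
#' Centers each gene row by its mean and scales by its sample (n-1) standard
#' deviation, over the cell population being scored. Zero-variance rows map
#' to all zeros with a warning.
#'
#' @param norm Normalized genes-by-cells matrix with at least 2 cells.
#' @return Dense Z-score matrix of the same dimensions.
#' @export
zscore_genes <- function(norm) {
  if (ncol(norm) < 2L) stop("Z-scores need at least 2 cells (sd undefined)")
  x <- as.matrix(norm)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) mapped to all-zero Z rows")
    sdv[zero] <- 1
  }
  z <- (x - mu) / sdv
  z[zero, ] <- 0
  z
}

#' Score cells against a gene signature
#'
#' Per-cell unweighted mean of Z-scored expression over the signature genes
#' present in the matrix. Missing genes are reported in attributes, never
#' imputed.
#'
#' @param z Z-score matrix from [zscore_genes()] (genes x cells, rownames).
#' @param signature A [gene_signature()].
#' @return Named numeric vector of per-cell scores with attributes
#'   `signature`, `n_found`, `missing`.
#' @export
score_signature <- function(z, signature) {
  stopifnot(inherits(signature, "gene_signature"))
  found <- intersect(signature$genes, rownames(z))
  if (length(found) == 0L) {
    stop("no genes of signature '", signature$name, "' present in the matrix")
  }
  s <- colMeans(z[found, , drop = FALSE])
  attr(s, "signature") <- signature$name
  attr(s, "n_found") <- length(found)
  attr(s, "missing") <- setdiff(signature$genes, found)
  s
}

#' Built-in T-cell and macrophage gene signatures
#'
#' Returns the signatures used throughout the left/right TME analysis:
#'
#' * `naiveness` — the 4 canonical naive T-cell markers (CCR7, TCF7, LEF1,
#'   SELL).
#' * `cytotoxicity` — 12 cytotoxicity-associated genes.
#' * `coinhibition` — the 24-gene T-cell coinhibitory program.
#' * `exhaustion` — a 90-slot list of tumor-infiltrating exhausted-CD8
#'   markers. The canonical 90-gene panel is study-specific, so the default
#'   shipped here is an illustrative placeholder assembled from widely used
#'   exhaustion-associated genes; supply your own via `exhaustion_genes`.
#' * `m1_panel` / `m2_panel` — illustrative default M1 (pro-inflammatory)
#'   and M2 (tissue-remodeling) macrophage polarization panels, also
#'   intended to be overridden by study-specific panels.
#'
#' @param exhaustion_genes Optional character vector replacing the default
#'   exhaustion list.
#' @param m1_genes,m2_genes Optional replacements for the macrophage panels.
#' @return Named list of [gene_signature()] objects.
#' @export
builtin_signatures <- function(exhaustion_genes = NULL, m1_genes = NULL,
                               m2_genes = NULL) {
  naiveness <- c("CCR7", "TCF7", "LEF1", "SELL")
  cytotoxicity <- c("PRF1", "IFNG", "GNLY", "NKG7", "GZMB", "GZMA", "GZMH",
                    "KLRK1", "KLRB1", "KLRD1", "CTSW", "CST7")
  coinhibition <- c("CTLA4", "PDCD1", "TIGIT", "HAVCR2", "LAG3", "BTLA",
                    "PDPN", "CD160", "GP49A", "LILRB4", "CD274", "CD200",
                    "CD244", "PILRA", "SIRPB1", "LAIR1", "CEACAM1", "KLRA7",
                    "KLRA3", "KLRA9", "PTGER4", "KLRD1", "KLRC1", "PROCR")
  if (is.null(exhaustion_genes)) {
    exhaustion_genes <- default_exhaustion_genes()
  }
  if (is.null(m1_genes)) {
    m1_genes <- c("IL1B", "TNF", "CXCL9", "CXCL10", "CXCL11", "CD80", "CD86",
                  "IL6", "IL12B", "NOS2", "SOCS1", "TLR2", "TLR4", "FCGR1A")
  }
  if (is.null(m2_genes)) {
    m2_genes <- c("MRC1", "CD163", "MSR1", "CCL22", "CCL17", "IL10", "TGFB1",
                  "MAF", "ARG1", "CLEC7A", "CD209", "STAB1", "LYVE1", "F13A1")
  }
  list(
    naiveness = gene_signature("naiveness", naiveness),
    cytotoxicity = gene_signature("cytotoxicity", cytotoxicity),
    coinhibition = gene_signature("coinhibition", coinhibition),
    exhaustion = gene_signature("exhaustion", exhaustion_genes),
    m1_panel = gene_signature("m1_panel", m1_genes),
    m2_panel = gene_signature("m2_panel", m2_genes)
  )
}

# illustrative 90-gene exhaustion placeholder (checkpoints, exhaustion TFs,
# and activation/dysfunction-associated genes); meant to be user-replaced
default_exhaustion_genes <- function() {
  path <- system.file("extdata", "exhaustion_default.txt", package = "tmeside")
  readLines(path)
}

#' Read signatures from a plain-text config
#'
#' Parses a two-column TSV (`name`, `genes`) with comma-separated gene
#' lists.
#'
#' @param path Config file path.
#' @return Named list of [gene_signature()] objects.
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "genes") %in% names(df)))
  sigs <- lapply(seq_len(nrow(df)), function(i) {
    gene_signature(df$name[i], trimws(strsplit(df$genes[i], ",")[[1]]))
  })
  stats::setNames(sigs, df$name)
}

#' Mean-expression fold change of a gene panel between two cell groups
#'
#' Ratio of the mean normalized expression over the panel's genes in group A
#' to the same mean in group B. A plain ratio, not a log.
#'
#' @param norm Normalized genes-by-cells matrix.
#' @param panel A [gene_signature()].
#' @param group_a,group_b Logical masks or index vectors over cells; both
#'   non-empty.
#' @return Positive scalar fold change.
#' @export
panel_fold_change <- function(norm, panel, group_a, group_b) {
  stopifnot(inherits(panel, "gene_signature"))
  genes <- intersect(panel$genes, rownames(norm))
  if (length(genes) == 0L) stop("no panel genes present")
  a <- norm[genes, group_a, drop = FALSE]
  b <- norm[genes, group_b, drop = FALSE]
  if (ncol(a) == 0L || ncol(b) == 0L) stop("empty cell group")
  mat_mean <- function(m) sum(m) / (as.numeric(nrow(m)) * ncol(m))
  denom <- mat_mean(b)
  if (denom == 0) stop("denominator group has zero mean panel expression")
  mat_mean(a) / denom
}

#' LOESS trend of a score along a trajectory component
#'
#' First-degree locally weighted regression (tricube weights) of per-cell
#' scores on a trajectory component, evaluated on a 100-point grid spanning
#' the component range.
#'
#' @param component Per-cell numeric trajectory coordinate (e.g. a pseudotime
#'   component or a PC); must not be constant.
#' @param scores Per-cell numeric scores, same length.
#' @param span LOESS span in (0, 1]. Default 0.5.
#' @return A `trend_fit` list: `grid`, `fitted`, `span`, `n`.
#' @export
fit_score_trend <- function(component, scores, span = 0.5) {
  stopifnot(length(component) == length(scores))
  if (length(component) < 10L) stop("need at least 10 cells")
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  if (diff(range(component)) == 0) stop("constant component; trend undefined")
  fit <- stats::loess(scores ~ component, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(component), max(component), length.out = 100L)
  structure(
    list(grid = grid,
         fitted = unname(stats::predict(fit, data.frame(component = grid))),
         span = span, n = length(component)),
    class = "trend_fit"
  )
}

#' First two principal components as a trajectory surrogate
#'
#' A plumbing surrogate for an external trajectory embedding: returns the
#' first two PCs of the Z-scaled compartment so score-versus-component
#' trends can be fitted without any trajectory-inference dependency. This is
#' an ordinary PCA, not a trajectory method; treat the components as a
#' stand-in ordering only.
#'
#' @param norm Normalized genes-by-cells matrix (the compartment to embed).
#' @param genes Optional gene subset (defaults to all rows).
#' @return Cells-by-2 matrix of component coordinates.
#' @export
trajectory_surrogate <- function(norm, genes = rownames(norm)) {
  x <- as.matrix(norm[intersect(genes, rownames(norm)), , drop = FALSE])
  sdv <- apply(x, 1, stats::sd)
  x <- x[sdv > 0, , drop = FALSE]
  z <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  p <- stats::prcomp(t(z), center = FALSE, rank. = 2L)$x
  colnames(p) <- c("component1", "component2")
  p
}
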