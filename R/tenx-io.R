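#' Write a count experiment as a 10x-style MatrixMarket bundle
#'
#' Writes `matrix.mtx` (MatrixMarket triplet), `features.tsv`,
#' `barcodes.tsv`, and `cell_metadata.tsv` (barcode, sample_id, side, plus
#' `cell_type`/`cluster` when present) into `directory`. The bundle
#' round-trips losslessly through [read_tenx_like()].
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay and `colData`
#'   columns `sample_id` and `side`.
#' @param directory Output directory; created if missing.
#' @return `directory`, invisibly.
#' @export
write_tenx_like <- function(sce, directory) {
  stopifnot(methods::is(sce, "SingleCellExperiment"))
  counts <- SummarizedExperiment::assay(sce, "counts")
  barcodes <- colnames(sce)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes; refusing to write")
  if (any(!is.finite(counts@x))) stop("non-finite counts")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)

  Matrix::writeMM(counts, file.path(directory, "matrix.mtx"))
  writeLines(rownames(sce), file.path(directory, "features.tsv"))
  writeLines(barcodes, file.path(directory, "barcodes.tsv"))

  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  keep <- intersect(c("sample_id", "side", "cell_type", "cluster"), names(cd))
  meta <- cbind(data.frame(barcode = barcodes, stringsAsFactors = FALSE),
                cd[, keep, drop = FALSE])
  utils::write.table(meta, file.path(directory, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory)
}

#' Read a 10x-style MatrixMarket bundle
#'
#' Counterpart of [write_tenx_like()].
#'
#' @param directory Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and (optionally) `cell_metadata.tsv`.
#' @return A `SingleCellExperiment` with a sparse `counts` assay.
#' @export
read_tenx_like <- function(directory) {
  mtx <- file.path(directory, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", directory)
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- readLines(file.path(directory, "features.tsv"))
  barcodes <- readLines(file.path(directory, "barcodes.tsv"))
  if (length(features) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop("features/barcodes do not match matrix dimensions")
  }
  dimnames(counts) <- list(features, barcodes)

  meta_path <- file.path(directory, "cell_metadata.tsv")
  cd <- if (file.exists(meta_path)) {
    m <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    stopifnot(identical(m$barcode, barcodes))
    S4Vectors::DataFrame(m[, setdiff(names(m), "barcode"), drop = FALSE],
                         row.names = barcodes)
  } else {
    S4Vectors::DataFrame(row.names = barcodes)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd
  )
}
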