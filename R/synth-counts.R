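#' Describe one simulated cell type
#'
#' A cell type is a cluster-generating program: a set of marker genes whose
#' expected expression is multiplied by the simulation's `marker_boost`, and a
#' baseline log-mean shared by all its non-marker genes.
#'
#' @param name Cluster/cell-type label.
#' @param marker_genes Character vector of marker gene names; must be
#'   non-empty and free of duplicates. Marker names become features of the
#'   simulated matrix, so real gene symbols (e.g. `"CCR7"`) can be planted.
#' @param baseline_logmean Log expected (unscaled) expression of non-marker
#'   genes for cells of this type. Default 0.
#' @return An object of class `cell_type_spec`.
#' @export
cell_type_spec <- function(name, marker_genes, baseline_logmean = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(marker_genes) == 0L) {
    stop("cell type '", name, "': marker_genes must be non-empty")
  }
  if (anyDuplicated(marker_genes)) {
    stop("cell type '", name, "': duplicated marker genes")
  }
  structure(
    list(
      name = name,
      marker_genes = as.character(marker_genes),
      baseline_logmean = as.numeric(baseline_logmean)
    ),
    class = "cell_type_spec"
  )
}

#' Configure the two-condition single-cell count simulator
#'
#' Defines a multi-sample, two-condition (left/right) 10x-style experiment.
#' Counts are drawn gene-wise from a negative binomial whose mean combines a
#' per-gene baseline, the cell type's program (markers boosted by
#' `marker_boost`), and a per-(sample, gene) log-normal random effect
#' emulating donor variation; each cell's gene means are then rescaled so
#' their sum equals the cell's log-normally drawn library size.
#'
#' @param n_genes Total number of features. Marker genes named in
#'   `cell_types` are included among them; the remainder are filler genes
#'   (`G0001`, ...).
#' @param cell_types List of [cell_type_spec()] objects.
#' @param composition Numeric matrix of expected cell-type fractions:
#'   rows = cell-type names, columns = sides (`"left"`, `"right"`). Each
#'   side's column must sum to 1 (tolerance 1e-9).
#' @param samples `data.frame` with columns `sample_id`, `side`
#'   (`"left"`/`"right"`), `n_cells`.
#' @param marker_boost Multiplicative expression factor (> 1) applied to a
#'   type's marker genes in cells of that type. Default 8.
#' @param library_size_mean Expected total counts per cell. Default 2500.
#' @param library_size_cv Coefficient of variation of the log-normal library
#'   size. Default 0.3; 0 gives every cell the same depth.
#' @param dispersion Negative-binomial overdispersion `phi`
#'   (variance = mu + phi * mu^2). 0 selects the Poisson limit.
#' @param sample_effect_sd SD of the per-(sample, gene) normal random effect
#'   on the log scale. Default 0.1.
#' @param gene_logmean_sd SD of the per-gene baseline log-mean spread (makes
#'   non-marker genes heterogeneous, so variance-based feature selection has
#'   structure to find). Default 1.
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes,
                              cell_types,
                              composition,
                              samples,
                              marker_boost = 8,
                              library_size_mean = 2500,
                              library_size_cv = 0.3,
                              dispersion = 0.5,
                              sample_effect_sd = 0.1,
                              gene_logmean_sd = 1,
                              seed = 1L) {
  stopifnot(is.list(cell_types), length(cell_types) >= 1L)
  if (!all(vapply(cell_types, inherits, logical(1), "cell_type_spec"))) {
    stop("cell_types must be a list of cell_type_spec objects")
  }
  type_names <- vapply(cell_types, `[[`, character(1), "name")
  if (anyDuplicated(type_names)) stop("duplicated cell type names")

  composition <- as.matrix(composition)
  if (is.null(rownames(composition)) || is.null(colnames(composition))) {
    stop("composition must have cell types as rownames and sides as colnames")
  }
  bad_side <- setdiff(colnames(composition), c("left", "right"))
  if (length(bad_side)) {
    stop("unknown side label in composition: ", paste(bad_side, collapse = ", "))
  }
  if (!setequal(rownames(composition), type_names)) {
    stop("composition rows must match cell type names")
  }
  composition <- composition[type_names, , drop = FALSE]
  for (s in colnames(composition)) {
    tot <- sum(composition[, s])
    if (abs(tot - 1) > 1e-9) {
      stop("composition for side '", s, "' sums to ", format(tot), ", not 1")
    }
    if (any(composition[, s] < 0)) stop("negative fraction for side '", s, "'")
  }

  samples <- as.data.frame(samples)
  stopifnot(all(c("sample_id", "side", "n_cells") %in% names(samples)))
  bad <- setdiff(unique(samples$side), c("left", "right"))
  if (length(bad)) stop("unknown side label in samples: ", paste(bad, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id")
  stopifnot(all(samples$n_cells >= 1))

  markers <- unique(unlist(lapply(cell_types, `[[`, "marker_genes")))
  if (n_genes < length(markers)) {
    stop("n_genes (", n_genes, ") smaller than the number of distinct marker genes (",
         length(markers), ")")
  }
  stopifnot(marker_boost > 0, library_size_mean > 0, library_size_cv >= 0,
            dispersion >= 0, sample_effect_sd >= 0, gene_logmean_sd >= 0)

  structure(
    list(
      n_genes = as.integer(n_genes),
      cell_types = cell_types,
      composition = composition,
      samples = samples,
      marker_boost = marker_boost,
      library_size_mean = library_size_mean,
      library_size_cv = library_size_cv,
      dispersion = dispersion,
      sample_effect_sd = sample_effect_sd,
      gene_logmean_sd = gene_logmean_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# feature universe of a config: marker genes first, then numbered fillers
sim_features <- function(config) {
  markers <- unique(unlist(lapply(config$cell_types, `[[`, "marker_genes")))
  n_fill <- config$n_genes - length(markers)
  fillers <- if (n_fill > 0) sprintf("G%04d", seq_len(n_fill)) else character(0)
  c(markers, fillers)
}

#' Simulate a 10x-style count experiment
#'
#' Draws each cell's type from its sample side's composition row, then draws
#' gene counts from the negative-binomial model described in
#' [simulation_config()]. Deterministic given the config's seed.
#'
#' @param config A [simulation_config()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay, `colData` columns `sample_id`, `side`,
#'   `cell_type` (the ground-truth label), and
#'   `metadata(sce)$realized_composition` — the realized cell-type-by-sample
#'   count table.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  features <- sim_features(config)
  n_genes <- config$n_genes
  type_names <- vapply(config$cell_types, `[[`, character(1), "name")
  n_cells_total <- sum(config$samples$n_cells)

  # per-gene baseline spread, shared across types and samples
  gene_base <- stats::rnorm(n_genes, 0, config$gene_logmean_sd)

  # per-type unscaled mean profile (before sample effect)
  type_logmean <- matrix(gene_base, n_genes, length(type_names),
                         dimnames = list(features, type_names))
  for (ct in config$cell_types) {
    type_logmean[, ct$name] <- type_logmean[, ct$name] + ct$baseline_logmean
    idx <- match(ct$marker_genes, features)
    type_logmean[idx, ct$name] <- type_logmean[idx, ct$name] + log(config$marker_boost)
  }

  # per-(sample, gene) donor effect
  sample_ids <- as.character(config$samples$sample_id)
  sample_eff <- matrix(
    if (config$sample_effect_sd > 0)
      stats::rnorm(n_genes * length(sample_ids), 0, config$sample_effect_sd)
    else 0,
    n_genes, length(sample_ids), dimnames = list(features, sample_ids)
  )

  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  meanlog <- log(config$library_size_mean) - sdlog^2 / 2

  blocks <- vector("list", nrow(config$samples))
  meta <- vector("list", nrow(config$samples))
  for (i in seq_len(nrow(config$samples))) {
    smp <- config$samples[i, ]
    side <- as.character(smp$side)
    n_c <- smp$n_cells
    probs <- config$composition[, side]
    cell_type <- sample(type_names, n_c, replace = TRUE, prob = probs)
    lib <- if (config$library_size_cv > 0) {
      stats::rlnorm(n_c, meanlog, sdlog)
    } else {
      rep(config$library_size_mean, n_c)
    }

    cnt <- matrix(0L, n_genes, n_c)
    for (tn in unique(cell_type)) {
      j <- which(cell_type == tn)
      mu_gene <- exp(type_logmean[, tn] + sample_eff[, as.character(smp$sample_id)])
      mu_gene <- mu_gene / sum(mu_gene)
      mu <- outer(mu_gene, lib[j])          # genes x cells in this block
      draws <- if (config$dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      } else {
        stats::rpois(length(mu), lambda = mu)
      }
      cnt[, j] <- draws
    }
    blocks[[i]] <- cnt
    meta[[i]] <- data.frame(
      sample_id = rep(as.character(smp$sample_id), n_c),
      side = rep(side, n_c),
      cell_type = cell_type,
      stringsAsFactors = FALSE
    )
  }

  counts <- do.call(cbind, blocks)
  cd <- do.call(rbind, meta)
  barcodes <- sprintf("%s_cell%05d", cd$sample_id,
                      stats::ave(seq_len(nrow(cd)), cd$sample_id, FUN = seq_along))
  dimnames(counts) <- list(features, barcodes)

  realized <- table(cell_type = cd$cell_type, sample_id = cd$sample_id)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")),
    colData = S4Vectors::DataFrame(cd, row.names = barcodes)
  )
  S4Vectors::metadata(sce)$realized_composition <- realized
  S4Vectors::metadata(sce)$config_seed <- config$seed
  sce
}
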