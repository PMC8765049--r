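# shared fixtures: small simulation configs used across test files

two_type_config <- function(n_cells_per_side = 100, n_genes = 300,
                            marker_boost = 12, seed = 42,
                            frac_a = c(left = 0.5, right = 0.5), ...) {
  types <- list(
    cell_type_spec("typeA", c("MA1", "MA2", "MA3", "MA4", "MA5")),
    cell_type_spec("typeB", c("MB1", "MB2", "MB3", "MB4", "MB5"))
  )
  comp <- rbind(typeA = frac_a, typeB = 1 - frac_a)
  samples <- data.frame(
    sample_id = c("L1", "R1"), side = c("left", "right"),
    n_cells = n_cells_per_side, stringsAsFactors = FALSE
  )
  simulation_config(n_genes = n_genes, cell_types = types, composition = comp,
                    samples = samples, marker_boost = marker_boost,
                    seed = seed, ...)
}

# T-cell program fixture: an exhausted-like and a naive-like population
program_config <- function(n_cells_per_side = 150, seed = 11) {
  types <- list(
    cell_type_spec("exhausted", c("PDCD1", "CTLA4", "LAG3", "HAVCR2", "TIGIT",
                                  "GZMB", "PRF1", "GNLY", "NKG7")),
    cell_type_spec("naive", c("CCR7", "TCF7", "LEF1", "SELL"))
  )
  comp <- rbind(exhausted = c(left = 0.5, right = 0.5),
                naive = c(left = 0.5, right = 0.5))
  samples <- data.frame(sample_id = c("L1", "R1"), side = c("left", "right"),
                        n_cells = n_cells_per_side, stringsAsFactors = FALSE)
  simulation_config(n_genes = 400, cell_types = types, composition = comp,
                    samples = samples, marker_boost = 10, seed = seed)
}

logcounts_of <- function(sce) {
  normalize_log_cp10k(SummarizedExperiment::assay(sce, "counts"))
}

# rank-based AUROC of scores for separating positives from negatives
auroc <- function(score_pos, score_neg) {
  r <- rank(c(score_pos, score_neg))
  n1 <- length(score_pos); n2 <- length(score_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
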