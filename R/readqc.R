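#' Sliding-window quality trim
#'
#' Scans the read 5' to 3' with a `window`-base wide sliding window (step 1)
#' and cuts at the start of the first window whose mean Phred quality drops
#' below `threshold`. Windows that would extend past the 3' end are not
#' evaluated.
#'
#' @param qualities Integer vector of per-base Phred scores.
#' @param window Window width (>= 1). Default 4.
#' @param threshold Mean-quality cutoff; a window with mean `< threshold`
#'   triggers the cut. Default 10.
#' @return Retained 5' prefix length (0 for an empty read or an immediately
#'   failing first window).
#' @export
sliding_window_trim <- function(qualities, window = 4L, threshold = 10) {
  stopifnot(window >= 1L)
  n <- length(qualities)
  if (n == 0L) return(0L)
  if (n < window) return(n)
  cs <- c(0, cumsum(as.numeric(qualities)))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  fail <- which(means < threshold)
  if (length(fail) == 0L) n else fail[1L] - 1L
}

#' Trim trailing low-quality or N bases
#'
#' Removes the maximal 3' suffix in which every base either has quality below
#' `min_q` or is an `N`.
#'
#' @param bases Base string (A/C/G/T/N).
#' @param qualities Integer Phred vector, same length as `bases`.
#' @param min_q Quality threshold; bases with quality `< min_q` are trimmable.
#'   Default 3.
#' @return Retained length.
#' @export
trim_trailing <- function(bases, qualities, min_q = 3L) {
  n <- nchar(bases)
  stopifnot(length(qualities) == n)
  if (n == 0L) return(0L)
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  bad <- qualities < min_q | ch %in% c("N", "n")
  keep <- n
  while (keep > 0L && bad[keep]) keep <- keep - 1L
  keep
}

#' Remove a 3' adapter by exact match or terminal prefix overlap
#'
#' Truncates at the leftmost exact occurrence of the full adapter; failing
#' that, at the longest exact adapter *prefix* of at least `min_overlap`
#' bases that ends flush with the read's 3' end.
#'
#' @param bases Base string.
#' @param adapter Non-empty adapter sequence.
#' @param min_overlap Minimum terminal prefix-overlap length. Default 3.
#' @return Retained length (full length when no match).
#' @export
remove_adapter <- function(bases, adapter, min_overlap = 3L) {
  stopifnot(nchar(adapter) >= 1L)
  n <- nchar(bases)
  if (n == 0L) return(0L)
  hit <- regexpr(adapter, bases, fixed = TRUE)
  if (hit > 0L) return(as.integer(hit) - 1L)
  max_ov <- min(n, nchar(adapter) - 1L)
  if (max_ov >= min_overlap) {
    for (ov in max_ov:min_overlap) {
      if (substr(bases, n - ov + 1L, n) == substr(adapter, 1L, ov)) {
        return(n - ov)
      }
    }
  }
  n
}

# apply the per-mate trimming cascade; returns retained length
qc_keep_length <- function(bases, qualities, adapter = NULL,
                           window = 4L, window_q = 10, trail_q = 3L,
                           min_overlap = 3L) {
  keep <- sliding_window_trim(qualities, window, window_q)
  bases <- substr(bases, 1L, keep)
  qualities <- qualities[seq_len(keep)]
  keep <- trim_trailing(bases, qualities, trail_q)
  bases <- substr(bases, 1L, keep)
  if (!is.null(adapter) && nzchar(adapter) && keep > 0L) {
    keep <- remove_adapter(bases, adapter, min_overlap)
  }
  keep
}

read_fastq_pairs <- function(path) {
  # the reader warns about dropped metadata columns on plain FASTQ; benign
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(
    ids = names(x),
    bases = as.character(x),
    quals = as.list(methods::as(Biostrings::quality(x), "IntegerList"))
  )
}

write_fastq <- function(ids, bases, quals, path) {
  qs <- vapply(quals, function(q) {
    rawToChar(as.raw(as.integer(q) + 33L))
  }, character(1))
  seqs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(bases),
    Biostrings::PhredQuality(qs)
  )
  names(seqs) <- ids
  Biostrings::writeQualityScaledXStringSet(
    seqs, path, compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Run the five-step paired-end read quality control
#'
#' Per mate, in order: (a) sliding-window quality trim, (b) trailing
#' low-quality/N removal, (c) adapter removal, then (d) drop mates shorter
#' than `min_len` bases and (e) discard any pair with a dropped mate.
#' Quality encoding is Phred+33.
#'
#' @param in1,in2 Paths to the mate-1 and mate-2 FASTQ files (plain or .gz).
#' @param out1,out2 Optional output FASTQ paths for surviving pairs.
#' @param adapter Adapter sequence, or `NULL` to skip adapter removal (no
#'   default adapter is assumed).
#' @param window,window_q Sliding-window width and mean-quality threshold.
#' @param trail_q Trailing-base quality threshold.
#' @param min_len Minimum retained mate length; shorter mates sink the pair.
#'   Default 26.
#' @param min_overlap Minimum terminal adapter-prefix overlap.
#' @return A `qc_report` list: pair counts in/out, per-mate drop counts,
#'   per-step total trimmed bases, and the logical survival vector.
#' @export
run_read_qc <- function(in1, in2, out1 = NULL, out2 = NULL, adapter = NULL,
                        window = 4L, window_q = 10, trail_q = 3L,
                        min_len = 26L, min_overlap = 3L) {
  r1 <- read_fastq_pairs(in1)
  r2 <- read_fastq_pairs(in2)
  n1 <- length(r1$ids); n2 <- length(r2$ids)
  if (n1 != n2) {
    stop("mismatched pair files: ", n1, " records in ", in1, " vs ", n2,
         " in ", in2, "; first unmatched record at offset ", min(n1, n2) + 1L)
  }

  trim_mate <- function(r) {
    keep <- integer(n1)
    steps <- c(window = 0, trailing = 0, adapter = 0)
    for (i in seq_len(n1)) {
      b <- r$bases[i]; q <- r$quals[[i]]; n0 <- nchar(b)
      k1 <- sliding_window_trim(q, window, window_q)
      k2 <- trim_trailing(substr(b, 1L, k1), q[seq_len(k1)], trail_q)
      k3 <- if (!is.null(adapter) && nzchar(adapter) && k2 > 0L) {
        remove_adapter(substr(b, 1L, k2), adapter, min_overlap)
      } else k2
      steps["window"] <- steps["window"] + (n0 - k1)
      steps["trailing"] <- steps["trailing"] + (k1 - k2)
      steps["adapter"] <- steps["adapter"] + (k2 - k3)
      keep[i] <- k3
    }
    list(keep = keep, steps = steps)
  }
  t1 <- trim_mate(r1)
  t2 <- trim_mate(r2)

  ok1 <- t1$keep >= min_len
  ok2 <- t2$keep >= min_len
  survive <- ok1 & ok2

  if (!is.null(out1)) {
    idx <- which(survive)
    write_fastq(r1$ids[idx], substr(r1$bases[idx], 1L, t1$keep[idx]),
                lapply(idx, function(i) r1$quals[[i]][seq_len(t1$keep[i])]), out1)
    write_fastq(r2$ids[idx], substr(r2$bases[idx], 1L, t2$keep[idx]),
                lapply(idx, function(i) r2$quals[[i]][seq_len(t2$keep[i])]), out2)
  }

  structure(
    list(
      n_pairs_in = n1,
      n_pairs_out = sum(survive),
      n_mate1_dropped = sum(!ok1),
      n_mate2_dropped = sum(!ok2),
      bases_trimmed_mate1 = t1$steps,
      bases_trimmed_mate2 = t2$steps,
      survive = survive,
      params = list(window = window, window_q = window_q, trail_q = trail_q,
                    min_len = min_len, min_overlap = min_overlap,
                    adapter = adapter)
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Paired-end read QC\n")
  cat("  pairs in:  ", x$n_pairs_in, "\n")
  cat("  pairs out: ", x$n_pairs_out,
      sprintf(" (%.1f%%)\n", 100 * x$n_pairs_out / max(1, x$n_pairs_in)))
  cat("  mate1 dropped:", x$n_mate1_dropped,
      " mate2 dropped:", x$n_mate2_dropped, "\n")
  invisible(x)
}

#' Write a QC report as a two-column TSV
#'
#' @param report A `qc_report` from [run_read_qc()].
#' @param path Output TSV path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("n_pairs_in", "n_pairs_out", "n_mate1_dropped", "n_mate2_dropped",
               paste0("mate1_trimmed_", names(report$bases_trimmed_mate1)),
               paste0("mate2_trimmed_", names(report$bases_trimmed_mate2))),
    value = c(report$n_pairs_in, report$n_pairs_out, report$n_mate1_dropped,
              report$n_mate2_dropped, unname(report$bases_trimmed_mate1),
              unname(report$bases_trimmed_mate2))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
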