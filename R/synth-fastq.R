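#' Generate a paired FASTQ fixture with known QC ground truth
#'
#' Emits paired-end FASTQ files in which each mate belongs to one of four
#' planted classes, chosen with probabilities `class_probs`:
#'
#' * `clean` — full-length high-quality read; survives QC.
#' * `low_tail` — last `tail_len` bases at `tail_quality`; the sliding-window
#'   trim removes the tail but the remainder stays at or above the minimum
#'   length, so the mate survives.
#' * `adapter_early` — a full adapter copy planted so the retained prefix is
#'   shorter than the minimum length; the mate is dropped.
#' * `garbage` — every base at `tail_quality`; trimmed to length 0, dropped.
#'
#' Survival of a *pair* (both mates in a surviving class) is therefore known
#' by construction, without running the QC code: the truth sidecar is written
#' from the planted classes.
#'
#' @param n_pairs Number of read pairs.
#' @param out1,out2 Output FASTQ paths (`.gz` honored).
#' @param truth_path Optional path for the truth sidecar TSV (per-pair mate
#'   classes and expected survival).
#' @param length_range Integer read-length interval; the lower bound must be
#'   at least `min_len + tail_len` so a trimmed `low_tail` mate still
#'   survives. Default `c(80, 100)`.
#' @param class_probs Named probabilities over
#'   `clean`/`low_tail`/`adapter_early`/`garbage`. Default
#'   `c(0.55, 0.2, 0.15, 0.1)`.
#' @param adapter Adapter sequence to plant. Default `"AGATCGGAAGAGC"`.
#' @param base_quality,tail_quality Phred scores (in \[0, 41\]) of good and
#'   planted-bad bases. Defaults 38 and 2.
#' @param tail_len Length of the planted low-quality tail. Default 10.
#' @param min_len Minimum surviving mate length assumed by the design.
#'   Default 26.
#' @param seed Integer seed.
#' @return Invisibly, a `data.frame` with `pair_id`, `class1`, `class2`,
#'   `survives`; the same table is written to `truth_path` when given.
#' @export
generate_read_fixture <- function(n_pairs, out1, out2, truth_path = NULL,
                                  length_range = c(80L, 100L),
                                  class_probs = c(clean = 0.55, low_tail = 0.2,
                                                  adapter_early = 0.15,
                                                  garbage = 0.1),
                                  adapter = "AGATCGGAAGAGC",
                                  base_quality = 38L, tail_quality = 2L,
                                  tail_len = 10L, min_len = 26L,
                                  seed = 1L) {
  stopifnot(n_pairs >= 1L, length(length_range) == 2L)
  if (length_range[1] < 1L) stop("length_range lower bound must be >= 1")
  if (length_range[1] < min_len + tail_len) {
    stop("length_range lower bound must be at least min_len + tail_len (",
         min_len + tail_len, ") so trimmed low_tail reads survive")
  }
  stopifnot(base_quality >= 0, base_quality <= 41,
            tail_quality >= 0, tail_quality <= 41)
  if (tail_quality >= 10) {
    stop("tail_quality must be below the window threshold of 10 to plant ",
         "trimmable tails")
  }
  classes <- c("clean", "low_tail", "adapter_early", "garbage")
  stopifnot(setequal(names(class_probs), classes))
  set.seed(seed)

  rand_bases <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }
  make_mate <- function(cls) {
    len <- sample(length_range[1]:length_range[2], 1L)
    if (cls == "clean") {
      list(b = rand_bases(len), q = rep(base_quality, len))
    } else if (cls == "low_tail") {
      list(b = rand_bases(len),
           q = c(rep(base_quality, len - tail_len), rep(tail_quality, tail_len)))
    } else if (cls == "adapter_early") {
      pre <- sample(0:(min_len - 1L), 1L)   # retained prefix < min_len
      b <- paste0(rand_bases(pre), adapter,
                  rand_bases(max(0L, len - pre - nchar(adapter))))
      list(b = b, q = rep(base_quality, nchar(b)))
    } else {
      list(b = rand_bases(len), q = rep(tail_quality, len))
    }
  }

  cls1 <- sample(classes, n_pairs, replace = TRUE, prob = class_probs[classes])
  cls2 <- sample(classes, n_pairs, replace = TRUE, prob = class_probs[classes])
  ok <- c(clean = TRUE, low_tail = TRUE, adapter_early = FALSE, garbage = FALSE)

  ids <- sprintf("pair%05d", seq_len(n_pairs))
  m1 <- lapply(cls1, make_mate)
  m2 <- lapply(cls2, make_mate)
  write_fastq(paste0(ids, "/1"), vapply(m1, `[[`, character(1), "b"),
              lapply(m1, `[[`, "q"), out1)
  write_fastq(paste0(ids, "/2"), vapply(m2, `[[`, character(1), "b"),
              lapply(m2, `[[`, "q"), out2)

  truth <- data.frame(pair_id = ids, class1 = cls1, class2 = cls2,
                      survives = unname(ok[cls1] & ok[cls2]),
                      stringsAsFactors = FALSE)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(truth)
}
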