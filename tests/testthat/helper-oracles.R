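# independent reference implementations used only to check the package

# --- per-read QC hand-trace: plain loops, no shared code with the package ---

oracle_window_trim <- function(q, window = 4, threshold = 10) {
  n <- length(q)
  if (n < window) return(n)
  for (i in seq_len(n - window + 1)) {
    if (mean(q[i:(i + window - 1)]) < threshold) return(i - 1)
  }
  n
}

oracle_trailing <- function(ch, q, min_q = 3) {
  keep <- length(ch)
  while (keep > 0) {
    if (q[keep] < min_q || ch[keep] == "N" || ch[keep] == "n") {
      keep <- keep - 1
    } else {
      break
    }
  }
  keep
}

oracle_adapter <- function(ch, adapter, min_overlap = 3) {
  n <- length(ch)
  a <- strsplit(adapter, "")[[1]]
  la <- length(a)
  for (start in seq_len(max(0, n - la + 1))) {
    if (all(ch[start:(start + la - 1)] == a)) return(start - 1)
  }
  if (n >= min_overlap) {
    for (ov in min(n, la - 1):min_overlap) {
      if (ov < min_overlap) break
      if (all(ch[(n - ov + 1):n] == a[seq_len(ov)])) return(n - ov)
    }
  }
  n
}

oracle_mate_keep <- function(bases, quals, adapter) {
  ch <- strsplit(bases, "")[[1]]
  k <- oracle_window_trim(quals)
  ch <- ch[seq_len(k)]; quals <- quals[seq_len(k)]
  k <- oracle_trailing(ch, quals)
  ch <- ch[seq_len(k)]
  if (!is.null(adapter) && length(ch) > 0) {
    k <- oracle_adapter(ch, adapter)
  }
  k
}

# survival of each pair in two FASTQ files, traced read by read
oracle_qc_survival <- function(in1, in2, adapter, min_len = 26) {
  parse_fq <- function(path) {
    ln <- readLines(path)
    list(bases = ln[seq(2, length(ln), by = 4)],
         quals = lapply(ln[seq(4, length(ln), by = 4)], function(s) {
           as.integer(charToRaw(s)) - 33L
         }))
  }
  f1 <- parse_fq(in1); f2 <- parse_fq(in2)
  vapply(seq_along(f1$bases), function(i) {
    k1 <- oracle_mate_keep(f1$bases[i], f1$quals[[i]], adapter)
    k2 <- oracle_mate_keep(f2$bases[i], f2$quals[[i]], adapter)
    k1 >= min_len && k2 >= min_len
  }, logical(1))
}

# --- exact Wilcoxon two-sided p by subset enumeration (recursive, no combn) ---

oracle_wilcox_exact <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n <- length(r)
  e_s <- n1 * (n + 1) / 2
  s_obs <- sum(r[seq_len(n1)])
  sums <- c()
  pick <- function(start, left, acc) {
    if (left == 0) {
      sums <<- c(sums, acc)
      return(invisible())
    }
    if (start > n) return(invisible())
    for (i in start:n) {
      if (n - i + 1 < left) break
      pick(i + 1, left - 1, acc + r[i])
    }
  }
  pick(1, n1, 0)
  mean(abs(sums - e_s) >= abs(s_obs - e_s) - 1e-9)
}

# --- hypergeometric upper tail by enumeration of all hit draws ---

oracle_ora_p <- function(universe_size, set_size, n_hits, overlap) {
  draws <- utils::combn(universe_size, n_hits)
  in_set <- draws <= set_size   # wlog the set is elements 1..set_size
  mean(colSums(in_set) >= overlap)
}

# --- Pearson correlation from first principles ---

oracle_pearson <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}
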