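# Independent oracles used across the suite. Each is deliberately naive
# (enumeration / all-pairs) and never shares code with the package paths
# it checks.

# Subset-counting table for the hypergeometric: W[j+1, s+1] = number of
# j-subsets of an N-item population (K of them successes) containing s
# successes. Built by processing items one at a time — an enumeration
# collapsed by dynamic programming, no binomial coefficients involved.
subset_count_table <- function(N, K) {
  W <- matrix(0, N + 1, K + 1)
  W[1, 1] <- 1
  for (i in seq_len(N)) {
    for (j in rev(seq_len(i))) {
      if (i <= K) {
        W[j + 1, 2:(K + 1)] <- W[j + 1, 2:(K + 1)] + W[j, 1:K, drop = FALSE]
      } else {
        W[j + 1, ] <- W[j + 1, ] + W[j, ]
      }
    }
  }
  W
}

# Upper-tail mid-p by counting draws: P(X > k) + 0.5 P(X = k).
hypergeom_midp_oracle <- function(k, n_draws, K, N, table = NULL) {
  if (is.null(table)) table <- subset_count_table(N, K)
  row <- table[n_draws + 1, ]
  s <- seq_along(row) - 1
  (sum(row[s > k]) + 0.5 * sum(row[s == k])) / sum(row)
}

# Literal enumeration over combn() draws, used to validate the DP table
# on small populations.
hypergeom_midp_combn <- function(k, n_draws, K, N) {
  draws <- utils::combn(N, n_draws)
  succ <- colSums(draws <= K)  # first K items are the successes
  mean(succ > k) + 0.5 * mean(succ == k)
}

# Two-sided exact Wilcoxon rank-sum p by full enumeration of group
# assignments (doubled smaller tail, capped at 1).
wilcoxon_p_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  sums <- combn(length(pooled), nx, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
}

# All-pairs overlap quantification: the brute-force counterpart of
# annotate_overlaps on 0-based half-open intervals.
overlap_raw_oracle <- function(cohort, genes) {
  raw <- matrix(0L, nrow(genes), length(cohort),
                dimnames = list(genes$symbol, names(cohort)))
  for (s in names(cohort)) {
    rec <- cohort[[s]]
    for (i in seq_len(nrow(rec))) {
      for (gidx in seq_len(nrow(genes))) {
        if (rec$chrom[i] == genes$chrom[gidx] &&
            rec$start[i] < genes$end[gidx] &&
            genes$start[gidx] < rec$end[i]) {
          raw[gidx, s] <- raw[gidx, s] + rec$split_reads[i]
        }
      }
    }
  }
  raw
}

# Random single-sample record table for coalescing/filter properties.
random_records <- function(n, seed, sample_id = "S1") {
  set.seed(seed)
  chrom <- sample(paste0("chr", 1:3), n, replace = TRUE)
  start <- sample.int(2000, n, replace = TRUE)
  len <- sample.int(500, n, replace = TRUE) + 49L
  ecc_records(sample_id, chrom, start, start + len,
              sample.int(5, n, replace = TRUE))
}

# Canonical row order for comparing record tables regardless of input order.
canon <- function(df) {
  df <- df[order(df$chrom, df$start, df$end, df$split_reads), , drop = FALSE]
  rownames(df) <- NULL
  df
}
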