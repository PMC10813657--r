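#' Coalesce breakpoint-jittered circle calls
#'
#' Split-read callers emit near-duplicate circle calls whose breakpoints
#' jitter by a few base pairs. Within one sample, records on the same
#' chromosome are linked when both their start and their end coordinates
#' differ by less than `d_min`; clusters are the transitive closure
#' (single linkage) of that relation. Each cluster is replaced by a single
#' record taking the coordinates of the member with the most split reads
#' (ties broken by smallest start, then smallest end) and the sum of the
#' members' split reads, so total split-read support is conserved exactly.
#'
#' @param records eccDNA records from a single sample.
#' @param d_min Linkage distance in bp (default 10).
#' @return Merged eccDNA records, sorted by chromosome, start, end.
#' @export
merge_clusters <- function(records, d_min = 10L) {
  stopifnot(d_min >= 0)
  if (nrow(records) == 0L) return(records)
  if (length(unique(records$sample_id)) > 1L)
    stop("merge_clusters expects records from a single sample")
  merged <- lapply(split(records, records$chrom), function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    n <- nrow(df)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    # starts are sorted: every linkable pair sits inside a d_min window
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && df$start[j] - df$start[i] < d_min) {
        if (abs(df$end[j] - df$end[i]) < d_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
        j <- j + 1L
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    rows <- lapply(unname(split(seq_len(n), comp)), function(m) {
      sub <- df[m, , drop = FALSE]
      rep_i <- order(-sub$split_reads, sub$start, sub$end)[1L]
      out <- sub[rep_i, , drop = FALSE]
      out$split_reads <- sum(sub$split_reads)
      out
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, merged)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter merged circle records
#'
#' Applies, in order: the split-read support filter (drop records with
#' fewer than `min_split_reads` post-merge split reads), the chromosome
#' exclusion list (mitochondrial circles by default), and the small-circle
#' length cutoff (records strictly longer than `max_circle_len` are
#' dropped; a record exactly at the cutoff is kept). Record order is
#' otherwise preserved and an empty result is allowed.
#'
#' @param records Merged eccDNA records.
#' @param config A [pipeline_config()].
#' @return The surviving records.
#' @export
apply_filters <- function(records, config = pipeline_config()) {
  keep <- records$split_reads >= config$min_split_reads &
    !(records$chrom %in% config$excluded_chroms) &
    records$length <= config$max_circle_len
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preprocess one sample: coalesce then filter
#' @param records Raw eccDNA records from one sample.
#' @param config A [pipeline_config()].
#' @return Filtered, merged records.
#' @export
preprocess_sample <- function(records, config = pipeline_config()) {
  apply_filters(merge_clusters(records, config$d_min), config)
}

#' Per-group summaries of unique eccDNA counts
#'
#' The per-sample count of unique eccDNAs (post-merge, post-filter records)
#' is the classical circulome group comparator; each group is summarised by
#' its mean and the standard error of the mean (sd/sqrt(n)).
#'
#' @param cohort Named list of (filtered) record data.frames, one per sample.
#' @param groups Named character vector mapping every sample id to a group.
#' @return A data.frame with one row per group: group, n_samples, mean, sem,
#'   and a list-column per_sample_counts.
#' @export
sample_counts <- function(cohort, groups) {
  missing <- setdiff(names(cohort), names(groups))
  if (length(missing))
    stop("samples without a group assignment: ", paste(missing, collapse = ", "))
  counts <- vapply(cohort, nrow, integer(1))
  grp <- as.character(groups[names(cohort)])
  by_group <- split(counts, grp)
  out <- data.frame(group = names(by_group),
                    n_samples = lengths(by_group),
                    mean = vapply(by_group, mean, numeric(1)),
                    sem = vapply(by_group, function(x) {
                      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  out$per_sample_counts <- unname(by_group)
  rownames(out) <- NULL
  out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact permutation p-value when the combined sample size is at most 16
#' and the data are tie-free; otherwise the normal approximation with tie
#' and continuity correction. Two-sided throughout.
#'
#' @param x,y Non-empty numeric vectors (e.g. per-sample circle counts).
#' @return A list with `statistic` (the Mann-Whitney W for `x`) and
#'   `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 16L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Ratio of group means
#' @param x,y Numeric vectors; returns mean(x)/mean(y).
#' @return The fold ratio of the means.
#' @export
mean_fold_ratio <- function(x, y) {
  if (mean(y) <= 0) stop("denominator group mean must be positive")
  mean(x) / mean(y)
}

#' Cumulative length-frequency curves per group
#'
#' For each sample, the cumulative percentage of circle lengths less than
#' or equal to each bin edge; per group, the mean curve and a per-bin
#' standard-deviation band. Samples with zero circles have no defined
#' curve and are skipped with a warning.
#'
#' @param cohort Named list of (filtered) record data.frames.
#' @param groups Named character vector sample id -> group.
#' @param bin_edges Strictly increasing vector of length edges in bp; the
#'   last edge should reach the circle-length cutoff so curves end at 100.
#' @return A list per group: group, bin_edges, per_sample matrix
#'   (samples x bins, percent), mean_curve, sd_band.
#' @export
length_cdf <- function(cohort, groups,
                       bin_edges = c(100, 200, 300, 400, 500, 750, 1000,
                                     2000, 5000, 10000)) {
  stopifnot(all(diff(bin_edges) > 0))
  empty <- names(cohort)[vapply(cohort, nrow, integer(1)) == 0L]
  if (length(empty)) {
    warning("samples with zero circles skipped: ", paste(empty, collapse = ", "))
    cohort <- cohort[setdiff(names(cohort), empty)]
  }
  curves <- t(vapply(cohort, function(rec) {
    vapply(bin_edges, function(e) 100 * mean(rec$length <= e), numeric(1))
  }, numeric(length(bin_edges))))
  colnames(curves) <- bin_edges
  grp <- groups[rownames(curves)]
  lapply(stats::setNames(unique(grp), unique(grp)), function(g) {
    m <- curves[grp == g, , drop = FALSE]
    list(group = g, bin_edges = bin_edges, per_sample = m,
         mean_curve = colMeans(m),
         sd_band = apply(m, 2, stats::sd))
  })
}
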