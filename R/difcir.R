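#' Call differentially produced per-gene eccDNAs (DPpGCs)
#'
#' The DifCir selection: for every gene, a two-sample Student's t-test
#' (pooled variance, two-sided) compares the PpGC values of group A against
#' group B. A gene is selected as a DPpGC when the absolute difference of
#' the group means (the log2 fold change, since PpGCs live on the log2
#' scale) is at least `theta_dppgc` and the p-value is at most
#' `alpha_dppgc`. The direction is the group with the higher mean; within
#' each direction genes are ranked by ascending p-value, ties broken by
#' descending absolute fold change, then alphabetically.
#'
#' Genes with zero raw counts in all samples of both groups are excluded
#' before testing. Genes with zero variance in both groups are degenerate
#' for the t statistic: their p-value is set to 0 when the means differ
#' (flagged "degenerate") and to 1 when they do not.
#'
#' @param mat A `ppgc_matrix` (or a plain numeric genes x samples matrix of
#'   PpGC values).
#' @param groups Named character vector mapping sample ids to groups.
#' @param group_a,group_b The two group labels to compare (defaults: the
#'   first two labels in `groups`).
#' @param config A [pipeline_config()] supplying `theta_dppgc` and
#'   `alpha_dppgc`.
#' @param welch Use the Welch (unequal-variance) test instead of the
#'   classical pooled-variance test. Default FALSE.
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   and applied to the selection p-values; "none" (default) reproduces
#'   raw-p selection.
#' @return A list with `up_in_a` and `up_in_b` (ranked selected records)
#'   and `full_table` (per-gene statistics for every tested gene):
#'   columns symbol, mean_a, mean_b, delta, p_value, neglog10_p,
#'   direction, degenerate, selected, rank.
#' @export
call_dppgc <- function(mat, groups, group_a = NULL, group_b = NULL,
                       config = pipeline_config(), welch = FALSE,
                       adjust = "none") {
  if (inherits(mat, "ppgc_matrix")) {
    values <- mat$values
    raw <- mat$raw
  } else {
    values <- mat
    raw <- mat
  }
  groups <- groups[intersect(colnames(values), names(groups))]
  labels <- unique(as.character(groups))
  if (is.null(group_a)) group_a <- labels[1]
  if (is.null(group_b)) group_b <- labels[2]
  a_cols <- names(groups)[groups == group_a]
  b_cols <- names(groups)[groups == group_b]
  na <- length(a_cols); nb <- length(b_cols)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 samples (", group_a, ": ", na,
         ", ", group_b, ": ", nb, ")")

  keep <- rowSums(raw[, c(a_cols, b_cols), drop = FALSE]) > 0
  va <- values[keep, a_cols, drop = FALSE]
  vb <- values[keep, b_cols, drop = FALSE]

  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  delta <- mean_a - mean_b
  var_a <- apply(va, 1, stats::var)
  var_b <- apply(vb, 1, stats::var)

  if (welch) {
    se <- sqrt(var_a / na + var_b / nb)
    df <- (var_a / na + var_b / nb)^2 /
      ((var_a / na)^2 / (na - 1) + (var_b / nb)^2 / (nb - 1))
  } else {
    s2 <- ((na - 1) * var_a + (nb - 1) * var_b) / (na + nb - 2)
    se <- sqrt(s2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  }
  degenerate <- se == 0
  tstat <- ifelse(degenerate, NA_real_, delta / se)
  p <- ifelse(degenerate,
              ifelse(delta == 0, 1, 0),
              2 * stats::pt(-abs(tstat), df))
  p_sel <- stats::p.adjust(p, method = adjust)

  tab <- data.frame(symbol = rownames(va),
                    mean_a = mean_a, mean_b = mean_b, delta = delta,
                    t = tstat, p_value = p,
                    neglog10_p = -log10(p),
                    direction = ifelse(delta >= 0, "up_in_a", "up_in_b"),
                    degenerate = degenerate & delta != 0,
                    stringsAsFactors = FALSE)
  tab$selected <- abs(tab$delta) >= config$theta_dppgc &
    p_sel <= config$alpha_dppgc
  rownames(tab) <- NULL

  rank_within <- function(df) {
    if (nrow(df) == 0L) { df$rank <- integer(0); return(df) }
    o <- order(df$p_value, -abs(df$delta), df$symbol)
    df <- df[o, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    df
  }
  up_a <- rank_within(tab[tab$selected & tab$delta > 0, , drop = FALSE])
  up_b <- rank_within(tab[tab$selected & tab$delta < 0, , drop = FALSE])
  tab$rank <- NA_integer_
  tab$rank[match(up_a$symbol, tab$symbol)] <- up_a$rank
  tab$rank[match(up_b$symbol, tab$symbol)] <- up_b$rank
  list(up_in_a = up_a, up_in_b = up_b, full_table = tab,
       group_a = group_a, group_b = group_b)
}

#' Write a DPpGC table as TSV
#' @param dppgc Result of [call_dppgc()].
#' @param path Output path.
#' @param full Write the full per-gene table (default) or only selected
#'   DPpGCs.
#' @export
write_dppgc_table <- function(dppgc, path, full = TRUE) {
  tab <- if (full) dppgc$full_table else
    rbind(dppgc$up_in_a, dppgc$up_in_b)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
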