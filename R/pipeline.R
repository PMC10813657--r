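#' Run the full genic-profiling pipeline on a cohort
#'
#' Executes preprocess (coalesce + filter) per sample, quantification into
#' a PpGC matrix, the DifCir differential call for every configured group
#' pair in both directions, and the enrichment stage (chromosome
#' landscape; fragile-site over-representation when a CFS table is
#' supplied). All stages are deterministic given the inputs. When
#' `out_dir` is given, every stage writes its TSV there together with a
#' run manifest recording the configuration and L_Max.
#'
#' @param cohort Named list of raw per-sample eccDNA record tables.
#' @param manifest Data.frame with columns sample_id, group (see
#'   [read_manifest()]); every cohort sample must appear.
#' @param genes Gene-model data.frame.
#' @param config A [pipeline_config()].
#' @param cfs Optional fragile-site table for set enrichment.
#' @param homologs Optional homolog map used with `cfs`.
#' @param comparisons Optional list of c(group_a, group_b) pairs; default:
#'   every ordered pair of distinct groups (each unordered pair once —
#'   both directions are contained in one DifCir result).
#' @param out_dir Optional output directory for stage TSVs.
#' @return A list: filtered cohort, counts summary, ppgc matrix, dppgc
#'   results per comparison, enrichment results per comparison and
#'   direction, summary table of CFS percentages per direction.
#' @export
run_pipeline <- function(cohort, manifest, genes,
                         config = pipeline_config(),
                         cfs = NULL, homologs = NULL,
                         comparisons = NULL, out_dir = NULL) {
  if (!all(names(cohort) %in% manifest$sample_id))
    stop("cohort samples missing from the manifest: ",
         paste(setdiff(names(cohort), manifest$sample_id), collapse = ", "))
  groups <- stats::setNames(manifest$group, manifest$sample_id)[names(cohort)]
  glabels <- unique(unname(groups))
  if (length(glabels) < 2L) stop("pipeline needs at least 2 groups")
  if (is.null(comparisons))
    comparisons <- utils::combn(glabels, 2, simplify = FALSE)

  filtered <- lapply(cohort, preprocess_sample, config = config)
  counts <- sample_counts(filtered, groups)
  raw <- annotate_overlaps(filtered, genes)
  ppgc <- ppgc_matrix(raw, genes)

  universe <- rownames(raw)[rowSums(raw) > 0]
  all_records <- do.call(rbind, filtered)

  dppgc <- list(); enrich <- list(); summary_rows <- list()
  for (cmp in comparisons) {
    key <- paste(cmp[1], "vs", cmp[2])
    res <- call_dppgc(ppgc, groups, group_a = cmp[1], group_b = cmp[2],
                      config = config)
    dppgc[[key]] <- res
    for (dir_label in c("a", "b")) {
      up <- if (dir_label == "a") res$up_in_a else res$up_in_b
      up_group <- if (dir_label == "a") cmp[1] else cmp[2]
      e <- list(
        chromosome = if (nrow(up) > 0)
          chromosome_enrichment(up$symbol, all_records, genes) else NULL)
      if (!is.null(cfs)) {
        ann <- annotate_cfs(up$symbol, cfs, homologs)
        target <- attr(annotate_cfs(universe, cfs, homologs), "pooled")
        e$cfs_annotation <- ann
        e$cfs <- set_enrichment(up$symbol, universe, target,
                                label = paste0(key, " up-in-", up_group),
                                alpha = config$alpha_cfs)
        summary_rows[[paste(key, up_group)]] <- data.frame(
          comparison = key, up_in = up_group,
          n_dppgc = nrow(up), n_cfs = e$cfs$k,
          percentage = e$cfs$percentage, mid_p = e$cfs$mid_p,
          stars = e$cfs$stars, stringsAsFactors = FALSE)
      } else {
        summary_rows[[paste(key, up_group)]] <- data.frame(
          comparison = key, up_in = up_group,
          n_dppgc = nrow(up), n_cfs = NA_integer_,
          percentage = NA_real_, mid_p = NA_real_, stars = "",
          stringsAsFactors = FALSE)
      }
      enrich[[paste(key, "up-in", up_group)]] <- e
    }
  }
  summary <- do.call(rbind, unname(summary_rows))

  out <- list(filtered = filtered, counts = counts, ppgc = ppgc,
              dppgc = dppgc, enrichment = enrich, summary = summary,
              groups = groups, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(res$filtered))
    write_eccdna_table(res$filtered[[s]],
                       file.path(out_dir, paste0(s, ".ecc.tsv")))
  counts <- res$counts
  counts$per_sample_counts <- vapply(counts$per_sample_counts,
                                     paste, "", collapse = ",")
  utils::write.table(counts, file.path(out_dir, "counts_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ppgc_matrix(res$ppgc, file.path(out_dir, "ppgc.tsv"))
  for (key in names(res$dppgc))
    write_dppgc_table(res$dppgc[[key]],
                      file.path(out_dir, paste0(gsub(" ", "_", key), ".dppgc.tsv")))
  for (key in names(res$enrichment)) {
    e <- res$enrichment[[key]]
    base <- gsub(" ", "_", key)
    if (!is.null(e$chromosome))
      utils::write.table(e$chromosome,
                         file.path(out_dir, paste0(base, ".chrom.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(e$cfs_annotation) && nrow(e$cfs_annotation))
      utils::write.table(e$cfs_annotation,
                         file.path(out_dir, paste0(base, ".cfs.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(res$summary, file.path(out_dir, "enrichment_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(
    sprintf("l_max\t%d", res$ppgc$l_max),
    sprintf("d_min\t%d", res$config$d_min),
    sprintf("min_split_reads\t%d", res$config$min_split_reads),
    sprintf("max_circle_len\t%d", res$config$max_circle_len),
    sprintf("excluded_chroms\t%s", paste(res$config$excluded_chroms, collapse = ",")),
    sprintf("theta_dppgc\t%g", res$config$theta_dppgc),
    sprintf("alpha_dppgc\t%g", res$config$alpha_dppgc),
    sprintf("seed\t%d", res$config$seed))
  writeLines(manifest, file.path(out_dir, "run_manifest.tsv"))
  invisible(out_dir)
}
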