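#' Sum split reads of circles over the genes they overlap
#'
#' A circle contributes its full split-read count to every gene it overlaps
#' by at least one base pair, with bedtools-intersect semantics on 0-based
#' half-open intervals (abutting intervals do not overlap). Genes never hit
#' get zero. No apportioning is done for circles spanning several genes:
#' each overlapped gene receives the full count.
#'
#' @param cohort Named list of filtered eccDNA record data.frames.
#' @param genes Gene-model data.frame ([gene_models()]).
#' @return An integer genes x samples matrix of unscaled per-gene
#'   split-read sums (unscaled PpGC).
#' @export
annotate_overlaps <- function(cohort, genes) {
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  raw <- matrix(0L, nrow = nrow(genes), ncol = length(cohort),
                dimnames = list(genes$symbol, names(cohort)))
  for (s in names(cohort)) {
    rec <- cohort[[s]]
    if (nrow(rec) == 0L) next
    gr <- GenomicRanges::GRanges(
      rec$chrom, IRanges::IRanges(rec$start + 1L, rec$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_genes, gr))
    if (length(hits)) {
      sums <- tapply(rec$split_reads[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits), sum)
      raw[as.integer(names(sums)), s] <- as.integer(sums)
    }
  }
  raw
}

#' Build the produced-per-gene-circle (PpGC) matrix
#'
#' Scales each gene's unscaled split-read sum by `L_Max / L_i`, where `L_i`
#' is the gene length and `L_Max` the length of the longest gene found in
#' the dataset (by default the longest gene with at least one split read),
#' then equalizes with the log2(x + 1) transform:
#' `values[i, s] = log2(raw[i, s] * L_Max / L_i + 1)`.
#'
#' @param raw Integer genes x samples matrix from [annotate_overlaps()].
#' @param genes Gene-model data.frame covering every row of `raw`.
#' @param l_max_mode "detected" takes L_Max over genes with a nonzero raw
#'   entry (the genes found in the dataset); "all" takes it over every
#'   annotated gene.
#' @return A list of class `ppgc_matrix`: genes, samples, raw, gene_lengths,
#'   l_max, values.
#' @export
ppgc_matrix <- function(raw, genes, l_max_mode = c("detected", "all")) {
  l_max_mode <- match.arg(l_max_mode)
  if (any(raw < 0)) stop("raw counts must be non-negative")
  L <- genes$length[match(rownames(raw), genes$symbol)]
  if (anyNA(L)) stop("genes missing from the annotation: ",
                     paste(utils::head(rownames(raw)[is.na(L)]), collapse = ", "))
  if (any(L == 0L)) stop("gene with zero length")
  detected <- rowSums(raw) > 0
  l_max <- if (l_max_mode == "detected" && any(detected))
    max(L[detected]) else max(L)
  values <- log2(raw * (l_max / L) + 1)
  structure(list(genes = rownames(raw), samples = colnames(raw),
                 raw = raw, gene_lengths = stats::setNames(L, rownames(raw)),
                 l_max = l_max, values = values),
            class = "ppgc_matrix")
}

#' @export
print.ppgc_matrix <- function(x, ...) {
  cat(sprintf("PpGC matrix: %d genes x %d samples (L_Max = %d bp, %d genes with circles)\n",
              length(x$genes), length(x$samples), x$l_max,
              sum(rowSums(x$raw) > 0)))
  invisible(x)
}

#' Write a PpGC matrix as TSV (genes in rows, samples in columns)
#' @param mat A `ppgc_matrix`.
#' @param path Output path.
#' @export
write_ppgc_matrix <- function(mat, path) {
  df <- data.frame(symbol = rownames(mat$values), mat$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
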