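#' Pipeline configuration
#'
#' Bundles every tunable threshold of the eccDNA genic-profiling pipeline.
#' Defaults follow the published analysis: circle calls whose breakpoints
#' jitter by less than `d_min` = 10 bp are coalesced, circles supported by
#' fewer than 2 split reads are dropped, mitochondrial circles are excluded,
#' 10 kb is the cutoff for small circles, and DPpGC selection uses a log2
#' fold-change threshold of 1 at significance level 0.05.
#'
#' @param d_min Coalescing distance in bp; circle calls on one chromosome
#'   whose start and end coordinates each differ by less than `d_min` are
#'   merged into one circle.
#' @param min_split_reads Minimum post-merge split-read support for a circle.
#' @param max_circle_len Maximum circle length in bp (strictly longer circles
#'   are dropped; a circle exactly at the cutoff is kept).
#' @param excluded_chroms Chromosome names removed before quantification.
#' @param theta_dppgc Log2 fold-change selection threshold for DPpGCs.
#' @param alpha_dppgc Significance level for the DifCir t-test.
#' @param alpha_cfs Significance level for fragile-site enrichment.
#' @param alpha_gwas Significance level for GWAS-trait enrichment.
#' @param seed Integer seed governing every stochastic operation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(d_min = 10L,
                            min_split_reads = 2L,
                            max_circle_len = 10000L,
                            excluded_chroms = "chrM",
                            theta_dppgc = 1,
                            alpha_dppgc = 0.05,
                            alpha_cfs = 0.05,
                            alpha_gwas = 0.05,
                            seed = 1L) {
  stopifnot(d_min >= 0, min_split_reads >= 0, max_circle_len > 0,
            theta_dppgc >= 0,
            alpha_dppgc > 0, alpha_dppgc < 1,
            alpha_cfs > 0, alpha_cfs < 1,
            alpha_gwas > 0, alpha_gwas < 1)
  structure(list(d_min = as.integer(d_min),
                 min_split_reads = as.integer(min_split_reads),
                 max_circle_len = as.integer(max_circle_len),
                 excluded_chroms = as.character(excluded_chroms),
                 theta_dppgc = theta_dppgc,
                 alpha_dppgc = alpha_dppgc,
                 alpha_cfs = alpha_cfs,
                 alpha_gwas = alpha_gwas,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Construct a table of eccDNA records
#'
#' One row per detected circle in one sample: a 0-based half-open genomic
#' interval plus the number of split reads supporting the circle junction.
#'
#' @param sample_id Sample identifier (recycled if length 1).
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval coordinates.
#' @param split_reads Positive integer split-read counts.
#' @return A data.frame with columns sample_id, chrom, start, end,
#'   split_reads, length.
#' @export
ecc_records <- function(sample_id, chrom, start, end, split_reads) {
  n <- length(chrom)
  if (length(sample_id) == 1L) sample_id <- rep(sample_id, n)
  start <- as.integer(start); end <- as.integer(end)
  split_reads <- as.integer(split_reads)
  if (any(is.na(start)) || any(is.na(end)) || any(is.na(split_reads)))
    stop("non-integer coordinates or split-read counts")
  if (any(start >= end)) stop("start must be < end for every record")
  if (any(split_reads < 1L)) stop("split_reads must be >= 1")
  data.frame(sample_id = as.character(sample_id),
             chrom = as.character(chrom),
             start = start, end = end,
             split_reads = split_reads,
             length = end - start,
             stringsAsFactors = FALSE)
}

#' Construct a table of gene models
#'
#' Named genomic intervals (0-based half-open) whose lengths `L_i` drive the
#' PpGC length scaling. Symbols must be unique within one annotation set.
#'
#' @param gene_id Stable gene identifiers.
#' @param symbol Gene symbols (unique).
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param strand "+", "-" or "." (read but never used by overlap logic).
#' @return A data.frame with columns gene_id, symbol, chrom, start, end,
#'   strand, length.
#' @export
gene_models <- function(gene_id, symbol, chrom, start, end, strand = ".") {
  n <- length(symbol)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (length(gene_id) == 1L && n > 1L) gene_id <- rep(gene_id, n)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("gene with non-positive length")
  if (anyDuplicated(symbol)) stop("duplicated gene symbols: ",
                                  paste(unique(symbol[duplicated(symbol)]), collapse = ", "))
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  data.frame(gene_id = as.character(gene_id),
             symbol = as.character(symbol),
             chrom = as.character(chrom),
             start = start, end = end,
             strand = strand,
             length = end - start,
             stringsAsFactors = FALSE)
}

# agents recognised in fragile-site tables (HumCFS vocabulary)
CFS_AGENTS <- c("aphidicolin", "folic acid", "BrdU", "5-azacytidine", "distamycinA")
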