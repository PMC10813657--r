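#' Upper-tail hypergeometric mid-p-value
#'
#' For X ~ Hypergeometric(N, K, n_draws), returns
#' `P(X > k) + 0.5 * P(X = k)` — the enrichment tail with the observed
#' outcome counted at half weight. The mid-p correction compensates the
#' conservativeness of discrete tail tests.
#'
#' @param k Observed successes among the draws.
#' @param n_draws Number of draws.
#' @param K Successes in the population.
#' @param N Population size.
#' @return The mid-p-value in (0, 1].
#' @export
hypergeom_midp <- function(k, n_draws, K, N) {
  if (any(k < 0 | k > pmin(n_draws, K) | n_draws > N | K > N | K < 0))
    stop("invalid hypergeometric query: need 0 <= k <= min(n_draws, K), n_draws <= N, K <= N")
  stats::phyper(k, K, N - K, n_draws, lower.tail = FALSE) +
    0.5 * stats::dhyper(k, K, N - K, n_draws)
}

#' Star labels for mid-p significance
#'
#' "" when p > 0.01; otherwise k stars for p in (10^-(k+2), 10^-(k+1)]:
#' one star for 0.01 >= p > 0.001, two for 0.001 >= p > 0.0001, and so on.
#'
#' @param p Probabilities in (0, 1].
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi) || pi > 0.01) return("")
    # nudge guards exact powers of ten sitting on a bracket boundary
    k <- floor(-log10(pi) + 1e-9) - 1L
    strrep("*", max(k, 1L))
  }, character(1))
}

#' Chromosome enrichment landscape from count vectors
#'
#' The statistical core of [chromosome_enrichment()], operating directly
#' on per-chromosome counts of DPpGC genes (`nd_c`) and eccDNAs (`n_c`).
#'
#' @param chroms Chromosome labels.
#' @param nd_c DPpGC genes per chromosome.
#' @param n_c eccDNAs per chromosome.
#' @return A data.frame: chrom, Nd_c, N_c, Nd_g, N_g, delta_c, mid_p, stars.
#' @export
chrom_landscape_from_counts <- function(chroms, nd_c, n_c) {
  nd_g <- sum(nd_c)
  n_g <- sum(n_c)
  delta_c <- 100 * (nd_c / n_c - nd_g / n_g)
  mid_p <- mapply(function(k, K) {
    k_adm <- min(k, nd_g, K)
    hypergeom_midp(k_adm, nd_g, K, n_g)
  }, nd_c, n_c)
  data.frame(chrom = chroms, Nd_c = nd_c, N_c = n_c,
             Nd_g = nd_g, N_g = n_g,
             delta_c = delta_c, mid_p = mid_p,
             stars = significance_stars(mid_p),
             stringsAsFactors = FALSE)
}

#' Chromosome landscape of DPpGC enrichment
#'
#' Per chromosome c, the enrichment percentage
#' `delta_c = 100 * (Nd_c/N_c - Nd_g/N_g)`, where Nd_c is the number of
#' DPpGC genes on c, N_c the number of eccDNAs on c, and Nd_g, N_g the
#' genome-wide totals. Positive values mark enrichment, negative depletion.
#' Significance comes from the upper-tail hypergeometric mid-p on the same
#' counts (population N_g, successes N_c, draws Nd_g, observed Nd_c), with
#' star labels attached. Chromosomes bearing no eccDNA are omitted.
#'
#' @param dppgc_genes Symbols of the selected DPpGCs.
#' @param eccdna_records Post-filter eccDNA records pooled over the cohort
#'   (a single data.frame or a list of per-sample data.frames).
#' @param genes Gene-model data.frame resolving each symbol to a chromosome.
#' @return A data.frame: chrom, Nd_c, N_c, Nd_g, N_g, delta_c, mid_p, stars.
#' @export
chromosome_enrichment <- function(dppgc_genes, eccdna_records, genes) {
  if (is.list(eccdna_records) && !is.data.frame(eccdna_records))
    eccdna_records <- do.call(rbind, eccdna_records)
  idx <- match(dppgc_genes, genes$symbol)
  if (anyNA(idx))
    stop("DPpGC gene absent from the gene models: ",
         paste(dppgc_genes[is.na(idx)], collapse = ", "))
  chroms <- sort(unique(eccdna_records$chrom))
  n_c <- vapply(chroms, function(cc) sum(eccdna_records$chrom == cc), integer(1))
  gene_chrom <- genes$chrom[idx]
  nd_c <- vapply(chroms, function(cc) sum(gene_chrom == cc), integer(1))
  chrom_landscape_from_counts(chroms, nd_c, n_c)
}

#' Over-representation of a gene set among hits
#'
#' Counts k = |hits ∩ target|, K = |universe ∩ target|, draws = |hits|,
#' N = |universe| and reports the hit percentage 100*k/|hits| together
#' with the upper-tail hypergeometric mid-p.
#'
#' @param hits Hit gene symbols (must lie within the universe).
#' @param universe Background gene symbols.
#' @param target_set Symbols of the annotated set (e.g. fragile-site genes).
#' @param label Category label carried into the result.
#' @param alpha Significance level used for the `significant` flag.
#' @return A one-row data.frame: label, k, n_draws, K, N, percentage,
#'   mid_p, stars, significant, flagged, plus a `members` attribute listing
#'   the hit symbols in the target.
#' @export
set_enrichment <- function(hits, universe, target_set, label = "set",
                           alpha = 0.05) {
  hits <- unique(hits); universe <- unique(universe)
  target_set <- unique(target_set)
  if (length(setdiff(hits, universe)))
    stop("hits outside the universe: ",
         paste(utils::head(setdiff(hits, universe)), collapse = ", "))
  K <- length(intersect(universe, target_set))
  N <- length(universe)
  members <- intersect(hits, target_set)
  k <- length(members)
  n_draws <- length(hits)
  if (n_draws == 0L) {
    out <- data.frame(label = label, k = 0L, n_draws = 0L, K = K, N = N,
                      percentage = 0, mid_p = 1, stars = "",
                      significant = FALSE, flagged = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    mid_p <- hypergeom_midp(k, n_draws, K, N)
    out <- data.frame(label = label, k = k, n_draws = n_draws, K = K, N = N,
                      percentage = 100 * k / n_draws, mid_p = mid_p,
                      stars = significance_stars(mid_p),
                      significant = mid_p <= alpha, flagged = FALSE,
                      stringsAsFactors = FALSE)
  }
  attr(out, "members") <- members
  out
}

#' Map gene symbols through a homolog table
#'
#' Case-insensitive lookup; a source symbol may map to several targets.
#' Unmapped symbols are dropped.
#'
#' @param symbols Query symbols.
#' @param homologs Homolog map data.frame (source_symbol, target_symbol),
#'   or NULL for identity.
#' @return A data.frame with columns source, target.
#' @export
map_homologs <- function(symbols, homologs = NULL) {
  if (is.null(homologs))
    return(data.frame(source = symbols, target = symbols,
                      stringsAsFactors = FALSE))
  m <- merge(data.frame(source = symbols, key = toupper(symbols),
                        stringsAsFactors = FALSE),
             data.frame(key = toupper(homologs$source_symbol),
                        target = homologs$target_symbol,
                        stringsAsFactors = FALSE),
             by = "key")
  unique(m[, c("source", "target")])
}

#' Annotate genes with chromosomal fragile sites
#'
#' Labels each query gene with the fragile sites (and inducing agents) of
#' its human counterpart: symbols are first sent through the homolog map
#' (identity when `homologs` is NULL), then matched case-insensitively
#' against the fragile-site table. Genes may collect several (cfs_id,
#' agent) labels; `pooled` is TRUE whenever at least one label exists.
#'
#' @param genes Query gene symbols.
#' @param cfs Fragile-site table (see [read_cfs_table()]).
#' @param homologs Optional homolog map for cross-species queries.
#' @return A data.frame with columns symbol, mapped_symbol, cfs_id, agent
#'   (one row per label; zero rows for unlabeled genes) plus a `pooled`
#'   attribute: the labeled query symbols.
#' @export
annotate_cfs <- function(genes, cfs, homologs = NULL) {
  mapped <- map_homologs(genes, homologs)
  hit <- merge(data.frame(symbol = mapped$source,
                          key = toupper(mapped$target),
                          mapped_symbol = mapped$target,
                          stringsAsFactors = FALSE),
               data.frame(key = toupper(cfs$gene_symbol),
                          cfs_id = cfs$cfs_id, agent = cfs$agent,
                          stringsAsFactors = FALSE),
               by = "key")
  out <- unique(hit[, c("symbol", "mapped_symbol", "cfs_id", "agent")])
  out <- out[order(match(out$symbol, genes), out$cfs_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pooled") <- unique(out$symbol)
  out
}

#' Intersect DPpGCs with a GWAS trait's mapped genes
#'
#' Filters the association table to rows whose trait equals `trait`
#' exactly, splits multi-gene mapped-gene cells on commas, semicolons and
#' " - ", and intersects with the query genes (homolog-mapped when a map
#' is supplied). Enrichment of the overlap is assessed against `universe`
#' with the hypergeometric mid-p.
#'
#' @param genes Query gene symbols.
#' @param gwas_table GWAS association table (see [read_gwas_table()]).
#' @param trait Exact trait string to select.
#' @param universe Background symbols for the enrichment test.
#' @param homologs Optional homolog map applied to `genes` first.
#' @param alpha Significance level.
#' @return A list: `common` (query symbols mapped into the trait's gene
#'   set), `trait_genes`, `enrichment` (a [set_enrichment()] row), and
#'   `flagged` when the trait is absent from the table.
#' @export
gwas_intersect <- function(genes, gwas_table, trait, universe,
                           homologs = NULL, alpha = 0.05) {
  rows <- gwas_table[gwas_table$trait == trait, , drop = FALSE]
  if (nrow(rows) == 0L)
    return(list(common = character(0), trait_genes = character(0),
                enrichment = NULL, flagged = TRUE))
  trait_genes <- unique(trimws(unlist(
    strsplit(rows$mapped_gene, ",|;| - "))))
  trait_genes <- trait_genes[nzchar(trait_genes)]
  mapped <- map_homologs(genes, homologs)
  common <- unique(mapped$source[toupper(mapped$target) %in% toupper(trait_genes)])
  hits_in_universe <- intersect(genes, universe)
  target <- if (is.null(homologs)) trait_genes else {
    back <- map_homologs(universe, homologs)
    unique(back$source[toupper(back$target) %in% toupper(trait_genes)])
  }
  enr <- set_enrichment(hits_in_universe, universe, target,
                        label = trait, alpha = alpha)
  list(common = common, trait_genes = trait_genes,
       enrichment = enr, flagged = FALSE)
}

#' Cross-species intersection of two DPpGC profiles
#'
#' Maps the species-A profile through the homolog table and keeps the
#' pairs whose target occurs in the species-B profile (case-insensitive),
#' deduplicated and reported in the rank order of `genes_a`.
#'
#' @param genes_a Ranked symbols from species A.
#' @param genes_b Symbols from species B.
#' @param homologs Homolog map covering the A -> B direction.
#' @return A data.frame of pairs (symbol_a, symbol_b).
#' @export
intersect_profiles <- function(genes_a, genes_b, homologs = NULL) {
  mapped <- map_homologs(genes_a, homologs)
  keep <- toupper(mapped$target) %in% toupper(genes_b)
  out <- unique(data.frame(symbol_a = mapped$source[keep],
                           symbol_b = mapped$target[keep],
                           stringsAsFactors = FALSE))
  out <- out[order(match(out$symbol_a, genes_a)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Over-representation of GMT gene sets among hits
#'
#' Runs [set_enrichment()] for every set in a GMT collection.
#'
#' @param hits Hit symbols.
#' @param universe Background symbols.
#' @param gene_sets Named list of symbol vectors (see [read_gmt()]).
#' @param alpha Significance level.
#' @return A data.frame with one [set_enrichment()] row per set, sorted by
#'   mid_p.
#' @export
gmt_enrichment <- function(hits, universe, gene_sets, alpha = 0.05) {
  rows <- lapply(names(gene_sets), function(nm)
    set_enrichment(hits, universe, gene_sets[[nm]], label = nm, alpha = alpha))
  out <- do.call(rbind, rows)
  out <- out[order(out$mid_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
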