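#' Simulation configuration for synthetic circulome cohorts
#'
#' Defines the study conditions the generator emulates: a two-group plasma
#' design (12 wild-type vs 11 knockout samples), a few hundred background
#' circles per sample with a nucleosome-footprint length profile (mixture
#' peaks near 180 and 360 bp), split-read support of 2 plus Poisson noise,
#' occasional near-duplicate calls with breakpoint jitter below the
#' coalescing distance, and a set of effect genes whose excision rate in
#' the knockout group is elevated by a fold multiplier over the local
#' background expectation.
#'
#' @param n_chroms Number of chromosomes.
#' @param genes_per_chrom Genes placed (non-overlapping) per chromosome.
#' @param gene_length_range Log-uniform bounds on gene length in bp.
#' @param n_samples_per_group Named counts for the two groups
#'   (default c(WT = 12, KO = 11)).
#' @param background_rate Expected background circles per sample.
#' @param effect_genes Number of planted effect genes.
#' @param effect_multiplier Fold elevation of per-gene excision in KO
#'   relative to the gene's background expectation.
#' @param length_mixture Truncated-normal mixture over circle lengths:
#'   list(means, sds, weights), truncated to [50, 10000] bp.
#' @param split_read_mean Expected split reads beyond the minimum of 2.
#' @param jitter_prob Probability a circle is emitted twice, the duplicate
#'   with start/end jitter strictly below `d_min`.
#' @param d_min Jitter magnitude bound in bp (matches the pipeline's
#'   coalescing distance).
#' @param cfs_fraction Fraction of genes labeled as fragile-site genes in
#'   the synthetic CFS table.
#' @param seed Integer master seed; per-sample substreams are derived by
#'   counter offset.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 5L,
                       genes_per_chrom = 40L,
                       gene_length_range = c(10000, 100000),
                       n_samples_per_group = c(WT = 12L, KO = 11L),
                       background_rate = 300,
                       effect_genes = 20L,
                       effect_multiplier = 8,
                       length_mixture = list(means = c(180, 360),
                                             sds = c(40, 60),
                                             weights = c(0.7, 0.3)),
                       split_read_mean = 1,
                       jitter_prob = 0.1,
                       d_min = 10L,
                       cfs_fraction = 0.15,
                       seed = 1L) {
  stopifnot(n_chroms > 0, genes_per_chrom > 0,
            length(gene_length_range) == 2, diff(gene_length_range) >= 0,
            all(n_samples_per_group > 0), length(n_samples_per_group) == 2,
            background_rate > 0, effect_genes >= 0, effect_multiplier >= 1,
            abs(sum(length_mixture$weights) - 1) < 1e-9,
            split_read_mean >= 0, jitter_prob >= 0, jitter_prob <= 1,
            d_min >= 1, cfs_fraction >= 0, cfs_fraction <= 1)
  if (is.null(names(n_samples_per_group)))
    names(n_samples_per_group) <- c("WT", "KO")
  structure(as.list(environment()), class = "sim_config")
}

# truncated-normal mixture sampler over [lo, hi]
sample_lengths <- function(n, mixture, lo = 50, hi = 10000) {
  if (n == 0L) return(integer(0))
  comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                     prob = mixture$weights)
  len <- stats::rnorm(n, mixture$means[comp], mixture$sds[comp])
  bad <- which(len < lo | len > hi)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    len[bad] <- stats::rnorm(length(bad), mixture$means[comp[bad]],
                             mixture$sds[comp[bad]])
    bad <- which(len < lo | len > hi)
    tries <- tries + 1L
  }
  len <- pmin(pmax(len, lo), hi)
  as.integer(round(len))
}

#' Simulate a genome with gene models and fragile-site labels
#'
#' Places non-overlapping genes with log-uniform lengths along each
#' chromosome, separated by exponential gaps, assigns a `cfs_fraction`
#' subset random fragile-site ids and inducing agents, and returns an
#' identity homolog map over the simulated symbols. Reproducible under the
#' configured seed.
#'
#' @param config A [sim_config()].
#' @return A list: `genes` (gene models), `chrom_lengths` (named bp
#'   vector), `cfs` (synthetic fragile-site table), `homologs` (identity
#'   map).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  lo <- config$gene_length_range[1]; hi <- config$gene_length_range[2]
  all_genes <- list()
  chrom_lengths <- integer(config$n_chroms)
  names(chrom_lengths) <- paste0("chr", seq_len(config$n_chroms))
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    g <- config$genes_per_chrom
    lens <- as.integer(round(exp(stats::runif(g, log(lo), log(hi)))))
    gaps <- as.integer(round(stats::rexp(g + 1L, rate = 1 / 20000)) + 1000L)
    starts <- cumsum(gaps[seq_len(g)]) + c(0L, cumsum(lens))[seq_len(g)]
    ends <- starts + lens
    if (any(starts >= ends)) stop("gene placement failed for lengths ", lo, "-", hi)
    sym <- sprintf("G%04d", gi + seq_len(g))
    gi <- gi + g
    all_genes[[ci]] <- gene_models(gene_id = paste0("SIM", sym), symbol = sym,
                                   chrom = names(chrom_lengths)[ci],
                                   start = starts, end = ends,
                                   strand = sample(c("+", "-"), g, replace = TRUE))
    chrom_lengths[ci] <- ends[g] + gaps[g + 1L]
  }
  genes <- do.call(rbind, all_genes)
  n_cfs <- floor(config$cfs_fraction * nrow(genes))
  cfs_genes <- if (n_cfs > 0) sort(sample(genes$symbol, n_cfs)) else character(0)
  cfs <- data.frame(gene_symbol = cfs_genes,
                    cfs_id = sprintf("FRA%s", seq_along(cfs_genes)),
                    chrom = genes$chrom[match(cfs_genes, genes$symbol)],
                    agent = if (n_cfs > 0)
                      sample(CFS_AGENTS, n_cfs, replace = TRUE) else character(0),
                    pooled = rep(TRUE, n_cfs),
                    stringsAsFactors = FALSE)
  list(genes = genes, chrom_lengths = chrom_lengths, cfs = cfs,
       homologs = identity_homolog_map(genes$symbol))
}

#' Simulate a two-group eccDNA cohort with planted effect genes
#'
#' For each sample, Poisson(background_rate) circles fall uniformly over
#' the genome (chromosome chosen proportional to its length) with lengths
#' from the truncated mixture and split reads 2 + Poisson(split_read_mean).
#' In knockout samples, each effect gene additionally emits
#' Poisson(lambda_i * effect_multiplier) circles inside its gene body,
#' where lambda_i = background_rate * L_i / genome_length is the gene's
#' background excision expectation — so the multiplier reads directly as a
#' rate fold change. With probability `jitter_prob` a circle is emitted a
#' second time with both breakpoints jittered by less than `d_min`,
#' exercising the coalescing step. Per-sample randomness flows through
#' substreams derived from the master seed by counter offset.
#'
#' @param config A [sim_config()].
#' @param genome Result of [simulate_genome()] under the same config.
#' @return A list: `cohort` (named list of per-sample record tables),
#'   `manifest` (sample_id, group, tissue, protocol), `truth`
#'   (effect_gene_symbols, per-sample provenance counts, cfs table).
#' @export
simulate_cohort <- function(config = sim_config(), genome = simulate_genome(config)) {
  genes <- genome$genes
  chrom_lengths <- genome$chrom_lengths
  genome_len <- sum(chrom_lengths)
  set.seed(config$seed + 997L)
  effect_syms <- if (config$effect_genes > 0)
    sort(sample(genes$symbol, config$effect_genes)) else character(0)
  eff <- genes[match(effect_syms, genes$symbol), , drop = FALSE]

  groups <- rep(names(config$n_samples_per_group), config$n_samples_per_group)
  sample_ids <- sprintf("%s%02d", groups,
                        unlist(lapply(config$n_samples_per_group, seq_len)))
  ko_label <- names(config$n_samples_per_group)[2]

  one_sample <- function(i) {
    set.seed(config$seed + 1000L + i)
    sid <- sample_ids[i]
    n_bg <- stats::rpois(1, config$background_rate)
    chrom <- sample(names(chrom_lengths), n_bg, replace = TRUE,
                    prob = chrom_lengths)
    len <- sample_lengths(n_bg, config$length_mixture)
    start <- as.integer(floor(stats::runif(n_bg) *
                                pmax(chrom_lengths[chrom] - len, 1)))
    origin <- rep("background", n_bg)
    if (groups[i] == ko_label && nrow(eff) > 0) {
      lambda <- config$background_rate * eff$length / genome_len *
        config$effect_multiplier
      n_pl <- stats::rpois(nrow(eff), lambda)
      if (sum(n_pl) > 0) {
        gidx <- rep(seq_len(nrow(eff)), n_pl)
        plen <- sample_lengths(sum(n_pl), config$length_mixture)
        room <- pmax(eff$length[gidx] - plen, 1L)
        pstart <- eff$start[gidx] +
          as.integer(floor(stats::runif(sum(n_pl)) * room))
        chrom <- c(chrom, eff$chrom[gidx])
        start <- c(start, pstart)
        len <- c(len, plen)
        origin <- c(origin, rep("planted", sum(n_pl)))
      }
    }
    n <- length(start)
    sr <- 2L + stats::rpois(n, config$split_read_mean)
    rec <- ecc_records(sid, chrom, start, start + len, sr)
    rec$origin <- origin
    dup <- which(stats::runif(n) < config$jitter_prob)
    if (length(dup)) {
      jmax <- config$d_min - 1L
      j1 <- sample(seq(-jmax, jmax), length(dup), replace = TRUE)
      j2 <- sample(seq(-jmax, jmax), length(dup), replace = TRUE)
      d <- rec[dup, , drop = FALSE]
      d$start <- pmax(d$start + j1, 0L)
      d$end <- d$end + j2
      d$length <- d$end - d$start
      d$split_reads <- 2L + stats::rpois(length(dup), config$split_read_mean)
      d$origin <- "jitter_duplicate"
      rec <- rbind(rec, d)
    }
    rec[order(rec$chrom, rec$start, rec$end), , drop = FALSE]
  }

  cohort <- stats::setNames(lapply(seq_along(sample_ids), one_sample),
                            sample_ids)
  provenance <- do.call(rbind, lapply(sample_ids, function(s) {
    tab <- table(factor(cohort[[s]]$origin,
                        levels = c("background", "planted", "jitter_duplicate")))
    data.frame(sample_id = s, background = tab[[1]], planted = tab[[2]],
               jitter_duplicate = tab[[3]], stringsAsFactors = FALSE)
  }))
  manifest <- data.frame(sample_id = sample_ids, group = groups,
                         tissue = "plasma", protocol = "Tn",
                         stringsAsFactors = FALSE)
  cohort <- lapply(cohort, function(df) {
    rownames(df) <- NULL
    df[, c("sample_id", "chrom", "start", "end", "split_reads", "length")]
  })
  list(cohort = cohort, manifest = manifest,
       truth = list(effect_gene_symbols = effect_syms,
                    provenance = provenance,
                    cfs = genome$cfs))
}
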