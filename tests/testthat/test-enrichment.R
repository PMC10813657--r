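test_that("mid-p examples match enumeration arithmetic", {
  expect_equal(hypergeom_midp(k = 4, n_draws = 4, K = 5, N = 10),
               2.5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_midp(k = 0, n_draws = 3, K = 0, N = 10), 0.5)
  expect_equal(hypergeom_midp(k = 10, n_draws = 10, K = 10, N = 20),
               0.5 / 184756, tolerance = 1e-15)
  expect_error(hypergeom_midp(5, 4, 5, 10), "invalid")
})

test_that("mid-p is the upper tail minus half the observed mass", {
  set.seed(9)
  for (i in 1:50) {
    N <- sample(5:200, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(hypergeom_midp(k, n, K, N),
                 upper - 0.5 * dhyper(k, K, N - K, n), tolerance = 1e-12)
  }
})

test_that("star labels follow the decade brackets", {
  expect_equal(significance_stars(c(0.5, 0.02, 0.011)), c("", "", ""))
  expect_equal(significance_stars(0.005), "*")
  expect_equal(significance_stars(0.01), "*")
  expect_equal(significance_stars(0.0005), "**")
  expect_equal(significance_stars(0.001), "**")
  expect_equal(significance_stars(0.0001), "***")
  expect_equal(significance_stars(3e-6), "****")
})

test_that("chromosome landscape computes delta_c from the count ratios", {
  rows <- chrom_landscape_from_counts(c("chr1", "chr2"),
                                      nd_c = c(2L, 2L), n_c = c(10L, 90L))
  expect_equal(rows$delta_c[1], 100 * (2 / 10 - 4 / 100))
  expect_equal(rows$delta_c[1], 16.0)
  expect_equal(rows$Nd_g, c(4L, 4L))

  uniform <- chrom_landscape_from_counts(paste0("chr", 1:4),
                                         nd_c = c(1L, 2L, 3L, 4L),
                                         n_c = c(10L, 20L, 30L, 40L))
  expect_equal(uniform$delta_c, rep(0, 4))

  single <- chrom_landscape_from_counts("chr1", 3L, 50L)
  expect_equal(single$delta_c, 0)
  expect_true(single$mid_p > 0 && single$mid_p <= 1)
})

test_that("chromosome enrichment resolves symbols and omits empty chromosomes", {
  genes <- gene_models(paste0("g", 1:4), c("A", "B", "C", "D"),
                       c("chr1", "chr1", "chr2", "chr3"),
                       c(0L, 100L, 0L, 0L), c(50L, 150L, 50L, 50L))
  rec <- ecc_records("S1", c(rep("chr1", 6), rep("chr2", 4)),
                     0:9 * 10L, 0:9 * 10L + 5L, 2L)
  rows <- chromosome_enrichment(c("A", "B", "C"), rec, genes)
  expect_equal(rows$chrom, c("chr1", "chr2"))  # chr3 has no eccDNA
  expect_equal(rows$Nd_c, c(2L, 1L))
  expect_equal(rows$N_c, c(6L, 4L))
  expect_error(chromosome_enrichment("Zz", rec, genes), "Zz")
})

test_that("set over-representation counts, percentages and flags", {
  universe <- sprintf("U%03d", 1:100)
  hits <- universe[1:13]
  target <- c(universe[1:2], universe[50:60])
  e <- set_enrichment(hits, universe, target)
  expect_equal(e$k, 2L)
  expect_equal(round(e$percentage, 2), 15.38)
  expect_equal(e$mid_p, hypergeom_midp(2, 13, 13, 100))

  disjoint <- set_enrichment(universe[1:5], universe, universe[90:95])
  expect_equal(disjoint$percentage, 0)
  expect_gte(disjoint$mid_p, 0.5)

  empty <- set_enrichment(character(0), universe, target)
  expect_true(empty$flagged)
  expect_equal(empty$mid_p, 1)

  shuffled <- set_enrichment(rev(hits), sample(universe), sample(target))
  expect_equal(shuffled$mid_p, e$mid_p)
  expect_error(set_enrichment("missing", universe, target), "outside")
})

test_that("fragile-site annotation maps homologs case-insensitively", {
  cfs <- data.frame(gene_symbol = c("DAB1", "DAB1", "KCNQ5"),
                    cfs_id = c("FRA1B", "FRA1C", "FRA6X"),
                    chrom = c("chr1", "chr1", "chr6"),
                    agent = c("aphidicolin", "folic acid", "BrdU"),
                    pooled = TRUE, stringsAsFactors = FALSE)
  hom <- data.frame(source_symbol = c("Dab1", "Kcnq5"),
                    target_symbol = c("DAB1", "KCNQ5"),
                    stringsAsFactors = FALSE)
  ann <- annotate_cfs(c("Dab1", "Gm123"), cfs, hom)
  expect_equal(nrow(ann), 2L)  # two (cfs_id, agent) labels for Dab1
  expect_setequal(ann$cfs_id, c("FRA1B", "FRA1C"))
  expect_equal(attr(ann, "pooled"), "Dab1")  # one pooled membership
  expect_false("Gm123" %in% ann$symbol)

  ident <- annotate_cfs("kcnq5", cfs)  # identity map, case-insensitive
  expect_equal(ann_id <- ident$cfs_id, "FRA6X")
})

test_that("GWAS intersection parses multi-gene cells and exact traits", {
  gwas <- data.frame(
    mapped_gene = c("JAZF1, TSPAN14", "DOCK10", "BACH2 - LOC1", "OTHER"),
    trait = c(rep("systemic lupus erythematosus", 3), "height"),
    stringsAsFactors = FALSE)
  universe <- c("JAZF1", "DOCK10", "BACH2", "X", sprintf("U%02d", 1:40))
  res <- gwas_intersect(c("JAZF1", "DOCK10", "BACH2", "X"), gwas,
                        "systemic lupus erythematosus", universe)
  expect_setequal(res$common, c("JAZF1", "DOCK10", "BACH2"))
  expect_true("TSPAN14" %in% res$trait_genes)
  expect_true("LOC1" %in% res$trait_genes)
  expect_equal(res$enrichment$k, 3L)

  absent <- gwas_intersect("JAZF1", gwas, "no such trait", universe)
  expect_true(absent$flagged)
  empty <- gwas_intersect(character(0), gwas,
                          "systemic lupus erythematosus", universe)
  expect_equal(empty$common, character(0))
})

test_that("cross-species profile intersection keeps rank order and dedups", {
  hom <- data.frame(source_symbol = c("Rorb", "Fto", "Fto", "Tnik"),
                    target_symbol = c("RORB", "FTO", "FTO2", "TNIK"),
                    stringsAsFactors = FALSE)
  pairs <- intersect_profiles(c("Tnik", "Rorb", "Fto", "Xyz"),
                              c("RORB", "TNIK", "FTO"), hom)
  expect_equal(pairs$symbol_a, c("Tnik", "Rorb", "Fto"))
  expect_equal(pairs$symbol_b, c("TNIK", "RORB", "FTO"))
  expect_equal(nrow(intersect_profiles("A", "B", NULL)), 0L)
  expect_equal(intersect_profiles("A", "A", NULL),
               data.frame(symbol_a = "A", symbol_b = "A",
                          stringsAsFactors = FALSE))
})

test_that("GMT over-representation ranks sets by mid-p", {
  universe <- sprintf("U%02d", 1:50)
  sets <- list(strong = universe[1:8], weak = universe[c(1, 30:36)])
  res <- gmt_enrichment(universe[1:8], universe, sets)
  expect_equal(res$label[1], "strong")
  expect_true(!is.unsorted(res$mid_p))
})
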