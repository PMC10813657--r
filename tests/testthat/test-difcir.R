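fake_ppgc <- function(values, raw = NULL) {
  if (is.null(raw)) raw <- (values > 0) + 0L
  structure(list(genes = rownames(values), samples = colnames(values),
                 raw = raw, gene_lengths = NULL, l_max = NA,
                 values = values), class = "ppgc_matrix")
}

random_ppgc <- function(n_genes, na, nb, seed) {
  set.seed(seed)
  v <- matrix(round(abs(rnorm(n_genes * (na + nb), 2, 1.5)), 3),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              c(paste0("A", seq_len(na)), paste0("B", seq_len(nb)))))
  groups <- setNames(rep(c("A", "B"), c(na, nb)), colnames(v))
  list(mat = fake_ppgc(v, raw = matrix(1L, n_genes, na + nb,
                                       dimnames = dimnames(v))),
       groups = groups)
}

test_that("the pooled-variance t selection matches the worked example", {
  v <- matrix(c(4, 5, 6, 1, 2, 3), nrow = 1,
              dimnames = list("G1", paste0("S", 1:6)))
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(v))
  res <- call_dppgc(fake_ppgc(v), groups, "A", "B")
  row <- res$full_table
  expect_equal(row$delta, 3)
  expect_equal(row$t, 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(row$p_value, 0.0213, tolerance = 1e-3)
  expect_equal(res$up_in_a$symbol, "G1")
  expect_equal(nrow(res$up_in_b), 0L)
})

test_that("the per-gene test agrees with stats::t.test to 1e-10", {
  rp <- random_ppgc(50, 4, 5, seed = 21)
  res <- call_dppgc(rp$mat, rp$groups, "A", "B")
  for (i in seq_len(20)) {
    g <- res$full_table$symbol[i]
    tt <- t.test(rp$mat$values[g, 1:4], rp$mat$values[g, 5:9],
                 var.equal = TRUE)
    expect_equal(res$full_table$p_value[res$full_table$symbol == g],
                 tt$p.value, tolerance = 1e-10)
  }
  resw <- call_dppgc(rp$mat, rp$groups, "A", "B", welch = TRUE)
  g <- resw$full_table$symbol[1]
  ttw <- t.test(rp$mat$values[g, 1:4], rp$mat$values[g, 5:9])
  expect_equal(resw$full_table$p_value[resw$full_table$symbol == g],
               ttw$p.value, tolerance = 1e-10)
})

test_that("duplicating one group into both yields no selections", {
  v <- matrix(rnorm(40, 3), nrow = 10,
              dimnames = list(sprintf("G%02d", 1:10), paste0("S", 1:4)))
  v2 <- cbind(v, v)
  colnames(v2) <- paste0("S", 1:8)
  groups <- setNames(rep(c("A", "B"), each = 4), colnames(v2))
  res <- call_dppgc(fake_ppgc(abs(v2)), groups, "A", "B")
  expect_equal(nrow(res$up_in_a), 0L)
  expect_equal(nrow(res$up_in_b), 0L)
  expect_true(all(res$full_table$delta == 0))
})

test_that("swapping group labels mirrors the selection exactly", {
  rp <- random_ppgc(200, 5, 6, seed = 33)
  ab <- call_dppgc(rp$mat, rp$groups, "A", "B")
  ba <- call_dppgc(rp$mat, rp$groups, "B", "A")
  expect_equal(ab$up_in_a$symbol, ba$up_in_b$symbol)
  expect_equal(ab$up_in_b$symbol, ba$up_in_a$symbol)
  merged <- merge(ab$full_table, ba$full_table, by = "symbol")
  expect_equal(merged$delta.x, -merged$delta.y)
  expect_equal(merged$p_value.x, merged$p_value.y)
})

test_that("selection is monotone in both thresholds", {
  rp <- random_ppgc(200, 4, 4, seed = 55)
  sel <- function(theta, alpha) {
    cfg <- pipeline_config(theta_dppgc = theta, alpha_dppgc = alpha)
    res <- call_dppgc(rp$mat, rp$groups, "A", "B", config = cfg)
    c(res$up_in_a$symbol, res$up_in_b$symbol)
  }
  base <- sel(0.5, 0.1)
  expect_true(all(sel(1.0, 0.1) %in% base))
  expect_true(all(sel(0.5, 0.02) %in% base))
  expect_true(all(sel(1.5, 0.01) %in% sel(1.0, 0.05)))
})

test_that("degenerate zero-variance genes get the prescribed p-values", {
  v <- matrix(c(rep(2, 3), rep(0, 3),   # constant, differing means
                rep(1, 6)),             # constant, equal means
              nrow = 2, byrow = TRUE,
              dimnames = list(c("G1", "G2"), paste0("S", 1:6)))
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(v))
  res <- call_dppgc(fake_ppgc(v, raw = matrix(1L, 2, 6, dimnames = dimnames(v))),
                    groups, "A", "B")
  tab <- res$full_table
  expect_equal(tab$p_value[tab$symbol == "G1"], 0)
  expect_true(tab$degenerate[tab$symbol == "G1"])
  expect_equal(tab$p_value[tab$symbol == "G2"], 1)
  expect_false(tab$degenerate[tab$symbol == "G2"])
})

test_that("all-zero genes are excluded and small groups rejected", {
  v <- matrix(c(1, 2, 1, 2, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("G1", "G0"), paste0("S", 1:4)))
  raw <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
                dimnames = dimnames(v))
  groups <- setNames(rep(c("A", "B"), each = 2), colnames(v))
  res <- call_dppgc(fake_ppgc(v, raw), groups, "A", "B")
  expect_equal(res$full_table$symbol, "G1")
  expect_error(call_dppgc(fake_ppgc(v, raw), groups[1:3], "A", "B"),
               "at least 2 samples")
})

test_that("ranking is by p, then |fold change|, then symbol", {
  v <- matrix(c(9, 9.1, 8.9, 1, 1.1, 0.9,    # strong effect
                5, 5.4, 4.9, 2, 2.2, 1.9,    # weaker
                6, 6.4, 5.9, 3, 3.2, 2.9),   # same stats as row 2, later name
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Gc", "Ga", "Gb"), paste0("S", 1:6)))
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(v))
  res <- call_dppgc(fake_ppgc(v, matrix(1L, 3, 6, dimnames = dimnames(v))),
                    groups, "A", "B")
  up <- res$up_in_a
  expect_equal(up$rank, seq_len(nrow(up)))
  expect_true(!is.unsorted(up$p_value))
  ties <- duplicated(up$p_value) | duplicated(up$p_value, fromLast = TRUE)
  if (any(ties)) {
    tied <- up[ties, ]
    expect_true(all(diff(-abs(tied$delta)) >= 0))
  }
})
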