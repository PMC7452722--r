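mk_records <- function(n, te, expr = NULL) {
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             tpm_input = if (is.null(expr)) rep(10, n) else expr,
             tpm_ip = 1, log2te = te, stringsAsFactors = FALSE)
}

test_that("TE is zero for equal abundances and invariant to IP depth", {
  set.seed(21)
  lens <- sample(500:3000, 30)
  cnt <- matrix(rpois(120, 500), 30, 4,
                dimnames = list(sprintf("g%04d", 1:30), NULL))
  te_same <- compute_te(cnt, cnt, lens, pseudocount = 0)
  expect_true(all(abs(te_same$log2te) < 1e-12))
  ip <- matrix(rpois(120, 300), 30, 4, dimnames = dimnames(cnt))
  te1 <- compute_te(cnt, ip, lens)
  te2 <- compute_te(cnt, ip * 5, lens)
  expect_equal(te1$log2te, te2$log2te, tolerance = 1e-12)
})

test_that("vectorized TPM/TE equals the naive per-gene loop oracle", {
  set.seed(22)
  lens <- sample(500:3000, 25)
  cnt <- matrix(rpois(100, 400), 25, 4,
                dimnames = list(sprintf("g%04d", 1:25), NULL))
  ip <- matrix(rpois(100, 250), 25, 4, dimnames = dimnames(cnt))
  got <- compute_te(cnt, ip, lens)
  want <- oracle_te(cnt, ip, lens)
  expect_equal(got$log2te, want$log2te[match(got$gene_id, want$gene_id)],
               tolerance = 1e-9)
})

test_that("expression floor removes unexpressed genes", {
  lens <- rep(1000, 5)
  cnt <- matrix(c(0, 1, 100, 100, 100), 5, 2,
                dimnames = list(sprintf("g%d", 1:5), NULL))
  te <- compute_te(cnt, cnt, lens, expression_floor = 1)
  expect_false("g1" %in% te$gene_id)
})

test_that("ten distinct genes split exactly 3/4/3", {
  r <- bin_translome(mk_records(10, te = (1:10) / 2,
                                expr = 10 + 1:10))
  expect_equal(as.vector(table(r$te_bin)), c(3, 4, 3))
  expect_equal(as.vector(table(r$expr_bin)), c(3, 4, 3))
})

test_that("the 30/40/30 split holds within one gene of target on random input", {
  set.seed(23)
  for (n in c(11, 57, 100, 501)) {
    r <- bin_translome(mk_records(n, te = rnorm(n), expr = rlnorm(n, 3)))
    tab <- table(r$te_bin)
    expect_lte(abs(tab[["low"]] - 0.3 * n), 1)
    expect_lte(abs(tab[["medium"]] - 0.4 * n), 1)
    expect_lte(abs(tab[["high"]] - 0.3 * n), 1)
    # categories conserve the expressed-gene count
    expect_equal(sum(table(r$category)), n)
    expect_true(all(r$category %in% 1:9))
  }
})

test_that("a constant ranking variable puts every gene in medium", {
  r <- bin_translome(mk_records(40, te = rep(1.5, 40),
                                expr = rlnorm(40, 3)))
  expect_true(all(r$te_bin == "medium"))
})

test_that("bins are invariant under monotone transformation of the ranking variable", {
  set.seed(24)
  rec <- mk_records(90, te = rnorm(90), expr = rlnorm(90, 3))
  r1 <- bin_translome(rec)
  rec2 <- rec
  rec2$log2te <- exp(rec$log2te)          # strictly increasing transform
  r2 <- bin_translome(rec2)
  expect_identical(r1$te_bin, r2$te_bin)
  expect_identical(r1$category, r2$category)
})

test_that("category numbering follows the high-TE-first grid", {
  r <- bin_translome(mk_records(10, te = (1:10) / 2, expr = 10 + 1:10))
  g1 <- r[r$te_bin == "high" & r$expr_bin == "high", ]
  expect_true(all(g1$category == 1))
  g9 <- r[r$te_bin == "low" & r$expr_bin == "low", ]
  expect_true(all(g9$category == 9))
  g4 <- r[r$te_bin == "medium" & r$expr_bin == "high", ]
  expect_true(all(g4$category == 4))
})

test_that("TE rises with 3'UTR length when that association is planted", {
  set.seed(25)
  n <- 400
  utr3 <- sample(c(100, 700, 1500, 3000), n, replace = TRUE) +
    sample(0:200, n, replace = TRUE)
  te <- 0.4 * log2(utr3 / 500) + rnorm(n, sd = 0.5)
  rec <- mk_records(n, te = te)
  lens <- setNames(utr3, rec$gene_id)
  out <- te_by_utr3(rec, lens)
  s <- out$summary
  expect_equal(which.max(s$mean_log2te), nrow(s))   # >2 kb bin on top
  expect_lt(out$pairwise_p[1, nrow(s)], 0.05)
  # permuted lengths break the association in >= 90% of reshuffles
  null_p <- replicate(20, {
    out0 <- te_by_utr3(rec, setNames(sample(utr3), rec$gene_id))
    min(out0$pairwise_p, na.rm = TRUE)
  })
  expect_gte(mean(null_p > 0.05 / 6), 0.7)
  # a single bin degenerates to the global mean
  one <- te_by_utr3(rec, lens, length_edges = numeric(0))
  expect_equal(one$summary$mean_log2te, mean(rec$log2te))
})

test_that("NMD magnitude couples to TE only in the well-translated group", {
  fx <- fx_bulk()
  truth <- fx$g$truth
  wt <- fx$b$sample_sheet$sample[fx$b$sample_sheet$genotype == "WT"]
  te <- compute_te(fx$b$exonic[, wt],
                   fx$b$ip[, grepl("^WT", colnames(fx$b$ip))],
                   fx$b$gene_lengths)
  de_truth <- data.frame(gene_id = truth$gene_id,
                         log2fc = truth$planted_log2fc,
                         padj = ifelse(truth$is_upregulated, 1e-6, 0.9))
  up <- truth$gene_id[truth$is_upregulated]
  r <- nmd_magnitude_vs_te(de_truth, te, up, mode = "correlation")
  expect_gte(r$high$r_squared, 0.4)
  expect_lte(r$low$r_squared, 0.1)
  # the most-translated tertile shifts more than the least-translated
  bn <- nmd_magnitude_vs_te(de_truth, te, up, mode = "bins")
  expect_gt(bn$summary$mean_log2fc[bn$summary$tertile == "a"],
            bn$summary$mean_log2fc[bn$summary$tertile == "c"])
  expect_lt(bn$p_a_vs_c, 0.05)
  # downregulated control genes show no TE-magnitude association
  down <- truth$gene_id[truth$is_downregulated]
  bd <- nmd_magnitude_vs_te(de_truth, te, down, mode = "bins")
  expect_gt(bd$p_a_vs_c, 0.05)
})

test_that("degenerate correlation inputs report absence, not zero", {
  rec <- mk_records(2, te = c(2, 2))
  de <- data.frame(gene_id = rec$gene_id, log2fc = c(1, 2))
  r <- nmd_magnitude_vs_te(de, rec, rec$gene_id, mode = "correlation")
  expect_true(is.na(r$high$r_squared))
  # three genes, zero TE variance -> still undefined
  rec3 <- mk_records(3, te = rep(1.5, 3))
  de3 <- data.frame(gene_id = rec3$gene_id, log2fc = 1:3)
  r3 <- nmd_magnitude_vs_te(de3, rec3, rec3$gene_id, mode = "correlation")
  expect_true(is.na(r3$high$r_squared))
})
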