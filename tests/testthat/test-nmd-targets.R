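test_that("upregulated selection filters on padj and sign", {
  tbl <- mosn_target_table()
  de <- data.frame(gene_id = tbl$gene_symbol, log2fc = tbl$log2fc,
                   padj = tbl$padj)
  expect_true("Sik1" %in% select_upregulated(de))
  expect_setequal(select_upregulated(de), tbl$gene_symbol)
  de2 <- rbind(de, data.frame(gene_id = c("flat", "down"),
                              log2fc = c(0, -2), padj = c(1e-9, 1e-9)))
  sel <- select_upregulated(de2)
  expect_false(any(c("flat", "down") %in% sel))
  # set-comprehension oracle on a random table
  set.seed(11)
  rde <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    log2fc = rnorm(200), padj = runif(200))
  want <- rde$gene_id[rde$padj < 0.05 & rde$log2fc > 0]
  expect_identical(select_upregulated(rde), want)
  rde$padj[5] <- NA
  expect_warning(select_upregulated(rde), "missing padj")
})

test_that("tier assignment is the deterministic cross of the three flags", {
  nif <- data.frame(gene_id = c("a", "b", "c", "d"),
                    has_dej = c(TRUE, FALSE, FALSE, FALSE),
                    has_uorf = FALSE, has_long_utr3 = c(FALSE, TRUE,
                                                        FALSE, FALSE),
                    any_nif = c(TRUE, TRUE, FALSE, FALSE))
  tiers <- call_tiers(upregulated = c("a", "b", "c"),
                      stabilized = c("a", "c", "d"), nif = nif)
  got <- setNames(as.character(tiers$tier), tiers$gene_id)
  expect_identical(got[["a"]], "high_confidence")  # up + stab + dEJ
  expect_identical(got[["b"]], "candidate_nif")    # up + NIF, not stab
  expect_identical(got[["c"]], "none")             # up + stab, no NIF
  expect_identical(got[["d"]], "none")             # stabilized only
  expect_true(all(tiers$tier[tiers$tier == "high_confidence"] >=
                    tiers$tier[tiers$tier == "candidate_nif"]))
})

test_that("tier cardinalities respect the containment chain", {
  fx <- fx_bulk()
  truth <- fx$g$truth
  de_truth <- data.frame(
    gene_id = truth$gene_id, log2fc = truth$planted_log2fc,
    padj = ifelse(truth$is_upregulated | truth$is_downregulated,
                  1e-6, 0.9))
  prof <- profile_transcriptome(fx$g$models)
  tiers <- call_tiers(select_upregulated(de_truth),
                      truth$gene_id[truth$is_stabilized], prof)
  n <- tier_counts(tiers)
  expect_lte(n$n_high_confidence, n$n_stabilized_up)
  expect_lte(n$n_stabilized_up, n$n_upregulated)
  # with truth inputs the planted design is reproduced exactly
  expect_equal(n$n_upregulated, 127)
  expect_equal(n$n_stabilized_up, 82)
  expect_equal(n$n_candidate_nif, 73)
  expect_equal(n$n_high_confidence, 52)
})

test_that("tier counts are monotone when the DE threshold is relaxed", {
  fx <- fx_bulk()
  de <- minimal_nb_de(fx$b$exonic, fx$b$sample_sheet)
  st <- infer_stability(fx$b$exonic, fx$b$intronic, fx$b$sample_sheet)
  prof <- profile_transcriptome(fx$g$models)
  stab <- st$gene_id[st$stabilized]
  n_strict <- tier_counts(call_tiers(select_upregulated(de, 0.01),
                                     stab, prof))
  n_loose <- tier_counts(call_tiers(select_upregulated(de, 0.1),
                                    stab, prof))
  for (k in names(n_strict))
    expect_gte(n_loose[[k]], n_strict[[k]])
})

test_that("minimal NB test is calibrated on null counts and recovers planted folds", {
  null_truth <- gen_transcriptome(800, tier_design = NULL,
                                  seed = 421)$truth
  b0 <- simulate_bulk(null_truth, seed = 422)
  de0 <- minimal_nb_de(b0$exonic, b0$sample_sheet)
  expect_lte(mean(de0$p < 0.05), 0.07)
  expect_lte(sum(de0$padj < 0.05), 3)
  # planted 4-fold changes at high depth estimate near log2fc = 2
  td <- list(n_up = 60L, n_down = 0L, n_stabilized = 60L,
             n_stab_nif = 0L, n_up_only_nif = 0L)
  g4 <- gen_transcriptome(800, tier_design = td, effect_mode = "fixed",
                          fixed_lfc = 2, seed = 423)
  b4 <- simulate_bulk(g4$truth, depth_exonic = 8e6, seed = 424)
  de4 <- minimal_nb_de(b4$exonic, b4$sample_sheet)
  planted <- g4$truth$gene_id[g4$truth$is_upregulated]
  est <- de4$log2fc[match(planted, de4$gene_id)]
  expect_lt(abs(mean(est) - 2), 0.3)
  # swapping genotype labels negates every estimate exactly
  sheet_sw <- b4$sample_sheet
  sheet_sw$genotype <- ifelse(sheet_sw$genotype == "WT", "KO", "WT")
  de_sw <- minimal_nb_de(b4$exonic, sheet_sw)
  expect_equal(de_sw$log2fc, -de4$log2fc, tolerance = 1e-12)
})

test_that("minimal NB fold changes track an established DE implementation", {
  skip_if_not_installed("DESeq2")
  fx <- fx_bulk()
  keep <- rowSums(fx$b$exonic) > 0
  cnt <- fx$b$exonic[keep, ]
  de <- minimal_nb_de(cnt, fx$b$sample_sheet)
  cd <- data.frame(genotype = factor(fx$b$sample_sheet$genotype,
                                     levels = c("WT", "KO")))
  dds <- DESeq2::DESeqDataSetFromMatrix(round(cnt), cd, ~genotype)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  common <- intersect(de$gene_id, rownames(res))
  expect_gt(cor(de$log2fc[match(common, de$gene_id)],
                res$log2FoldChange[match(common, rownames(res))]), 0.95)
  planted_up <- fx$g$truth$gene_id[fx$g$truth$is_upregulated]
  both_called <- intersect(
    de$gene_id[de$padj < 0.05 & de$log2fc > 0],
    rownames(res)[!is.na(res$padj) & res$padj < 0.05 &
                    res$log2FoldChange > 0])
  expect_gt(mean(both_called %in% planted_up), 0.8)
})

test_that("known-target overlap is an exact set intersection", {
  ov <- overlap_known_targets(mosn_target_table()$gene_symbol,
                              prior_nmd_targets())
  expect_equal(ov$count, 11)
  expect_true(all(ov$intersection %in% prior_nmd_targets()))
  expect_equal(overlap_known_targets(c("A", "B"), character(0))$count, 0)
  set.seed(12)
  a <- sample(sprintf("g%03d", 1:300), 80)
  b <- sample(sprintf("g%03d", 1:300), 80)
  expect_setequal(overlap_known_targets(a, b)$intersection,
                  unique(a[a %in% b]))
})
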