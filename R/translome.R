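# RiboTag translation efficiency and its strata: TPM-based TE, the
# 30/40/30 expression and TE bins, the 3x3 category grid, TE vs 3'UTR
# length, and the NMD-magnitude-vs-translation analyses.

#' Transcripts per million
#'
#' @param counts Gene x sample count matrix.
#' @param lengths Per-gene transcript lengths (nt), aligned with rows.
#' @return TPM matrix of the same shape.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Compute translation efficiency from input and IP counts
#'
#' TE is the ratio of ribosome-associated (RiboTag IP) to steady-state
#' (input RNA-seq) abundance: `log2te = log2((tpm_ip + c)/(tpm_input + c))`
#' on per-condition mean TPM. Genes below the input expression floor are
#' excluded as unexpressed.
#'
#' @param input_counts,ip_counts Gene x sample count matrices with
#'   identical row order (samples may differ).
#' @param gene_lengths Per-gene transcript lengths aligned with rows.
#' @param expression_floor Minimum mean input TPM (default 1).
#' @param pseudocount TPM pseudocount (default 0.1).
#' @return Data frame: gene_id, tpm_input, tpm_ip, log2te.
#' @export
compute_te <- function(input_counts, ip_counts, gene_lengths,
                       expression_floor = 1, pseudocount = 0.1) {
  stopifnot(identical(rownames(input_counts), rownames(ip_counts)))
  tin <- rowMeans(tpm(input_counts, gene_lengths))
  tip <- rowMeans(tpm(ip_counts, gene_lengths))
  keep <- tin >= expression_floor
  data.frame(gene_id = rownames(input_counts)[keep],
             tpm_input = tin[keep], tpm_ip = tip[keep],
             log2te = log2((tip[keep] + pseudocount) /
                             (tin[keep] + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# rank-based low/medium/high split; ties broken by stable gene_id order;
# a constant ranking variable puts everything in "medium"
split_30_40_30 <- function(values, ids, fractions = c(0.3, 0.4, 0.3)) {
  n <- length(values)
  if (n >= 2 && stats::sd(values) == 0)
    return(factor(rep("medium", n), levels = c("low", "medium", "high")))
  ord <- order(values, ids)
  n_low <- round(fractions[1] * n)
  n_high <- round(fractions[3] * n)
  bin <- character(n)
  bin[ord[seq_len(n_low)]] <- "low"
  bin[ord[seq(n - n_high + 1, n)]] <- "high"
  bin[bin == ""] <- "medium"
  factor(bin, levels = c("low", "medium", "high"))
}

#' Bin the translome into expression and TE strata
#'
#' Genes are split by rank into high (top 30 percent), medium (middle 40
#' percent) and low (bottom 30 percent) groups, independently for TE and
#' for steady-state expression, and crossed into 9 categories. Category 1
#' is high expression and high TE; numbering runs across expression
#' (high, medium, low) within each TE row (high, medium, low), so
#' categories 1-3 are the highly translated genes and category 9 is low
#' on both axes.
#'
#' @param records Output of [compute_te()] (>= 10 genes).
#' @param fractions Bin fractions, low/medium/high (default 0.3/0.4/0.3).
#' @return `records` with added `te_bin`, `expr_bin`, `category` columns.
#' @export
bin_translome <- function(records, fractions = c(0.3, 0.4, 0.3)) {
  stopifnot(nrow(records) >= 10, abs(sum(fractions) - 1) < 1e-9)
  records$te_bin <- split_30_40_30(records$log2te, records$gene_id,
                                   fractions)
  records$expr_bin <- split_30_40_30(log2(records$tpm_input + 0.1),
                                     records$gene_id, fractions)
  te_rank <- 4L - as.integer(records$te_bin)     # high = 1
  expr_rank <- 4L - as.integer(records$expr_bin)
  records$category <- 3L * (te_rank - 1L) + expr_rank
  records
}

#' Mean TE by 3'UTR-length bin
#'
#' @param records Output of [compute_te()].
#' @param utr3_len Named per-gene 3'UTR lengths (names = gene ids).
#' @param length_edges Interior bin edges in nt (default 500/1000/2000).
#' @return List: `summary` (bin, n, mean_log2te), `pairwise_p` (matrix of
#'   two-sided Mann-Whitney p-values between bins).
#' @export
te_by_utr3 <- function(records, utr3_len,
                       length_edges = c(500, 1000, 2000)) {
  len <- utr3_len[records$gene_id]
  keep <- !is.na(len)
  records <- records[keep, ]
  len <- len[keep]
  edges <- c(0, sort(length_edges), Inf)
  labs <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  bin <- cut(len, breaks = edges, right = FALSE, labels = labs)
  groups <- split(records$log2te, bin)
  summary <- data.frame(bin = names(groups),
                        n = vapply(groups, length, integer(1)),
                        mean_log2te = vapply(groups, function(v)
                          if (length(v)) mean(v) else NA_real_, numeric(1)),
                        stringsAsFactors = FALSE)
  k <- length(groups)
  pw <- matrix(NA_real_, k, k, dimnames = list(names(groups),
                                               names(groups)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && length(groups[[i]]) > 1 && length(groups[[j]]) > 1)
      pw[i, j] <- pw[j, i] <-
        stats::wilcox.test(groups[[i]], groups[[j]])$p.value
  }
  list(summary = summary, pairwise_p = pw)
}

#' NMD magnitude versus translation efficiency
#'
#' Two views of the translation dependence of NMD. In `bins` mode the
#' supplied genes are split into TE tertiles a (highest), b, c (lowest)
#' and the mean expression shift (log2FC in the NMD-deficient genotype)
#' is compared between the extreme tertiles with a two-sided Mann-Whitney
#' test. In `correlation` mode the genes are split at
#' `log2te > high_te_cutoff` and a least-squares fit of log2FC on log2TE
#' is summarized by R-squared within each group; groups with fewer than 3
#' genes or zero TE variance get `NA` (undefined, not zero).
#'
#' @param de Data frame with `gene_id` and `log2fc`.
#' @param records Output of [compute_te()].
#' @param genes Gene ids to analyze (e.g. the upregulated set).
#' @param mode `"bins"` or `"correlation"`.
#' @param high_te_cutoff log2TE split point for `correlation` mode
#'   (default 1).
#' @return `bins` mode: list with `summary` (tertile, n, mean_log2fc) and
#'   `p_a_vs_c`. `correlation` mode: list with `high` and `low`, each
#'   containing `n`, `r_squared`, `slope`.
#' @export
nmd_magnitude_vs_te <- function(de, records, genes,
                                mode = c("bins", "correlation"),
                                high_te_cutoff = 1) {
  mode <- match.arg(mode)
  d <- merge(de[de$gene_id %in% genes, c("gene_id", "log2fc")],
             records[, c("gene_id", "log2te")], by = "gene_id")
  if (mode == "bins") {
    ord <- order(-d$log2te, d$gene_id)
    n <- nrow(d)
    tert <- character(n)
    cut1 <- ceiling(n / 3); cut2 <- ceiling(2 * n / 3)
    tert[ord[seq_len(cut1)]] <- "a"
    tert[ord[seq(cut1 + 1, cut2)]] <- "b"
    tert[ord[seq(cut2 + 1, n)]] <- "c"
    groups <- split(d$log2fc, tert)
    summary <- data.frame(tertile = names(groups),
                          n = vapply(groups, length, integer(1)),
                          mean_log2fc = vapply(groups, mean, numeric(1)),
                          stringsAsFactors = FALSE)
    p <- if (length(groups$a) > 1 && length(groups$c) > 1)
      stats::wilcox.test(groups$a, groups$c)$p.value else NA_real_
    return(list(summary = summary, p_a_vs_c = p))
  }
  fit_group <- function(sub) {
    if (nrow(sub) < 3 || stats::sd(sub$log2te) == 0)
      return(list(n = nrow(sub), r_squared = NA_real_, slope = NA_real_))
    fit <- stats::lm(log2fc ~ log2te, data = sub)
    list(n = nrow(sub), r_squared = summary(fit)$r.squared,
         slope = unname(stats::coef(fit)[2]))
  }
  list(high = fit_group(d[d$log2te > high_te_cutoff, ]),
       low = fit_group(d[d$log2te <= high_te_cutoff, ]))
}
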