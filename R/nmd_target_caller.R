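# Combining differential expression, stabilization and NIF status into
# candidate and high-confidence NMD-target tiers.

#' Select upregulated genes from a differential-expression table
#'
#' @param de Data frame with columns `gene_id`, `log2fc` (KO over WT) and
#'   `padj`; rows with missing `padj` are dropped with a warning.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Character vector of gene ids with `padj < alpha` and
#'   `log2fc > 0`.
#' @export
select_upregulated <- function(de, alpha = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(de)))
  bad <- is.na(de$padj)
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing padj dropped")
    de <- de[!bad, ]
  }
  de$gene_id[de$padj < alpha & de$log2fc > 0]
}

#' Assign NMD-target tiers
#'
#' Upregulation in the NMD-deficient genotype makes a gene a candidate
#' direct target; carrying at least one NMD-inducing feature promotes it
#' to `candidate_nif`; additional stabilization (reduced decay) makes it
#' `high_confidence`. Gene universes of the three inputs are reconciled
#' by union; genes absent from an input simply lack that property.
#'
#' @param upregulated Character vector of upregulated gene ids.
#' @param stabilized Character vector of stabilized gene ids.
#' @param nif Data frame from [profile_transcriptome()] (needs `gene_id`,
#'   `has_dej`, `has_uorf`, `has_long_utr3`, `any_nif`).
#' @return Data frame ordered by tier then gene_id: gene_id, upregulated,
#'   stabilized, nif_dej, nif_uorf, nif_long3utr, n_nifs, tier (factor
#'   `none` < `candidate_nif` < `high_confidence`).
#' @export
call_tiers <- function(upregulated, stabilized, nif) {
  genes <- sort(union(union(upregulated, stabilized), nif$gene_id))
  idx <- match(genes, nif$gene_id)
  flag <- function(col) {
    v <- nif[[col]][idx]
    v[is.na(v)] <- FALSE
    v
  }
  dej <- flag("has_dej"); uorf <- flag("has_uorf")
  long3 <- flag("has_long_utr3")
  up <- genes %in% upregulated
  stab <- genes %in% stabilized
  n_nifs <- dej + uorf + long3
  tier <- ifelse(up & stab & n_nifs >= 1, "high_confidence",
                 ifelse(up & n_nifs >= 1, "candidate_nif", "none"))
  out <- data.frame(gene_id = genes, upregulated = up, stabilized = stab,
                    nif_dej = dej, nif_uorf = uorf, nif_long3utr = long3,
                    n_nifs = as.integer(n_nifs),
                    tier = factor(tier, levels = c("none", "candidate_nif",
                                                   "high_confidence"),
                                  ordered = TRUE),
                    stringsAsFactors = FALSE)
  out <- out[order(-as.integer(out$tier), out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Tier cardinalities
#'
#' @param tiers Output of [call_tiers()].
#' @return Named list: n_upregulated, n_stabilized_up (upregulated and
#'   stabilized), n_candidate_nif (upregulated with >= 1 NIF, including
#'   the high-confidence genes), n_high_confidence.
#' @export
tier_counts <- function(tiers) {
  list(n_upregulated = sum(tiers$upregulated),
       n_stabilized_up = sum(tiers$upregulated & tiers$stabilized),
       n_candidate_nif = sum(tiers$upregulated & tiers$n_nifs >= 1),
       n_high_confidence = sum(tiers$tier == "high_confidence"))
}

#' Minimal negative-binomial differential-expression test
#'
#' A deliberately small NB Wald test used as plumbing when no external
#' differential-expression table is supplied: median-of-ratios size
#' factors, per-gene method-of-moments NB dispersion pooled across
#' genotypes and shrunk toward the transcriptome-wide median (prior
#' weight `prior_df`, an empirical-Bayes moderation that stabilizes the
#' per-gene estimate at small replicate numbers), a normal Wald statistic
#' on the log2 fold change of normalized group means, and
#' Benjamini-Hochberg adjustment. It is a convenience substitute for a
#' full shrinkage-based DE package, not a clone of one.
#'
#' @param counts Gene x sample raw count matrix.
#' @param sample_sheet Data frame with `sample` and `genotype` columns;
#'   >= 2 replicates per genotype.
#' @param pseudo Pseudo-mean added to group means before the log ratio.
#' @param prior_df Prior degrees of freedom of the dispersion shrinkage
#'   (default 20).
#' @return Data frame: gene_id, base_mean, log2fc (KO over WT), p, padj.
#'   All-zero genes are dropped.
#' @export
minimal_nb_de <- function(counts, sample_sheet, pseudo = 0.5,
                          prior_df = 20) {
  stopifnot(all(colnames(counts) %in% sample_sheet$sample))
  geno <- sample_sheet$genotype[match(colnames(counts),
                                      sample_sheet$sample)]
  stopifnot(sum(geno == "WT") >= 2, sum(geno == "KO") >= 2)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]

  # median-of-ratios size factors
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  sf <- apply(counts, 2, function(cnt)
    exp(stats::median(log(cnt[use]) - logg[use])))
  norm <- sweep(counts, 2, sf, "/")

  ko <- norm[, geno == "KO", drop = FALSE]
  wt <- norm[, geno == "WT", drop = FALSE]
  n1 <- ncol(ko); n2 <- ncol(wt)
  m1 <- rowMeans(ko); m2 <- rowMeans(wt)
  v1 <- apply(ko, 1, stats::var); v2 <- apply(wt, 1, stats::var)

  # pooled method-of-moments dispersion (var = mu + a mu^2), shrunk
  # toward the transcriptome-wide median to tame its sampling noise
  mu_bar <- (m1 + m2) / 2
  v_bar <- (v1 + v2) / 2
  a_mom <- pmax(0, (v_bar - mu_bar) / mu_bar^2)
  resid_df <- n1 + n2 - 2
  a_prior <- stats::median(a_mom[mu_bar > 5])
  if (!is.finite(a_prior)) a_prior <- stats::median(a_mom)
  a <- (resid_df * a_mom + prior_df * a_prior) / (resid_df + prior_df)

  lfc <- log2(m1 + pseudo) - log2(m2 + pseudo)
  se <- sqrt((m1 + a * m1^2) / (n1 * pmax(m1 + pseudo, pseudo)^2) +
               (m2 + a * m2^2) / (n2 * pmax(m2 + pseudo, pseudo)^2)) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(z)] <- 1
  data.frame(gene_id = rownames(counts), base_mean = mu_bar,
             log2fc = lfc, p = p, padj = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Overlap calls with a list of previously defined NMD targets
#'
#' Exact, case-sensitive symbol intersection (no alias resolution, to
#' avoid silent mis-joins).
#'
#' @param symbols Character vector of called gene symbols.
#' @param known Character vector of previously defined target symbols.
#' @return List: `intersection` (sorted) and `count`.
#' @export
overlap_known_targets <- function(symbols, known) {
  inter <- sort(intersect(symbols, known))
  list(intersection = inter, count = length(inter))
}
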