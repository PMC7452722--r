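# Relative RNA stability from exonic (mature mRNA) vs intronic (pre-mRNA)
# read signal. The per-gene, per-sample statistic
#   delta = log2(exonic density) - log2(intronic density)
# tracks the mature/pre-mRNA ratio, i.e. steady-state level divided by
# transcription rate, which is proportional to mRNA half-life. Differences
# of delta between genotypes (ddelta) therefore estimate log2 decay-rate
# ratios independent of transcriptional changes.

#' Per-gene, per-sample exon-intron stability statistic
#'
#' `delta[g, s] = log2((x[g,s] + c) / N[s]) - log2((i[g,s] + c) / M[s])`
#' where `x`/`i` are exonic/intronic counts, `N`/`M` the exonic/intronic
#' library sizes (column sums) and `c` a pseudocount. Genes with zero
#' intronic counts in every sample carry no pre-mRNA signal and are
#' flagged unmeasurable (their delta is still returned but downstream
#' calls exclude them).
#'
#' @param exonic,intronic Gene x sample count matrices with identical
#'   dimnames.
#' @param pseudocount Added to every count before the log (default 0.5).
#' @return List: `delta` (gene x sample matrix), `unmeasurable` (logical
#'   per gene), `mean_log_expr` (per-gene mean log2 exonic abundance, the
#'   bias-correction covariate).
#' @export
compute_delta <- function(exonic, intronic, pseudocount = 0.5) {
  if (!identical(dim(exonic), dim(intronic)) ||
      !identical(rownames(exonic), rownames(intronic)) ||
      !identical(colnames(exonic), colnames(intronic))) {
    gd <- c(setdiff(rownames(exonic), rownames(intronic)),
            setdiff(rownames(intronic), rownames(exonic)))
    sd_ <- c(setdiff(colnames(exonic), colnames(intronic)),
             setdiff(colnames(intronic), colnames(exonic)))
    stop("exonic and intronic tables disagree; gene diff: {",
         paste(utils::head(gd, 10), collapse = ", "), "}, sample diff: {",
         paste(utils::head(sd_, 10), collapse = ", "), "}")
  }
  n_lib <- colSums(exonic)
  m_lib <- colSums(intronic)
  if (any(n_lib <= 0) || any(m_lib <= 0))
    stop("library sizes must be positive")
  delta <- sweep(log2(exonic + pseudocount), 2, log2(n_lib)) -
    sweep(log2(intronic + pseudocount), 2, log2(m_lib))
  list(delta = delta,
       unmeasurable = rowSums(intronic) == 0,
       mean_log_expr = rowMeans(log2(exonic + pseudocount)))
}

#' Remove the abundance-dependent bias trend from delta
#'
#' The raw exon-intron statistic carries a gene-abundance-dependent bias
#' (coverage, length and pseudocount effects). Per sample, a running
#' median of delta along the expression covariate is subtracted; with a
#' window fraction of 1 this degenerates to subtracting the per-sample
#' median. With fewer than 50 measurable genes the trend is too poorly
#' determined and correction is skipped with a warning.
#'
#' @param delta Gene x sample delta matrix.
#' @param abundance Per-gene covariate (mean log2 exonic abundance).
#' @param window_frac Running-median window as a fraction of the gene
#'   count (default 0.1).
#' @return Corrected matrix of the same shape.
#' @export
bias_correct <- function(delta, abundance, window_frac = 0.1) {
  n <- nrow(delta)
  if (n < 50) {
    warning("fewer than 50 genes; bias correction skipped")
    return(delta)
  }
  ord <- order(abundance)
  out <- delta
  if (window_frac >= 1) {
    return(sweep(delta, 2, apply(delta, 2, stats::median)))
  }
  k <- max(3L, round(window_frac * n))
  if (k %% 2L == 0L) k <- k + 1L
  for (s in seq_len(ncol(delta))) {
    trend <- stats::runmed(delta[ord, s], k, endrule = "median")
    out[ord, s] <- delta[ord, s] - trend
  }
  out
}

#' Call genotype-dependent stabilization
#'
#' A gene is stabilized when its genotype delta difference
#' `ddelta = mean(delta KO) - mean(delta WT)` exceeds
#' `stabilization_min_ddelta` and a two-sided Welch t-test across
#' replicate delta values is significant at `alpha` (optionally after
#' Benjamini-Hochberg adjustment for genome-wide screens; the default is
#' unadjusted, matching the statistic's use as a filter inside a small
#' candidate set). With a single replicate per genotype the test is
#' skipped and the threshold alone decides, with a warning.
#'
#' @param delta Gene x sample (bias-corrected) delta matrix.
#' @param sample_sheet Data frame with columns `sample` (matching the
#'   delta columns) and `genotype` (`WT`/`KO`).
#' @param stabilization_min_ddelta Minimum ddelta (default 0).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param unmeasurable Optional logical per gene; flagged genes are never
#'   called and get NA statistics.
#' @return Data frame: gene_id, delta_wt, delta_ko, ddelta, p_value,
#'   stabilized.
#' @export
call_stabilized <- function(delta, sample_sheet,
                            stabilization_min_ddelta = 0, alpha = 0.05,
                            p_adjust = c("none", "BH"),
                            unmeasurable = NULL) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(colnames(delta) %in% sample_sheet$sample))
  geno <- sample_sheet$genotype[match(colnames(delta),
                                      sample_sheet$sample)]
  wt <- delta[, geno == "WT", drop = FALSE]
  ko <- delta[, geno == "KO", drop = FALSE]
  if (ncol(wt) == 0 || ncol(ko) == 0)
    stop("both genotypes must be present")
  ddelta <- rowMeans(ko) - rowMeans(wt)
  if (ncol(wt) < 2 || ncol(ko) < 2) {
    warning("single replicate; threshold-only stabilization calls")
    p <- rep(NA_real_, nrow(delta))
    called <- ddelta > stabilization_min_ddelta
  } else {
    w <- welch_rows(ko, wt)
    p <- w$p
    padj <- if (p_adjust == "BH") stats::p.adjust(p, "BH") else p
    called <- ddelta > stabilization_min_ddelta & padj <= alpha
  }
  out <- data.frame(gene_id = rownames(delta),
                    delta_wt = rowMeans(wt), delta_ko = rowMeans(ko),
                    ddelta = ddelta, p_value = p, stabilized = called,
                    stringsAsFactors = FALSE)
  if (!is.null(unmeasurable)) {
    out$stabilized[unmeasurable] <- FALSE
    out$p_value[unmeasurable] <- NA_real_
    out$unmeasurable <- unmeasurable
  }
  rownames(out) <- NULL
  out
}

#' One-call stability inference from count tables
#'
#' Convenience wrapper: [compute_delta()], [bias_correct()],
#' [call_stabilized()].
#'
#' @inheritParams compute_delta
#' @inheritParams call_stabilized
#' @param window_frac Passed to [bias_correct()].
#' @return As [call_stabilized()].
#' @export
infer_stability <- function(exonic, intronic, sample_sheet,
                            pseudocount = 0.5, window_frac = 0.1,
                            stabilization_min_ddelta = 0, alpha = 0.05,
                            p_adjust = c("none", "BH")) {
  d <- compute_delta(exonic, intronic, pseudocount)
  corr <- bias_correct(d$delta, d$mean_log_expr, window_frac)
  call_stabilized(corr, sample_sheet,
                  stabilization_min_ddelta = stabilization_min_ddelta,
                  alpha = alpha, p_adjust = p_adjust,
                  unmeasurable = d$unmeasurable)
}
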