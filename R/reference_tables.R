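# Bundled reference tables: the published high-confidence mOSN NMD-target
# table and the list of previously defined mouse NMD targets that overlap
# it. Shipped as plain-text fixtures so desk-scale checks (overlap counts,
# long-3'UTR threshold behavior, dominance arithmetic) need no downloads.

#' Published high-confidence mOSN NMD-target table
#'
#' The 52 genes upregulated and stabilized in NMD-deficient mature
#' olfactory sensory neurons that carry at least one NMD-inducing
#' feature, with their log2 fold change (KO/WT), adjusted p-value,
#' downstream-exon-junction and uORF status, and 3'UTR length.
#'
#' @return Data frame with columns gene_symbol, log2fc, padj, dej, uorf,
#'   utr3_len.
#' @export
mosn_target_table <- function() {
  read_tsv(system.file("extdata", "mosn_high_confidence_targets.tsv",
                       package = "nmdscope", mustWork = TRUE))
}

#' Previously defined mouse NMD-target symbols
#'
#' The published list of likely mouse NMD substrates (at least one known
#' NMD-inducing feature plus experimental evidence from at least one
#' assay) that overlap the high-confidence mOSN target set.
#'
#' @return Character vector of gene symbols.
#' @export
prior_nmd_targets <- function() {
  readLines(system.file("extdata", "prior_mouse_nmd_targets.txt",
                        package = "nmdscope", mustWork = TRUE))
}

#' NIF status of the published target table at a given 3'UTR threshold
#'
#' Re-derives the any-NIF flag of each published row from its printed
#' dEJ/uORF status and 3'UTR length, at an arbitrary long-3'UTR
#' threshold.
#'
#' @param tbl Output of [mosn_target_table()] (default).
#' @param long_utr3_min_nt Long-3'UTR threshold in nt.
#' @return Logical vector, one element per row.
#' @export
table_any_nif <- function(tbl = mosn_target_table(),
                          long_utr3_min_nt = 1000L) {
  tbl$dej == "YES" | tbl$uorf == "YES" |
    call_long_utr3(tbl$utr3_len, long_utr3_min_nt)
}
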