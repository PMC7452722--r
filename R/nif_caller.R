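#' Default NIF-calling thresholds
#'
#' Downstream exon junction: >= 50 nt of 3'UTR between the stop codon and
#' the junction (the "-50-nt boundary rule"). uORF: >= 30 nt from AUG
#' through stop. Long 3'UTR: >= 1000 nt (the literature gives no single
#' canonical cutoff; 1000 nt is the package default and is configurable).
#'
#' @return Named list of thresholds.
#' @export
nif_thresholds <- function(dej_min_nt = 50L, min_uorf_len = 30L,
                           long_utr3_min_nt = 1000L) {
  list(dej_min_nt = as.integer(dej_min_nt),
       min_uorf_len = as.integer(min_uorf_len),
       long_utr3_min_nt = as.integer(long_utr3_min_nt))
}

#' Call a downstream exon junction (dEJ)
#'
#' A transcript harbors a dEJ when at least one exon-exon junction lies
#' >= `dej_min_nt` nt downstream of the stop codon terminating the main ORF.
#' A junction is assigned the transcript coordinate of the last base of its
#' upstream exon; for a junction at position `j >= cds_end` the downstream
#' distance is `d = j - cds_end + 1` (the number of 3'UTR bases 5' of and
#' including the junction's last upstream base). Ribosomes displace
#' exon-junction complexes less than ~50 nt past termination, so only
#' junctions at `d >= 50` (default) mark the transcript for EJC-dependent
#' NMD.
#'
#' @param model A `transcript_model`.
#' @param utr Output of [annotate_utrs()] for `model` (computed if missing).
#' @param dej_min_nt Minimum downstream distance in nt (default 50).
#' @return List with `has_dej` and `dej_max_distance` (NA when no junction
#'   lies downstream of the stop codon).
#' @export
call_dej <- function(model, utr = annotate_utrs(model), dej_min_nt = 50L) {
  j <- utr$junction_positions
  j <- j[j >= model$cds_end]
  if (length(j) == 0)
    return(list(has_dej = FALSE, dej_max_distance = NA_integer_))
  d <- j - model$cds_end + 1L
  list(has_dej = max(d) >= dej_min_nt, dej_max_distance = max(d))
}

#' Call upstream open reading frames (uORFs)
#'
#' Scans every AUG in the 5'UTR (all three frames) and reports those
#' satisfying the four classic criteria: (i) the ORF lies in the 5'UTR,
#' (ii) the initiation context is favorable - a purine (A/G) at position -3
#' or a G at position +4 relative to the A of the AUG (+1), (iii) the ORF is
#' at least `min_uorf_len` nt long (AUG through stop codon inclusive), and
#' (iv) the ORF does not overlap the main ORF (the stop codon's last base
#' must not extend past `cds_start`). An AUG whose first in-frame stop falls
#' beyond the 5'UTR overlaps the main ORF and is rejected. Lowercase or
#' ambiguous bases at -3/+4 fail the context test (conservative).
#'
#' @param model A `transcript_model`.
#' @param min_uorf_len Minimum ORF length in nt, stop codon included
#'   (default 30, i.e. >= 10 codons).
#' @return Data frame of hits in 5'-to-3' order: `start` (0-based transcript
#'   coordinate of the A of the AUG), `length_nt`, `minus3`, `plus4`,
#'   `context_ok`. Zero rows when no uORF qualifies.
#' @export
call_uorfs <- function(model, min_uorf_len = 30L) {
  cds_start <- model$cds_start
  seqc <- model$sequence
  hits <- list()
  if (cds_start >= 6L) {   # smallest conceivable: AUG at position >= 3
    starts <- as.integer(gregexpr("(?=ATG)", substr(seqc, 1L, cds_start),
                                  perl = TRUE)[[1]])
    starts <- starts[starts > 0] - 1L          # to 0-based
    for (s in starts) {
      if (s < 3L) next                         # no -3 position
      if (s + 3L >= nchar(seqc)) next          # no +4 position
      minus3 <- substr(seqc, s - 2L, s - 2L)   # 0-based s-3 -> 1-based s-2
      plus4 <- substr(seqc, s + 4L, s + 4L)
      context_ok <- minus3 %in% c("A", "G") || plus4 == "G"
      if (!context_ok) next
      # walk in-frame codons until the first stop
      len <- NA_integer_
      p <- s + 3L
      while (p + 3L <= cds_start) {
        codon <- substr(seqc, p + 1L, p + 3L)
        if (codon %in% STOP_CODONS) {
          len <- p + 3L - s
          break
        }
        p <- p + 3L
      }
      if (is.na(len)) next                     # runs into the main ORF
      if (len < min_uorf_len) next
      hits[[length(hits) + 1]] <- data.frame(
        start = s, length_nt = len, minus3 = minus3, plus4 = plus4,
        context_ok = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), length_nt = integer(0),
                      minus3 = character(0), plus4 = character(0),
                      context_ok = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$start), , drop = FALSE]
}

#' Call a long 3'UTR
#'
#' @param utr Output of [annotate_utrs()], or a numeric 3'UTR length in nt.
#' @param long_utr3_min_nt Minimum 3'UTR length in nt (default 1000).
#' @return `TRUE` iff the 3'UTR length is >= the threshold.
#' @export
call_long_utr3 <- function(utr, long_utr3_min_nt = 1000L) {
  len <- if (is.list(utr)) utr$utr3_len else utr
  len >= long_utr3_min_nt
}

#' Profile a transcriptome for NMD-inducing features
#'
#' Runs the dEJ, uORF, and long-3'UTR calls on one representative transcript
#' per gene (default: longest CDS; see [pick_representative()]) or, with
#' `scope = "any_isoform"`, flags a gene when any eligible isoform carries
#' the feature. Transcripts without a detectable 5'UTR and 3'UTR are
#' ineligible and excluded (their count is reported as an attribute).
#'
#' @param models List of `transcript_model` objects (may span many genes).
#' @param thresholds Output of [nif_thresholds()].
#' @param scope `"representative"` (default) or `"any_isoform"`.
#' @return Data frame with one row per annotatable gene: gene_id,
#'   gene_symbol, transcript_id, has_dej, dej_max_distance, n_uorfs,
#'   has_uorf, utr3_len, has_long_utr3, any_nif, plus the thresholds used.
#'   Attribute `n_ineligible` counts excluded transcripts.
#' @export
profile_transcriptome <- function(models, thresholds = nif_thresholds(),
                                  scope = c("representative",
                                            "any_isoform")) {
  scope <- match.arg(scope)
  if (length(models) == 0) {
    warning("no transcript models supplied; empty NIF profile")
    return(data.frame(gene_id = character(0)))
  }
  gene_ids <- vapply(models, function(m) m$gene_id, character(1))
  n_inelig <- 0L
  rows <- list()
  for (g in unique(gene_ids)) {
    gm <- models[gene_ids == g]
    utrs <- lapply(gm, annotate_utrs)
    elig <- vapply(utrs, `[[`, logical(1), "eligible")
    n_inelig <- n_inelig + sum(!elig)
    if (!any(elig)) next
    rep_m <- pick_representative(gm)
    rep_u <- annotate_utrs(rep_m)
    use <- if (scope == "representative") list(rep_m) else gm[elig]
    dej <- lapply(use, function(m)
      call_dej(m, annotate_utrs(m), thresholds$dej_min_nt))
    uorfs <- lapply(use, call_uorfs, min_uorf_len = thresholds$min_uorf_len)
    long3 <- vapply(use, function(m)
      call_long_utr3(annotate_utrs(m), thresholds$long_utr3_min_nt),
      logical(1))
    has_dej <- any(vapply(dej, `[[`, logical(1), "has_dej"))
    dmax <- suppressWarnings(
      max(vapply(dej, `[[`, integer(1), "dej_max_distance"), na.rm = TRUE))
    if (!is.finite(dmax)) dmax <- NA_integer_
    has_uorf <- any(vapply(uorfs, nrow, integer(1)) > 0)
    rows[[g]] <- data.frame(
      gene_id = g, gene_symbol = rep_m$gene_symbol,
      transcript_id = rep_m$transcript_id,
      has_dej = has_dej, dej_max_distance = dmax,
      n_uorfs = sum(vapply(uorfs, nrow, integer(1))),
      has_uorf = has_uorf,
      utr3_len = rep_u$utr3_len,
      has_long_utr3 = any(long3),
      any_nif = has_dej || has_uorf || any(long3),
      dej_min_nt = thresholds$dej_min_nt,
      min_uorf_len = thresholds$min_uorf_len,
      long_utr3_min_nt = thresholds$long_utr3_min_nt,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ineligible") <- n_inelig
  out
}
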