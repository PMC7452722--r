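#' Construct a transcript model
#'
#' A transcript model holds the spliced transcript sequence together with its
#' exon structure and the location of the main open reading frame, all in
#' transcript coordinates. It is the substrate for NMD-inducing-feature (NIF)
#' annotation: the 5'UTR, CDS and 3'UTR are read directly off `cds_start` and
#' `cds_end`, and exon-exon junction positions are derived from the exon
#' lengths.
#'
#' Coordinate conventions: all internal coordinates are 0-based, half-open,
#' and transcript-oriented (position 0 is the transcript 5' end regardless of
#' genomic strand). `cds_end` includes the stop codon, so the 3'UTR begins at
#' the first base after the stop codon. Exons are stored as genomic 0-based
#' half-open intervals ordered 5'-to-3' in transcript orientation (descending
#' genomic coordinates on the minus strand).
#'
#' @param transcript_id,gene_id,gene_symbol Identifier strings.
#' @param seqname Name of the genomic contig the transcript lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with columns `start`, `end` (genomic 0-based
#'   half-open), rows ordered 5'-to-3' in transcript orientation.
#' @param cds_start,cds_end Transcript-coordinate offsets (0-based half-open)
#'   of the main ORF including its stop codon.
#' @param sequence Spliced transcript sequence, 5'-to-3', uppercase ACGTN.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_symbol = gene_id,
                             seqname = NA_character_, strand = "+",
                             exons, cds_start, cds_end, sequence) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  m <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         gene_symbol = as.character(gene_symbol),
         seqname = as.character(seqname),
         strand = match.arg(strand, c("+", "-")),
         exons = exons,
         cds_start = as.integer(cds_start),
         cds_end = as.integer(cds_end),
         sequence = toupper(as.character(sequence))),
    class = "transcript_model")
  validate_transcript_model(m)
  m
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s, %s strand)\n",
              x$transcript_id, x$gene_id, x$strand))
  cat(sprintf("  %d exon(s), length %d nt; CDS [%d, %d)\n",
              nrow(x$exons), nchar(x$sequence), x$cds_start, x$cds_end))
  invisible(x)
}

validate_transcript_model <- function(m) {
  len <- nchar(m$sequence)
  widths <- m$exons[, "end"] - m$exons[, "start"]
  if (any(widths <= 0))
    stop("transcript ", m$transcript_id, ": empty or inverted exon interval")
  if (sum(widths) != len)
    stop("transcript ", m$transcript_id,
         ": sequence length does not equal total exon length")
  ord <- order(m$exons[, "start"])
  sorted <- m$exons[ord, , drop = FALSE]
  if (nrow(sorted) > 1 &&
      any(sorted[-nrow(sorted), "end"] > sorted[-1, "start"]))
    stop("transcript ", m$transcript_id, ": overlapping exons")
  if (m$cds_start < 0 || m$cds_start >= m$cds_end || m$cds_end > len)
    stop("transcript ", m$transcript_id, ": CDS outside transcript bounds")
  if ((m$cds_end - m$cds_start) %% 3L != 0L)
    stop("transcript ", m$transcript_id, ": CDS length not a multiple of 3")
  start_cod <- substr(m$sequence, m$cds_start + 1L, m$cds_start + 3L)
  stop_cod <- substr(m$sequence, m$cds_end - 2L, m$cds_end)
  degen <- grepl("N", start_cod) || grepl("N", stop_cod)
  if (degen) {
    warning("transcript ", m$transcript_id,
            ": ambiguous base in start/stop codon, codon check skipped")
  } else {
    if (start_cod != "ATG")
      stop("transcript ", m$transcript_id, ": CDS does not begin with ATG")
    if (!stop_cod %in% STOP_CODONS)
      stop("transcript ", m$transcript_id,
           ": CDS does not end with a stop codon")
  }
  invisible(TRUE)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

exon_widths <- function(model) model$exons[, "end"] - model$exons[, "start"]

transcript_length <- function(model) nchar(model$sequence)

#' Map a transcript coordinate interval to genomic intervals
#'
#' Inverse of the splicing transform: a 0-based half-open interval in
#' transcript coordinates is projected onto the genome through the exon
#' structure, yielding one genomic interval per overlapped exon (in
#' transcript order).
#'
#' @param model A `transcript_model`.
#' @param t_start,t_end 0-based half-open transcript interval.
#' @return Integer matrix with columns `start`, `end` (genomic 0-based
#'   half-open), one row per overlapped exon segment.
#' @export
transcript_to_genomic <- function(model, t_start, t_end) {
  stopifnot(t_start >= 0, t_end > t_start,
            t_end <= transcript_length(model))
  w <- exon_widths(model)
  offs <- cumsum(c(0L, w[-length(w)]))   # transcript offset of each exon
  out <- NULL
  for (k in seq_len(nrow(model$exons))) {
    a <- max(t_start, offs[k])
    b <- min(t_end, offs[k] + w[k])
    if (a >= b) next
    if (model$strand == "+") {
      gs <- model$exons[k, "start"] + (a - offs[k])
      ge <- model$exons[k, "start"] + (b - offs[k])
    } else {
      # minus strand: transcript runs from the exon's genomic end backwards
      ge <- model$exons[k, "end"] - (a - offs[k])
      gs <- model$exons[k, "end"] - (b - offs[k])
    }
    out <- rbind(out, c(gs, ge))
  }
  colnames(out) <- c("start", "end")
  storage.mode(out) <- "integer"
  out
}

#' Map a genomic position to a transcript coordinate
#'
#' @param model A `transcript_model`.
#' @param gpos Genomic 0-based position(s) lying inside the model's exons.
#' @return Integer vector of 0-based transcript coordinates.
#' @export
genomic_to_transcript <- function(model, gpos) {
  w <- exon_widths(model)
  offs <- cumsum(c(0L, w[-length(w)]))
  vapply(gpos, function(g) {
    for (k in seq_len(nrow(model$exons))) {
      if (g >= model$exons[k, "start"] && g < model$exons[k, "end"]) {
        if (model$strand == "+")
          return(offs[k] + (g - model$exons[k, "start"]))
        return(offs[k] + (model$exons[k, "end"] - 1L - g))
      }
    }
    stop("genomic position ", g, " not exonic in ", model$transcript_id)
  }, integer(1))
}

#' Parse a GTF/GFF annotation plus genome FASTA into transcript models
#'
#' Reads exon and CDS features, splices exon sequences in silico (reverse
#' complementing minus-strand transcripts so that every model is 5'-to-3'),
#' and locates the main ORF in transcript coordinates. GTF `stop_codon`
#' features, when present, are unioned into the CDS so that `cds_end` always
#' includes the stop codon. 1-based inclusive GTF coordinates are converted
#' to the internal 0-based half-open convention.
#'
#' Transcripts whose CDS length is not a multiple of 3 (or that fail codon
#' validation) are excluded with a warning. A contig named in the annotation
#' but absent from the FASTA is a hard error.
#'
#' @param gtf_path Path to a GTF/GFF3 file with exon and CDS features.
#' @param fasta_path Path to the genome FASTA.
#' @return Named list of `transcript_model` objects (names = transcript ids).
#' @export
parse_annotation <- function(gtf_path, fasta_path) {
  gr <- rtracklayer::import(gtf_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  feat <- as.character(gr$type)
  keep <- feat %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]
  feat <- feat[keep]
  df <- data.frame(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = feat,
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    gene_symbol = if (!is.null(gr$gene_name)) as.character(gr$gene_name)
                  else as.character(gr$gene_id),
    stringsAsFactors = FALSE)

  missing_contigs <- setdiff(unique(df$seqname), names(genome))
  if (length(missing_contigs) > 0)
    stop("contig(s) missing from FASTA: ",
         paste(missing_contigs, collapse = ", "))

  contigs <- as.character(genome)   # character access is fast for splicing
  models <- list()
  skipped <- character(0)
  for (sub in split(df, df$transcript_id)) {
    tx <- sub$transcript_id[1]
    ex <- sub[sub$type == "exon", ]
    cds <- sub[sub$type %in% c("CDS", "stop_codon"), ]
    if (nrow(ex) == 0 || nrow(cds) == 0) next
    strand <- ex$strand[1]
    seqname <- ex$seqname[1]
    ex <- ex[order(ex$start), ]
    exons_plus <- cbind(start = ex$start, end = ex$end)

    # spliced sequence: concatenate in ascending genomic order, then
    # reverse complement once for minus-strand transcripts
    seq_chr <- paste(substring(contigs[[seqname]], exons_plus[, 1] + 1L,
                               exons_plus[, 2]), collapse = "")
    if (strand == "-") seq_chr <- revcomp(seq_chr)
    seq_chr <- toupper(seq_chr)

    exons_tx <- if (strand == "+") exons_plus else
      exons_plus[rev(seq_len(nrow(exons_plus))), , drop = FALSE]

    cds_len <- sum(cds$end - cds$start)
    if (cds_len %% 3L != 0L) {
      skipped <- c(skipped, tx)
      next
    }
    # 5'-most CDS base in transcript orientation
    g5 <- if (strand == "+") min(cds$start) else max(cds$end) - 1L
    model <- tryCatch({
      stub <- structure(list(transcript_id = tx, strand = strand,
                             exons = exons_tx, sequence = seq_chr),
                        class = "transcript_model")
      cds_start <- genomic_to_transcript(stub, g5)
      transcript_model(tx, sub$gene_id[1], sub$gene_symbol[1],
                       seqname = seqname, strand = strand, exons = exons_tx,
                       cds_start = cds_start, cds_end = cds_start + cds_len,
                       sequence = seq_chr)
    }, error = function(e) NULL)
    if (is.null(model)) {
      skipped <- c(skipped, tx)
      next
    }
    models[[tx]] <- model
  }
  if (length(skipped) > 0)
    warning(length(skipped), " transcript(s) excluded (invalid CDS): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  models
}

#' Annotate UTR lengths and junction positions of a transcript model
#'
#' The 5'UTR length equals `cds_start`; the 3'UTR length equals the
#' transcript length minus `cds_end` (the stop codon belongs to the CDS).
#' Junction positions are the transcript coordinates of the last base of
#' each non-terminal exon (0-based). A transcript is `eligible` for NIF
#' calling only when both UTRs are detectable (length >= 1 nt).
#'
#' @param model A `transcript_model`.
#' @return List with `transcript_id`, `utr5_len`, `utr3_len`,
#'   `junction_positions` (integer vector, possibly empty) and `eligible`.
#' @export
annotate_utrs <- function(model) {
  len <- transcript_length(model)
  w <- exon_widths(model)
  jp <- if (length(w) > 1) cumsum(w)[-length(w)] - 1L else integer(0)
  utr5 <- model$cds_start
  utr3 <- len - model$cds_end
  list(transcript_id = model$transcript_id,
       utr5_len = utr5,
       utr3_len = utr3,
       junction_positions = as.integer(jp),
       eligible = utr5 >= 1L && utr3 >= 1L)
}

#' Pick one representative transcript per gene
#'
#' Among the eligible isoforms of a gene (detectable 5'UTR and 3'UTR), the
#' representative is the one with the longest CDS; ties are broken by longest
#' transcript, then by lexicographically smallest transcript id, so the
#' choice is deterministic.
#'
#' @param models List of `transcript_model` objects, all from one gene.
#' @return The representative `transcript_model`, or `NULL` when no isoform
#'   is eligible (the gene is unannotatable).
#' @export
pick_representative <- function(models) {
  elig <- Filter(function(m) annotate_utrs(m)$eligible, models)
  if (length(elig) == 0) return(NULL)
  cds_len <- vapply(elig, function(m) m$cds_end - m$cds_start, integer(1))
  tx_len <- vapply(elig, transcript_length, integer(1))
  ids <- vapply(elig, function(m) m$transcript_id, character(1))
  ord <- order(-cds_len, -tx_len, ids)
  elig[[ord[1]]]
}

#' Summarize transcript models as a data frame
#'
#' @param models List of `transcript_model` objects.
#' @return Data frame with one row per transcript: transcript_id, gene_id,
#'   gene_symbol, strand, n_exons, utr5_len, cds_len, utr3_len, eligible.
#' @export
transcript_table <- function(models) {
  rows <- lapply(models, function(m) {
    u <- annotate_utrs(m)
    data.frame(transcript_id = m$transcript_id, gene_id = m$gene_id,
               gene_symbol = m$gene_symbol, strand = m$strand,
               n_exons = nrow(m$exons), utr5_len = u$utr5_len,
               cds_len = m$cds_end - m$cds_start, utr3_len = u$utr3_len,
               eligible = u$eligible, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write transcript models to GTF and FASTA
#'
#' Emits one `exon` feature per exon, `CDS` features excluding the stop
#' codon, and a separate `stop_codon` feature (the common GTF convention),
#' converting internal 0-based half-open coordinates back to 1-based
#' inclusive. The companion genome FASTA must be written separately (the
#' synthetic generator keeps contig sequences alongside its models).
#'
#' @param models List of `transcript_model` objects.
#' @param gtf_path Output GTF path.
#' @export
write_transcript_gtf <- function(models, gtf_path) {
  rows <- list()
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     m$gene_id, m$transcript_id, m$gene_symbol)
    ex <- m$exons[order(m$exons[, "start"]), , drop = FALSE]
    for (k in seq_len(nrow(ex)))
      rows[[length(rows) + 1]] <- c(m$seqname, "nmdscope", "exon",
                                    ex[k, 1] + 1L, ex[k, 2], ".", m$strand,
                                    ".", attrs)
    cds_g <- transcript_to_genomic(m, m$cds_start, m$cds_end - 3L)
    for (k in seq_len(nrow(cds_g)))
      rows[[length(rows) + 1]] <- c(m$seqname, "nmdscope", "CDS",
                                    cds_g[k, 1] + 1L, cds_g[k, 2], ".",
                                    m$strand, "0", attrs)
    stop_g <- transcript_to_genomic(m, m$cds_end - 3L, m$cds_end)
    for (k in seq_len(nrow(stop_g)))
      rows[[length(rows) + 1]] <- c(m$seqname, "nmdscope", "stop_codon",
                                    stop_g[k, 1] + 1L, stop_g[k, 2], ".",
                                    m$strand, "0", attrs)
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, gtf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(gtf_path)
}
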