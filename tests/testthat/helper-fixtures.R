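# Shared generated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 300 genes with planted NIF classes, written to disk and reparsed
fx_planted <- function() fixture("planted", function() {
  out <- gen_transcriptome(300, seed = 401, outdir = tempfile("planted"))
  out$parsed <- parse_annotation(out$paths$gtf, out$paths$fasta)
  out
})

# 250 unconstrained random models for oracle comparisons
fx_random <- function() fixture("random", function() {
  gen_random_models(250, seed = 402)
})

# default-design bulk study: transcriptome truth + one count simulation
fx_bulk <- function() fixture("bulk", function() {
  g <- gen_transcriptome(1200, tier_design = default_tier_design(),
                         seed = 403)
  b <- simulate_bulk(g$truth, seed = 404)
  list(g = g, b = b)
})

# small single-cell assay with a planted selection shift
fx_cells <- function() fixture("cells", function() {
  simulate_cells(n_cells = 1200, seed = 405,
                 selection_factor = selection_factor_for(0.13, 0.07))
})

# a tiny hand-made transcript: 5'UTR 12 nt, CDS 24 nt, 3'UTR variable,
# optionally split into exons at given transcript offsets
toy_model <- function(utr5 = "CCCCCCCCCCCC", cds_codons = 6,
                      utr3_len = 60, cuts = integer(0), strand = "+") {
  cds <- paste0("ATG", strsplit("GATGCTGGAGCAGCTGAA", "")[[1]] |>
                  (\(x) paste(x[seq_len(3 * (cds_codons - 2))],
                              collapse = ""))(), "TAA")
  tseq <- paste0(utr5, cds, paste(rep("C", utr3_len), collapse = ""))
  len <- nchar(tseq)
  bounds <- c(0L, sort(unique(as.integer(cuts))), len)
  exons <- cbind(start = 100L + bounds[-length(bounds)] +
                   200L * (seq_len(length(bounds) - 1) - 1L),
                 end = 100L + bounds[-1] +
                   200L * (seq_len(length(bounds) - 1) - 1L))
  if (strand == "-") {
    # mirror: place exons on the minus strand of a virtual contig
    m <- 100000L
    exons <- cbind(start = m - exons[, "end"], end = m - exons[, "start"])
  }
  transcript_model("toy.t1", "toy", seqname = "ctg_toy", strand = strand,
                   exons = exons, cds_start = nchar(utr5),
                   cds_end = nchar(utr5) + nchar(cds), sequence = tseq)
}
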