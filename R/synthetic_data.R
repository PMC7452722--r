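# Synthetic-data generators. Every downstream stage of the package is
# exercised against these: transcript models with constructively planted
# NMD-inducing features, negative-binomial bulk counts with planted
# genotype-dependent decay changes, and single-cell UMI matrices with a
# planted dominant olfactory receptor per neuron.

rand_seq <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random sequence guaranteed to contain no ATG (so it can never seed an ORF)
atg_free_seq <- function(n) {
  s <- rand_seq(n)
  while (grepl("ATG", s, fixed = TRUE))
    s <- gsub("ATG", "ACG", s, fixed = TRUE)
  s
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

random_cds <- function(n_codons) {
  body <- paste(sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
                collapse = "")
  paste0("ATG", body, sample(STOP_CODONS, 1))
}

# a 5'UTR carrying exactly one qualifying uORF (A at -3, >= min_len nt,
# first in-frame stop inside the UTR); rejection-sampled so the planted
# AUG is the only AUG in the UTR
plant_uorf_utr5 <- function(min_len = 30L) {
  repeat {
    n_pre <- sample(10:40, 1)
    n_body <- sample(8:28, 1)            # ORF length 3*(n_body+2) >= 30
    n_suf <- sample(3:30, 1)
    pre <- paste0(atg_free_seq(n_pre - 3L), "A", atg_free_seq(2L))
    body <- paste(sample(setdiff(NONSTOP_CODONS, "ATG"), n_body,
                         replace = TRUE), collapse = "")
    orf <- paste0("ATG", body, sample(STOP_CODONS, 1))
    utr5 <- paste0(pre, orf, sample(c("C", "G", "T"), 1),
                   atg_free_seq(n_suf - 1L))
    m <- gregexpr("ATG", utr5, fixed = TRUE)[[1]]
    if (length(m) == 1 && m[1] == n_pre + 1L &&
        nchar(orf) >= min_len)
      return(list(seq = utr5, uorf_start = n_pre, uorf_len = nchar(orf)))
  }
}

# Assemble one synthetic gene: transcript model + genomic contig, with the
# requested NIF class planted constructively (and every other rule violated).
build_synthetic_gene <- function(gene_id, symbol, nif_class,
                                 long_utr3_min_nt = 1000L) {
  utr5 <- switch(nif_class,
    uorf = plant_uorf_utr5()$seq,
    atg_free_seq(sample(20:200, 1)))
  cds <- random_cds(sample(100:500, 1))
  utr3_len <- switch(nif_class,
    long3utr = sample(long_utr3_min_nt:3000, 1),
    dej = sample(120:900, 1),
    sample(30:900, 1))
  utr3 <- rand_seq(utr3_len)
  tseq <- paste0(utr5, cds, utr3)
  len <- nchar(tseq)
  cds_start <- nchar(utr5)
  cds_end <- cds_start + nchar(cds)

  # exon cut points: a cut at transcript offset c puts a junction at c-1;
  # a junction is a dEJ iff c >= cds_end + dej_min_nt
  n_extra <- sample(0:4, 1)
  max_nondej_cut <- min(len - 1L, cds_end + 49L)
  cuts <- integer(0)
  if (n_extra > 0)
    cuts <- sample(seq_len(max_nondej_cut), min(n_extra, max_nondej_cut))
  if (nif_class == "dej") {
    room <- utr3_len - 50L
    cuts <- c(cuts, cds_end + 50L + sample(0:max(room - 1L, 0L), 1))
  }
  cuts <- sort(unique(cuts))
  bounds <- c(0L, cuts, len)
  widths <- diff(bounds)

  strand <- sample(c("+", "-"), 1)
  segs <- substring(tseq, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- vapply(seq_len(max(length(widths) - 1L, 0L)),
                    function(i) rand_seq(sample(60:300, 1)), character(1))
  flank5 <- rand_seq(50)
  flank3 <- rand_seq(50)

  if (strand == "+") {
    gsegs <- segs
  } else {
    gsegs <- rev(vapply(segs, revcomp, character(1), USE.NAMES = FALSE))
  }
  pieces <- character(0)
  gstarts <- integer(length(gsegs))
  pos <- nchar(flank5)
  pieces <- flank5
  for (i in seq_along(gsegs)) {
    gstarts[i] <- pos
    pieces <- c(pieces, gsegs[i])
    pos <- pos + nchar(gsegs[i])
    if (i < length(gsegs)) {
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  pieces <- c(pieces, flank3)
  contig <- paste(pieces, collapse = "")
  exons_asc <- cbind(start = gstarts,
                     end = gstarts + nchar(gsegs))
  exons_tx <- if (strand == "+") exons_asc else
    exons_asc[rev(seq_len(nrow(exons_asc))), , drop = FALSE]

  model <- transcript_model(
    transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
    gene_symbol = symbol, seqname = paste0("ctg_", gene_id),
    strand = strand, exons = exons_tx,
    cds_start = cds_start, cds_end = cds_end, sequence = tseq)
  list(model = model, contig = contig)
}

#' Generate unconstrained random transcript models
#'
#' Models with random exon structure, random sequence (AUGs and stop codons
#' fall where they may), random UTR lengths, and a valid main ORF - the
#' stress input for brute-force oracle comparisons of the NIF calls and for
#' coordinate round-trip checks. A small fraction of models lack a 5' or
#' 3'UTR to exercise the eligibility filter.
#'
#' @param n Number of models.
#' @param seed Random seed.
#' @return List with `models` (list of `transcript_model`) and `genome`
#'   (named character vector of contig sequences).
#' @export
gen_random_models <- function(n, seed = 1L) {
  set.seed(seed)
  models <- vector("list", n)
  contigs <- character(n)
  for (i in seq_len(n)) {
    gene_id <- sprintf("rg%04d", i)
    utr5_len <- sample(c(0L, sample(1:150, 1)), 1, prob = c(0.05, 0.95))
    utr3_len <- sample(c(0L, sample(1:2500, 1)), 1, prob = c(0.05, 0.95))
    cds <- random_cds(sample(50:400, 1))
    tseq <- paste0(rand_seq(utr5_len), cds, rand_seq(utr3_len))
    len <- nchar(tseq)
    n_cuts <- sample(0:6, 1)
    cuts <- sort(sample(seq_len(len - 1L), min(n_cuts, len - 1L)))
    bounds <- c(0L, cuts, len)
    strand <- sample(c("+", "-"), 1)
    segs <- substring(tseq, bounds[-length(bounds)] + 1L, bounds[-1])
    gsegs <- if (strand == "+") segs else
      rev(vapply(segs, revcomp, character(1), USE.NAMES = FALSE))
    gaps <- c("", vapply(seq_len(max(length(gsegs) - 1L, 0L)),
                         function(k) rand_seq(sample(40:200, 1)),
                         character(1)))
    pos <- 20L
    contig <- rand_seq(20)
    gstarts <- integer(length(gsegs))
    for (k in seq_along(gsegs)) {
      contig <- paste0(contig, gaps[k])
      pos <- pos + nchar(gaps[k])
      gstarts[k] <- pos
      contig <- paste0(contig, gsegs[k])
      pos <- pos + nchar(gsegs[k])
    }
    contig <- paste0(contig, rand_seq(20))
    exons_asc <- cbind(start = gstarts, end = gstarts + nchar(gsegs))
    exons_tx <- if (strand == "+") exons_asc else
      exons_asc[rev(seq_len(nrow(exons_asc))), , drop = FALSE]
    models[[i]] <- transcript_model(
      paste0(gene_id, ".t1"), gene_id, seqname = paste0("ctg_", gene_id),
      strand = strand, exons = exons_tx, cds_start = utr5_len,
      cds_end = utr5_len + nchar(cds), sequence = tseq)
    contigs[i] <- contig
  }
  names(contigs) <- vapply(models, function(m) m$seqname, character(1))
  list(models = models, genome = contigs)
}

#' Generate a synthetic transcriptome with planted NIF classes
#'
#' Each gene is assigned a NIF class (`none`, `dej`, `uorf`, `long3utr`)
#' and its single transcript is built constructively: the `dej` class gets
#' an exon-exon junction >= 50 nt into the 3'UTR, the `uorf` class gets an
#' AUG with A at -3 and an in-frame stop inside the 5'UTR (ORF >= 30 nt),
#' the `long3utr` class draws its 3'UTR length at or above the long-UTR
#' threshold, and `none` genes are built to violate all three rules (no
#' downstream junction past 49 nt, AUG-free 5'UTR, 3'UTR < 1000 nt).
#'
#' With `tier_design`, the generator additionally emulates the bulk study
#' design: a set of upregulated genes (a subset stabilized, i.e. planted
#' decay-rate decrease in the knockout; a subset NIF-bearing) and a set of
#' transcriptionally downregulated genes. Planted log2 fold changes for
#' upregulated genes are either TE-coupled (above log2TE = 1 the magnitude
#' grows linearly with TE, mirroring the translation dependence of NMD) or
#' a fixed value.
#'
#' @param n_genes Number of genes.
#' @param nif_fractions Named fractions for classes dej/uorf/long3utr among
#'   genes not covered by `tier_design` (remainder is class `none`).
#' @param tier_design `NULL`, or a list with `n_up`, `n_down`,
#'   `n_stabilized`, `n_stab_nif`, `n_up_only_nif` (see
#'   [default_tier_design()]).
#' @param effect_mode `"te_coupled"` or `"fixed"` planted log2FC for
#'   upregulated genes.
#' @param fixed_lfc Planted log2 decay-rate ratio when
#'   `effect_mode = "fixed"`.
#' @param long_utr3_min_nt Planting threshold for the `long3utr` class.
#' @param te_sd Standard deviation of planted per-gene log2 TE.
#' @param seed Random seed; the same seed and parameters regenerate
#'   byte-identical outputs.
#' @param outdir Optional directory; when given, writes `transcripts.gtf`,
#'   `genome.fa` and `truth.tsv` there.
#' @return List with `models`, `genome` (named character vector), `truth`
#'   (data frame) and, when `outdir` is given, the three file paths.
#' @export
gen_transcriptome <- function(n_genes = 2000L,
                              nif_fractions = c(dej = 0.25, uorf = 0.25,
                                                long3utr = 0.25),
                              tier_design = NULL,
                              effect_mode = c("te_coupled", "fixed"),
                              fixed_lfc = 1,
                              long_utr3_min_nt = 1000L,
                              te_sd = 1.2,
                              seed = 1L, outdir = NULL) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(sum(nif_fractions) <= 1)
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  symbols <- sprintf("Gene%04d", seq_len(n_genes))

  is_up <- rep(FALSE, n_genes)
  is_down <- rep(FALSE, n_genes)
  is_stab <- rep(FALSE, n_genes)
  nif_class <- rep(NA_character_, n_genes)

  if (!is.null(tier_design)) {
    td <- tier_design
    stopifnot(td$n_stabilized <= td$n_up,
              td$n_stab_nif <= td$n_stabilized,
              td$n_up_only_nif <= td$n_up - td$n_stabilized,
              td$n_up + td$n_down <= n_genes)
    up_idx <- sample.int(n_genes, td$n_up)
    down_idx <- sample(setdiff(seq_len(n_genes), up_idx), td$n_down)
    is_up[up_idx] <- TRUE
    is_down[down_idx] <- TRUE
    stab_idx <- sample(up_idx, td$n_stabilized)
    is_stab[stab_idx] <- TRUE
    nif_idx <- c(sample(stab_idx, td$n_stab_nif),
                 sample(setdiff(up_idx, stab_idx), td$n_up_only_nif))
    nif_class[nif_idx] <- sample(c("dej", "uorf", "long3utr"),
                                 length(nif_idx), replace = TRUE)
    nif_class[intersect(up_idx, which(is.na(nif_class)))] <- "none"
  }
  free <- which(is.na(nif_class))
  classes <- c(names(nif_fractions), "none")
  probs <- c(nif_fractions, none = 1 - sum(nif_fractions))
  nif_class[free] <- sample(classes, length(free), replace = TRUE,
                            prob = probs)

  models <- vector("list", n_genes)
  contigs <- character(n_genes)
  for (i in seq_len(n_genes)) {
    g <- build_synthetic_gene(gene_ids[i], symbols[i], nif_class[i],
                              long_utr3_min_nt = long_utr3_min_nt)
    models[[i]] <- g$model
    contigs[i] <- g$contig
  }
  names(contigs) <- vapply(models, function(m) m$seqname, character(1))

  tt <- transcript_table(models)
  tx_len <- tt$utr5_len + tt$cds_len + tt$utr3_len

  # expression structure shared by all bulk simulations from this truth
  expr_weight <- stats::rlnorm(n_genes, 0, 1)   # relative transcription
  intron_factor <- stats::runif(n_genes, 0.1, 0.5)

  # Planted TE, recentered so the library-weighted mean IP enrichment is
  # 1: TPM normalization makes measured TE relative, so this puts the
  # planted and measured log2TE on the same scale. In te_coupled mode the
  # upregulated genes split into a well-translated and a little-translated
  # mode (the translation dependence of NMD: only the well-translated
  # mode's magnitude tracks TE; the rest vary in a narrow band).
  planted_te <- stats::rnorm(n_genes, 0, te_sd)
  hi_mode <- rep(FALSE, n_genes)
  if (effect_mode == "te_coupled" && any(is_up)) {
    hi_mode[is_up] <- stats::runif(sum(is_up)) < 0.5
    planted_te[hi_mode] <- 2.0 + abs(stats::rnorm(sum(hi_mode), 0, 1.1))
    planted_te[is_up & !hi_mode] <-
      0.2 - abs(stats::rnorm(sum(is_up & !hi_mode), 0, 0.9))
  }
  wl <- expr_weight * tx_len
  planted_te <- planted_te - log2(sum(wl * 2^planted_te) / sum(wl))

  lfc <- numeric(n_genes)
  if (any(is_up)) {
    if (effect_mode == "fixed") {
      lfc[is_up] <- fixed_lfc
    } else {
      lfc[hi_mode] <- pmax(0.3 + 0.9 * planted_te[hi_mode] +
                             stats::rnorm(sum(hi_mode), 0, 0.25), 0.2)
      lo <- is_up & !hi_mode
      lfc[lo] <- stats::runif(sum(lo), 1.4, 1.9)
    }
  }
  lfc[is_down] <- -stats::runif(sum(is_down), 1, 2.5)
  truth <- data.frame(
    gene_id = gene_ids, transcript_id = tt$transcript_id,
    gene_symbol = symbols, nif_class = nif_class,
    strand = tt$strand, n_exons = tt$n_exons,
    utr5_len = tt$utr5_len, cds_len = tt$cds_len, utr3_len = tt$utr3_len,
    tx_len = tx_len,
    is_upregulated = is_up, is_downregulated = is_down,
    is_stabilized = is_stab,
    planted_log2fc = lfc, planted_te = planted_te,
    expr_weight = expr_weight, intron_factor = intron_factor,
    stringsAsFactors = FALSE)

  out <- list(models = models, genome = contigs, truth = truth, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    gtf <- file.path(outdir, "transcripts.gtf")
    fa <- file.path(outdir, "genome.fa")
    tr <- file.path(outdir, "truth.tsv")
    write_transcript_gtf(models, gtf)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), fa)
    write_tsv(truth, tr)
    out$paths <- list(gtf = gtf, fasta = fa, truth = tr)
  }
  out
}

#' Default bulk tier design
#'
#' The study-design constants the generator emulates: 127 upregulated genes
#' (82 stabilized, 52 of those NIF-bearing, plus 21 NIF-bearing upregulated
#' genes that are not stabilized, i.e. 73 of 127 with at least one NIF) and
#' 108 downregulated genes, in a 2000-gene transcriptome.
#'
#' @export
default_tier_design <- function() {
  list(n_up = 127L, n_down = 108L, n_stabilized = 82L,
       n_stab_nif = 52L, n_up_only_nif = 21L)
}

#' Simulate bulk exonic, intronic and RiboTag-IP count tables
#'
#' Per gene, a transcription rate (genotype-invariant except for planted
#' transcriptional up/down regulation) drives the intronic (pre-mRNA)
#' signal; the exonic (mature mRNA) signal is transcription divided by
#' decay, with decay reduced by `2^planted_log2fc` in the knockout for
#' planted stabilized genes; the IP signal is the exonic signal scaled by
#' `2^planted_te`. Within a sample, the exonic and intronic counts of a
#' gene share one Gamma-distributed biological factor (the replicate's
#' transcription-rate fluctuation), so marginal counts are negative
#' binomial with the stated dispersion while the exon-intron log-ratio
#' cancels most of the biological noise - the property the exon/intron
#' stability design relies on.
#'
#' @param truth Truth data frame from [gen_transcriptome()].
#' @param n_reps RNA-seq replicates per genotype (default 4).
#' @param n_reps_ip RiboTag IP replicates per genotype (default 3).
#' @param depth_exonic,depth_intronic,depth_ip Expected library sizes.
#' @param dispersion Negative-binomial dispersion of the marginal counts.
#' @param seed Random seed.
#' @return List with matrices `exonic`, `intronic`, `ip`, data frames
#'   `sample_sheet` and `sample_sheet_ip`, vector `gene_lengths`, and the
#'   `truth` passed in.
#' @export
simulate_bulk <- function(truth, n_reps = 4L, n_reps_ip = 3L,
                          depth_exonic = 3e6, depth_intronic = 1.5e6,
                          depth_ip = 3e6, dispersion = 0.1, seed = 1L) {
  set.seed(seed)
  n <- nrow(truth)
  w <- truth$expr_weight                 # relative transcription rates
  il <- truth$intron_factor              # intron signal per transcript unit
  len <- truth$tx_len
  shape <- 1 / dispersion

  trans_mult_ko <- ifelse(truth$is_upregulated & !truth$is_stabilized,
                          2^truth$planted_log2fc,
                          ifelse(truth$is_downregulated,
                                 2^truth$planted_log2fc, 1))
  decay_mult_ko <- ifelse(truth$is_stabilized, 2^truth$planted_log2fc, 1)

  draw <- function(genotype, depth_ex, depth_in) {
    tm <- if (genotype == "KO") trans_mult_ko else rep(1, n)
    dm <- if (genotype == "KO") decay_mult_ko else rep(1, n)
    p_ex <- w * tm * dm * len
    p_in <- w * tm * il * len
    mu_ex <- depth_ex * p_ex / sum(p_ex)
    mu_in <- depth_in * p_in / sum(p_in)
    a <- stats::rgamma(n, shape = shape, rate = shape)
    list(ex = stats::rpois(n, mu_ex * a),
         inn = stats::rpois(n, mu_in * a))
  }

  samples <- c(paste0("WT_", seq_len(n_reps)), paste0("KO_", seq_len(n_reps)))
  genos <- rep(c("WT", "KO"), each = n_reps)
  exonic <- matrix(0, n, length(samples),
                   dimnames = list(truth$gene_id, samples))
  intronic <- exonic
  for (s in seq_along(samples)) {
    d <- draw(genos[s], depth_exonic, depth_intronic)
    exonic[, s] <- d$ex
    intronic[, s] <- d$inn
  }

  ip_samples <- c(paste0("WT_IP_", seq_len(n_reps_ip)),
                  paste0("KO_IP_", seq_len(n_reps_ip)))
  ip_genos <- rep(c("WT", "KO"), each = n_reps_ip)
  ip <- matrix(0, n, length(ip_samples),
               dimnames = list(truth$gene_id, ip_samples))
  for (s in seq_along(ip_samples)) {
    tm <- if (ip_genos[s] == "KO") trans_mult_ko else rep(1, n)
    dm <- if (ip_genos[s] == "KO") decay_mult_ko else rep(1, n)
    p_ip <- w * tm * dm * len * 2^truth$planted_te
    mu_ip <- depth_ip * p_ip / sum(p_ip)
    a <- stats::rgamma(n, shape = shape, rate = shape)
    ip[, s] <- stats::rpois(n, mu_ip * a)
  }

  list(exonic = exonic, intronic = intronic, ip = ip,
       sample_sheet = data.frame(sample = samples, genotype = genos,
                                 replicate = rep(seq_len(n_reps), 2),
                                 stringsAsFactors = FALSE),
       sample_sheet_ip = data.frame(sample = ip_samples, genotype = ip_genos,
                                    replicate = rep(seq_len(n_reps_ip), 2),
                                    stringsAsFactors = FALSE),
       gene_lengths = stats::setNames(len, truth$gene_id),
       truth = truth)
}

#' Selection factor reproducing a target knockout selection probability
#'
#' In the single-cell generator, knockout cells draw their dominant
#' receptor after multiplying the weights of a designated receptor subset
#' by a `selection_factor` and renormalizing. The factor that turns a
#' wild-type subset probability `p_wt` into a knockout probability `p_ko`
#' is the odds ratio `odds(p_ko)/odds(p_wt)`.
#'
#' @param p_wt,p_ko Subset selection probabilities in the two genotypes.
#' @export
selection_factor_for <- function(p_wt, p_ko) {
  (p_ko / (1 - p_ko)) / (p_wt / (1 - p_wt))
}

#' Simulate single-cell UMI matrices with one dominant receptor per neuron
#'
#' Every simulated mature or immature olfactory sensory neuron draws one
#' dominant Olfr gene from a categorical distribution over the panel; in
#' knockout cells the weights of the designated subset are multiplied by
#' `selection_factor` and renormalized. The dominant gene receives a high
#' UMI count (Poisson), all other panel genes leak background UMIs, and
#' non-receptor filler genes are expressed at levels that satisfy the QC
#' thresholds. Cells are split evenly over `n_samples` mice per genotype.
#'
#' @param n_cells Cells per genotype.
#' @param n_samples Mice (samples) per genotype.
#' @param n_olfr Size of the Olfr panel.
#' @param n_subset Number of designated subset receptors.
#' @param subset_mass Total wild-type selection probability of the subset.
#' @param selection_factor Multiplier applied to subset weights in the
#'   knockout before renormalization.
#' @param dominant_mean Poisson mean UMI of the dominant receptor.
#' @param background_rate Poisson mean UMI of non-dominant receptors.
#' @param n_other_genes Non-receptor filler genes.
#' @param other_mean Poisson mean UMI of each filler gene.
#' @param n_mito Mitochondrial filler genes.
#' @param mito_mean Poisson mean UMI of each mitochondrial gene.
#' @param cell_type_probs Named probabilities of cell types per cell;
#'   dominant receptors are planted in `mOSN` and `iOSN` cells only.
#' @param ko_cell_type_factors Named multipliers applied to
#'   `cell_type_probs` in the knockout (renormalized), e.g.
#'   `c(HBC = 0.5)` to plant an HBC depletion.
#' @param seed Random seed.
#' @return A `cell_assay` (see [cell_assay()]) with a `truth` element
#'   giving each cell's planted dominant receptor (NA for non-OSN cells).
#' @export
simulate_cells <- function(n_cells = 3200L, n_samples = 4L,
                           n_olfr = 120L, n_subset = 78L,
                           subset_mass = 0.13, selection_factor = 0.5,
                           dominant_mean = 20, background_rate = 0.05,
                           n_other_genes = 600L, other_mean = 3,
                           n_mito = 10L, mito_mean = 0.1,
                           cell_type_probs = c(HBC = 0.08, GBC = 0.12,
                                               iOSN = 0.25, mOSN = 0.55),
                           ko_cell_type_factors = NULL,
                           seed = 1L) {
  stopifnot(n_subset <= n_olfr, subset_mass < 1)
  set.seed(seed)
  olfr_genes <- sprintf("Olfr%04d", seq_len(n_olfr))
  subset_genes <- olfr_genes[seq_len(n_subset)]
  other_genes <- sprintf("Gene%04d", seq_len(n_other_genes))
  mito_genes <- sprintf("mt-Gene%02d", seq_len(n_mito))
  genes <- c(olfr_genes, other_genes, mito_genes)

  w <- stats::runif(n_olfr, 0.5, 1.5)
  in_subset <- seq_len(n_olfr) <= n_subset
  w[in_subset] <- w[in_subset] / sum(w[in_subset]) * subset_mass
  w[!in_subset] <- w[!in_subset] / sum(w[!in_subset]) * (1 - subset_mass)
  w_ko <- w
  w_ko[in_subset] <- w_ko[in_subset] * selection_factor
  w_ko <- w_ko / sum(w_ko)

  build_genotype <- function(genotype) {
    probs <- cell_type_probs
    if (genotype == "KO" && !is.null(ko_cell_type_factors)) {
      probs[names(ko_cell_type_factors)] <-
        probs[names(ko_cell_type_factors)] * ko_cell_type_factors
    }
    probs <- probs / sum(probs)
    types <- sample(names(probs), n_cells, replace = TRUE, prob = probs)
    weights <- if (genotype == "KO") w_ko else w
    is_osn <- types %in% c("mOSN", "iOSN")
    dominant <- rep(NA_character_, n_cells)
    dominant[is_osn] <- sample(olfr_genes, sum(is_osn), replace = TRUE,
                               prob = weights)
    olfr_block <- matrix(stats::rpois(n_cells * n_olfr, background_rate),
                         n_cells, n_olfr)
    idx <- match(dominant[is_osn], olfr_genes)
    olfr_block[cbind(which(is_osn), idx)] <-
      stats::rpois(sum(is_osn), dominant_mean) + 1L
    other_block <- matrix(stats::rpois(n_cells * n_other_genes, other_mean),
                          n_cells, n_other_genes)
    mito_block <- matrix(stats::rpois(n_cells * n_mito, mito_mean),
                         n_cells, n_mito)
    list(m = cbind(olfr_block, other_block, mito_block),
         types = types, dominant = dominant)
  }

  wt <- build_genotype("WT")
  ko <- build_genotype("KO")
  m <- rbind(wt$m, ko$m)
  cell_ids <- c(sprintf("WT_cell%05d", seq_len(n_cells)),
                sprintf("KO_cell%05d", seq_len(n_cells)))
  sample_ids <- c(paste0("WT_m", rep_len(seq_len(n_samples), n_cells)),
                  paste0("KO_m", rep_len(seq_len(n_samples), n_cells)))
  cells <- data.frame(
    cell_id = cell_ids, sample_id = sample_ids,
    genotype = rep(c("WT", "KO"), each = n_cells),
    cell_type = c(wt$types, ko$types), stringsAsFactors = FALSE)
  gene_meta <- data.frame(
    gene_id = genes,
    is_olfr = genes %in% olfr_genes,
    is_mito = genes %in% mito_genes, stringsAsFactors = FALSE)

  assay <- cell_assay(Matrix::Matrix(m, sparse = TRUE,
                                     dimnames = list(cell_ids, genes)),
                      cells, gene_meta)
  assay$truth <- data.frame(
    cell_id = cell_ids, planted_dominant = c(wt$dominant, ko$dominant),
    stringsAsFactors = FALSE)
  assay$subset_genes <- subset_genes
  assay
}
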