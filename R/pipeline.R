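# End-to-end orchestration: NIF annotation -> differential expression ->
# stability -> target tiers -> translome -> single-cell receptor
# statistics, driven by a single config, with a JSON run report.

default_config <- function() {
  list(
    inputs = list(gtf = NULL, fasta = NULL,
                  exonic = NULL, intronic = NULL, sample_sheet = NULL,
                  de = NULL, stability = NULL,
                  ip = NULL, gene_lengths = NULL,
                  sc_mtx = NULL, sc_cells = NULL, sc_genes = NULL,
                  olfr_query = NULL, known_targets = NULL),
    thresholds = list(dej_min_nt = 50L, min_uorf_len = 30L,
                      long_utr3_min_nt = 1000L, nif_scope = "representative",
                      alpha = 0.05, stabilization_min_ddelta = 0,
                      stability_p_adjust = "none",
                      pseudocount = 0.5, window_frac = 0.1,
                      expression_floor = 1, te_pseudocount = 0.1,
                      bin_fractions = c(0.3, 0.4, 0.3),
                      high_te_cutoff = 1,
                      min_features = 500L, min_counts = 1500L,
                      max_mito_frac = 0.002, min_cells = 3L),
    outdir = "nmdscope_out",
    seed = 1L)
}

merge_config <- function(user, defaults) {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown config key: ", nm)
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(user[[nm]], defaults[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' @param config A named list, or the path of a YAML file. Unknown keys
#'   are rejected; omitted keys take the documented defaults.
#' @return The merged config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(config, default_config())
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, null = "null",
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the NMD-target pipeline end to end
#'
#' Executes the stages for which inputs are configured, in dependency
#' order: transcript parsing and NIF annotation (gtf + fasta), differential
#' expression (external table, or the minimal NB test on the exonic
#' counts), exon-intron stability (external table or computed), target
#' tiers, translome statistics (IP counts), and single-cell dominant-Olfr
#' statistics (MTX + metadata). Writes `nif.tsv`, `de.tsv`,
#' `stability.tsv`, `targets.tsv`, `translome.tsv`, `olfr_stats.json`,
#' `report.json` and `run.log` into the output directory.
#'
#' @param config Config list or YAML path (see [load_config()]).
#' @return The report list, invisibly; the output directory holds the
#'   files.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  th <- cfg$thresholds
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$outdir, "run.log")
  cat(sprintf("[%s] nmdscope %s starting\n", format(Sys.time()),
              as.character(utils::packageVersion("nmdscope"))),
      file = logfile)
  logmsg <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                      sprintf(...)),
                              file = logfile, append = TRUE)
  need <- function(key) {
    p <- cfg$inputs[[key]]
    if (is.null(p)) stop("config missing required input: inputs$", key)
    if (!file.exists(p)) stop("input file not found (inputs$", key, "): ", p)
    p
  }
  set.seed(cfg$seed)
  report <- list(version = as.character(utils::packageVersion("nmdscope")),
                 seed = cfg$seed, config = cfg,
                 config_hash = config_hash(cfg))

  nif <- NULL
  gene_lengths <- NULL
  if (!is.null(cfg$inputs$gtf)) {
    models <- parse_annotation(need("gtf"), need("fasta"))
    logmsg("parsed %d transcript models", length(models))
    nif <- profile_transcriptome(
      models,
      nif_thresholds(th$dej_min_nt, th$min_uorf_len, th$long_utr3_min_nt),
      scope = th$nif_scope)
    write_tsv(nif, file.path(cfg$outdir, "nif.tsv"))
    logmsg("NIF profile: %d genes, %d ineligible transcripts",
           nrow(nif), attr(nif, "n_ineligible"))
    gene_lengths <- stats::setNames(
      vapply(models, transcript_length, integer(1)),
      vapply(models, function(m) m$gene_id, character(1)))
  }

  exonic <- intronic <- sample_sheet <- NULL
  if (!is.null(cfg$inputs$exonic)) {
    exonic <- read_count_matrix(need("exonic"))
    sample_sheet <- read_tsv(need("sample_sheet"))
  }
  if (!is.null(cfg$inputs$intronic))
    intronic <- read_count_matrix(need("intronic"))

  de <- NULL
  if (!is.null(cfg$inputs$de)) {
    de <- read_tsv(need("de"))
    logmsg("external DE table: %d genes", nrow(de))
  } else if (!is.null(exonic)) {
    de <- minimal_nb_de(exonic, sample_sheet)
    logmsg("minimal NB DE computed on exonic counts")
  }
  if (!is.null(de)) write_tsv(de, file.path(cfg$outdir, "de.tsv"))

  stab_tab <- NULL
  if (!is.null(cfg$inputs$stability)) {
    stab_tab <- read_tsv(need("stability"))
    logmsg("external stability table: %d genes", nrow(stab_tab))
  } else if (!is.null(exonic) && !is.null(intronic)) {
    stab_tab <- infer_stability(
      exonic, intronic, sample_sheet,
      pseudocount = th$pseudocount, window_frac = th$window_frac,
      stabilization_min_ddelta = th$stabilization_min_ddelta,
      alpha = th$alpha, p_adjust = th$stability_p_adjust)
    logmsg("stability inferred from exonic/intronic counts")
  }
  if (!is.null(stab_tab))
    write_tsv(stab_tab, file.path(cfg$outdir, "stability.tsv"))

  if (!is.null(de) && !is.null(stab_tab) && !is.null(nif)) {
    up <- select_upregulated(de, alpha = th$alpha)
    stab_genes <- stab_tab$gene_id[stab_tab$stabilized]
    tiers <- call_tiers(up, stab_genes, nif)
    write_tsv(tiers, file.path(cfg$outdir, "targets.tsv"))
    report$tier_counts <- tier_counts(tiers)
    logmsg("tiers: %d up, %d stabilized+up, %d candidate, %d high-confidence",
           report$tier_counts$n_upregulated,
           report$tier_counts$n_stabilized_up,
           report$tier_counts$n_candidate_nif,
           report$tier_counts$n_high_confidence)
    if (!is.null(cfg$inputs$known_targets)) {
      known <- readLines(need("known_targets"))
      hc <- tiers$gene_id[tiers$tier == "high_confidence"]
      sym <- nif$gene_symbol[match(hc, nif$gene_id)]
      ov <- overlap_known_targets(ifelse(is.na(sym), hc, sym), known)
      report$known_target_overlap <- ov$count
    }
  }

  if (!is.null(cfg$inputs$ip) && !is.null(exonic)) {
    ip <- read_count_matrix(need("ip"))
    if (is.null(gene_lengths)) {
      gl <- read_tsv(need("gene_lengths"))
      gene_lengths <- stats::setNames(gl[[2]], gl[[1]])
    }
    common <- intersect(rownames(exonic), rownames(ip))
    wt_cols <- sample_sheet$sample[sample_sheet$genotype == "WT"]
    te <- compute_te(exonic[common, wt_cols, drop = FALSE],
                     ip[common, grepl("^WT", colnames(ip)), drop = FALSE],
                     gene_lengths[common],
                     expression_floor = th$expression_floor,
                     pseudocount = th$te_pseudocount)
    te <- bin_translome(te, th$bin_fractions)
    write_tsv(te, file.path(cfg$outdir, "translome.tsv"))
    report$n_expressed <- nrow(te)
    report$category_counts <- as.list(table(te$category))
    logmsg("translome: %d expressed genes binned", nrow(te))
  }

  if (!is.null(cfg$inputs$sc_mtx)) {
    assay <- read_cell_assay(need("sc_mtx"), need("sc_cells"),
                             need("sc_genes"))
    assay <- qc_filter(assay, th$min_features, th$min_counts,
                       th$max_mito_frac, th$min_cells)
    logmsg("QC: %d cells removed, %d genes removed",
           attr(assay, "n_cells_removed"), attr(assay, "n_genes_removed"))
    query <- if (!is.null(cfg$inputs$olfr_query))
      readLines(need("olfr_query")) else
      assay$genes$gene_id[assay$genes$is_olfr]
    olfr_stats <- list()
    for (geno in c("WT", "KO")) {
      sel <- assay$cells$cell_id[assay$cells$genotype == geno &
                                   assay$cells$cell_type == "mOSN"]
      calls <- call_dominant_olfr(assay, sel)
      olfr_stats[[geno]] <- subset_dominance_fraction(calls, query)
    }
    cmp <- compare_fractions(olfr_stats$WT$k, olfr_stats$WT$n,
                             olfr_stats$KO$k, olfr_stats$KO$n)
    olfr_stats$comparison <- cmp[c("p", "odds_ratio", "method")]
    jsonlite::write_json(olfr_stats,
                         file.path(cfg$outdir, "olfr_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    report$dominance <- olfr_stats
    logmsg("dominance: WT %d/%d (%d%%), KO %d/%d (%d%%), p=%.3g",
           olfr_stats$WT$k, olfr_stats$WT$n, olfr_stats$WT$percent_display,
           olfr_stats$KO$k, olfr_stats$KO$n, olfr_stats$KO$percent_display,
           cmp$p)
  }

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  logmsg("done")
  invisible(report)
}
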