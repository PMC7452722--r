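#' Construct a cell x gene UMI assay
#'
#' Thin container tying a sparse cell-by-gene UMI count matrix to aligned
#' cell metadata (cell_id, sample_id, genotype, cell_type) and gene
#' metadata (gene_id, is_olfr, is_mito).
#'
#' @param counts Sparse (or dense) cell x gene matrix of non-negative
#'   integer UMI counts; dimnames must match the metadata.
#' @param cells Data frame with columns `cell_id`, `sample_id`, `genotype`,
#'   `cell_type`, one row per matrix row.
#' @param genes Data frame with columns `gene_id`, `is_olfr`, `is_mito`,
#'   one row per matrix column.
#' @return Object of class `cell_assay`.
#' @export
cell_assay <- function(counts, cells, genes) {
  counts <- methods::as(counts, "CsparseMatrix")
  stopifnot(nrow(counts) == nrow(cells), ncol(counts) == nrow(genes),
            all(c("cell_id", "sample_id", "genotype", "cell_type") %in%
                  names(cells)),
            all(c("gene_id", "is_olfr", "is_mito") %in% names(genes)))
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("UMI counts must be non-negative integers")
  dimnames(counts) <- list(cells$cell_id, genes$gene_id)
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "cell_assay")
}

#' @export
print.cell_assay <- function(x, ...) {
  cat(sprintf("cell_assay: %d cells x %d genes (%d Olfr, %d mito)\n",
              nrow(x$counts), ncol(x$counts), sum(x$genes$is_olfr),
              sum(x$genes$is_mito)))
  invisible(x)
}

#' Read a cell assay from MTX plus metadata TSVs
#'
#' The matrix on disk is cell x gene MatrixMarket; `cells_path` and
#' `genes_path` are tab-delimited with the metadata columns described in
#' [cell_assay()].
#'
#' @param mtx_path,cells_path,genes_path File paths.
#' @return A `cell_assay`.
#' @export
read_cell_assay <- function(mtx_path, cells_path, genes_path) {
  m <- Matrix::readMM(mtx_path)
  cells <- read_tsv(cells_path)
  genes <- read_tsv(genes_path)
  cell_assay(m, cells, genes)
}

#' Write a cell assay as MTX plus metadata TSVs
#'
#' @param assay A `cell_assay`.
#' @param dir Output directory (created if needed).
#' @return Paths of the three files, invisibly.
#' @export
write_cell_assay <- function(assay, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(mtx = file.path(dir, "matrix.mtx"),
                cells = file.path(dir, "cells.tsv"),
                genes = file.path(dir, "genes.tsv"))
  Matrix::writeMM(assay$counts, paths$mtx)
  write_tsv(assay$cells, paths$cells)
  write_tsv(assay$genes, paths$genes)
  invisible(paths)
}

#' Quality-filter a cell assay
#'
#' Cells are retained when they exceed `min_features` detected genes and
#' `min_counts` UMIs and fall below `max_mito_frac` mitochondrial UMI
#' fraction; genes are retained when detected in at least `min_cells`
#' retained cells. Cell and gene filtering are iterated to a fixed point,
#' so filtering an already-filtered assay changes nothing.
#'
#' @param assay A `cell_assay`.
#' @param min_features Detected-gene threshold (strictly greater than;
#'   default 500).
#' @param min_counts UMI threshold (strictly greater than; default 1500).
#' @param max_mito_frac Mitochondrial fraction ceiling (strictly less
#'   than; default 0.002, i.e. 0.2 percent).
#' @param min_cells Gene detection floor (at least this many cells;
#'   default 3).
#' @return Filtered `cell_assay`; attributes `n_cells_removed` and
#'   `n_genes_removed` record the totals.
#' @export
qc_filter <- function(assay, min_features = 500L, min_counts = 1500L,
                      max_mito_frac = 0.002, min_cells = 3L) {
  n_cells0 <- nrow(assay$counts)
  n_genes0 <- ncol(assay$counts)
  if (n_cells0 == 0 || n_genes0 == 0) {
    warning("empty assay; nothing to filter")
    return(assay)
  }
  repeat {
    m <- assay$counts
    detected <- Matrix::rowSums(m > 0)
    total <- Matrix::rowSums(m)
    mito <- if (any(assay$genes$is_mito))
      Matrix::rowSums(m[, assay$genes$is_mito, drop = FALSE]) else 0
    mito_frac <- ifelse(total > 0, mito / total, 0)
    keep_cells <- detected > min_features & total > min_counts &
      mito_frac < max_mito_frac
    m2 <- m[keep_cells, , drop = FALSE]
    keep_genes <- Matrix::colSums(m2 > 0) >= min_cells
    if (all(keep_cells) && all(keep_genes)) break
    assay <- cell_assay(m2[, keep_genes, drop = FALSE],
                        assay$cells[keep_cells, , drop = FALSE],
                        assay$genes[keep_genes, , drop = FALSE])
    if (nrow(assay$counts) == 0 || ncol(assay$counts) == 0) {
      warning("QC filter removed all cells or genes")
      break
    }
  }
  attr(assay, "n_cells_removed") <- n_cells0 - nrow(assay$counts)
  attr(assay, "n_genes_removed") <- n_genes0 - ncol(assay$counts)
  assay
}

#' Call the dominant Olfr gene of each cell
#'
#' The dominant receptor of a cell is the Olfr gene with the highest UMI
#' count in that cell. Ties are broken deterministically: first by the
#' higher total UMI count of the gene across the analyzed cell subset,
#' then by lexicographically smaller gene id. Cells with zero Olfr UMIs
#' get no call (`NA`).
#'
#' @param assay A `cell_assay` with `is_olfr` flags set.
#' @param cells Optional character vector of cell ids to restrict to.
#' @return Data frame: `cell_id`, `dominant_gene` (NA when absent),
#'   `dominant_umi`, `total_olfr_umi`.
#' @export
call_dominant_olfr <- function(assay, cells = NULL) {
  keep <- if (is.null(cells)) rep(TRUE, nrow(assay$counts)) else
    assay$cells$cell_id %in% cells
  m <- as.matrix(assay$counts[keep, assay$genes$is_olfr, drop = FALSE])
  olfr_ids <- assay$genes$gene_id[assay$genes$is_olfr]
  totals <- colSums(m)
  # tie-break ordering: by descending subset-wide total, then gene id
  pref <- order(-totals, olfr_ids)
  m_ord <- m[, pref, drop = FALSE]
  ids_ord <- olfr_ids[pref]
  best_idx <- max.col(m_ord, ties.method = "first")
  best_umi <- m_ord[cbind(seq_len(nrow(m_ord)), best_idx)]
  total_olfr <- rowSums(m)
  data.frame(
    cell_id = assay$cells$cell_id[keep],
    dominant_gene = ifelse(total_olfr == 0, NA_character_,
                           ids_ord[best_idx]),
    dominant_umi = ifelse(total_olfr == 0, 0L, best_umi),
    total_olfr_umi = total_olfr,
    stringsAsFactors = FALSE)
}

#' Fraction of a count out of a population, with display rounding
#'
#' Internal full-precision percentage plus the integer-rounded display
#' value used in reports.
#'
#' @param k,n Numerator and denominator counts.
#' @return List: `k`, `n`, `percent` (full precision), `percent_display`
#'   (rounded to the nearest integer).
#' @export
dominance_fraction <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  pct <- 100 * k / n
  list(k = as.integer(k), n = as.integer(n), percent = pct,
       percent_display = round(pct))
}

#' Fraction of cells whose dominant receptor falls in a query set
#'
#' @param calls Output of [call_dominant_olfr()].
#' @param query Character vector of Olfr gene ids.
#' @param denominator `"all_cells"` (default; all cells in `calls`) or
#'   `"called_cells"` (cells with at least one Olfr UMI).
#' @return As [dominance_fraction()].
#' @export
subset_dominance_fraction <- function(calls, query,
                                      denominator = c("all_cells",
                                                      "called_cells")) {
  denominator <- match.arg(denominator)
  k <- sum(!is.na(calls$dominant_gene) & calls$dominant_gene %in% query)
  n <- if (denominator == "all_cells") nrow(calls) else
    sum(!is.na(calls$dominant_gene))
  dominance_fraction(k, n)
}

#' Compare two proportions
#'
#' Two-sided chi-square test without continuity correction; Fisher's exact
#' test is substituted when any expected cell count is below 5. The odds
#' ratio and its 95 percent Wald confidence interval are reported.
#'
#' @param k_wt,n_wt Wild-type numerator and denominator.
#' @param k_ko,n_ko Knockout numerator and denominator.
#' @return List: `p`, `odds_ratio`, `conf_int`, `method`.
#' @export
compare_fractions <- function(k_wt, n_wt, k_ko, n_ko) {
  stopifnot(n_wt > 0, n_ko > 0)
  tab <- matrix(c(k_wt, n_wt - k_wt, k_ko, n_ko - k_ko), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    p <- ft$p.value
    method <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    method <- "chisq"
  }
  or <- (k_wt / max(n_wt - k_wt, 0.5)) / (k_ko / max(n_ko - k_ko, 0.5))
  se <- sqrt(1 / max(k_wt, 0.5) + 1 / max(n_wt - k_wt, 0.5) +
               1 / max(k_ko, 0.5) + 1 / max(n_ko - k_ko, 0.5))
  ci <- exp(log(or) + c(-1.96, 1.96) * se)
  list(p = p, odds_ratio = or, conf_int = ci, method = method)
}

#' Compare cell-subset frequencies between genotypes
#'
#' Computes, per sample (mouse), the fraction of cells carrying a given
#' cluster label - either out of all OSN-lineage cells (`per_all_osn`:
#' HBC, GBC, iOSN, mOSN) or out of all cells (`per_all_cells`) - and
#' compares genotypes with a two-sided Welch t-test on the per-sample
#' fractions. The sample, not the cell, is the replicate unit.
#'
#' @param assay A `cell_assay`.
#' @param cluster Cell-type label of interest (e.g. `"HBC"`).
#' @param level `"per_all_osn"` or `"per_all_cells"`.
#' @param osn_types Labels counted as OSN lineage.
#' @return List: `fractions` (data frame sample/genotype/fraction), `p`,
#'   `mean_wt`, `mean_ko`.
#' @export
compare_subset_frequencies <- function(assay, cluster,
                                       level = c("per_all_osn",
                                                 "per_all_cells"),
                                       osn_types = c("HBC", "GBC", "iOSN",
                                                     "mOSN")) {
  level <- match.arg(level)
  cells <- assay$cells
  denom_cells <- if (level == "per_all_osn")
    cells[cells$cell_type %in% osn_types, ] else cells
  per_sample <- lapply(split(denom_cells, denom_cells$sample_id),
                       function(d) data.frame(
                         sample = d$sample_id[1], genotype = d$genotype[1],
                         fraction = mean(d$cell_type == cluster),
                         stringsAsFactors = FALSE))
  fr <- do.call(rbind, per_sample)
  rownames(fr) <- NULL
  wt <- fr$fraction[fr$genotype == "WT"]
  ko <- fr$fraction[fr$genotype == "KO"]
  if (length(wt) < 2 || length(ko) < 2)
    stop("need >= 2 samples per genotype")
  tt <- stats::t.test(wt, ko)
  list(fractions = fr, p = tt$p.value, mean_wt = mean(wt), mean_ko = mean(ko))
}
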