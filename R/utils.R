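# small shared helpers

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Write a data frame as a tab-delimited file
#'
#' Tab-delimited, header line, no quoting, `.` for missing values (the
#' on-disk convention used by every pipeline output).
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a tab-delimited file written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

read_count_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

write_count_matrix <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

# Welch two-sample t-test, vectorized over rows of two matrices.
# Returns list(diff, p, df). Zero pooled variance: p = 1 if diff == 0 else 0.
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  d <- m1 - m2
  tt <- d / sqrt(se2)
  dfw <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), dfw)
  zero <- !is.finite(tt)
  p[zero] <- ifelse(d[zero] == 0, 1, 0)
  list(diff = d, p = p, df = dfw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
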