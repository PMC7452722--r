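# Brute-force oracles, written independently of the package internals:
# plain loops over every candidate position, applying the biological rules
# literally. They are deliberately slow and simple.

# exhaustive junction scan: walk exons, accumulate widths, test every
# junction coordinate against the downstream-distance rule
oracle_dej <- function(model, dej_min_nt = 50) {
  widths <- model$exons[, "end"] - model$exons[, "start"]
  best <- NA_integer_
  hit <- FALSE
  acc <- 0
  for (k in seq_along(widths)) {
    acc <- acc + widths[k]
    if (k == length(widths)) break
    j <- acc - 1                       # last base of exon k, 0-based
    if (j >= model$cds_end) {
      d <- j - model$cds_end + 1
      if (is.na(best) || d > best) best <- d
      if (d >= dej_min_nt) hit <- TRUE
    }
  }
  list(has_dej = hit, dej_max_distance = best)
}

# exhaustive AUG enumeration: test every position in every frame of the
# 5'UTR against all four uORF criteria
oracle_uorfs <- function(model, min_uorf_len = 30) {
  s <- strsplit(model$sequence, "")[[1]]
  cds_start <- model$cds_start
  starts <- integer(0)
  if (cds_start >= 3) {
    for (i in 0:(cds_start - 3)) {         # 0-based AUG start candidates
      if (!(s[i + 1] == "A" && s[i + 2] == "T" && s[i + 3] == "G")) next
      if (i < 3) next                                    # needs -3
      if (i + 4 > length(s)) next                        # needs +4
      ctx <- s[i - 2] %in% c("A", "G") || s[i + 4] == "G"
      if (!ctx) next
      # find the first in-frame stop, anywhere in the transcript
      stop_end <- NA
      p <- i + 3
      while (p + 3 <= length(s)) {
        codon <- paste(s[(p + 1):(p + 3)], collapse = "")
        if (codon %in% c("TAA", "TAG", "TGA")) { stop_end <- p + 3; break }
        p <- p + 3
      }
      if (is.na(stop_end)) next                          # no ORF at all
      if (stop_end > cds_start) next                     # overlaps main ORF
      if (stop_end - i < min_uorf_len) next              # too short
      starts <- c(starts, i)
    }
  }
  starts
}

# naive per-cell loop recomputation of the exon-intron delta statistic
oracle_delta <- function(exonic, intronic, pseudocount = 0.5) {
  out <- matrix(NA_real_, nrow(exonic), ncol(exonic),
                dimnames = dimnames(exonic))
  for (g in seq_len(nrow(exonic))) for (smp in seq_len(ncol(exonic))) {
    out[g, smp] <-
      log2((exonic[g, smp] + pseudocount) / sum(exonic[, smp])) -
      log2((intronic[g, smp] + pseudocount) / sum(intronic[, smp]))
  }
  out
}

# naive per-gene TPM and TE
oracle_te <- function(input_counts, ip_counts, lengths, floor = 1,
                      pseudo = 0.1) {
  tpm1 <- function(cnt) {
    r <- numeric(length(cnt))
    for (g in seq_along(cnt)) r[g] <- cnt[g] / lengths[g]
    r / sum(r) * 1e6
  }
  tin <- rowMeans(apply(input_counts, 2, tpm1))
  tip <- rowMeans(apply(ip_counts, 2, tpm1))
  keep <- tin >= floor
  data.frame(gene_id = rownames(input_counts)[keep],
             log2te = log2((tip[keep] + pseudo) / (tin[keep] + pseudo)))
}

# nif class predicted from a profile row, for truth comparisons
profile_class <- function(prof) {
  ifelse(prof$has_dej, "dej",
         ifelse(prof$has_uorf, "uorf",
                ifelse(prof$has_long_utr3, "long3utr", "none")))
}
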