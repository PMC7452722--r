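# nmdscope

Identification of in vivo nonsense-mediated mRNA decay (NMD) target mRNAs
from bulk and single-cell RNA-seq of wild-type versus NMD-deficient
tissue, with downstream olfactory-receptor selection statistics.

NMD degrades its substrates, so a tissue's direct targets must be inferred
from pathway loss. `nmdscope` combines three lines of evidence into target
tiers, following the analytic chain used to define high-confidence NMD
targets in mature olfactory sensory neurons (mOSNs) of *Upf3b*-null mice:

1. **Upregulation** in the knockout (padj < 0.05, log2FC > 0) — NMD is a
   negative regulator, so its targets rise when it fails.
2. **Stabilization** — the exon–intron statistic
   Δ = log2(exonic density) − log2(intronic density) separates decay from
   transcription (intronic reads track pre-mRNA, i.e. transcription;
   exonic reads track mature mRNA, i.e. transcription/decay), so
   ΔΔ = Δ(KO) − Δ(WT) estimates the log2 decay-rate change.
3. **NMD-inducing features (NIFs)** from a per-transcript sequence scan:
   - **dEJ** — an exon-exon junction ≥ 50 nt downstream of the main ORF's
     stop codon (the "−50-nt boundary rule");
   - **uORF** — an upstream ORF (≥ 30 nt, AUG through stop) contained in
     the 5'UTR with a favorable initiation context (purine at −3 or G at
     +4);
   - **long 3'UTR** — ≥ 1,000 nt by default (configurable).

Upregulated ∧ NIF = *candidate*; upregulated ∧ stabilized ∧ NIF =
*high-confidence*. The package also computes RiboTag translation
efficiency (TE = log2 IP TPM / input TPM) with 30/40/30 strata and the
3×3 expression×TE grid, per-cell dominant olfactory-receptor calls with
genotype selection-fraction tests, a minimal negative-binomial DE test as
plumbing, and a synthetic-data generator that plants ground truth for
every stage.

## Worked example

A complete synthetic study — 2,000-gene transcriptome scaled to 1,000
genes here, with 127 planted upregulated genes of which 82 stabilized and
52 NIF-bearing — analyzed end to end with estimated (not planted) DE and
stability:

```r
library(nmdscope)

g  <- gen_transcriptome(1000, tier_design = default_tier_design(), seed = 1)
b  <- simulate_bulk(g$truth, seed = 1)
de <- minimal_nb_de(b$exonic, b$sample_sheet)
st <- infer_stability(b$exonic, b$intronic, b$sample_sheet)
prof  <- profile_transcriptome(g$models)
tiers <- call_tiers(select_upregulated(de),
                    st$gene_id[st$stabilized], prof)
unlist(tier_counts(tiers))
#>     n_upregulated   n_stabilized_up   n_candidate_nif n_high_confidence
#>               128                82                75                52
head(tiers[, c("gene_id", "upregulated", "stabilized", "n_nifs", "tier")], 4)
#>   gene_id upregulated stabilized n_nifs            tier
#> 1   g0022        TRUE       TRUE      1 high_confidence
#> 2   g0040        TRUE       TRUE      1 high_confidence
#> 3   g0045        TRUE       TRUE      1 high_confidence
#> 4   g0051        TRUE       TRUE      1 high_confidence
```

The estimated tiers (128/82/75/52) recover the planted design (127/82/73/52)
within sampling error; given truth DE and stability tables the pipeline
reproduces it exactly.

The published desk-verifiable numbers ship as plain-text fixtures:

```r
ov <- overlap_known_targets(mosn_target_table()$gene_symbol,
                            prior_nmd_targets())
ov$count
#> [1] 11
wt  <- dominance_fraction(490, 3887)     # WT mOSNs with a subset-dominant Olfr
cmp <- compare_fractions(490, 3887, 328, 4654)
sprintf("WT: %d/%d = %.1f%% (display %d%%), chi-square p = %.2g",
        wt$k, wt$n, wt$percent, wt$percent_display, cmp$p)
#> [1] "WT: 490/3887 = 12.6% (display 13%), chi-square p = 3.5e-18"
```

`run_pipeline(config)` (list or YAML; see `?load_config` for keys and
defaults) orchestrates the stages end to end and writes `nif.tsv`,
`de.tsv`, `stability.tsv`, `targets.tsv`, `translome.tsv`,
`olfr_stats.json`, and a `report.json` with tier counts, thresholds, and
provenance. A thin command-line front-end lives at
`inst/scripts/nmdscope` (`nif`, `run`, `simulate` subcommands).

The methods vignette (`vignettes/nmd-target-discovery.Rmd`) documents the
models, every tunable threshold with its default and rationale, the
synthetic generator's design, and known limitations.

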