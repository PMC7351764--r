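# gecpop — dim and bright glomerular endothelial cell subpopulations

Glomerular endothelial cells (GEC) carrying a Tek-driven tdTomato
reporter split into two reproducible classes — a **dim** and a
**bright** subpopulation — visible both in confocal z-stacks of intact
glomeruli and in flow cytometry of glomerular digests. In wild-type
mice the composition is roughly 40% dim / 60% bright; in Alport
(Col4a3-deficient) mice the balance shifts toward bright cells. This
package implements the quantitative machinery needed to identify and
characterize these subpopulations, and ships seeded synthetic-data
generators so the whole chain is testable end to end without any
external download.

## What it computes

**Confocal morphometry.** For each candidate cell, the maximum reporter
intensity inside a 1.5 µm ROI is traced across depth. Peaks that form
plateaus (detector saturation) are discarded, peaks deeper than 35 µm
are excluded, and the densest 15 µm depth window is retained. Each
glomerulus's peak intensities are then split into bright and dim at the
largest adjacent gap of the sorted values — the split is accepted only
when the between-group gap strictly exceeds every within-group gap:

    sort x (1) ≥ … ≥ x (n);  cut at argmax_c [ x (c) − x (c+1) ]

Per-glomerulus composition is pooled and Welch's t-test (two-tailed,
unpaired, Welch–Satterthwaite df) compares bright vs dim mean
intensities.

**Cytometry.** Debris (scatter floor) and doublets (area/height ratio
ceiling) are gated out; the negative/dim and dim/bright thresholds are
placed at the deepest valleys of a kernel-density estimate of
log-intensity; composition percentages use the reporter-positive pool
as denominator; marker positivity (Ehd3-like, WT1-like channels) is the
fraction of events at or above a cutoff.

**Expression set algebra.** CPM/RPKM normalization, a clearly labeled
t-based stand-in DE test with an edgeR-compatible table schema, the
published cutoff policy (p < 0.05, logCPM > 1, |log2FC| ≥ 1.5), four-way
Venn decomposition with margin checks, inversely regulated genes
(significant in both contrasts with opposite fold-change signs), and
transcripts solely expressed in one subpopulation (RPKM ≥ 1 in every
replicate of one side, < 1 in every replicate of the other).

**Enrichment and quantitation.** Hypergeometric over-representation
P[X ≥ k] with BH adjustment; 2^−ΔΔCt (Livak) relative qPCR
quantification; housekeeping-normalized densitometry ratios.

## Worked example

```r
library(gecpop)

# 20,000 synthetic wild-type cytometry events, full chain
sim <- gen_facs_events(sim_config("WT"), seed = 1)
res <- cytometry_pipeline(sim$events)
round(res$stats[, c("pct_dim_of_positive", "pct_bright_of_positive",
                    "pct_positive_of_total")], 1)
#>   pct_dim_of_positive pct_bright_of_positive pct_positive_of_total
#> 1                38.1                   61.9                  49.9
```

38.1% of reporter-positive events are classified dim and 61.9% bright —
the wild-type preset composition (39/61) recovered through gating,
automatic threshold estimation and classification. The full synthetic
study (imaging → cytometry → expression → enrichment → quantitation) is
scripted as numbered drivers under `analysis/`; run them in order from
the repository root after installing the package:

```sh
Rscript analysis/01_simulate.R     # writes results/data/
Rscript analysis/02_morphometry.R  # composition + Welch test
Rscript analysis/03_cytometry.R    # WT/AS composition, marker positivity
Rscript analysis/04_expression_sets.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_quantitation.R
```

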