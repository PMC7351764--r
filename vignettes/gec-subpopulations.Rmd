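---
title: "Quantifying dim and bright glomerular endothelial cell subpopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dim and bright glomerular endothelial cell subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gecpop)
```

## The problem

Endothelial cells lining the glomerular capillaries of reporter mice
(tdTomato driven from the Tek promoter) are not a homogeneous pool:
both confocal imaging of intact glomeruli and flow cytometry of
glomerular digests resolve a *dim* and a *bright* reporter-intensity
class. Quantifying that split — per glomerulus in images, per digest in
cytometry, and per subpopulation at the transcriptome level — is the
analysis this package implements. Because the original measurements are
microscope and cytometer sessions, every stage here is exercised on
synthetic data with known ground truth; the generators are first-class,
tested code, and their presets encode the study conditions (wild-type
composition 40/60 in imaging and 39/61 in cytometry, Alport 22/78,
eight glomeruli with ~11 analyzable cells each, four expression groups
with three replicates).

## Imaging morphometry

Each cell is measured through a 1.5 µm-diameter ROI: per z-slice the
maximum intensity inside the disk, after re-centering the seed within a
1 µm radius so the recorded peak is the highest attainable locally
(the manual protocol places the ROI "such that the signal is measured
at its peak"; a small deterministic search is the reproducible analog).

Quality control and filtering follow the published protocol, with the
two knobs the protocol leaves verbal made explicit and configurable:

* **Plateau exclusion.** A peak is a plateau when the longest run of
  samples within 5% of the profile maximum (`plateau_tolerance`)
  reaches 4 samples (`plateau_min_width`, i.e. 2 µm at the 0.5 µm
  z-step). Saturated acquisitions clip at the 12-bit ceiling and
  produce exactly this signature; clean Gaussian peaks at our axial
  blob width stay ~3 samples wide at the 95% level, so the defaults
  separate the two by construction. Before the run test the 20% lower
  quantile of the profile is subtracted, so a constant background
  offset does not flatten the relative variation of dim cells.
* **Depth and range filters.** Peaks deeper than 35 µm are dropped,
  then the densest 15 µm depth window is retained. The window anchor is
  not defined in the protocol; anchoring candidate windows at each peak
  depth and keeping the most populated one (ties toward smaller mean
  depth) is the unique order-independent reading.

The bright/dim boundary is the largest adjacent gap of the sorted peak
values, accepted only when that gap strictly exceeds every other
adjacent gap — the published criterion that between-group separation
exceed within-group separation. Two equal maximal gaps flag the
glomerulus as ambiguous rather than silently picking one. In the
pipeline the gap is measured on the **log** scale: fluorescence classes
differ multiplicatively, and depth attenuation stretches the linear
scale of the bright group far more than the dim group, so a linear gap
can exceed the class separation within a handful of bright cells while
the log gap cannot. `split_bright_dim()` defaults to the linear scale
and takes `log = TRUE`; labels are invariant to input order and to
positive rescaling either way.

Composition percentages use bright + dim as denominator and Welch's
t-test (implemented directly from the statistic and the
Welch–Satterthwaite df, cross-checked against `stats::t.test` in the
suite) compares per-glomerulus class means.

## Cytometry

Gating is a scalar stand-in for the acquisition GUI's polygon gates,
which exist only as figures: an absolute forward-scatter floor removes
debris (synthetic debris occupy the bottom of the scatter range by
construction) and an area/height ratio ceiling of 1.5 removes doublets.
Thresholds between the negative, dim and bright components are placed
at the deepest density minima between the three highest modes of a
Gaussian-kernel density estimate (Silverman bandwidth) of log
intensity; fixed overrides in `gate_config()` keep unattended runs
reproducible and are required when fewer than three modes exist.
Subpopulation percentages are reported over the reporter-positive pool
— the denominator the study's composition figures use — with the
positive fraction of all gated events reported separately.

## Expression set algebra

The DE step is deliberately a **stand-in**: a per-gene Welch t-test on
log2(CPM + 0.5) with BH adjustment and a ratio-of-means log2 fold
change. It is not an exact negative-binomial test — at three replicates
it is conservative (measured type-I error ≈ 0.037 at α = 0.05; it
reaches its nominal size by ten replicates, which is what the
calibration test uses) — but its table schema matches externally
produced DGE tables, so either source feeds the downstream set algebra.
The published cutoffs (p < 0.05, logCPM > 1, logFC > 1.5) are applied
with the fold-change threshold read on the log2 scale, the scale DE
tools report; a p-only mode exists because the inverse-regulation table
includes genes below the fold-change cutoff (e.g. |FC| ≈ 1.1). Venn
decomposition partitions the universe into commonly up/down, one-side
only, discordant and non-significant regions, and re-derives the
per-contrast totals from the regions as a consistency check — the same
margin arithmetic that ties the published region counts (totals 1,564
and 2,627; shared down 497; one-side counts 455/1,498/470/490) to a
shared up-count of 142 from either margin. Solely expressed transcripts
default to an RPKM ≥ 1 threshold, the conventional detection floor,
applied to every replicate of both sides.

## Enrichment and quantitation

Over-representation is the flat hypergeometric upper tail through
`stats::phyper` with BH adjustment; the suite checks it against an
explicit log-space tail summation to 1e-10. Ontology-graph
decorrelation (conditional testing) is deliberately not implemented;
any term → gene mapping is accepted and the effective universe is the
assayed one. Because the hypergeometric null is discrete, the null
calibration test compares empirical rejection at p ≤ 0.05 to the
*attained* level of the discrete null rather than to 0.05 itself.

The 2^−ΔΔCt method averages replicate Ct values arithmetically before
differencing (the aggregation is not specified in the protocol; a
per-replicate variant is available by flag) with amplification
efficiency fixed at 2. Densitometry ratios are target/housekeeping per
sample, invariant to global exposure scaling.

## The synthetic generators

* **Imaging.** Cells are 3D Gaussian blobs (σ_xy 1.6 µm, σ_z 2 µm) on a
  128 px × 0.5 µm lateral grid, 0.5 µm z-step, 50 µm stack. Peak
  amplitudes are class-conditional log-normals (dim ~150, bright ~1500
  arbitrary 12-bit units, sdlog 0.15 — Bayes error far below 1%)
  attenuated by exp(−z/50 µm). Analyzable cells sit at 5–19 µm so the
  15 µm range filter is exercised but not lossy on clean cells; 10% of
  cells are placed below 35 µm to exercise the depth filter and 10% are
  rendered saturated (clipped at 4095) to exercise the plateau filter —
  saturation is assigned independently of class so shape-QC exclusion
  stays composition-neutral. Noise is Poisson on signal plus background
  (40 counts) with Gaussian read noise (σ = 4), added last. Dim/bright
  labels are allocated across glomeruli by largest remainder, so the
  realized composition equals the preset as closely as integer counts
  allow — emulating the tight per-animal composition of the source
  dot plots while leaving within-glomerulus assignment random; the FACS
  generator, with 20,000 events, keeps fully independent draws.
* **Cytometry.** A three-component log-normal intensity mixture
  (negative/dim/bright at ~30/300/3000, sdlog 0.35), 50% reporter
  positive, 5% debris and 3% doublets by default; marker channels are
  positive with the preset probabilities (Ehd3-like 0.95–0.96, WT1-like
  0.02) independent of reporter class.
* **Expression.** Negative-binomial counts, gene means log-normal
  (median 100, sdlog 1), dispersion 0.04 (biological CV 20%, typical
  for genetically identical sorted material). Planted effects: 4% DE
  per within-genotype contrast at |log2FC| = 2, 0.5% inversely
  regulated (sign flips between genotypes), 20 solely expressed genes
  (mean forced ≥ 80 on the expressed side, 0.001 on the excluded side).

What the generators deliberately do **not** model: optics beyond
Gaussian blobs (no PSF tails, no scattering), spectral spillover,
compensation, cytometer file formats (tables are TSV, not FCS),
library-composition biases that TMM-style normalization corrects, and
correlated gene expression. Passing tests therefore demonstrate that
the analysis chain recovers known structure under the stated noise
models — not that it is robust to every artifact of real acquisitions.

## Problem sizes and numerical choices

The shipped presets — 8 glomeruli × 11 cells (≈ the study's n = 87
cells), 20,000 events per cytometry run, 5,000 genes × 12 samples — run
the full chain in seconds and give Monte-Carlo standard errors
comfortably inside the tolerances used in the tests (binomial SE ≈ 0.35
percentage points at n = 20,000; the imaging estimator, at ~70 cells
after QC, has an SD of ≈ 3 percentage points, which is why its recovery
band is ±5 while the cytometry bands are ±2). Degenerate inputs are
defined errors, not crashes: fewer than two values to split, fewer than
two replicates per group, unimodal intensity distributions without
threshold overrides, ROIs outside the image. All randomness flows from
a master seed through named per-stage substreams (`stage_seed`), so
adding a stage never perturbs another stage's draws and reruns are
bit-identical.

## Known limitations

The stand-in DE test is conservative at n = 3 and does not moderate
variances; real studies should supply edgeR/limma tables through the
shared schema. The KDE threshold estimator assumes three resolvable
modes and will refuse unimodal data rather than guess. The gap split
assumes at most two populations per glomerulus. The depth-attenuation
model is a single exponential; no per-slide calibration exists.
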