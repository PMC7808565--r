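---
title: "Measuring copy-number fidelity between patient tumors and PDX models"
author: "cnafid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring copy-number fidelity between patient tumors and PDX models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnafid)
```

## The problem

Patient-derived xenografts (PDXs) are human tumor fragments engrafted and
serially passaged in immunodeficient mice. A central question for their use
as preclinical models is whether the mouse host systematically reshapes the
tumor genome: do somatic copy-number alterations (CNAs) drift, and if so, is
the drift directional? `cnafid` implements a quantitative framework for
answering this from segment-level copy-number calls: pairwise concordance
between patient tumor (PT) and PDX samples, residual-based altered-gene
calling, model-based recurrence, cohort-level recurrence (G-score) shift
analysis, and an expression-based inference arm — together with a
ground-truthed simulator that makes every stage testable without external
data.

## The segment currency and its preparation

All DNA-side analyses consume one representation: per-sample genomic
segments annotated with the log2 ratio of total copy number to the sample
baseline (`cna_profile`; 0-based half-open coordinates; mitochondrial and Y
contigs are dropped, X is retained). Upstream callers (ASCAT, Sequenza,
QDNAseq, SNP-array pipelines) produce SEG-like tables read by
`read_segments()`.

Preparation follows four steps, each a separate function:

* **Filtering** (`filter_segments()`): segments under 1 kb are removed on
  every platform; SNP-array segments must additionally be supported by more
  than ten probes at an average density of at least one probe per 5 kb.
* **Median centering** (`median_center()`): the profile is binned into
  10-kb windows and the median window value is subtracted, so the centered
  profile's own window median is zero. This approximates normalization by
  sample ploidy; it cannot distinguish genome-wide ploidy multiplication,
  which is a stated limitation of the whole framework.
* **Window binning** (`bin_profile()`): fixed-width windows (100 kb by
  default) take the value of the overlapping segment with the largest
  overlap, ties going to the leftmost segment. The tie rule is a package
  decision — any deterministic rule works, and largest-overlap preserves
  the dominant signal in a window.
* **Gene assignment** (`gene_copy_number()`): where a gene spans several
  segments, the most conservative (lowest) estimate represents the intact
  gene.

The degree of aberration of a profile is summarized by the 5–95%
inter-percentile range (IPR) of binned values (`aberration_summary()`).
The IPR is preferred over the variance because focal extreme events inflate
the variance while a narrow IPR directly certifies that at least 90% of the
covered genome is near-neutral. Profiles with IPR < 0.3 are treated as
non-aberrant; gain/loss labels use strict thresholds (log2 ratio > 0.1 or
< −0.1), while segment-size statistics use the inclusive |log2| ≥ 0.1
convention — both conventions appear in the field and the package keeps
them where each is used. Segment statistics are computed after filtering
and before centering by default (a flag-free choice; centering shifts all
values equally and the statistics are computed on the values actually
reported by each convention's consumers).

## Pairwise concordance: the improved regression

Samples of one PDX model are compared pairwise (`enumerate_pairs()`:
PT–PDX, PDX–PDX, intra-patient PT–PT, and optional cross-model background
pairs restricted to a common tumor type, center and platform; PDX samples
without passage information are omitted). Concordance of a pair has two
parts:

1. **Correlation**: the Pearson correlation of gene-level (or 100-kb
   window) log2 ratios over shared features. Correlation avoids making
   threshold-based gain/loss calls, which are fragile under baseline and
   dynamic-range differences between samples.
2. **The improved linear regression** (`cna_pair_fit()`): gene values below
   −3 are floored at −3 (extreme negative log values otherwise dominate the
   fit), the second sample is regressed on the first by OLS, genes with
   |externally studentized residual| > 3 are removed, and the model is
   refit. Raw residuals (log2 units) from the improved fit, computed for
   every shared gene, measure per-gene copy-number change free of global
   biases (stromal compression, platform scale).

Genes with |residual| > 0.5 are "altered" at the subclonal-inclusive
threshold; |residual| > 1.0 selects changes with likely functional impact,
and at that threshold genes deleted to the floor in both samples are
omitted (the difference between two floored deletions is uninterpretable).
Thresholding uses raw residuals, not studentized ones: the threshold is a
copy-number magnitude in log2 units, not a significance measure.

Three deliberate conventions, fixed because reproducibility requires an
orientation even though either choice is defensible:

* The *reference* sample is the predictor: PT in PT–PDX pairs, the
  lower-passage sample in PDX–PDX pairs. Residuals are therefore changes
  *of the later sample relative to the earlier*.
* "Studentized" means externally studentized (leave-one-out variance), the
  standard outlier diagnostic for which the |·| > 3 convention is stated.
* Pair validity and discordance combine correlation with aberration: a
  pair is dropped only when r < 0.6 *and* either sample is non-aberrant
  (IPR < 0.3) — low correlation between genomically stable tumors carries
  no information; a pair is flagged highly discordant when r < 0.6 although
  *both* samples are clearly aberrant (IPR > 0.5). Samples whose low
  intra-model correlation coincides with high correlation to another model
  are reported for review as potential label swaps (`flag_mislabeled()`),
  never dropped silently.

Degenerate fits are handled explicitly: an essentially perfect fit
(residual sigma below ~1e-8 of the response scale) has no outliers by
definition, and a point whose removal makes the remaining fit perfect is
treated as an infinite outlier. Without these rules the studentized
residuals of near-perfect fits are numerical noise.

## Recurrence, gene sets and the drug screen

Altered genes at the stringent threshold are aggregated per model
(`recurrence_frequency()`): a gene altered in any number of pairs of one
model counts once, avoiding bias toward heavily sampled models. The
denominator is the number of models contributing at least one valid pair of
the comparison type — models that could not be evaluated do not deflate
frequencies.

`geneset_proportions()` computes, per pair and gene set, the fraction of
the set's genes (within the evaluated universe) called altered, and
compares each set's distribution across pairs against the protein-coding
background by a one-sided Wilcoxon rank-sum test. The gene universe is the
protein-coding genes present in both samples' gene-level profiles.

`drug_association()` screens gene-level CN against drug AUC sensitivity
across cell lines by Pearson correlation with Bonferroni correction over
the whole tested family (the family-size choice is ours; the conservative
joint family is the default), keeps associations at q < 0.1, and confirms
them only when the gene's *expression* also correlates with the drug
response at nominal p < 0.05 in the same direction. The expression
significance level is not dictated by the upstream method and is exposed as
a parameter.

## Expression-based inference (e-karyotyping + PCF)

Where only expression is available, relative expression along the genome
proxies copy number. Preprocessing (`preprocess_expression()`) follows the
e-karyotyping recipe: sex-chromosome genes are dropped; genes below the
floor (1 TPM for RNA-seq, log2 intensity 6 for arrays) in more than 20% of
the dataset are removed and remaining sub-floor values are raised to the
floor; of multiple transcripts/probesets per gene the one with the highest
dataset-wide median is kept; the 10% most variable genes (sum of squared
deviations from the gene's own cross-sample median) are removed; and each
tumor profile is expressed relative to the per-gene median of normal
samples (NORM) or of the tumor set itself (TUM). Transcript collapsing
precedes the variability filter (the filter is meant to act on the
gene-level profile that will be segmented).

Segmentation is an exact penalized piecewise constant fit
(`pcf_segment()`): per chromosome, dynamic programming minimizes the sum of
squared residuals plus a per-breakpoint penalty. Parameters mirror the
published e-karyotyping settings with three explicit mappings, documented
as approximations because the original tool's internal variant is not fully
published:

| parameter | default | meaning here |
|---|---|---|
| penalty | 12 | per-breakpoint penalty on MAD-standardized values |
| winsorize quantile | 0.001 | values clamped to the (q, 1−q) empirical quantiles |
| least aberration size | 30 genes | minimum gene count for a gain/loss call (not a segmentation constraint) |
| least deviation | 0.25 | minimum |segment mean| for a call |
| threshold | 0.01 | two-sided t-test level on the segment mean, additionally required |

Values are standardized by the profile's median absolute deviation before
penalization so one penalty is comparable across samples; segment means are
reported in the original units. `expression_cna_to_segments()` converts
calls into genomic segments consumable by the DNA-side machinery, clamping
boundary overlaps from overlapping gene bodies.

The 30-gene minimum implies the expression route can only recover events of
several megabases — by design it is the coarsest platform, and the package's
tests verify recovery only for chromosome-arm-scale events.

## Cohort G scores, rescaling and shift analysis

For cohort-level recurrence the package computes a simplified G score per
100-kb bin: the mean over samples of max(log2 − t, 0) for amplifications
and of max(−log2 − t, 0) for deletions, with event threshold t = 0.1
(aligned with the gain/loss threshold). This is frequency × average
amplitude in one expression — the quantity needed for comparing recurrence
tracks across cohorts. The full GISTIC background model, peel-off and peak
calling are intentionally not reproduced: cohort-shift analysis needs
comparable tracks, not peak calls, and externally produced gene-level
G scores can be substituted at the `delta_g()` / `gsea_preranked()` layer.
Significance uses cyclic within-genome permutation of each sample's bin
values — preserving each sample's amplitude spectrum and segment-length
structure — with the permuted scores pooled across bins as the null,
Benjamini–Hochberg adjustment, and a q < 0.25 significance mask.

Because stromal DNA dilutes PT signal, PT cohorts show compressed G-score
ranges. `scale_gscores()` maps PDX gene-level scores onto the PT scale via
a global linear regression (amplifications and deletions separately);
scaling is idempotent and preserves gene-level correlations. Shifts are
then ΔG = G(later) − G(earlier) per gene, and the correlation between the
PT→PDX-early and PDX-early→PDX-late ΔG vectors asks whether drift is
directional.

A caveat the package's tests make explicit: the two ΔG vectors share the
middle cohort, so its estimation noise (platform noise, cohort sampling)
enters both with opposite signs and biases the correlation negative —
regression to the mean, not selection. Under neutral drift the correlation
is therefore expected to be *absent or slightly negative*; the tests assert
the ±0.1 band on a construction with independent drift at both steps, and
assert "not significantly positive" for the end-to-end trio.

`gsea_preranked()` is a classic preranked GSEA (weighted KS running score
with weight exponent 1, gene-label permutations for NES/p/FDR) with one
addition: genomic gene sets often contain many positionally adjacent genes
inside a single amplicon, which produces spurious enrichment. A set is
called significant only if NES > 1.5, q < 0.05, *and* the leading-edge
genes that individually pass the cohort's G-score significance mask make up
at least 20% of the set.

## The simulator: what it emulates and what it does not

`simulate_cohort()` generates ground-truthed cohorts with the statistical
structure the analyses assume:

* **Clonal profiles**: per model, a Poisson(25) number of clonal events
  with lengths log-uniform on [100 kb, 50 Mb] (capped at 90% of a
  chromosome) and log2 amplitudes drawn from
  {±0.3, ±0.58, ±1, −3} weighted toward low-level events with rare deep
  deletions; a minor subclone (cellular fraction 0.3) carries extra private
  events. Observed per-gene truth composes events multiplicatively on the
  linear copy scale.
* **Lineage passaging with drift**: each PDX lineage adds Poisson(2) new
  subclonal events per passage (cellular fraction uniform on [0.3, 1], so
  residual-based calling sees attenuated amplitudes — exercising the
  subclonal rationale of the 0.5 threshold); the lineage splits into two
  mice after P1 and the branches drift independently, so different-lineage
  pairs accumulate more true differences than same-lineage pairs at equal
  passage distance.
* **Stromal dilution**: on the linear copy scale, observed CN =
  (1−f)·tumor + f·2, then logged — the physically correct mixture. PT
  stromal fractions are Beta(2, 3) (mean 0.4, a typical resected-tumor
  purity range); PDXs are nearly pure (f = 0.05).
* **Platform rendering**: resolution floors (SNP 50 kb, WGS 200 kb, WES
  1 Mb) absorb sub-resolution segments into the longer neighbor; additive
  Gaussian noise on segment means (SD 0.05/0.10/0.15 for SNP/WGS/WES);
  deep deletions clipped at platform dynamic-range floors (−8.6 SNP, −3.0
  WGS/WES). These reproduce the observed platform ordering: SNP finest and
  widest, WES coarsest and most compressed.
* **CN-coupled expression**: tumor log2 expression = per-gene baseline +
  true gene log2 ratio + noise (SD 0.3), with 20% of genes decoupled from
  copy number, emulating the limited fidelity of expression-based
  inference; matched normals are baseline + noise.

The default genome is the human autosome + X set scaled to ~310 Mb, keeping
realistic relative chromosome sizes and, with 2000 genes, a realistic gene
density (~6.5 genes/Mb), so gene-count-based rules (the 30-gene PCF
minimum) translate to the same physical scales as on the full genome. Tests
and the acceptance script use 20 models (~140 samples) on this genome;
these sizes are the package's chosen study conditions.

Not emulated, hence not certified by passing tests: point mutations and
selection (drift is strictly neutral), realistic karyotype rearrangement
structure (events are independent intervals), allele-specific copy number,
wave/GC artifacts in real array data, platform-specific probe placement,
and expression covariates beyond a per-gene baseline. Parameter-recovery
results on the simulator bound what the method can do under its own
assumptions; they do not measure robustness to violations of those
assumptions.

## Numerical choices and degenerate inputs

* Quantiles use R's default type-7 interpolation everywhere (IPR,
  winsorization).
* Empty profiles cannot be centered; profiles need ≥ 20 covered windows
  for an aberration summary, pairs ≥ 200 shared genes (configurable),
  cross-platform comparisons ≥ 100 shared windows, cohorts ≥ 5 samples for
  G scores.
* All-tied group comparisons return p = 1 with a warning; zero-variance
  correlation inputs return NA and flag the pair invalid; a zero
  denominator IPR makes the range ratio NA.
* Permutation p-values use the add-one convention ((1 + #extreme)/(1 + N))
  so they are never zero.
* Every stochastic step takes an explicit seed; fixed seeds give
  bit-identical truth sets and renderings.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_models = 5)
sim <- simulate_cohort(cfg, seed = 42)
profiles <- render_cohort(sim, platform = "WGS", seed = 42)
prep <- prepare_profiles(profiles, sim$metadata, sim$genes)
pairs <- enumerate_pairs(sim$metadata)
res <- pair_concordance(pairs, prep)
res
```

## Known limitations

* Median centering cannot detect genome-wide ploidy changes between
  samples of a model; the correlation statistic is invariant to them.
* The simplified G score has no arm-level/focal decomposition and no
  peel-off; its q values calibrate the significance *mask*, not peak
  boundaries.
* The PCF parameter mapping to the original e-karyotyping tool is
  approximate in three documented places (penalty scale, aberration-size
  semantics, the meaning of the 0.01 threshold).
* Cross-model background pairs use gene-based correlation (consistent with
  intra-model pairs); window-based background correlation is available by
  calling the window route directly.
* X-chromosome windows are retained in DNA-based correlations by default
  (upstream callers commonly emit X); drop X from the input segments if a
  cohort mixes sexes in a way that confounds this.
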