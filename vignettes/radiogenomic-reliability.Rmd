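---
title: "Reliability of radiogenomic heterogeneity features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability of radiogenomic heterogeneity features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radhet)
```

## What the package measures

Tumor heterogeneity biomarkers sit downstream of processing choices that the
literature has not standardized. `radhet` studies two of them.

**Population-allele-frequency (PAF) cutoff.** Tumor-only exome panels cannot
subtract germline variants with a matched normal; they instead discard any
variant whose frequency in a population database (general or East-Asian)
reaches a cutoff, with both 1% and 0.01% in common use. Three per-tumor
features are computed from the surviving somatic calls at each cutoff:

* TMB, somatic mutations per megabase of the 45.0-Mb exonic probe;
* MATH, `100 × MAD / median` of the mutant-allele fractions (VAFs, percent),
  where the MAD is the *plain* median absolute deviation from the median —
  some MATH literature multiplies by the 1.4826 normal-consistency factor,
  which is exposed as `scale_factor` but defaults to 1;
* the Shannon entropy (bits) of the VAF histogram over ten 10-percent bins.

**PET reconstruction matrix size.** The same acquisition reconstructed at a
256×256 matrix (2.7×2.7×2.79 mm voxels) or a 128×128 matrix (5.4×5.4 mm
in-plane) yields different partial-volume averaging. Four first-order
glycolytic features are computed per grid after 41%-of-SUVmax threshold
segmentation: SUVmax, SUVmean, MTV (mL), TLG = MTV × SUVmean, and the
intensity entropy over fixed 0.25-SUV bins with an ε ≈ 2.2×10⁻¹⁶ guard
inside the logarithm.

Reliability across each pair of conditions is the two-way random,
single-measurement, *consistency* intraclass correlation, ICC(C,1) =
(MSR − MSE)/(MSR + (k − 1)·MSE) from the subjects × conditions ANOVA.
Consistency (rather than absolute agreement) is the right notion here: a
uniform offset between conditions — e.g. the systematic SUVmax drop on the
coarser grid — does not destroy a biomarker's usefulness, whereas
patient-reordering noise does. ICC(A,1) is available behind
`type = "agreement"` for sensitivity checks. Bands follow the usual
convention, with endpoints assigned as poor < 0.5 ≤ moderate ≤ 0.75 < good
≤ 0.9 < excellent.

## The synthetic cohort generator

No patient data ship with the package, so every analysis is exercised on a
generator (`cohort_spec()`, `simulate_cohort()`) that emulates the data
structure of a 46-patient prospective NSCLC cohort. Its defaults *are* the
study conditions; they were chosen once, against the published cohort
moments, and are not tuning knobs for individual analyses.

### Variant tables

Per patient: tumor purity is drawn as `0.2 + 0.8·Beta(1.1, 1.7)` (median
≈ 0.50, IQR ≈ 0.33, range 20–100% — the reported distribution of
tumor-cell content in FFPE specimens). True somatic mutations (150–620)
carry cancer-cell fraction (CCF) 1, or, in the 40% of patients flagged
bimodal, are split between clones at CCF 1 and 0.35; a per-variant lognormal
CCF perturbation (sd 0.45) stands in for the residual subclonal structure
and copy-number distortion that spread real VAF distributions. The expected
VAF of a variant is `100 · purity · CCF / 2` (heterozygous, diploid).
Germline contaminants (1050–1350 per table) sit at VAF ≈ 50% (10%
homozygous at ≈ 100%) and carry PAFs drawn log-uniformly over
[10⁻⁴, 50] percent, so both the 1% and the 0.01% cutoff bite (≈ 30% of
contaminants survive the 1% cutoff, ≈ 65% are removed at 0.01%). Somatic
variants are absent from the database: PAF zero or missing. Read depth is
negative-binomial around a per-specimen mean that is itself lognormal
(sd 0.35) about 119× — surgical resections and small biopsies do not
sequence equally deep — and read counts are beta-binomial with intra-class
correlation 0.005. The overdispersion is deliberately small: the germline
heterozygous peak must stay narrow, because blurring it into the somatic
mass suppresses exactly the bimodal structure whose median-instability the
analysis is designed to expose. Bin-edge convention: VAF bins are
half-open `[lo, hi)` with the top bin closed at 100.

This geometry is what makes MATH fragile by construction. At the 1% cutoff
roughly 70% of germline contamination survives and the VAF median sits in
the germline peak near 50; at 0.01% only ~35% survives, and whether the
median stays there or drops into the somatic mass depends on each patient's
somatic/germline balance — a patient-specific, erratic shift. The entropy of
the histogram, by contrast, changes smoothly when bin mass is removed.
Consistency ICC of TMB across cutoffs stays high for a different reason: the
germline count range is narrow, so the between-cutoff difference
(≈ 0.35·G/45 per Mb) is nearly constant across patients and is absorbed by
the consistency model's condition effect.

### PET phantoms

An ellipsoidal tumor (mean radius 8–30 mm, semi-axes perturbed ±15%) is
placed on a uniform SUV-0.5 background in a 64×64×48 standard grid. Tumor
uptake is `base · (1 + 0.35·G)`, clipped positive, with `base` uniform on
2.5–12 and `G` a unit-variance Gaussian random field generated by FFT
convolution of white noise with a Gaussian kernel of 8-mm correlation
length — a single-knob texture model, not a scanner noise model. The reduced
matrix is *derived* from the standard grid by 2×2 in-plane block averaging
(z untouched), which conserves total uptake exactly and can only decrease
SUVmax — the partial-volume direction expected physically. This is the only
desk-scale surrogate for two independent scanner reconstructions and is a
stated limitation: genuinely independent reconstructions would add
uncorrelated noise and lower the ICCs somewhat. A visible consequence: a
perfectly uniform tumor has entropy exactly 0 on the standard grid but
≈ 0.9 bits on the derived reduced grid, because rim blocks average tumor
with background into a handful of partial-volume levels.

Segmentation thresholds at 41% of the VOI SUVmax and keeps the 26-connected
component containing the peak voxel, so a generous VOI containing a second
hot structure does not leak into the mask; each grid is segmented
independently with its own SUVmax (resampling the standard-grid mask would
make the two conditions artificially agree). Intensity bins are anchored at
integer multiples of 0.25 SUV; min-anchored edges are the documented
alternative and differ only by sub-bin shifts.

### Clinical and survival layer

Stage IV is drawn from a logistic model with baseline probability 0.435 and
optional coefficients on standardized features; smoking (58.7% ever) and
histology (76.1% adenocarcinoma) follow fixed marginals. Overall survival is
exponential with log-hazard `Σ βf · feature_f` on the raw feature scale
(median 24 months at the null), so a univariate Cox fit recovers each β per
unit. Censoring is *independent* exponential with its rate chosen so the
expected censored fraction equals `censor_rate` (default 0.76, matching
11/46 observed deaths); censoring a subject at a fraction of their own event
time would violate independent censoring and bias the Cox estimates. All
link coefficients default to zero so reliability analyses run on null
cohorts.

### Determinism

Every draw descends from the master seed through fixed per-patient,
per-stage sub-seeds, so one seed reproduces the cohort bit-identically and
individual generators can be called in isolation. A patient whose table
retains no somatic variant at the strictest cutoff is regenerated from a
perturbed sub-seed with a logged retry count (never observed under the
defaults).

## Statistical layer

* `icc_consistency()` computes the ANOVA mean squares in closed form from
  sums of squares; it is checked in the tests against an independent
  `aov()`-based oracle to 10⁻⁶. Listwise deletion with reported `n_used`;
  fewer than 3 complete pairs or zero variance yield `NA` ("undefined"), not
  an error, so degenerate cohorts flow through the pipeline with a warning.
* `correlation_matrix()` is pairwise-complete Pearson (`cor.test`), with
  both raw and Bonferroni-corrected significance flags reported rather than
  choosing one.
* `compare_groups()` makes the "t-test or Mann–Whitney as appropriate"
  choice algorithmic and reproducible: Mann–Whitney when either group has
  n < 20 or fails a Shapiro–Wilk screen at p < 0.05, Welch t otherwise; the
  chosen test is always recorded. Fully tied data return the midrank
  convention's null (p = 1).
* `cox_univariate()` fits the partial likelihood by Newton–Raphson
  (`survival::coxph`, Breslow ties by default, Efron optional, tolerance
  10⁻¹⁰), reporting HR per unit of the feature as provided, Wald 95% CI and
  p. Monotone-likelihood fits are flagged in the result rather than returned
  silently. The tests check the estimate against a hand-written Breslow
  partial likelihood maximized by grid search plus golden-section refinement.

## Problem sizes and what the tests do (and do not) show

The packaged analyses use cohorts of 40–46 patients, 20 replicate seeds for
the cutoff-reliability contrast, 40 phantoms for the matrix-size contrast,
and n = 100–500 for the survival checks — sizes chosen to mirror the
emulated study's scale while keeping a full run in the order of a minute.
Passing tests show that the *pipeline* reproduces the qualitative reliability
structure (TMB and all four PET features excellent; VAF entropy markedly
more reliable than MATH; PET entropy still good in tumors under 10 mL) on
data with the assumed generative structure. They cannot certify the exact
published ICCs, which belong to one specific undeposited cohort; nor do the
phantoms model scanner PSF, respiratory motion, reconstruction noise, or
real FFPE artifact spectra. The tumor-purity correction debate for TMB is
deliberately out of scope: features are computed uncorrected, and purity
only enters through the VAF scale.

## Known limitations

* The reduced PET grid is a deterministic function of the standard grid, so
  matrix-size ICCs are upper bounds relative to independent reconstructions.
* Germline PAFs are log-uniform; a real gnomAD frequency spectrum is far
  more mass-concentrated at common frequencies, which would strengthen the
  1% cutoff's germline removal.
* MATH/entropy are reported `NA` for tumors with no somatic variant or zero
  median VAF; the ICC layer handles these by listwise deletion with the
  used n reported.
* Clone structure is at most two clones; no phylogenies, no read-level
  simulation (FASTQ/BAM), no copy-number segments.
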