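---
title: "Methods: models, parameters and design choices in lipidpipe"
author: "lipidpipe maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lipidpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidpipe)
```

`lipidpipe` re-creates, as a tested and reusable pipeline, the analysis
chain used in untargeted negative-mode FT-ICR lipidomics of cultured
mosquito cells: peak-list preprocessing, normalization, multivariate and
univariate statistics, and exact-mass annotation.  Because the interesting
behaviour of such a chain only shows under realistic inputs, the package
ships a synthetic study generator whose ground truth embeds the class-level
effect sizes reported for *Wolbachia*-infected *Aedes albopictus* Aa23
cells, so every downstream stage can be validated against known answers.
This vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## The synthetic study generator

### What it emulates

The default design mirrors the emulated experiment: 7 uninfected control
samples, 6 samples infected with the *w*Mel strain and 6 with *w*MelPop;
technical triplicates per sample; direct-infusion spectra assembled from 12
overlapping SIM windows spanning *m/z* 120–1200 (equal width, 10 Da
overlap — boundaries are not reported for the original instrument method,
so an even tiling was chosen); four pooled-QC acquisitions and three
solvent blanks.  An LC mode (single acquisition per sample, retention-time
column, no windows) feeds the same downstream chain.

The species library holds 422 annotated lipids across 13 classes with the
class-wise species counts of the emulated data set (57 Cer, 29 HexCer, 14
LacCer, 12 SM, 16 PE-Cer, 53 PC, 11 LPC, 81 PE, 9 LPE, 12 PS, 59 PI, 40
PG, 29 DG), with chain lengths and saturations spanning the ranges seen
there (e.g. Cer 32:0–44:x, including the flagship species Cer 36:1, DG
34:1 and LacCer 40:1).  Sum compositions are converted to elemental
formulae per class (e.g. Cer *n*:*d* = C~n~H~2n+1−2d~NO~3~) and monoisotopic
masses are computed from atomic masses, so the generator and the annotator
share one mass scale.

Each species is emitted under a realistic negative-ion series: a primary
quantifier ion (acetate adducts for choline-bearing and neutral classes —
Cer, SM, DG, PC, LPC — deprotonation for the rest), a chloride secondary at
15 % relative intensity with its ^37^Cl isotope peak, a ^13^C~1~
isotopologue for every ion (binomial expectation, `0.0107 nC/(1-0.0107)`),
and a doubly charged `[M-2H]2-` form for the intense PE and PG classes.

### Ground-truth effects

Group effects are multiplicative factors on species abundance
(`1 + percent change/100`), control fixed at exactly 1: Cer 0.38/0.80
(*w*Mel/*w*MelPop), HexCer 0.68/1.05, SM 0.65/1.28, PC 0.62/0.96, PE
1.02/1.02, PI 1.94/1.27, PG 1.50/1.17, DG 0.68/1.17, with species
overrides DG 34:1 0.35/1.42, LacCer 40:1 0.19/0.49 and LacCer 34:1/36:1
raised 1.52/1.90-fold in *w*Mel.  PE-Cer (0.60/0.85) and the LacCer class
default (0.80/0.90) are stand-ins: those classes decrease consistently but
no class mean is reported, so they are excluded from recovery checks.
Classes without a reported change (PS, LPC, LPE, background) are left at 1.

### Noise model and its defaults

Biological variation is log-normal with a 25 % CV; technical replicates
add a 10 % CV; each SIM window carries an extra 10 % multiplicative gain
(corrected later by stitching); observed *m/z* is jittered by a 0.5 ppm
Gaussian error; intensities below 2.5 × 10^4^ (arbitrary units, against
class base intensities of 0.6–6 × 10^6^) are censored — absent, not zero —
because FT-ICR missingness is abundance-driven (MNAR).  These magnitudes
are typical of direct-infusion FT-ICR cell-extract work and were fixed
once: large enough that recovery is non-trivial (single-study class means
scatter by a few percentage points), small enough that the printed effects
are recoverable.  All randomness flows from the single design seed;
`noise_free()` zeroes every noise term for exactness checks.

### The unchanged background panel

Beyond the 422 annotated lipids the library carries 25 saturated free
fatty acids (solvent-borne: present in blanks at 60 % of their biological
intensity, so the 2× blank rule removes them — mirroring the high FFA
solvent background of real spectra) and, by default, 3000 synthetic
"unknown" compounds with plausible CHNOP formulae that are unchanged
across groups.  The size of this panel is a deliberate modelling choice:
PQN assumes that a majority of features are unperturbed, and with ~420
changed species against only a token background the per-sample median
quotient of an infected sample sits in the tail of the near-unity block
and is biased several percent low, which alone would distort a +94 % class
mean by tens of percentage points.  A quantile analysis of the quotient
mixture shows the residual group-level bias falls to ~2 % with a few
thousand unchanged features — which also matches the real matrices, where
only a minority of the thousands of signals were annotated lipids.  The
background formulae are sampled once (deterministically) with every
`[M-H]-` ion and its ^13^C partner kept at least 5 ppm away from every ion
the lipid library emits, so the background never aliases an annotated
species; this keeps the ground truth resolvable at the 2 ppm annotation
tolerance.  Similarly, the synthetic PS species carry 3–4 double bonds so
that the exact PC-acetate/PS isobar (PS(*n*+4:*d*−1) `[M-H]-` has the
identical ion formula to PC(*n*:*d*) `[M+OAc]-`) does not fold PS signal
into the PC class ground truth; the PE/PC chloride isobars, which affect
only secondary ions, are retained and exercised by the annotation tests.

### What the generator does not emulate

Profile-mode spectra, chromatographic peak shapes, ion suppression,
adduct-competition chemistry, instrument drift across the run order, and
correlated (pathway-level) biological variation are all absent.  Passing
the recovery tests therefore shows the *pipeline algebra* is right — the
filters, normalization and statistics recover known effects under
realistic noise — not that the pipeline is robust to every artefact of
real spectra.

## Preprocessing

Windows are stitched left to right: each window is rescaled by the median
intensity ratio of peaks shared (within the *m/z* tolerance) with the
already-stitched spectrum in the overlap region, then duplicates are
merged at the tolerance by intensity-weighted mean *m/z*; cluster
intensity is the per-window sum averaged over contributing windows, so two
genuinely distinct peaks that co-occur inside one window keep their summed
intensity.  An overlap without shared peaks warns and uses scale 1.

Technical replicates are merged by clustering peaks within the tolerance;
a peak is retained when it appears in at least 2 of 3 replicates, with the
mean over contributing replicates as its intensity.  Alignment across
samples is gap-based single-linkage clustering of pooled sorted *m/z*
values: a new feature starts wherever the gap between adjacent values
exceeds the tolerance (2 ppm by default, computed relative to the lower
value of the pair); clusters in which one sample spans more than the
tolerance are split at their largest internal gap.  For LC data, *m/z*
clusters are further split at retention-time gaps beyond 10 s.

The blank filter keeps a feature when its biological mean is at least
twice its blank mean (missing counted as zero on both sides; features
absent from all blanks always survive).  The sample filter keeps a feature
observed in at least 75 % of the biological samples of *at least one*
group; the per-group reading preserves group-specific features with these
small group sizes, and an overall-fraction mode is available by
configuration.  Filters only drop features — retained intensities are
never altered — and re-running the chain on its own output is a no-op.

## Normalization, imputation and the glog transform

PQN uses the per-feature median over biological samples as the reference
spectrum; each sample's dilution factor is the median of its quotients
against the reference over co-observed features, and QC samples are
normalized against the same reference.  Missing values are then imputed by
a feature-space KNN: neighbours are features, not samples, because with
6–7 samples per group sample-space distances are unstable while
feature-feature co-variation across 19+ columns is comparatively well
estimated.  Distances are Euclidean over co-observed samples scaled by the
co-observation count; the k = 5 nearest features vote with weights
`1/(distance + eps)`, neighbours missing at the target cell are skipped,
and a feature's observed mean is the fallback.  Observed cells are never
changed.

The generalized logarithm `y = ln((x + sqrt(x^2 + lambda))/2)` is applied
only for the multivariate stage; univariate fold changes always use the
normalized, imputed, untransformed matrix.  `lambda` is calibrated on the
QC technical replicates: the objective is the spread (SD across features)
of per-feature SDs of the transformed QC values, divided by its mean.  The
division makes the objective scale-free; without it the raw spread is
trivially minimized as `lambda` grows without bound, where the transform
collapses toward a constant.  A 40-point log-spaced grid over
`[0, max(x)^2]` is scanned and the best cell refined by golden-section
search; identical replicates give a degenerate all-zero objective and the
smallest grid value is returned.  The exact calibration objective of
historical in-house implementations is unpublished; ours is declared,
deterministic and configurable (a fixed `lambda` can be supplied).

## Multivariate statistics

PCA is mean-centered and unscaled.  PLS-DA is NIPALS PLS2 against
mean-centered one-hot class coding; prediction is the arg-max of the
predicted class scores with ties broken by class order.  Venetian-blinds
cross-validation orders samples by (class, position) and assigns every
*f*-th sample to the same fold (3 folds by default for 6–7 samples per
group); the model size minimizes CV error with ties going to the smaller
model, scanning up to `A_max` latent variables (pipeline default 5, ample
for these group structures).

The permutation test uses the venetian-blinds CV error as its statistic
and reports `p = (1 + #{permuted <= observed})/(B + 1)` over `B = 1000`
uniformly random relabelings.  The permuted statistic is recomputed at the
model size chosen on the observed labels rather than re-selecting the size
per permutation; re-selection would multiply the cost by `A_max` while
changing the null distribution only through a second-order selection
effect, and the chosen-size error is the statistic actually reported for
the observed model.

Variable importance is the standard VIP statistic,
`VIP_j = sqrt(J * sum_a ssy_a w_aj^2 / sum_a ssy_a)` with unit-norm
weights, whose squared scores always average 1.  Forward selection refits
the model on the top-*k* variables for *k* on a logarithmic grid (1, 2, 5,
10, … all) and returns the smallest *k* attaining the minimal CV error;
the grid is logarithmic for tractability since no step rule is reported
for the original scripts.

## Univariate statistics and class summaries

Per feature, a one-way fixed-effects ANOVA across the three cell lines is
computed by vectorized sums of squares (cross-checked against `stats::aov`
in the test suite), with `F = 0, p = 1` for degenerate all-equal features.
Benjamini–Hochberg q-values (via `stats::p.adjust`) are thresholded at
q < 0.05.  Percent change is `100 (mean_A - mean_ref)/mean_ref` on the
normalized, imputed, untransformed matrix; negative means lower in the
infected group.  Each significant feature gets a direction pair
(`-/-`, `+/+`, `-/+`, `+/-`) from the signs of its two infected-group
changes, `none` otherwise.

Class summaries count each species once through its class's primary ion
(the non-isotopologue, singly charged candidate of the class's primary
adduct with the smallest |ppm error|).  Class means average over *all*
annotated species of a class, not only significant ones, matching the
"overall mean change" reading; a significant-only mode exists.  Whether
the original class means weight species equally or by intensity is not
stated; equal weighting is used, and the recovery tolerance absorbs the
difference.  Direction-pair counts always sum to the species count.

## Annotation

Every (species, adduct) theoretical *m/z* within 2 ppm of a feature is a
candidate; isobars are kept and ranked by |ppm error|, unmatched features
are `unknown`.  Ion *m/z* includes the electron mass.  A feature at parent
*m/z* + 1.00336/|z| whose intensity ratio to its parent lies within
[0.25, 1.75] × (0.0107 × ion carbon count) is flagged as the ^13^C~1~
isotopologue and linked to its (nearest-*m/z*) parent; the window is
deliberately generous because SIM-edge effects distort FT-ICR isotope
ratios.  A flagged spacing of ~0.50168 Da marks a doubly charged ion,
which is linked to its singly charged partner at `2 m/z + 1.00728` when
present.  Online database lookups are replaced by the bundled offline
library; transformation-network annotation is out of scope.

## Numerical choices and degenerate inputs

All clustering is deterministic given the input order; ties in class
prediction go to the first class level; the permutation p-value never
reaches 0 by construction.  PQN returns factor 1 with a warning for a
sample sharing no features with the reference; fully missing features are
rejected before imputation (the sample filter removes them in the normal
chain); requesting more latent variables than the rank truncates with a
warning; empty replicate lists and empty stitching overlaps warn and
degrade gracefully.  Peak lists round-trip through plain TSV at full
double precision.

## Problem sizes used in the checks

The package's own validation runs at desk scale, chosen so the whole suite
exercises every stage end to end: the shipped recovery checks simulate ten
full default studies (~8 400 ions per acquisition, 78 acquisitions each)
for the class-mean comparisons, a single study for the PLS-DA models with
B = 1000 permutations, and fifty reduced null studies (3 samples per
group, 60-compound background) for the false-discovery calibration.  On
the default synthetic study the estimates recover every targeted class
mean within a few percentage points; in the noise-free limit recovery is
exact to machine precision, which pins the estimator algebra as distinct
from sampling noise.

## Known limitations

The PQN group-level bias is reduced, not removed, by the unchanged
background — strongly asymmetric perturbations still shift dilution
factors by ~1–2 %.  The isotope-ratio window cannot resolve near-isobars
whose merged intensity breaks the expected ratio (one such pair exists in
the default library; the merged feature keeps its dominant annotation).
KNN imputation of MNAR-censored values biases imputed intensities upward,
which is visible only for species close to the detection limit.  The
permutation test's fixed-model-size statistic slightly understates
selection optimism.  None of these affects the noise-free exactness
guarantees, and all are quantified by the shipped tests.
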