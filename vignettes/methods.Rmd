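---
title: "Methods: biochemometric feature ranking, networking and annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biochemometric feature ranking, networking and annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `phytoactive`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Data model

The unit of analysis is a **fraction series**: an extract split into
`n` fractions (typically ~21 from liquid–liquid partitioning followed by
size-exclusion chromatography), each profiled by flow-injection HRMS and
each assayed for bioactivity (% cell viability, mean ± SE over replicates).
Features are (RT, m/z) entities named `"RT_mz"` (RT in minutes to 2
decimals, m/z to 4 decimals). Positive- and negative-mode matrices are kept
separate end to end; all models are fit per mode and only the reports are
pooled.

Before modelling, both predictors and response are natural-log
transformed. Zeros in the intensity matrix receive a pseudo-count
δ = half the smallest non-zero intensity of the matrix — scale-adaptive
and conventional; a user constant can be supplied instead. Viability is
floored at 1 % before the log so fractions with complete cell death stay
finite. No between-fraction normalization is applied by default: fraction
loads genuinely differ, and that variation is part of the signal; an
optional total-intensity normalization is provided for instruments whose
injection volumes drift.

## Adduct/isotopologue deconvolution

Flow injection produces several ions per compound. `deconvolute()` groups
features that differ by a rule offset (defaults: +1.003355 Da for the 13C
isotopologue, +21.981944 Da for the Na−H adduct) within ±0.01 Da, share a
retention time within 0.05 min, and correlate across fractions at Pearson
r ≥ 0.9. Groups are merged transitively; the representative is the member
with the lowest m/z (the presumed parent ion) and the merged intensity is
the group sum, which conserves total matrix intensity and preserves
abundance for correlation analysis. This is a transparent stand-in for the
proprietary deconvolution of vendor software; its rules are exposed as
`adduct_rule()` objects.

## Selectivity ratio

A univariate-response PLS model (NIPALS-style deflation) is fit on the
column-centred, autoscaled log-intensity matrix. Autoscaling is on by
default — regression models of this type are sensitive to variable
scaling, and autoscaling is the convention in the selectivity-ratio
literature — and can be disabled.

The fitted model is rotated onto its regression vector (**target
projection**): `t_tp = X b/||b||`, `p_tp = X't_tp/(t_tp't_tp)`. Per
feature, the selectivity ratio is the ratio of explained to residual
variance along this single predictive component. `SR = f/(1-f)` where `f`
is the explained fraction, so `SR = 1` corresponds to exactly half of a
feature's variance explained. A residual-free feature receives `Inf` and
sorts first; ties are broken by ascending m/z. The module contains no
randomness.

**Component count.** Chosen by leave-one-out cross-validation over
`1..min(10, n-2)` (a left-out fold retains `n-1` rows, so `n-2` components
is the attainable maximum). Rather than the RMSECV minimum we take the
*largest* component count within one standard error of the minimum. The
rationale: at `n ≈ 21` the RMSECV curve is statistically flat over a wide
range, and the two rules give equally good predictors — but an
*underfitted* target projection concentrates on the dominant covariance
direction only and blurs the ranking of variables whose contribution
enters through later components. For a pure prediction task the usual
parsimony rule would be preferable; for variable ranking the richer
projection is. The component count is also settable explicitly for
reproducibility.

## Elastic Net ensemble

Each of `n_models` (default 1000) members draws a bootstrap resample of
the fractions (with replacement, same size), standardizes within the
resample (glmnet's internal standardization; coefficients are reported on
the original scale), fits the Elastic Net at fixed α (default 0.5) over a
lambda path, and keeps the coefficient vector at the lambda chosen by
internal 5-fold cross-validation on that resample using the **1-SE rule**
(largest lambda within one standard error of the CV minimum). The 1-SE
rule keeps members sparse; with the CV-minimizing lambda, members of a
21-sample problem average ~20 active coefficients and selection
frequencies lose discrimination. α is fixed rather than tuned — tuning the
mix per member with ~21 observations is unstable — and is exposed as a
parameter.

Features are ranked by selection frequency (share of members with a
non-zero coefficient), then mean |coefficient| over selecting members,
then ascending m/z. `n_selected` counts features ever selected; ranks are
reported as `"r (of N)"`. The bootstrap-ensemble construction is the
standard way to obtain stable selection frequencies from ~20 samples; the
resampling scheme is isolated behind `ensemble_config()` so alternatives
can be swapped in.

Fewer than 6 fractions is rejected: bootstrap resampling and internal CV
degenerate below that.

## Molecular networking

`cosine_score()` L2-normalizes fragment intensities per spectrum
(raw intensities, no square-root or m/z weighting by default — this keeps
the self-similarity = 1 and disjoint = 0 anchors exact) and pairs peaks
within ±0.05 Da, plus — for the **modified cosine**, on by default — peaks
offset by the precursor mass difference. Pairing is greedy by descending
intensity product with each peak used at most once; an exact
maximum-weight assignment is available (`matching = "exact"`) and is used
by the oracle tests, which also verify that greedy never exceeds exact.

`merge_identical()` collapses replicate spectra (precursor within
±0.01 Da, cosine ≥ 0.95) into consensus spectra in a greedy single pass —
a deliberate simplification of full MS/MS clustering. `build_network()`
keeps an edge iff cosine ≥ 0.70 **and** ≥ 6 peaks match, computes connected
components, and reports components with ≥ 3 nodes as clusters. No
edge-degree pruning (TopK) is applied by default. `map_bioactivity()`
matches node precursors to matrix features (±0.01 Da, RT within 0.2 min
when available) and attaches pie slices: each fraction containing the
feature contributes weight proportional to its intensity share, tagged
with the fraction's viability bin (defaults: full ≥ 100 %, partial
50–100 %, low < 50 %; configurable). GraphML export/import round-trips all
node and edge attributes.

## Annotation

Observed m/z values are converted to neutral masses assuming singly
(de)protonated ions (±1.007276 Da) and queried against a compound library
within a **closed** ±10 ppm window (the interval convention has to be fixed
somewhere; ties sort by |ppm error|). Annotations are validated by counting
reference fragments matched within 50 ppm (relative); validation requires
3 matches by default — the tolerance is standard, the count is a package
choice and configurable. Entries without reference fragments give an
indeterminate (not failed) validation.

## Synthetic data: what it emulates, and what it does not

The generator produces the study conditions every test runs under:
21 fractions, configurable feature count (default 1500 plus adduct
satellites), viability clipped to [5, 117] % — the range such assays
produce when some fractions are fully cytotoxic and others proliferative —
with Gaussian assay noise (default SD 4 percentage points, SE reported for
n = 6 replicates).

Feature profiles are a unimodal elution-like Gaussian bump over the
fraction index (random center, width 1.5–3.5 fractions, log-normal
amplitude) on a trace baseline (2 % of amplitude: carry-over keeps
compounds detectable across the series), multiplied by strong
fraction-specific log-normal variability (SD 0.7). That last term is
essential realism: fraction series from multi-step separations are patchy,
not smooth. Smoothness also matters statistically — with purely smooth
21-point profiles the profile space is so low-dimensional that dozens of
inactive features correlate with any response as well as the true drivers
do, and no marginal-type ranking can separate them.

The spiked bioactives are **co-eluting congeners**: abundant compounds
sharing one interior elution window and a common irregular abundance
component (log-SD 1.0) with small individual deviations (log-SD 0.4), with
all-positive effect sizes (6, 5, 4 percentage points viability per unit
log-intensity). This mirrors how related actives behave in real
fractionation campaigns — chemically similar compounds co-partition
through every separation step and co-occur in the protective fractions —
and it is the regime in which both estimators can be expected to converge
on the same top candidates. Effect sizes are sized so the linear viability
model rarely hits the clip bounds (clipping breaks the linearity the
ground truth is defined by) and are balanced so no single spike dominates
the log-scale response.

Satellite features (13C, Na−H offsets; 5 % of features by default) have
intensities proportional to their parent (ratio 0.1–0.5) with
near-perfect profile correlation, exercising the deconvolution step.
Intensities below a limit of detection (500 counts) are zeroed, exercising
the pseudo-count policy; spiked features stay quantifiable everywhere so
the generative viability model is well defined.

MS/MS spectra come in families of 3–5 members sharing a dominant common
fragment set (≥ max(6, 75 %) of peaks, so all within-family pairs clear
the 0.70/6-peak edge criterion) plus member-specific minor peaks; families
occupy disjoint fragment m/z windows, so inter-family pairs share almost
no matchable fragments. Singleton spectra are appended. The compound
library contains caffeoylquinic-acid and flavonoid reference entries with
MS/MS fragments plus decoys placed 50 ppm off the reference masses.

Not emulated: raw profile-mode spectra, chromatographic peak shapes in the
time domain, ion suppression, isotope-pattern shapes, or correlated assay
noise between fractions. Passing tests on this generator therefore show
that the estimators recover linear log-intensity drivers under realistic
cross-fraction variation — not that they are robust to matrix effects or
assay drift.

## Numerical choices and degenerate inputs

* PLS stops early (with an error on the first component) when the
  covariance between X and the response is numerically zero; constant
  columns get unit scale and zero weight.
* SR of a zero-variance (after centring) feature is defined as 0; a
  residual-free feature gets `Inf` and ranks first.
* Ensemble members whose bootstrap response is constant contribute
  all-zero coefficient vectors rather than errors; a single-column matrix
  is padded with an inert zero column to satisfy the solver's minimum.
* Cosine scores are clamped to [0, 1]; tie-breaking in greedy peak pairing
  is deterministic (by intensity product, then peak indices).
* All randomness flows from explicit seeds (`synthetic_config(seed=)`,
  `ensemble_config(seed=)`, `run_config(seed=)`); reruns are
  byte-identical. RNG state of the caller is saved and restored.

## Problem sizes used by the test suite

Unit tests run on 30–150-feature datasets. The parameter-recovery study
uses 50 replicate datasets of 21 fractions × 300 features with 3 spiked
bioactives and 1000-member ensembles — large enough that selection
frequencies stabilize, small enough that the suite completes on a single
CPU in well under half an hour. The end-to-end determinism check runs the
full pipeline twice on a generator-default dataset (1500 features) with an
80-member ensemble.

## Known limitations

* The deconvolution stand-in merges by fixed offsets and correlation; it
  does not model isotope-pattern intensity ratios and can over-merge
  heavily correlated co-eluting ions.
* The spectral merge step is a greedy single pass, order-dependent for
  borderline cases (deliberately simple; full clustering is out of scope).
* SR inherits the ambiguity of any projection method when predictors are
  nearly collinear with the response direction: closely co-varying
  inactive compounds rank adjacent to true actives, as they do on real
  data. The consensus with the Elastic Net ensemble (which sees individual
  coefficients, not projections) is the intended mitigation.
* With ~20 samples, any auto-selected model size (PLS components, lambda)
  is noisy; both selection rules are documented above and both are
  overridable for full reproducibility.
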