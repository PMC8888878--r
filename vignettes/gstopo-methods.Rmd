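---
title: "Static and dynamic global-signal topography: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic global-signal topography: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gstopo)
```

## The quantities this package computes

Resting-state BOLD signals share a brain-wide component: the *global
signal* (GS), defined here as the unweighted mean time course over all
gray-matter voxels. How strongly each voxel couples to the GS — the
*global-signal topography* (GST) — is summarized two ways:

* **Static GST**: the Pearson correlation of each GM voxel's full time
  course with the GS, Fisher r-to-z transformed
  (`z = atanh(r)`, with `|r|` clamped to `1 - 1e-7` so perfectly
  correlated voxels stay finite).
* **Dynamic GST**: the same correlation computed in rectangular sliding
  windows (default 22 TRs, step 1 TR; 30 TRs as a robustness
  alternative), giving a z-series per voxel. Its per-voxel sample SD
  (n − 1 denominator), mean, and coefficient of variation
  CV = SD/|mean| form the dynamic summary maps. With a full-length
  window the dynamic map reduces exactly to the static map, which is one
  of the package's invariant tests.

Window length is defined in TRs; the number of complete windows over T
samples is `floor((T - L)/step) + 1`, so 390 retained volumes with L = 22
and step 1 give 369 windows. (The source protocol annotates a 22-TR
window as 44 s despite TR = 1 s; the package treats TRs as the unit and
derives seconds from TR, leaving that inconsistency documented rather
than resolved.)

The CV divides by `|mean|` with a guard: voxels whose windowed mean-z
magnitude falls below `eps = 1e-3` get a missing CV rather than a huge
or sign-flipped one; a signed variant (`cv_mode = "signed"`) is
available. Summaries default to the Fisher-z scale; `scale = "r"` maps
the windowed values back through `tanh` first. The r scale matters for
noise-free validation data: as r approaches 1 the z transform's slope
diverges, so with no noise floor the z-scale SD is dominated by the near-
singular region and is asymptotically insensitive to the modulation
strength being recovered (see "Validation design" below).

## Preprocessing

The temporal pipeline applies, per run: motion QC, discard of the first
10 volumes, per-voxel despiking, nuisance regression, band-pass, and
Gaussian smoothing.

* **Motion QC** fails a run if any translation exceeds 3 mm or any
  rotation exceeds 3 degrees (strictly greater; exactly 3 passes).
  Rotations are stored in radians; degree thresholds are converted.
* **Despiking** fits a 3rd-order polynomial trend per voxel, scales
  residuals by the robust SD (1.4826 × median absolute residual), and
  compresses points with standardized residual `s > c1` to
  `fit + sigma*(c1 + (c2-c1)*tanh((s-c1)/(c2-c1)))`, symmetrically for
  negative spikes. Defaults `c1 = 2.5`, `c2 = 4.0` follow common
  despiking practice; the polynomial trend stands in for an
  under-specified "3rd-order fit" (knot placement for a literal spline is
  not stated anywhere authoritative), so the bound
  `|output - fit| <= sigma*c2` is the tested contract.
* **Nuisance regression** removes, by per-voxel OLS, an intercept,
  linear trend, the Friston-24 motion expansion (parameters, one-volume
  backward lags zero-padded at the first row, and both sets squared),
  and WM/CSF mean signals. Rank-deficient designs fall back to a
  projection (pivoted QR) with a warning — residuals are unique either
  way. Residual orthogonality to every design column is a tested
  invariant.
* **Band-pass** is an ideal rectangular DFT mask over 0.01–0.1 Hz
  (DC always removed): exact idempotence and exact annihilation of
  out-of-band bins are tested. A zero-phase Butterworth alternative is
  available via `bandpass_method = "butterworth"`.
* **Smoothing** is a separable Gaussian, sigma = FWHM/(voxel ×
  2√(2 ln 2)) per axis, truncated at 3.5 sigma, kernel renormalized over
  the in-volume support so constants are preserved exactly.

The default stage order is discard → despike → regression → band-pass →
smooth: despiking after filtering cannot remove spikes that have already
been smeared, so despiking runs first even though the source protocol
lists its stages in a different (and internally ambiguous) order. The
order is configurable (`stages =`), and re-ordering demonstrably changes
the output on drift-heavy input — a documented non-commutativity, not a
bug.

## Group inference

Per-subject summary maps (static z, dynamic SD, CV; each window length)
enter a voxelwise one-way fixed-effects ANOVA, df = (k−1, N−k), F = 0
where both variance components vanish. Supra-threshold voxels
(p < 0.001 uncorrected by default) are grouped into connected components
(26-connectivity default, 6 available), components below 15 voxels are
dropped, and each surviving cluster is reported with its size, peak-F
voxel and peak MNI coordinates (0-based voxel indices through the stored
affine), ordered by peak F. The 15-voxel minimum mirrors the smallest
cluster the reference analysis reported; the explicit
threshold-plus-extent rule replaces an unstated map-level correction and
is labeled as such in output tables.

For a data-driven alternative to the fixed extent,
`permutation_cluster_extent()` shuffles subject labels to estimate the
null distribution of the maximum cluster size and returns the extent
exceeded by at most 5% of permutations.

ROI-level analysis averages each subject's map over an ROI, reports
group means/SDs, the ordering of group means, and Welch pairwise t-tests
with Bonferroni adjustment (Welch because group sizes are unequal:
40/54/26). Behavior correlations are Pearson r with two-sided p, by
default over the patient groups only, dropping missing scores pairwise
and flagging constant scores or fewer than 3 complete pairs instead of
erroring.

## The synthetic cohort generator

No imaging data accompany the study this design follows, so validation
runs on a synthetic cohort with known ground truth. The phantom is a
deterministic geometry: WM core, GM shell, CSF rim on a centered grid
(3 mm voxels by default), with three disjoint GM ROIs ("right_insula",
"precuneus", "cerebellum_anterior") at fixed angular positions.

Each subject's voxel series follows

y_v(t) = b_v (1 + m_v sin(2π t TR/τ + φ_v)) g(t) + d_v(t) + ε_v(t)

* `g(t)`: a shared band-limited (0.01–0.1 Hz) unit-variance Gaussian
  process — generated inside the analysis band so band-pass
  preprocessing does not remove the signal of interest.
* `b_v`: static coupling, a smooth spatial profile over GM
  (0.7–1.3), zero in WM/CSF. WM/CSF carry only noise and drift: they are
  the pipeline's nuisance proxies, so coupling them to `g` would make
  tissue regression remove the very signal under study.
* `m_v`: modulation depth in [0, 1) — the *temporal variability* of
  coupling, the generator's ground-truth quantity. Baseline is a smooth
  GM profile (0.05–0.35); group effects add ROI offsets (below).
* `φ_v`: modulation phases restricted to {0, π} and greedily
  sign-balanced against the coupling-weighted depths, so the amplitude
  modulation cancels from the GM mean. This keeps `g` exactly
  recoverable from the global signal and makes each voxel's windowed
  correlation variability attributable to its own `m_v` — an
  identifiability choice a validation phantom needs; continuous random
  phases leave a voxel-level alignment noise between the modulation
  pattern and the realization of `g` that no amount of ROI averaging at
  the single-subject level removes. Each labeled ROI shares one phase
  sign (it enters the balance as a single item): spatially incoherent
  signs would let Gaussian smoothing cancel the modulation between
  neighboring voxels and erase the planted group effect from the fully
  preprocessed data.
* `d_v(t)`: slow drift, random cubic-polynomial shape per voxel, SD
  `drift_amp = 0.5` signal units.
* `ε`: white noise, `noise_sd = 1.0` (so a typical GM voxel correlates
  with the GS at r ≈ 0.6, a realistic static GST level).
* Modulation period τ = 60 s: slow enough that a 22-TR window sees a
  changing modulation state, fast enough that the scan covers several
  cycles.

Group effects raise `m_v` at the right insula by (0, +Δ/2, +Δ) for
(HC, ARCI, AUD-NCI) and by the reversed increments at the precuneus,
encoding the target pattern: controls lowest CV at the insula with
AUD-NCI highest, and the reverse ordering at the precuneus. Δ = 0.40 by
default. The magnitude is a synthetic design choice, not an estimate: no
effect size exists to copy, so Δ was calibrated once, by a pilot sweep
over simulated cohorts at the study's group sizes (40/54/26), to the
smallest value at which the weakest adjacent-group CV contrast (the
precuneus ARCI vs AUD-NCI pair under the 30-TR window) is recovered
reliably (≥ 90% of cohorts); Δ = 0.30 left that pair at 88%.

Behavioral scores are drawn per group from the reported
means/SDs (e.g. ADS 1.50 ± 0.74 for controls, 26.06 ± 3.55 for
patients), truncated at zero where negative values are meaningless.
MMSE and MoCA for the patient subgroups are truncated to respect the
grouping rule (ARCI: MMSE < 24 and MoCA < 26; AUD-NCI: the complement);
their SDs are not reported anywhere and are chosen as plausible clinical
values. All scores are drawn independently of the imaging model, so
score–imaging correlations are null by construction *except* through
the subgroup confound that MMSE/MoCA carry by definition of the
grouping rule — which is why the null-calibration analyses use the
scores whose distributions are identical across the patient subgroups.

### What the generator does and does not emulate

It reproduces the study's temporal geometry (400 volumes, TR 1 s, 10
discarded), group sizes, band-limited shared dynamics, ROI-localized
group differences in coupling variability, slow drifts, white noise and
small motion traces. It does not model hemodynamic response shapes,
physiological (cardiac/respiratory) noise spectra, spatial noise
correlations, motion artifacts in the voxel data, or registration
error. Passing recovery tests therefore demonstrates that the pipeline
measures what it claims on data obeying its assumptions — not that the
original clinical effects would replicate. One further caveat: because
modulation adds signal variance (Var ∝ b²(1 + m²/2)), groups with
deeper modulation also have marginally different *static* correlations
in the affected ROIs, so the phantom does not reproduce a perfectly
null static-GST group contrast.

## Validation design and problem sizes

The package's acceptance analyses (see `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`) recompute:

1. **Sliding-window oracle**: every windowed z equals a brute-force
   two-pass Pearson + atanh loop within 1e-10 (200 voxels × 369
   windows at the study geometry). The production path uses centered
   cumulative sums in C++; the oracle is plain `stats::cor`.
2. **Static/dynamic identity**: a full-length window reproduces the
   static map within 1e-12.
3. **ANOVA**: exact on a hand-computed toy (F = 3.0, df 2,6), equal to
   t² for two groups, and calibrated (type-I rate 0.05 ± 0.01 at
   p < 0.05) over 50 null cohorts at study group sizes.
4. **Preprocessing contracts**: residual orthogonality < 1e-6, band-pass
   idempotence and out-of-band annihilation, despike bounds.
5. **Parameter recovery**: 50 simulated cohorts (40/54/26 subjects,
   16³ grid, 400 volumes) must recover both ROI orderings for both
   window lengths in ≥ 90% of cohorts; noise-free single subjects must
   rank GM voxels by modulation depth (Spearman > 0.95) via the r-scale
   SD map. The recovery harness (`cohort_roi_summary()`) streams
   subjects in matrix form and applies discard + trend regression +
   dynamic GST; despiking, band-pass and smoothing are omitted there
   because the synthetic signal is generated band-limited and
   spike-free, and a test pins the harness to the full object pipeline
   bitwise on a reference subject. The z-scale SD is *not* used for the
   noise-free check: with ε = 0 and no drift, 1 − r ∝ m²·(window
   factor), so SD(atanh r) ≈ SD of a constant plus log(window factor) —
   independent of m — whereas SD(r) ∝ m² retains the ranking. With
   realistic noise the z scale is the variance-stabilized choice and is
   the default everywhere else.
6. **Null behavior correlations**: with scores independent of imaging,
   correlation p-values are uniform (KS p > 0.01 over 200 score
   redraws against fixed imaging values) and the count of nominal
   significances matches the binomial expectation.

Problem sizes were chosen to keep the full validation suite within a
coffee break on one core: the 16³ phantom holds ~780 GM voxels and
~85-voxel ROIs — large enough for cluster extents above the 15-voxel
minimum and stable ROI means, small enough that a 120-subject cohort
simulates and analyzes in ~12 s. Unit tests use a 12³ phantom and
shorter runs.

## Numerical choices and degenerate inputs

* Zero-variance voxels or windows yield r = 0 (counted and reported),
  so empty phantom background never poisons maps.
* Fisher z clamps |r| at 1 − 1e-7; inputs with |r| > 1 + 1e-9 are
  domain errors rather than silently clamped.
* Windowed sums run in double precision on globally centered series;
  agreement with the two-pass oracle is ~1e-13 in practice.
* Cluster peak ties break deterministically (first voxel in array
  order); reductions iterate voxels in fixed order, so outputs are
  bit-reproducible for a given seed (tested via byte-identical TSVs).
* All cohort randomness derives from one master seed through a stable
  string hash of subject ids, so adding subjects never perturbs
  existing ones.

## Known limitations

Spatial normalization, slice timing and rigid-body realignment are out
of scope (synthetic data are generated on a common grid). The
default cluster-extent rule is an explicit stand-in, not a random-field
correction; the permutation alternative controls the cluster-level rate
empirically but at simulation cost.
CV of near-zero-mean voxels is reported as missing rather than
rescued; analyses of CV maps should expect some missingness in weakly
coupled regions.
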