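---
title: "Seed and behaviour PLS: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed and behaviour PLS: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis

`seedpls` implements a multivariate seed partial least squares (PLS)
analysis for event-related fMRI that relates three kinds of measurements
— seed-region BOLD activity (functional), tract-wise fractional
anisotropy (structural, FA) and reaction times (behavioural, RT) — to
whole-brain spatiotemporal activity across task conditions.

The data enter as two blocks, built per experimental condition across
subjects:

* **Brain block (datamat).** For every trial, the BOLD volumes at the
  onset scan and the following five scans (a 6-lag window at TR = 3 s,
  spanning 18 s of hemodynamic response) are expressed as percent signal
  change against the onset scan and averaged within subject and
  condition. Stacked over subjects this gives the
  subjects x conditions x (lags x voxels) datamat.
* **Variable block.** Per subject and condition: the window-averaged
  seed-ROI signal, one FA scalar per tract (condition-invariant, so the
  same value enters every condition's row), and the mean RT over
  *accurate* trials only.

For each condition $c$ and variable $v$ the analysis computes the Pearson
correlation, across subjects, of $v$ with every (lag, voxel) column,
giving one row of the stacked cross-block matrix
$R \in \mathbb{R}^{(C \cdot V) \times (L \cdot Q)}$. Although the field
often calls $R$ a covariance matrix, its entries are correlations — the
behavioural-PLS convention, and the scale on which results are reported.
The SVD $R = U S V^\top$ yields latent variables (LVs): task saliences
(columns of $U$), voxel saliences (columns of $V$) and singular values.
The share of cross-block covariance an LV accounts for is
$100\, s_i^2 / \sum_j s_j^2$. Brain scores are the projection of each
subject's condition row of the datamat onto an LV's voxel salience;
their correlation with each variable, per condition, is the quantity
displayed in the per-LV report.

Inference is fully resampling-based:

* **Permutation test** (default 500 permutations): the subject pairing
  between the variable block and the brain block is shuffled
  independently within each condition, $R$ is rebuilt and re-decomposed,
  and the $i$-th singular values are compared without re-sorting. The
  add-one estimator $p_i = (1 + \#\{s_i^{perm} \ge s_i^{obs}\}) /
  (n_{perm} + 1)$ never returns zero.
* **Bootstrap** (default 100 iterations; 1000+ recommended for stable
  percentile intervals): subjects are resampled with replacement jointly
  across blocks; resampled saliences are aligned to the originals by
  orthogonal Procrustes (resolving sign flips and component swaps); the
  per-cell standard deviation over iterations is the salience SE, and
  bootstrap ratios (BSR = salience / SE) above 3.0 approximate p < .001.
  Correlation confidence intervals are percentile (2.5/97.5); a
  correlation is flagged significant when its 95% CI excludes zero.
* **Cluster reporting**: BSR maps are binarised at the threshold
  separately for the positive and negative salience poles (the two ends
  of an LV express anti-correlated activity patterns and are reported
  separately), 3D connected components are labelled within each lag map,
  clusters under the minimum extent (default 100 voxels) are discarded,
  and one peak per cluster is reported in MNI millimetres, sorted
  posterior to anterior.

## Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `lag_count` | 6 | scans (TR = 3 s) | trial window covering the HRF |
| `n_perm` | 500 | — | LV significance |
| `n_boot` | 100 | — | salience SEs and percentile CIs |
| `bsr_threshold` | 3.0 | — | approximates p < .001 |
| `min_cluster` | 100 | voxels | counted within one lag map |
| `connectivity` | 26 | — | 6 selectable |
| `z_outlier` | 3 | SD | subject exclusion on any variable |
| `seed_radius` | 1 | voxels | 27-voxel cube around the seed coordinate |

## Design choices where the method was genuinely open

* **Window baseline.** Percent signal change relative to the onset-scan
  value, per trial; seed activity is conventionally displayed in percent
  signal change, and the referencing makes the datamat invariant to
  scanner gain (scaling all volumes by a constant changes nothing).
  The lag-0 columns are identically zero under this convention; they are
  kept for shape consistency and carry zero correlation by construction.
* **Onset-to-scan mapping.** The scan at or before the onset. Onsets are
  jittered off the scan grid in this task design, so an exact-grid
  mapping is unavailable.
* **Seed extent.** Published seed analyses often give a point MNI
  coordinate; a single voxel is noise-dominated, so the seed set is the
  coordinate's voxel plus its 26-neighbourhood within the mask
  (configurable radius).
* **Seed region excluded from the brain block.** The seed variable *is*
  the average of its ROI columns; leaving those columns in the datamat
  couples the two blocks through shared scan noise even when no signal
  exists, which makes the permutation test anticonservative. The seed is
  therefore correlated with all *other* brain voxels. This also matches
  how seed analyses are described: seed activity against the rest of the
  brain.
* **Per-index permutation statistic.** Permuted singular values are
  compared index-to-index after the decomposition's own descending sort;
  re-sorting against the observed spectrum is not applied (configurable
  in principle, but the non-resorted convention is the default and the
  one validated here).
* **Percentile CIs.** The bootstrap interval method is the percentile
  2.5/97.5 rule; normal-approximation intervals are not used.
* **Procrustes scope.** The bootstrap aligns and tracks only the LVs
  under report (default 2). Aligning the full set of trailing noise
  components lets the orthogonal transform absorb reference noise, which
  measurably deflates salience SEs and roughly doubles the false-positive
  tail of the BSR map. If the full set is wanted, `n_lv = NULL` tracks
  all components.
* **Sign convention.** Each LV's sign is pinned so its largest-magnitude
  task salience is positive; resampling and reports inherit the pinned
  sign. SVD signs are otherwise arbitrary and would break reproducibility.
* **Coordinates.** Voxel indices are 1-based in R; the NIfTI affine is
  applied to 0-based indices, so reported MNI coordinates follow the
  NIfTI convention exactly.
* **Missing data.** Subjects missing a required FA tract are dropped
  listwise and reported; a subject x condition cell with no accurate
  trial is flagged and the subject dropped, never imputed.

## The synthetic-data generator

Real scans for this design are not redistributable, so the package ships
a generator that plants a known latent network and emulates the task
structure: four expectancy conditions (angry/happy video crossed with
congruent/incongruent cue), ~40 subjects, multi-trial event-related BOLD
with a hemodynamic response, and condition-wise coupling between a
planted voxel-salience pattern and the seed/FA/RT variables.

**Generative model.** Each subject $i$ receives an independent standard
normal latent score $z_{ic}$ per condition. The planted voxel salience is
a compact positive blob and a compact negative blob (300 voxels total by
default, split 2:1, ~17% of the 12^3 demonstration grid — conservative
relative to the widespread networks such seed analyses report), times a
hemodynamic lag profile (a 3-s boxcar convolved with the canonical
double-gamma HRF, averaged over the uniform onset phase within one TR).
Voxel time courses are baseline plus the lag profile scaled by
$z_{ic} \times$ salience at each trial's window scans, plus white
Gaussian noise. FA and RT are
$x = \rho\,(u^\top z) + \sqrt{1-\rho^2}\,\varepsilon$ with $u$ the
planted per-variable condition weights and $\rho$ the coupling strength
(RT weights negative: stronger network expression, faster responses); FA
is drawn once per subject and loads on every condition's latent score.
The seed variable is not simulated separately — the seed ROI sits at the
centre of the positive blob, so the extracted seed signal is a linear
function of the latent scores automatically.

**Calibration constants** (chosen once, stated here as the package's
conditions): peak planted response 0.5% signal change for a subject one
SD above the mean latent score; per-trial peak SNR 0.5, where the noise
of a single-trial percent-signal value carries a factor $\sqrt 2$ from
the onset-scan reference, hence `noise_sd = peak_psc / (snr * sqrt(2))`;
12 trials per condition; RT ~ 1500 +/- 300 ms between subjects with
100 ms trial noise, bounded by the 3 s response window; FA ~ 0.5 +/-
0.08; accuracy Bernoulli(0.9) with at least one accurate trial forced
per condition cell.

**Null regime.** `coupling_strength = 0` generates the *global* null: no
network is planted at all. Decoupling only FA/RT would not be a null for
this pipeline, because the seed variable is extracted from the brain
itself and would retain genuine coupling with any planted signal.

**Trial spacing.** Onsets are jittered uniformly within one TR (so the
onset-to-scan mapping is exercised) but spaced `(lag_count + 1) * TR`
apart by default, keeping consecutive trial windows on disjoint scans.
Overlapping windows — as in the real task — make condition rows share
scan noise; together with the condition-invariant FA variable this
couples the blocks and biases the permutation null.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: overlapping event-related designs,
physiological and temporally autocorrelated noise, motion artefacts,
multi-run session structure, spatial smoothness of noise, anatomical
variability, and audio-visual stimulus content. Recovery results here
validate the *pipeline*, not the acquisition.

## Numerical choices and degenerate inputs

* Wide matrices are decomposed via the eigen-decomposition of the small
  Gram matrix $RR^\top$; singular vectors are validated in the test
  suite against LAPACK's SVD, a brute-force eigendecomposition of
  $R^\top R$ and an independent power-iteration-with-deflation oracle.
* Zero-variance voxel columns yield r = 0 with one aggregated warning; a
  zero-variance *variable* within a condition is an error naming the
  (condition, variable) cell.
* An all-zero correlation matrix is a "degenerate matrix" error; percent
  covariance is undefined there.
* Bootstrap draws in which a variable collapses to zero variance are
  redrawn and counted; more than 20% redraws aborts.
* SE = 0 cells (noise-free data) give flagged, excluded bootstrap ratios
  rather than infinities.
* A rank-deficient Procrustes cross-product falls back to per-LV sign
  alignment and records the fallback.
* Peak ties within a cluster resolve to the smallest linear voxel index,
  making peak tables invariant to traversal order.

## Problem sizes used in the validation suite

The acceptance checks run on the 12^3 demonstration grid: 200 null
datasets (20 subjects, 6 trials per condition, 100 permutations) for the
calibration of the permutation test; 50 planted datasets (40 subjects,
12 trials per condition, coupling 0.8, trial SNR 0.5) for salience
recovery and BSR detection with the cluster extent scaled to 27 voxels
for this grid; 50 planted datasets at 20 subjects with 200 bootstrap
iterations for CI coverage; 100 random 20^3 maps for the
connected-components oracle; and randomly generated matrices up to
12 x 1200 for the SVD oracles. These sizes are the package's validation
conditions; all constants of the analysis itself (500 permutations, 100
bootstrap iterations, BSR 3.0, 100-voxel clusters at acquisition
resolution, z > 3 outlier screening) are the defaults of
`read_config()`.

## Known limitations

* Single-group behavioural/seed PLS only: no mean-centred task PLS,
  non-rotated PLS or multi-group variants.
* FA values are consumed as given; tractography and diffusion
  preprocessing are upstream concerns.
* fMRI preprocessing (slice timing, realignment, normalisation,
  smoothing) is assumed done; volumes are taken as already in a common
  space.
* Anatomical labelling of peaks (region names, Brodmann areas) requires
  an external atlas and is out of scope; peak tables carry coordinates
  only.
* With 100 bootstrap iterations the percentile CI endpoints are coarse;
  they stabilise at 1000+ iterations, at proportional cost.
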