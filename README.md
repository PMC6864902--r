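# seedpls

Seed and behaviour partial least squares (PLS) for event-related fMRI:
a multivariate analysis that relates seed-region BOLD activity,
white-matter fractional anisotropy (FA) and reaction times (RT) to
whole-brain voxel-lag activity across task conditions, with fully
resampling-based inference. It is written for neuroimaging researchers
who want a tested, scriptable, reproducible implementation of the
behavioural/seed-PLS workflow — and for methodologists who want every
stage verifiable against planted ground truth.

## The method

Per experimental condition `c` and variable `v` (seed mean, FA per
tract, mean accurate RT), the pipeline correlates `v` across subjects
with every (lag, voxel) column of the event-locked datamat — trial
windows of 6 repetition times expressed as percent signal change against
the onset scan and averaged within subject and condition. The stacked
matrix

```
R[(c,v), (lag,voxel)] = cor_subjects( v_c , datamat_c[ , (lag,voxel)] )
```

is decomposed by SVD, `R = U S Vᵀ`, into latent variables (LVs): task
saliences `U`, voxel saliences `V`, singular values `s`, with LV `i`
accounting for `100·s_i²/Σ_j s_j²` percent of the cross-block
covariance. Brain scores are the per-subject, per-condition projection
of the datamat onto an LV's voxel saliences. Inference: LV significance
by permutation of the subject pairing between blocks (`p = (1 + #{s_perm
≥ s_obs}) / (n_perm + 1)`); salience stability by subject-level
bootstrap with Procrustes alignment, thresholded as bootstrap ratios
(BSR = salience / SE > 3.0) with a cluster-extent filter; correlation
CIs by the percentile bootstrap.

A first-class synthetic-data generator plants a known latent network
(contiguous voxel blobs × hemodynamic lag profile, coupled to seed/FA/RT
through per-subject latent scores) so that recovery, calibration and
detection are measurable quantities, not hopes. See the methods
vignette (`vignettes/seed-behaviour-pls.Rmd`) for the model, parameter
semantics and design decisions.

## A worked example

```r
library(seedpls)

truth <- make_ground_truth(seed = 1)          # 12^3 grid, planted network
ds    <- simulate_dataset(truth, n_subjects = 40,
                          n_trials_per_condition = 12, seed = 101)
cfg   <- read_config(overrides = list(
  analysis = list(n_perm = 100, n_boot = 100, min_cluster = 27)))
res   <- pls_pipeline(ds, cfg)

res$reports[[1]]
evaluate_recovery(res$decomposition, ds$truth,
                  mask_idx = res$datamat$mask_idx)$cosine
```

which prints (abridged):

```
LV1: p = 0.0099, 59.41% covariance
  significant brain-score correlations (95% CI excludes 0):
    AC / seed: r = 0.94 [0.90, 0.97]
    AI / seed: r = 0.96 [0.93, 0.98]
    HC / seed: r = 0.97 [0.95, 0.98]
    HI / seed: r = 0.96 [0.92, 0.97]
    AC / fa_stria: r = 0.45 [0.18, 0.69]
    AC / rt: r = -0.62 [-0.82, -0.29]
    HC / rt: r = -0.66 [-0.80, -0.50]
    ...
  peaks: 3 positive-pole, 3 negative-pole cluster(s)
[1] 0.9257
```

Reading this: the first latent variable is significant at the smallest
p the 100 permutations can resolve (1/101); its network expression
(brain scores) tracks seed activity, stria FA and faster responses
(negative RT correlations) where the generator planted them; the
thresholded BSR map segments into positive- and negative-pole clusters;
and the estimated voxel salience matches the planted pattern with
cosine 0.93.

The same analysis runs from disk through a YAML config:

```sh
Rscript inst/cli/seedpls.R simulate --config analysis.yaml
Rscript inst/cli/seedpls.R analyze  --config analysis.yaml
Rscript inst/cli/seedpls.R report   --results results/
```

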