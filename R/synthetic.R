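# Synthetic multi-subject datasets with planted latent brain-behaviour
# structure. The generator is first-class: its ground truth defines the
# acceptance surface for every downstream stage.

# grow a spatially contiguous blob of `size` voxels by seeded random
# breadth-first accretion under 6-connectivity (hence contiguous under both
# 6- and 26-connectivity conventions)
grow_blob <- function(center_ijk, size, grid_shape, forbidden = integer(0)) {
  center <- ijk_to_index(matrix(center_ijk, ncol = 3), grid_shape)
  members <- center
  frontier <- integer(0)
  neighbours6 <- function(idx) {
    ijk <- index_to_ijk(idx, grid_shape)
    cand <- rbind(ijk + c(1, 0, 0), ijk - c(1, 0, 0),
                  ijk + c(0, 1, 0), ijk - c(0, 1, 0),
                  ijk + c(0, 0, 1), ijk - c(0, 0, 1))
    ok <- cand[, 1] >= 1 & cand[, 1] <= grid_shape[1] &
      cand[, 2] >= 1 & cand[, 2] <= grid_shape[2] &
      cand[, 3] >= 1 & cand[, 3] <= grid_shape[3]
    ijk_to_index(cand[ok, , drop = FALSE], grid_shape)
  }
  frontier <- setdiff(neighbours6(center), c(members, forbidden))
  while (length(members) < size) {
    if (length(frontier) == 0)
      stop("blob growth exhausted the grid before reaching ", size, " voxels")
    pick <- frontier[sample.int(length(frontier), 1)]
    members <- c(members, pick)
    frontier <- setdiff(unique(c(frontier, neighbours6(pick))),
                        c(members, forbidden))
  }
  sort(members)
}

#' Construct a planted ground truth for the synthetic PLS pipeline
#'
#' Defines one (optionally two) latent component(s), each consisting of a
#' spatially contiguous voxel-salience pattern — one compact blob per sign —
#' with a hemodynamic lag profile, and a signed (condition x variable)
#' salience pattern that couples the latent subject scores to the seed, FA
#' and RT variables. `coupling_strength = 0` defines the null regime.
#'
#' The BOLD noise standard deviation is derived from the per-trial
#' signal-to-noise ratio `trial_snr`: the planted percent-signal response at
#' the strongest (lag, voxel) cell of a subject one standard deviation above
#' the mean latent score is `peak_psc`, and the percent-signal-change noise
#' of a single trial at one lag has standard deviation
#' `noise_sd * sqrt(2)` (the onset-scan reference contributes a second,
#' independent noise term), so `noise_sd = peak_psc / (trial_snr * sqrt(2))`.
#'
#' @param grid_shape Integer vector of 3 voxel grid dimensions
#'   (default `c(12, 12, 12)`).
#' @param n_active_voxels Total number of voxels with nonzero salience in
#'   component 1 (default 300, about 17\% of the default grid — a
#'   conservative extent relative to the widespread networks such seed
#'   analyses report; split 2:1 between the positive and negative blob).
#' @param n_lags Trial-window length in scans (default 6).
#' @param conditions Condition labels (default `c("AC","AI","HC","HI")`:
#'   angry/happy videos crossed with cue congruency).
#' @param variables Variable names; names starting with `"fa"` are treated
#'   as condition-invariant subject-level tract values, names starting with
#'   `"rt"` as reaction times (negative planted coupling: stronger network
#'   expression goes with faster responses), `"seed"` as the seed-region
#'   mean whose coupling is realised through the planted brain signal
#'   itself. Default `c("seed", "fa_stria", "rt")`.
#' @param coupling_strength Scalar in `[0, 1]` controlling the magnitude of
#'   the planted brain-variable correlations (0 = null regime; default 0.8).
#' @param seed Integer RNG seed; the truth is deterministic given the seed.
#' @param n_components 1 (default) or 2; the optional second component has
#'   disjoint spatial support and a variable-salience pattern
#'   orthogonalised against component 1, at 0.6 times the coupling.
#' @param tr_s Repetition time in seconds (default 3).
#' @param peak_psc Planted peak response in percent-signal units for a
#'   subject one SD above the mean latent score (default 0.5).
#' @param trial_snr Per-trial peak signal-to-noise ratio (default 0.5).
#' @return An object of class `pls_ground_truth` with fields
#'   `voxel_salience` (`n_lags` x n-voxel matrix, unit Frobenius norm, per
#'   component), `variable_salience` (condition x variable matrix, unit
#'   Frobenius norm, per component), `active_voxel_set` (linear grid
#'   indices, exactly the support of the voxel salience), `coupling`,
#'   `noise_sd`, `regime` (`"planted"` or `"null"`), `seed_center_ijk`.
#' @export
make_ground_truth <- function(grid_shape = c(12, 12, 12),
                              n_active_voxels = 300,
                              n_lags = 6,
                              conditions = c("AC", "AI", "HC", "HI"),
                              variables = c("seed", "fa_stria", "rt"),
                              coupling_strength = 0.8,
                              seed = 1,
                              n_components = 1,
                              tr_s = 3,
                              peak_psc = 0.5,
                              trial_snr = 0.5) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            n_lags >= 2, length(conditions) >= 2, length(variables) >= 1,
            coupling_strength >= 0, coupling_strength <= 1,
            n_components %in% c(1, 2),
            trial_snr > 0, peak_psc > 0)
  n_vox <- prod(grid_shape)
  if (n_active_voxels < 1 || n_components * n_active_voxels > n_vox)
    stop(sprintf(paste0("n_active_voxels (%d per component, %d components) ",
                        "exceeds the voxel grid (%d voxels)"),
                 n_active_voxels, n_components, n_vox))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")

  lag_prof <- hrf_lag_profile(n_lags = n_lags, tr_s = tr_s)

  with_seed(seed, {
    centers <- list(
      pos = round(grid_shape * 0.32), neg = round(grid_shape * 0.68),
      pos2 = c(round(grid_shape[1] * 0.68), round(grid_shape[2] * 0.32),
               round(grid_shape[3] * 0.5)),
      neg2 = c(round(grid_shape[1] * 0.32), round(grid_shape[2] * 0.68),
               round(grid_shape[3] * 0.5)))
    n_pos <- max(1L, round(2 / 3 * n_active_voxels))
    n_neg <- max(1L, n_active_voxels - n_pos)

    components <- vector("list", n_components)
    taken <- integer(0)
    for (m in seq_len(n_components)) {
      cpos <- if (m == 1) centers$pos else centers$pos2
      cneg <- if (m == 1) centers$neg else centers$neg2
      pos <- grow_blob(cpos, n_pos, grid_shape, forbidden = taken)
      taken <- c(taken, pos)
      neg <- grow_blob(cneg, n_neg, grid_shape, forbidden = taken)
      taken <- c(taken, neg)
      spatial <- numeric(n_vox)
      spatial[pos] <- 1
      spatial[neg] <- -1
      sal <- outer(lag_prof, spatial)          # n_lags x n_vox
      sal <- sal / sqrt(sum(sal^2))
      components[[m]] <- list(positive = pos, negative = neg,
                              spatial = spatial, voxel_salience = sal)
    }

    # signed (condition x variable) weights: magnitudes seeded, RT negative
    n_c <- length(conditions); n_v <- length(variables)
    vs <- vector("list", n_components)
    for (m in seq_len(n_components)) {
      w <- matrix(runif(n_c * n_v, 0.5, 1), n_c, n_v,
                  dimnames = list(conditions, variables))
      for (v in seq_len(n_v))
        if (startsWith(variables[v], "rt")) w[, v] <- -w[, v]
      if (m == 2) {
        # orthogonalise against component 1 in the (condition,variable) space
        w1 <- vs[[1]]
        w <- w - sum(w * w1) / sum(w1 * w1) * w1
        if (sqrt(sum(w^2)) < 1e-8) w <- matrix(rnorm(n_c * n_v), n_c, n_v)
      }
      vs[[m]] <- w / sqrt(sum(w^2))
    }

    noise_sd <- peak_psc / (trial_snr * sqrt(2))
    coupling <- coupling_strength * c(1, 0.6)[seq_len(n_components)]

    structure(list(
      grid_shape = grid_shape,
      n_lags = n_lags,
      tr_s = tr_s,
      conditions = conditions,
      variables = variables,
      n_components = n_components,
      coupling_strength = coupling_strength,
      coupling = coupling,
      noise_sd = noise_sd,
      peak_psc = peak_psc,
      trial_snr = trial_snr,
      lag_profile = lag_prof,
      voxel_salience = components[[1]]$voxel_salience,
      variable_salience = vs[[1]],
      active_voxel_set = sort(c(components[[1]]$positive,
                                components[[1]]$negative)),
      components = lapply(seq_len(n_components), function(m) {
        list(voxel_salience = components[[m]]$voxel_salience,
             variable_salience = vs[[m]],
             positive = components[[m]]$positive,
             negative = components[[m]]$negative,
             active_voxel_set = sort(c(components[[m]]$positive,
                                       components[[m]]$negative)))
      }),
      seed_center_ijk = as.integer(if (n_components >= 1)
        round(grid_shape * 0.32) else NULL),
      regime = if (coupling_strength == 0) "null" else "planted",
      generator_seed = as.integer(seed)
    ), class = "pls_ground_truth")
  })
}

#' @export
print.pls_ground_truth <- function(x, ...) {
  cat(sprintf("Planted PLS ground truth (%s regime)\n", x$regime))
  cat(sprintf("  grid %s, %d lags (TR %g s), %d component(s)\n",
              paste(x$grid_shape, collapse = "x"), x$n_lags, x$tr_s,
              x$n_components))
  cat(sprintf("  %d active voxels, coupling %.2f, noise sd %.3f\n",
              length(x$active_voxel_set), x$coupling_strength, x$noise_sd))
  cat(sprintf("  conditions: %s; variables: %s\n",
              paste(x$conditions, collapse = ", "),
              paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' Planted voxel salience in datamat column order
#'
#' Flattens a ground-truth voxel-salience matrix to the (lag-major) column
#' order of the trial-window datamat, restricted to in-mask voxels.
#'
#' @param truth A `pls_ground_truth`.
#' @param mask_idx Linear indices of in-mask voxels (default: all voxels).
#' @param component Component number (default 1).
#' @return Numeric vector of length `n_lags * length(mask_idx)`.
#' @export
truth_salience_vector <- function(truth, mask_idx = NULL, component = 1) {
  sal <- truth$components[[component]]$voxel_salience
  if (is.null(mask_idx)) mask_idx <- seq_len(ncol(sal))
  as.vector(t(sal[, mask_idx, drop = FALSE]))
}

#' Simulate a multi-subject event-related dataset with planted structure
#'
#' Each subject receives an independent standard-normal latent score per
#' condition (and component). Voxel time courses are a constant baseline
#' plus hemodynamically convolved trial responses scaled by
#' (latent score x planted voxel salience) plus white Gaussian noise; FA
#' and reaction times are linear functions of the latent scores with
#' weights given by the planted (condition x variable) salience, scaled so
#' the strongest brain-variable population correlation equals the coupling
#' strength, plus independent noise. The seed-region variable is realised
#' through the planted brain signal itself: the seed ROI sits at the centre
#' of the positive blob.
#'
#' Trials of the four conditions are interleaved in seeded random order
#' with onsets jittered uniformly off the scan grid, emulating the
#' jittered inter-stimulus intervals of the task design (1 s emotion cue,
#' 0.5-1.5 s jittered interval, 3 s video with responses within 3 s).
#'
#' @param truth A `pls_ground_truth` from [make_ground_truth()].
#' @param n_subjects Number of subjects (default 40; must be >= 3).
#' @param n_trials_per_condition Trials per condition per subject
#'   (default 12).
#' @param seed Integer RNG seed.
#' @param baseline Baseline BOLD signal level (arbitrary units, default
#'   100, so signal units equal percent-signal-change units).

#' @param spacing_s Spacing between consecutive trial onsets in seconds;
#'   by default `(n_lags + 1) * tr_s` so that consecutive trial windows
#'   occupy disjoint scans (overlapping windows would share scan noise
#'   across condition rows and couple the blocks under the global null).
#' @param lead_in_s Scanner lead-in before the first trial (default 6 s).
#' @param accuracy_rate Per-trial Bernoulli probability of a correct
#'   response (default 0.9); inaccurate trials carry no RT.
#' @param rt_mean_ms,rt_sd_ms Between-subject mean and SD of condition-wise
#'   mean RTs (defaults 1500 and 300 ms).
#' @param rt_trial_sd_ms Within-subject trial-to-trial RT noise
#'   (default 100 ms).
#' @param fa_mean,fa_sd Mean and SD of the simulated tract FA values
#'   (defaults 0.5 and 0.08; values clamped to `[0.05, 0.95]`).
#' @param n_fa_missing Number of subjects whose FA rows are omitted from
#'   the FA table (emulates indeterminable tracts; default 0).
#' @return An object of class `pls_simulated_dataset`: per-subject
#'   `volume_series` BOLD, event tables, an FA table, a brain mask, the
#'   affine, the ground truth, and the latent scores used.
#' @export
simulate_dataset <- function(truth, n_subjects = 40,
                             n_trials_per_condition = 12, seed = 1,
                             baseline = 100, spacing_s = NULL,
                             lead_in_s = 6,
                             accuracy_rate = 0.9,
                             rt_mean_ms = 1500, rt_sd_ms = 300,
                             rt_trial_sd_ms = 100,
                             fa_mean = 0.5, fa_sd = 0.08,
                             n_fa_missing = 0) {
  stopifnot(inherits(truth, "pls_ground_truth"))
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (n_trials_per_condition < 1) stop("n_trials_per_condition must be >= 1")
  if (!is.numeric(truth$noise_sd) || truth$noise_sd < 0)
    stop("noise_sd must be non-negative (0 = noise-free regime)")

  tr <- truth$tr_s
  n_lags <- truth$n_lags
  grid_shape <- truth$grid_shape
  n_vox <- prod(grid_shape)
  conditions <- truth$conditions
  n_c <- length(conditions)
  n_trials <- n_trials_per_condition * n_c
  n_comp <- truth$n_components

  # default onset spacing keeps consecutive trial windows on disjoint
  # scans: overlapping windows would share scan noise across condition
  # rows, coupling the blocks under the global null
  spacing_s <- spacing_s %||% ((n_lags + 1) * tr)

  # scan count sized for the worst-case onset plus the full window
  max_onset <- lead_in_s + (n_trials - 1) * spacing_s + tr
  n_scans <- ceiling((max_onset + n_lags * tr + tr) / tr)
  if (n_scans < n_lags + 2)
    stop("trial window overruns the scan: increase the scan length")

  vox_mm <- 2.5
  affine <- diag(c(rep(vox_mm, 3), 1))
  affine[1:3, 4] <- -(grid_shape - 1) / 2 * vox_mm

  mask <- array(TRUE, dim = grid_shape)
  subjects <- sprintf("sub%02d", seq_len(n_subjects))

  # planted per-trial response at the window scans: the hemodynamic lag
  # profile of the ground truth itself (peak 1), so the planted datamat
  # pattern is exactly proportional to the stored voxel salience
  lag_prof <- truth$lag_profile

  with_seed(seed, {
    z <- array(rnorm(n_subjects * n_c * n_comp),
               dim = c(n_subjects, n_c, n_comp),
               dimnames = list(subjects, conditions, NULL))

    # variable block planted directly (FA, RT):
    # x = sum_m coupling_m * (u_m . z_m) + sqrt(1 - sum coupling_m^2) * eps
    # with u the per-variable unit condition-weight vector. At coupling 1
    # the variables are exact linear functions of the latents (noise-free
    # regime); at coupling 0 they are pure noise.
    var_x <- list()
    resid_sd <- sqrt(max(0, 1 - sum(truth$coupling^2)))
    for (v in truth$variables) {
      if (startsWith(v, "seed")) next
      xv <- matrix(0, n_subjects, n_c, dimnames = list(subjects, conditions))
      for (m in seq_len(n_comp)) {
        w <- truth$components[[m]]$variable_salience[, v]
        u <- w / sqrt(sum(w^2))
        if (startsWith(v, "fa")) {
          # condition-invariant: one subject-level value loading on every
          # condition's latent score
          xv <- xv + truth$coupling[m] *
            matrix(z[, , m] %*% u, n_subjects, n_c)
        } else {
          xv <- xv + truth$coupling[m] * sweep(z[, , m], 2, u, `*`)
        }
      }
      if (startsWith(v, "fa")) {
        xv <- xv + matrix(rnorm(n_subjects) * resid_sd, n_subjects, n_c)
      } else {
        xv <- xv + matrix(rnorm(n_subjects * n_c) * resid_sd,
                          n_subjects, n_c)
      }
      var_x[[v]] <- xv
    }

    fa_tracts <- truth$variables[startsWith(truth$variables, "fa")]
    fa_rows <- list()
    for (v in fa_tracts) {
      fa_val <- clamp(fa_mean + fa_sd * var_x[[v]][, 1], 0.05, 0.95)
      fa_rows[[v]] <- data.frame(subject_id = subjects,
                                 tract = sub("^fa_?", "", v),
                                 fa = fa_val, row.names = NULL)
    }
    fa_table <- if (length(fa_rows)) do.call(rbind, fa_rows) else
      data.frame(subject_id = character(0), tract = character(0),
                 fa = numeric(0))
    rownames(fa_table) <- NULL
    if (n_fa_missing > 0) {
      missing_ids <- subjects[sample.int(n_subjects, min(n_fa_missing,
                                                         n_subjects))]
      drop_tract <- fa_tracts[1]
      fa_table <- fa_table[!(fa_table$subject_id %in% missing_ids &
                               fa_table$tract == sub("^fa_?", "",
                                                     drop_tract)), ]
    } else missing_ids <- character(0)

    rt_name <- truth$variables[startsWith(truth$variables, "rt")]
    rt_mean_ic <- if (length(rt_name))
      rt_mean_ms + rt_sd_ms * var_x[[rt_name[1]]] else
        matrix(rt_mean_ms, n_subjects, n_c,
               dimnames = list(subjects, conditions))

    active <- lapply(seq_len(n_comp), function(m)
      truth$components[[m]]$active_voxel_set)
    spatial <- lapply(seq_len(n_comp), function(m) {
      s <- numeric(n_vox)
      s[truth$components[[m]]$positive] <- 1
      s[truth$components[[m]]$negative] <- -1
      s[active[[m]]]
    })

    bold <- vector("list", n_subjects)
    events <- vector("list", n_subjects)
    names(bold) <- names(events) <- subjects

    for (i in seq_len(n_subjects)) {
      cond_seq <- sample(rep(conditions, n_trials_per_condition))
      onsets <- lead_in_s + (seq_len(n_trials) - 1) * spacing_s +
        runif(n_trials, 0, tr)
      acc <- rbinom(n_trials, 1, accuracy_rate)
      for (cc in conditions) {
        idx <- which(cond_seq == cc)
        if (!any(acc[idx] == 1)) acc[idx[sample.int(length(idx), 1)]] <- 1L
      }
      ci <- match(cond_seq, conditions)
      rt <- rt_mean_ic[cbind(i, ci)] + rnorm(n_trials, 0, rt_trial_sd_ms)
      rt <- clamp(rt, 200, 3000)
      rt[acc == 0] <- NA_real_

      Y <- matrix(rnorm(n_scans * n_vox, 0, truth$noise_sd),
                  n_scans, n_vox) + baseline
      s0 <- floor(onsets / tr) + 1L      # scan at or before onset
      for (t in seq_len(n_trials)) {
        rows <- s0[t] + seq_len(n_lags) - 1L
        keep <- rows <= n_scans
        # in the null regime (coupling 0) no network is planted at all:
        # the seed variable is brain-derived, so a global null requires
        # the absence of the latent network, not just decoupled FA/RT
        for (m in seq_len(n_comp)) {
          if (truth$coupling[m] <= 0) next
          amp <- truth$peak_psc * z[i, ci[t], m] * baseline / 100
          Y[rows[keep], active[[m]]] <- Y[rows[keep], active[[m]]] +
            amp * outer(lag_prof[keep], spatial[[m]])
        }
      }
      # Y is (scan, voxel); store as (x, y, z, t)
      arr <- array(t(Y), dim = c(grid_shape, n_scans))
      bold[[i]] <- volume_series(arr, affine = affine, tr_s = tr)
      events[[i]] <- data.frame(onset = onsets, duration = 3,
                                condition = cond_seq, accuracy = acc,
                                rt = rt, row.names = NULL)
    }

    seed_ijk <- truth$seed_center_ijk
    seed_mni <- as.numeric(affine %*% c(seed_ijk - 1, 1))[1:3]

    structure(list(
      bold = bold, events = events, fa = fa_table, mask = mask,
      affine = affine, tr_s = tr, truth = truth, latents = z,
      subjects = subjects, conditions = conditions,
      seed_spec = list(mni = seed_mni, voxel = seed_ijk),
      fa_missing = missing_ids,
      params = list(n_subjects = n_subjects,
                    n_trials_per_condition = n_trials_per_condition,
                    seed = as.integer(seed), baseline = baseline,
                    spacing_s = spacing_s, lead_in_s = lead_in_s,
                    accuracy_rate = accuracy_rate, n_scans = n_scans)
    ), class = "pls_simulated_dataset")
  })
}

#' @export
print.pls_simulated_dataset <- function(x, ...) {
  cat(sprintf(paste0("Simulated event-related dataset: %d subjects, ",
                     "%d conditions, %d scans (TR %g s)\n"),
              length(x$subjects), length(x$conditions),
              x$params$n_scans, x$tr_s))
  print(x$truth)
  invisible(x)
}

#' Compare an estimated latent variable with the planted truth
#'
#' Computes the absolute cosine similarity between estimated and planted
#' voxel saliences (sign-invariant: an SVD component is defined up to
#' reflection) and, when a detected voxel set is supplied, the sensitivity
#' and specificity of the thresholded map against the planted support.
#'
#' @param estimated Numeric voxel-salience vector in datamat column order,
#'   or a `pls_decomposition` (its `lv`-th voxel salience is used).
#' @param truth A `pls_ground_truth`.
#' @param detected_voxels Optional linear grid indices of voxels declared
#'   active after thresholding.
#' @param mask_idx Linear indices of in-mask voxels used to build the
#'   datamat (default: all voxels).
#' @param component Planted component to compare against (default 1).
#' @param lv Latent-variable index when `estimated` is a decomposition.
#' @return A list with `cosine` and, if `detected_voxels` was given,
#'   `sensitivity`, `specificity` and `false_positive_rate`.
#' @export
evaluate_recovery <- function(estimated, truth, detected_voxels = NULL,
                              mask_idx = NULL, component = 1, lv = 1) {
  if (inherits(estimated, "pls_decomposition"))
    estimated <- estimated$voxel_salience[, lv]
  v_true <- truth_salience_vector(truth, mask_idx = mask_idx,
                                  component = component)
  if (length(estimated) != length(v_true))
    stop(sprintf("salience length mismatch: estimated %d, truth %d",
                 length(estimated), length(v_true)))
  cosine <- abs(sum(estimated * v_true)) /
    (sqrt(sum(estimated^2)) * sqrt(sum(v_true^2)))
  out <- list(cosine = cosine)
  if (!is.null(detected_voxels)) {
    act <- truth$components[[component]]$active_voxel_set
    n_vox <- prod(truth$grid_shape)
    tp <- sum(detected_voxels %in% act)
    fp <- length(setdiff(detected_voxels, act))
    out$sensitivity <- tp / length(act)
    out$specificity <- 1 - fp / (n_vox - length(act))
    out$false_positive_rate <- fp / (n_vox - length(act))
  }
  out
}
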