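# Datamat construction: event-locked trial windows, seed signal, reaction
# times and the variable block entering the cross-block correlation.

#' Extract event-locked trial windows into a datamat
#'
#' For every trial, takes the scan at (or immediately before) the video
#' onset and the following `lag_count - 1` scans, expresses each lag as
#' percent signal change relative to the onset-scan value, and averages
#' across trials within subject and condition. The result is the
#' subjects x conditions x (lags x voxels) datamat whose columns are
#' ordered lag-major (all in-mask voxels at lag 0, then lag 1, ...).
#'
#' All trials of a condition enter the BOLD average regardless of response
#' accuracy; accuracy filters apply to the behavioural variable only.
#'
#' @param bold Named list of [volume_series()], one per subject.
#' @param events Named list of event data frames (see [read_events()]),
#'   aligned with `bold`.
#' @param mask 3D logical array; columns are restricted to in-mask voxels.
#' @param lag_count Number of post-onset time points (default 6).
#' @param conditions Condition labels to extract, in row order; defaults
#'   to the sorted union of conditions present in the first event table.
#' @return An object of class `trial_window_matrix`: `values` (3D array
#'   subjects x conditions x (lags*voxels)), `col_lag` (0-based lag per
#'   column), `col_voxel` (linear grid index per column), `voxel_ijk`,
#'   `grid_shape`, `affine`, `tr_s`, `conditions`, `subjects`,
#'   `lag_count`, `mask_idx`.
#' @export
extract_trial_windows <- function(bold, events, mask, lag_count = 6,
                                  conditions = NULL) {
  stopifnot(is.list(bold), is.list(events), length(bold) == length(events))
  subjects <- names(bold)
  if (is.null(subjects) || is.null(names(events)) ||
      !setequal(subjects, names(events)))
    stop("bold and events must be named lists over the same subjects")
  events <- events[subjects]
  if (is.null(conditions))
    conditions <- sort(unique(events[[1]]$condition))
  mask_idx <- which(as.logical(mask))
  if (!length(mask_idx)) stop("mask is empty")
  grid_shape <- dim(mask)
  n_vox <- length(mask_idx)
  n_col <- lag_count * n_vox
  tr <- bold[[1]]$tr_s
  affine <- bold[[1]]$affine

  values <- array(NA_real_,
                  dim = c(length(subjects), length(conditions), n_col),
                  dimnames = list(subjects, conditions, NULL))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    vs <- bold[[s]]
    if (abs(vs$tr_s - tr) > 1e-9)
      stop("subjects have differing repetition times")
    d <- dim(vs$data)
    if (!all(d[1:3] == grid_shape))
      stop("BOLD grid of subject ", s, " does not match the mask")
    n_scans <- d[4]
    Y <- matrix(vs$data, prod(grid_shape), n_scans)[mask_idx, , drop = FALSE]
    ev <- events[[s]]
    for (ci in seq_along(conditions)) {
      cc <- conditions[ci]
      tri <- which(ev$condition == cc)
      if (!length(tri))
        stop("condition ", cc, " absent for subject ", s)
      s0 <- floor(ev$onset[tri] / tr) + 1L     # nearest scan at or before
      over <- which(s0 + lag_count - 1L > n_scans | s0 < 1L)
      if (length(over))
        stop(sprintf(paste0("trial %d (onset %.2f s) of subject %s, ",
                            "condition %s: window of %d scans overruns ",
                            "the series (%d scans)"),
                     tri[over[1]], ev$onset[tri[over[1]]], s, cc,
                     lag_count, n_scans))
      acc <- matrix(0, n_vox, lag_count)
      ref <- Y[, s0, drop = FALSE]
      for (l in seq_len(lag_count)) {
        acc[, l] <- rowMeans((Y[, s0 + l - 1L, drop = FALSE] - ref) / ref)
      }
      values[si, ci, ] <- as.vector(acc) * 100
    }
  }
  structure(list(
    values = values,
    col_lag = rep(seq_len(lag_count) - 1L, each = n_vox),
    col_voxel = rep(mask_idx, lag_count),
    voxel_ijk = index_to_ijk(mask_idx, grid_shape),
    grid_shape = grid_shape, affine = affine, tr_s = tr,
    conditions = conditions, subjects = subjects,
    lag_count = lag_count, mask_idx = mask_idx
  ), class = "trial_window_matrix")
}

#' @export
print.trial_window_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(paste0("trial_window_matrix: %d subjects x %d conditions x ",
                     "%d columns (%d lags x %d voxels, TR %g s)\n"),
              d[1], d[2], d[3], x$lag_count, length(x$mask_idx), x$tr_s))
  invisible(x)
}

# resolve a seed specification to in-mask voxel columns
resolve_seed <- function(windows, seed_spec, radius = 1) {
  grid_shape <- windows$grid_shape
  if (is.numeric(seed_spec) && length(seed_spec) == 3)
    seed_spec <- list(mni = seed_spec)
  if (!is.null(seed_spec$mni)) {
    ijk0 <- solve(windows$affine, c(seed_spec$mni, 1))[1:3]
    ijk <- round(ijk0) + 1L                    # affine applies to 0-based
  } else if (!is.null(seed_spec$voxel)) {
    ijk <- as.integer(seed_spec$voxel)
  } else stop("seed_spec must provide $mni or $voxel")
  if (any(ijk < 1) || any(ijk > grid_shape))
    stop(sprintf(paste0("seed voxel (%s) [MNI %s mm] falls outside the ",
                        "volume grid %s"),
                 paste(ijk, collapse = ", "),
                 paste(round(as.numeric(
                   windows$affine %*% c(ijk - 1, 1))[1:3], 1),
                   collapse = ", "),
                 paste(grid_shape, collapse = "x")))
  offs <- as.matrix(expand.grid(i = -radius:radius, j = -radius:radius,
                                k = -radius:radius))
  cand <- sweep(offs, 2, ijk, `+`)
  ok <- cand[, 1] >= 1 & cand[, 1] <= grid_shape[1] &
    cand[, 2] >= 1 & cand[, 2] <= grid_shape[2] &
    cand[, 3] >= 1 & cand[, 3] <= grid_shape[3]
  seed_vox <- intersect(ijk_to_index(cand[ok, , drop = FALSE], grid_shape),
                        windows$mask_idx)
  if (!length(seed_vox))
    stop(sprintf("seed voxel (%s) [MNI %s mm] lies outside the brain mask",
                 paste(ijk, collapse = ", "),
                 paste(round(as.numeric(
                   windows$affine %*% c(ijk - 1, 1))[1:3], 1),
                   collapse = ", ")))
  seed_vox
}

#' Window-averaged seed-region signal per subject and condition
#'
#' Averages the datamat over the seed voxel set and over all lags. The
#' seed set is the voxel containing the given MNI coordinate plus its
#' neighbours within a cube of the given radius (default 1, i.e. the
#' centre voxel and its 26-neighbourhood), intersected with the mask.
#'
#' @param windows A `trial_window_matrix`.
#' @param seed_spec MNI mm coordinate (length-3 numeric, or
#'   `list(mni = ...)`), or a 1-based voxel index `list(voxel = c(i,j,k))`.
#' @param radius Chebyshev radius of the seed cube in voxels (default 1).
#' @return Matrix subjects x conditions of seed means (percent signal
#'   change), with the resolved voxel set in `attr(, "seed_voxels")`.
#' @export
extract_seed_signal <- function(windows, seed_spec, radius = 1) {
  stopifnot(inherits(windows, "trial_window_matrix"))
  seed_vox <- resolve_seed(windows, seed_spec, radius)
  cols <- which(windows$col_voxel %in% seed_vox)
  out <- apply(windows$values[, , cols, drop = FALSE], c(1, 2), mean)
  dimnames(out) <- list(windows$subjects, windows$conditions)
  structure(out, seed_voxels = seed_vox)
}

#' Mean accurate reaction time per subject and condition
#'
#' Averages reaction times over trials with `accuracy == 1` and a recorded
#' RT, per subject and condition. A subject x condition cell with no
#' accurate trial is returned as `NA` and flagged in
#' `attr(, "flagged")` — flagged, never silently imputed.
#'
#' @param events Named list of event data frames.
#' @param conditions Condition labels (default: sorted union over the
#'   first table).
#' @return Matrix subjects x conditions of mean accurate RTs (ms).
#' @export
compute_condition_rt <- function(events, conditions = NULL) {
  stopifnot(is.list(events), !is.null(names(events)))
  if (is.null(conditions))
    conditions <- sort(unique(events[[1]]$condition))
  subjects <- names(events)
  out <- matrix(NA_real_, length(subjects), length(conditions),
                dimnames = list(subjects, conditions))
  flagged <- list()
  for (s in subjects) {
    ev <- events[[s]]
    if (!all(c("accuracy", "rt") %in% names(ev)))
      stop("event table of subject ", s, " lacks accuracy/rt fields")
    for (cc in conditions) {
      ok <- ev$condition == cc & ev$accuracy == 1 & !is.na(ev$rt)
      if (!any(ok)) {
        flagged[[length(flagged) + 1]] <-
          data.frame(subject = s, condition = cc)
      } else {
        out[s, cc] <- mean(ev$rt[ok])
      }
    }
  }
  structure(out, flagged = if (length(flagged))
    do.call(rbind, flagged) else NULL)
}

#' Assemble the functional/structural/behavioural variable block
#'
#' Inner-joins the seed means, FA table and RT table on subject ID.
#' Subjects missing any required FA tract, or flagged with an empty
#' accurate-RT cell, are dropped listwise and reported. FA values are
#' condition-invariant and replicated across conditions.
#'
#' @param seed_mean Matrix subjects x conditions from
#'   [extract_seed_signal()].
#' @param fa_table Data frame (`subject_id`, `tract`, `fa`).
#' @param rt_table Matrix subjects x conditions from
#'   [compute_condition_rt()].
#' @param tracts Required tract names (default: all tracts present).
#' @param variable_order Variable names in row order; default
#'   `c("seed", paste0("fa_", tracts), "rt")`.
#' @return An object of class `variable_block`: `values` (3D array
#'   subjects x conditions x variables), `variable_order`, `conditions`,
#'   `subjects`, `dropped` (data frame of dropped subjects with reasons).
#' @export
assemble_variable_block <- function(seed_mean, fa_table, rt_table,
                                    tracts = NULL, variable_order = NULL) {
  subj_seed <- rownames(seed_mean)
  subj_rt <- rownames(rt_table)
  if (is.null(tracts)) tracts <- unique(fa_table$tract)
  conditions <- colnames(seed_mean)
  if (!identical(conditions, colnames(rt_table)))
    stop("seed and RT tables disagree on conditions")

  fa_wide <- lapply(tracts, function(tr) {
    sub <- fa_table[fa_table$tract == tr, ]
    setNames(sub$fa, sub$subject_id)
  })
  names(fa_wide) <- tracts

  common <- intersect(subj_seed, subj_rt)
  for (tr in tracts) common <- intersect(common, names(fa_wide[[tr]]))
  if (!length(common))
    stop("no subjects shared across inputs; seed IDs: ",
         paste(head(subj_seed, 3), collapse = ", "),
         " ... FA IDs: ",
         paste(head(unique(fa_table$subject_id), 3), collapse = ", "))

  dropped <- data.frame(subject = character(0), reason = character(0))
  fa_missing <- setdiff(subj_seed, common)
  if (length(fa_missing))
    dropped <- rbind(dropped, data.frame(
      subject = fa_missing, reason = "missing FA tract or RT table row"))
  rt_na <- common[apply(rt_table[common, , drop = FALSE], 1,
                        function(r) any(is.na(r)))]
  if (length(rt_na)) {
    dropped <- rbind(dropped, data.frame(
      subject = rt_na, reason = "no accurate trials in some condition"))
    common <- setdiff(common, rt_na)
  }
  seed_na <- common[apply(seed_mean[common, , drop = FALSE], 1,
                          function(r) any(is.na(r)))]
  if (length(seed_na)) {
    dropped <- rbind(dropped, data.frame(
      subject = seed_na, reason = "missing seed signal"))
    common <- setdiff(common, seed_na)
  }
  if (!length(common))
    stop("all subjects dropped while assembling the variable block")

  variable_order <- variable_order %||%
    c("seed", paste0("fa_", tracts), "rt")
  values <- array(NA_real_,
                  dim = c(length(common), length(conditions),
                          length(variable_order)),
                  dimnames = list(common, conditions, variable_order))
  for (v in variable_order) {
    if (v == "seed") {
      values[, , v] <- seed_mean[common, , drop = FALSE]
    } else if (startsWith(v, "fa_")) {
      tr <- sub("^fa_", "", v)
      if (!tr %in% tracts) stop("unknown tract in variable_order: ", v)
      values[, , v] <- matrix(fa_wide[[tr]][common], length(common),
                              length(conditions))
    } else if (v == "rt") {
      values[, , v] <- rt_table[common, , drop = FALSE]
    } else stop("unknown variable in variable_order: ", v)
  }
  structure(list(values = values, variable_order = variable_order,
                 conditions = conditions, subjects = common,
                 dropped = dropped),
            class = "variable_block")
}

#' @export
print.variable_block <- function(x, ...) {
  cat(sprintf("variable_block: %d subjects x %d conditions x %d variables\n",
              length(x$subjects), length(x$conditions),
              length(x$variable_order)))
  cat("  variables:", paste(x$variable_order, collapse = ", "), "\n")
  if (nrow(x$dropped))
    cat("  dropped:", paste(x$dropped$subject, collapse = ", "), "\n")
  invisible(x)
}

#' Remove outlying subjects from a variable block
#'
#' Computes z-scores of every variable across subjects, per condition for
#' condition-wise variables, and removes subjects with any |z| above the
#' threshold. A variable with zero variance yields z = 0 for all subjects
#' and a warning.
#'
#' @param block A `variable_block`.
#' @param z_threshold Removal threshold on |z| (default 3).
#' @return A list with `block` (filtered `variable_block`) and `excluded`
#'   (data frame: subject, variable, condition, z of the triggering cell).
#' @export
exclude_outliers <- function(block, z_threshold = 3) {
  stopifnot(inherits(block, "variable_block"))
  vals <- block$values
  n <- dim(vals)[1]
  if (n < 3) stop("outlier screening needs at least 3 subjects")
  excluded <- data.frame(subject = character(0), variable = character(0),
                         condition = character(0), z = numeric(0))
  drop <- rep(FALSE, n)
  zero_var <- character(0)
  for (v in seq_len(dim(vals)[3])) {
    for (c in seq_len(dim(vals)[2])) {
      x <- vals[, c, v]
      s <- sd(x)
      if (!is.finite(s) || s == 0) {
        zero_var <- c(zero_var, sprintf("%s/%s", block$variable_order[v],
                                        block$conditions[c]))
        next
      }
      z <- (x - mean(x)) / s
      hit <- which(abs(z) > z_threshold)
      for (h in hit) {
        drop[h] <- TRUE
        excluded <- rbind(excluded, data.frame(
          subject = block$subjects[h],
          variable = block$variable_order[v],
          condition = block$conditions[c], z = z[h]))
      }
    }
  }
  if (length(zero_var))
    warning("zero variance (z-scores treated as 0) in: ",
            paste(zero_var, collapse = ", "))
  if (sum(!drop) < 3)
    stop("outlier removal would leave fewer than 3 subjects")
  out <- block
  out$values <- vals[!drop, , , drop = FALSE]
  out$subjects <- block$subjects[!drop]
  list(block = out, excluded = excluded)
}

#' Persist a datamat and variable block as an archived intermediate
#'
#' Writes the extracted trial-window datamat and the assembled variable
#' block to a directory together with a JSON manifest (subjects,
#' conditions, lag count, column geometry summary and a content hash), so
#' expensive extraction runs once per dataset.
#'
#' @param windows A `trial_window_matrix`.
#' @param variables A `variable_block` over the same subjects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_datamat <- function(windows, variables, dir) {
  stopifnot(inherits(windows, "trial_window_matrix"),
            inherits(variables, "variable_block"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(windows, file.path(dir, "datamat.rds"))
  saveRDS(variables, file.path(dir, "variables.rds"))
  manifest <- list(
    subjects = windows$subjects, conditions = windows$conditions,
    lag_count = windows$lag_count, n_voxels = length(windows$mask_idx),
    variable_order = variables$variable_order,
    grid_shape = windows$grid_shape,
    mask_hash = object_hash(windows$mask_idx))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a datamat archive written by [write_datamat()]
#'
#' @param dir Archive directory.
#' @return A list with `datamat`, `variables` and `manifest`.
#' @export
read_datamat <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  windows <- readRDS(file.path(dir, "datamat.rds"))
  variables <- readRDS(file.path(dir, "variables.rds"))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$lag_count),
                 as.integer(windows$lag_count)))
    stop("manifest and archive disagree on lag_count")
  list(datamat = windows, variables = variables, manifest = manifest)
}

#' Drop voxels from a trial-window datamat
#'
#' Removes all lag columns of the given voxels. Used to exclude the seed
#' region itself from the brain block: the seed variable is the average
#' of those very columns, so leaving them in couples the blocks through
#' shared scan noise even in the absence of any signal (the analysis
#' correlates the seed with all *other* brain regions).
#'
#' @param windows A `trial_window_matrix`.
#' @param voxels Linear grid indices of voxels to remove.
#' @return A `trial_window_matrix` without those voxels' columns.
#' @export
exclude_voxels <- function(windows, voxels) {
  stopifnot(inherits(windows, "trial_window_matrix"))
  keep <- !(windows$col_voxel %in% voxels)
  if (all(keep)) return(windows)
  windows$values <- windows$values[, , keep, drop = FALSE]
  windows$col_lag <- windows$col_lag[keep]
  windows$col_voxel <- windows$col_voxel[keep]
  windows$mask_idx <- setdiff(windows$mask_idx, voxels)
  windows$voxel_ijk <- index_to_ijk(windows$mask_idx, windows$grid_shape)
  windows
}

#' Restrict a trial-window datamat to a subject subset
#'
#' Keeps the datamat aligned with a variable block after joins and
#' exclusions.
#'
#' @param windows A `trial_window_matrix`.
#' @param subjects Character vector of subject IDs to keep, in order.
#' @return A `trial_window_matrix` over `subjects`.
#' @export
subset_subjects <- function(windows, subjects) {
  stopifnot(inherits(windows, "trial_window_matrix"))
  miss <- setdiff(subjects, windows$subjects)
  if (length(miss))
    stop("subjects absent from the datamat: ", paste(miss, collapse = ", "))
  windows$values <- windows$values[subjects, , , drop = FALSE]
  windows$subjects <- subjects
  windows
}
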