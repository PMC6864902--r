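# Cluster-thresholded reporting of bootstrap-ratio maps: 3D connected
# components per lag, peak tables in MNI millimetres, and the per-LV
# report document.

#' Label 3D connected components
#'
#' Labels the connected components of a 3D logical array under 6- or
#' 26-connectivity using an iterative frontier flood fill (vectorised over
#' the frontier, so large components are cheap).
#'
#' @param x 3D logical (or 0/1) array.
#' @param connectivity 6 (faces) or 26 (faces, edges and corners;
#'   default 26, the common convention in neuroimaging cluster reporting).
#' @return Integer array of the same shape; 0 outside components, labels
#'   1..n inside, numbered in order of their smallest linear index.
#' @export
label_clusters <- function(x, connectivity = 26) {
  if (length(dim(x)) != 3) stop("x must be a 3D array")
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26")
  d <- dim(x)
  # pad with FALSE so neighbour offsets never wrap across faces
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.logical(x)
  if (connectivity == 6) {
    offs_ijk <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    offs_ijk <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs_ijk <- offs_ijk[rowSums(abs(offs_ijk)) > 0, ]
  }
  offs <- offs_ijk[, 1] + offs_ijk[, 2] * dp[1] +
    offs_ijk[, 3] * dp[1] * dp[2]
  labels <- integer(prod(dp))
  active <- which(pad)
  remaining <- logical(prod(dp))
  remaining[active] <- TRUE
  lab <- 0L
  for (s in active) {
    if (!remaining[s]) next
    lab <- lab + 1L
    frontier <- s
    remaining[s] <- FALSE
    labels[s] <- lab
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[remaining[nb]]
      labels[nb] <- lab
      remaining[nb] <- FALSE
      frontier <- nb
    }
  }
  out <- array(labels, dp)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  array(as.integer(out), d)
}

#' Voxel indices to MNI millimetre coordinates
#'
#' Applies the NIfTI affine to 0-based voxel indices; this package stores
#' voxel indices 1-based (R arrays), so the affine is applied to
#' `ijk - 1`.
#'
#' @param ijk Integer vector of length 3, or an n x 3 matrix (1-based).
#' @param affine 4x4 voxel-to-world matrix.
#' @return Numeric vector or n x 3 matrix of mm coordinates.
#' @export
voxel_to_mni <- function(ijk, affine) {
  m <- matrix(as.numeric(ijk), ncol = 3)
  out <- t(affine %*% rbind(t(m) - 1, 1))[, 1:3, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  if (is.null(dim(ijk)) && length(ijk) == 3) out[1, ] else out
}

#' MNI millimetre coordinates to (1-based) voxel indices
#'
#' @param xyz Numeric vector of length 3, or an n x 3 matrix of mm
#'   coordinates.
#' @param affine 4x4 voxel-to-world matrix (invertible).
#' @return Integer voxel indices (rounded), 1-based.
#' @export
mni_to_voxel <- function(xyz, affine) {
  m <- matrix(as.numeric(xyz), ncol = 3)
  out <- t(solve(affine) %*% rbind(t(m), 1))[, 1:3, drop = FALSE] + 1
  out <- round(out)
  colnames(out) <- c("i", "j", "k")
  if (is.null(dim(xyz)) && length(xyz) == 3) as.integer(out[1, ]) else
    matrix(as.integer(out), ncol = 3, dimnames = list(NULL, c("i", "j", "k")))
}

#' Threshold a bootstrap-ratio map into cluster peaks
#'
#' Binarises the BSR map at `|BSR| >= threshold`, separately for the
#' positive and negative salience poles, labels 3D connected components
#' within each lag, discards clusters smaller than `min_cluster` voxels,
#' and returns one peak (the maximum-|BSR| voxel) per surviving cluster.
#' Peaks are sorted positive pole first, then posterior-to-anterior
#' (ascending MNI y), ties broken by descending |BSR|. Cells whose BSR is
#' `NA` (zero bootstrap SE) are excluded.
#'
#' @param bsr Numeric vector of bootstrap ratios over the datamat columns
#'   (lags x voxels), or a `bootstrap_result` (column `lv` of its `bsr`).
#' @param geometry An object carrying the column geometry (`col_lag`,
#'   `col_voxel`, `grid_shape`, `affine`, `mask_idx`): a
#'   `trial_window_matrix`, `stacked_corr` or `bootstrap_result`. Defaults
#'   to `bsr` itself when that is a `bootstrap_result`.
#' @param threshold BSR threshold (default 3.0, approximating p < 0.001).
#' @param min_cluster Minimum cluster extent in voxels, counted within one
#'   lag map (default 100).
#' @param connectivity 6 or 26 (default 26).
#' @param lv LV number when `bsr` is a `bootstrap_result`.
#' @return Data frame with one row per cluster peak: `sign`, `lag`,
#'   `i`, `j`, `k`, `x`, `y`, `z`, `bsr`, `voxels`; the member voxel
#'   indices of each cluster are in `attr(, "cluster_voxels")` (a list
#'   aligned with the rows). Empty (zero-row) when nothing survives.
#' @export
threshold_bsr <- function(bsr, geometry = NULL, threshold = 3,
                          min_cluster = 100, connectivity = 26, lv = 1) {
  if (inherits(bsr, "bootstrap_result")) {
    if (is.null(geometry)) geometry <- bsr
    bsr <- bsr$bsr[, lv]
  }
  if (is.null(geometry))
    stop("geometry (column lag/voxel mapping, grid, affine) is required")
  if (threshold <= 0) stop("threshold must be positive")
  if (min_cluster < 1) stop("min_cluster must be >= 1")
  stopifnot(length(bsr) == length(geometry$col_lag))
  grid_shape <- geometry$grid_shape
  peaks <- list()
  members <- list()
  for (lag in sort(unique(geometry$col_lag))) {
    in_lag <- geometry$col_lag == lag
    vox <- geometry$col_voxel[in_lag]
    val <- bsr[in_lag]
    for (pole in c("positive", "negative")) {
      hit <- if (pole == "positive") !is.na(val) & val >= threshold else
        !is.na(val) & val <= -threshold
      if (!any(hit)) next
      vol <- array(FALSE, grid_shape)
      vol[vox[hit]] <- TRUE
      labs <- label_clusters(vol, connectivity = connectivity)
      sizes <- tabulate(labs[labs > 0])
      bsr_vol <- array(NA_real_, grid_shape)
      bsr_vol[vox] <- val
      for (cl in which(sizes >= min_cluster)) {
        mem <- which(labs == cl)
        vb <- bsr_vol[mem]
        best <- abs(vb) == max(abs(vb))
        peak_vox <- min(mem[best])         # traversal-order invariant
        ijk <- index_to_ijk(peak_vox, grid_shape)
        mni <- voxel_to_mni(as.integer(ijk), geometry$affine)
        peaks[[length(peaks) + 1]] <- data.frame(
          sign = pole, lag = lag,
          i = ijk[1], j = ijk[2], k = ijk[3],
          x = mni[1], y = mni[2], z = mni[3],
          bsr = bsr_vol[peak_vox], voxels = sizes[cl])
        members[[length(members) + 1]] <- mem
      }
    }
  }
  if (!length(peaks))
    return(structure(
      data.frame(sign = character(0), lag = integer(0),
                 i = integer(0), j = integer(0), k = integer(0),
                 x = numeric(0), y = numeric(0), z = numeric(0),
                 bsr = numeric(0), voxels = integer(0)),
      cluster_voxels = list()))
  out <- do.call(rbind, peaks)
  ord <- order(match(out$sign, c("positive", "negative")),
               out$y, -abs(out$bsr))
  out <- out[ord, ]
  rownames(out) <- NULL
  structure(out, cluster_voxels = members[ord])
}

#' Assemble the per-LV report
#'
#' Combines, for one latent variable: the permutation p-value, percent
#' covariance, task saliences, per-(condition, variable) brain-score
#' correlations with bootstrap confidence intervals and significance
#' flags (CI excluding 0), and the thresholded cluster peak table split
#' into the positive and negative salience poles (the two ends of an LV
#' express two alternative, anti-correlated activity patterns).
#'
#' @param decomposition A `pls_decomposition`.
#' @param permutation A `permutation_result` from the same analysis.
#' @param bootstrap A `bootstrap_result` from the same analysis.
#' @param peaks Peak data frame from [threshold_bsr()] for this LV.
#' @param lv LV number (default 1).
#' @param run_id Optional analysis manifest identifier; if any input
#'   carries a differing `run_id` attribute the function stops.
#' @return An object of class `lv_report` (a nested list, JSON-ready).
#' @export
lv_report <- function(decomposition, permutation, bootstrap, peaks,
                      lv = 1, run_id = NULL) {
  ids <- c(attr(decomposition, "run_id"), attr(permutation, "run_id"),
           attr(bootstrap, "run_id"), run_id)
  if (length(unique(ids)) > 1)
    stop("inputs come from different analysis manifests: ",
         paste(unique(ids), collapse = " vs "))
  ts <- decomposition$task_salience[, lv]
  task <- data.frame(condition = decomposition$row_condition,
                     variable = decomposition$row_variable,
                     salience = ts)
  r <- bootstrap$correlation_observed[, , lv]
  lo <- bootstrap$correlation_ci_lower[, , lv]
  hi <- bootstrap$correlation_ci_upper[, , lv]
  cors <- data.frame(
    condition = rep(rownames(r), times = ncol(r)),
    variable = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), ci_lower = as.vector(lo), ci_upper = as.vector(hi))
  cors$significant <- cors$ci_lower > 0 | cors$ci_upper < 0
  structure(list(
    lv = lv,
    singular_value = decomposition$singular_values[lv],
    pct_covariance = decomposition$pct_covariance[lv],
    p_value = permutation$p_value[lv],
    task_salience = task,
    correlations = cors,
    peaks_positive = peaks[peaks$sign == "positive", , drop = FALSE],
    peaks_negative = peaks[peaks$sign == "negative", , drop = FALSE],
    run_id = if (length(ids)) ids[[1]] else NULL
  ), class = "lv_report")
}

#' @export
print.lv_report <- function(x, ...) {
  cat(sprintf("LV%d: p = %.4f, %.2f%% covariance\n",
              x$lv, x$p_value, x$pct_covariance))
  sig <- x$correlations[x$correlations$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant brain-score correlations (95% CI excludes 0):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s / %s: r = %.2f [%.2f, %.2f]\n",
                  sig$condition[i], sig$variable[i], sig$r[i],
                  sig$ci_lower[i], sig$ci_upper[i]))
  } else cat("  no significant brain-score correlations\n")
  cat(sprintf("  peaks: %d positive-pole, %d negative-pole cluster(s)\n",
              nrow(x$peaks_positive), nrow(x$peaks_negative)))
  invisible(x)
}
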