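# Resampling inference: permutation significance for latent variables,
# bootstrap estimation of salience standard errors, bootstrap ratios, and
# Procrustes alignment of resampled saliences.

# pull per-condition matrices out of the containers once; all resampling
# loops work on these
blocks_of <- function(datamat, variables) {
  n <- length(datamat$subjects)
  n_col <- dim(datamat$values)[3]
  lapply(seq_along(datamat$conditions), function(ci) {
    X <- matrix(variables$values[, ci, ], nrow = n,
                dimnames = list(NULL, variables$variable_order))
    Y <- matrix(datamat$values[, ci, ], nrow = n)
    list(X = X, Y = Y)
  })
}

# stacked correlation matrix from pre-extracted blocks, optionally with a
# per-condition permutation of the variable rows or bootstrap weights
stacked_from_blocks <- function(blocks, perm = NULL, w = NULL) {
  do.call(rbind, lapply(seq_along(blocks), function(ci) {
    X <- blocks[[ci]]$X
    if (!is.null(perm)) X <- X[perm[[ci]], , drop = FALSE]
    unclass(cor_cross(X, blocks[[ci]]$Y, w = w))
  }))
}

# singular values (and optionally vectors) of a wide matrix via its small
# Gram matrix; much faster than svd() on rows x (lags*voxels)
svd_wide <- function(R, vectors = FALSE) {
  G <- tcrossprod(R)
  e <- eigen(G, symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  if (!vectors) return(list(d = d))
  u <- e$vectors
  pos <- d > max(d) * 1e-12
  v <- matrix(0, ncol(R), length(d))
  v[, pos] <- crossprod(R, u[, pos, drop = FALSE]) %*%
    diag(1 / d[pos], sum(pos))
  list(d = d, u = u, v = v)
}

#' Permutation test of latent-variable significance
#'
#' Each permutation shuffles the subject assignment of the variable rows
#' relative to the brain rows, independently within each condition,
#' rebuilds the stacked correlation matrix and re-runs the SVD. The
#' p-value of LV \eqn{i} compares the i-th singular values without
#' re-sorting across permutations, with the add-one estimator
#' \eqn{p_i = (1 + \#\{s_i^{perm} \ge s_i^{obs}\}) / (n_{perm} + 1)},
#' which cannot return p = 0.
#'
#' @param datamat A `trial_window_matrix`.
#' @param variables A `variable_block` over the same subjects.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer RNG seed.
#' @return An object of class `permutation_result`: `p_value` per LV,
#'   `observed_singular_values`, `null_singular_values`
#'   (`n_perm` x n_LV), `n_perm`, `seed`.
#' @export
permutation_test <- function(datamat, variables, n_perm = 500, seed = 1) {
  stopifnot(inherits(datamat, "trial_window_matrix"),
            inherits(variables, "variable_block"))
  if (!identical(datamat$subjects, variables$subjects))
    stop("datamat and variable block must share the same subjects")
  n <- length(datamat$subjects)
  if (n < 4) stop("permutation test needs at least 4 subjects")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 20)
    warning("n_perm < 20: p-value resolution is coarse")

  blocks <- blocks_of(datamat, variables)
  R_obs <- suppressWarnings(stacked_from_blocks(blocks))
  if (any(is.na(R_obs)))
    stop("zero variance in a variable; cannot permute")
  obs <- svd_wide(R_obs)$d
  k <- length(obs)

  null_sv <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(p) {
      perm <- lapply(blocks, function(b) sample.int(n))
      svd_wide(suppressWarnings(stacked_from_blocks(blocks, perm = perm)))$d
    }, numeric(k)))
  })
  p <- (1 + colSums(null_sv >= matrix(obs, n_perm, k, byrow = TRUE))) /
    (n_perm + 1)
  structure(list(p_value = p, observed_singular_values = obs,
                 null_singular_values = null_sv, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d permutations\n", x$n_perm))
  k <- min(length(x$p_value), 5)
  for (i in seq_len(k))
    cat(sprintf("  LV%d: s = %.4f, p = %.4f\n", i,
                x$observed_singular_values[i], x$p_value[i]))
  if (length(x$p_value) > k) cat("  ...\n")
  invisible(x)
}

#' Orthogonal Procrustes alignment of resampled saliences
#'
#' Finds the orthogonal transform (rotation/reflection across LV axes)
#' that minimises the Frobenius distance between a resampled salience
#' matrix and the reference, and applies it. This resolves the arbitrary
#' sign and possible order swaps of SVD components across resamples. If
#' the cross-product is (numerically) rank deficient the function falls
#' back to per-LV sign alignment and records this in
#' `attr(, "fallback")`.
#'
#' @param boot_saliences Matrix (cells x LVs) of resampled saliences.
#' @param reference_saliences Matrix of the same shape; the original
#'   (unit-norm column) saliences.
#' @return The aligned salience matrix, with the transform in
#'   `attr(, "rotation")`.
#' @export
procrustes_align <- function(boot_saliences, reference_saliences) {
  B <- as.matrix(boot_saliences); R <- as.matrix(reference_saliences)
  if (!all(dim(B) == dim(R)))
    stop("salience matrices must have identical dimensions")
  M <- crossprod(B, R)
  sv <- svd(M)
  fallback <- FALSE
  if (min(sv$d) < max(sv$d, 1) * 1e-10) {
    d <- diag(M)
    Q <- diag(ifelse(d >= 0, 1, -1), ncol(B))
    fallback <- TRUE
  } else {
    Q <- sv$u %*% t(sv$v)
  }
  structure(B %*% Q, rotation = Q, fallback = fallback)
}

#' Bootstrap estimation of salience stability and correlation CIs
#'
#' Each iteration resamples subjects with replacement (the same resample
#' applied jointly to the brain and variable blocks), rebuilds the
#' stacked correlation matrix, re-runs the SVD and aligns the resampled
#' saliences to the original via [procrustes_align()]. The standard error
#' of each (lag, voxel) salience is the standard deviation of its aligned
#' values over iterations; correlation confidence intervals are the
#' 2.5/97.5 percentiles of the aligned brain-score/variable correlations
#' (percentile bootstrap). Bootstrap ratios are the original saliences
#' divided by their standard errors ([bootstrap_ratio()]).
#'
#' Draws in which any variable has zero variance within a condition are
#' redrawn (counted in `n_redrawn`); more than 20\% redraws is an error.
#'
#' @param datamat A `trial_window_matrix`.
#' @param variables A `variable_block` over the same subjects.
#' @param n_boot Number of bootstrap iterations (default 100, as commonly
#'   printed; >= 1000 is recommended for stable percentile CIs).
#' @param seed Integer RNG seed.
#' @param n_lv Number of latent variables to track (default: all).
#' @param align `"procrustes"` (default) or `"sign"` (per-LV sign
#'   alignment only).
#' @param ci_level Confidence level for the percentile intervals
#'   (default 0.95).
#' @return An object of class `bootstrap_result`: `salience_se`
#'   (cells x LVs), `bsr` (cells x LVs), `correlation_ci_lower`/`_upper`
#'   (conditions x variables x LVs), `correlation_observed`, `n_boot`,
#'   `n_redrawn`, plus column geometry.
#' @export
bootstrap_saliences <- function(datamat, variables, n_boot = 100, seed = 1,
                                n_lv = NULL, align = c("procrustes", "sign"),
                                ci_level = 0.95) {
  stopifnot(inherits(datamat, "trial_window_matrix"),
            inherits(variables, "variable_block"))
  align <- match.arg(align)
  if (!identical(datamat$subjects, variables$subjects))
    stop("datamat and variable block must share the same subjects")
  if (n_boot < 2) stop("n_boot must be >= 2")
  n <- length(datamat$subjects)
  conditions <- datamat$conditions
  vars <- variables$variable_order

  blocks <- blocks_of(datamat, variables)
  R_obs <- suppressWarnings(stacked_from_blocks(blocks))
  dec <- svd_wide(R_obs, vectors = TRUE)
  k_all <- length(dec$d)
  k <- if (is.null(n_lv)) k_all else min(n_lv, k_all)
  # reference with pinned signs, matching svd_decompose()
  u_ref <- dec$u[, seq_len(k), drop = FALSE]
  v_ref <- dec$v[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    j <- which.max(abs(u_ref[, i]))
    if (u_ref[j, i] < 0) {
      u_ref[, i] <- -u_ref[, i]; v_ref[, i] <- -v_ref[, i]
    }
  }
  p_cells <- nrow(v_ref)

  cor_obs <- array(NA_real_, c(length(conditions), length(vars), k),
                   dimnames = list(conditions, vars, NULL))
  for (ci in seq_along(conditions)) {
    sc <- blocks[[ci]]$Y %*% v_ref
    cor_obs[ci, , ] <- suppressWarnings(
      t(unclass(cor_cross(sc, blocks[[ci]]$X))))
  }

  s1 <- matrix(0, p_cells, k)
  s2 <- matrix(0, p_cells, k)
  cor_draws <- array(NA_real_, c(n_boot, length(conditions),
                                 length(vars), k))
  n_redrawn <- 0
  max_redraw <- ceiling(0.2 * n_boot)

  with_seed(seed, {
    b <- 1
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      w <- tabulate(idx, n)
      ok <- all(vapply(blocks, function(bl) {
        all(apply(bl$X, 2, function(x) {
          m <- sum(w * x) / n
          sum(w * (x - m)^2) > 1e-12
        }))
      }, logical(1)))
      if (!ok) {
        n_redrawn <- n_redrawn + 1
        if (n_redrawn > max_redraw)
          stop("more than 20% of bootstrap draws had zero-variance ",
               "variables; sample too small or variable degenerate")
        next
      }
      R_b <- suppressWarnings(stacked_from_blocks(blocks, w = w))
      dec_b <- svd_wide(R_b, vectors = TRUE)
      v_b <- dec_b$v[, seq_len(k), drop = FALSE]
      if (align == "procrustes") {
        v_a <- procrustes_align(v_b, v_ref)
        Q <- attr(v_a, "rotation")
      } else {
        signs <- sign(colSums(v_b * v_ref))
        signs[signs == 0] <- 1
        Q <- diag(signs, k)
        v_a <- v_b %*% Q
      }
      s1 <- s1 + v_a
      s2 <- s2 + v_a^2
      for (ci in seq_along(conditions)) {
        Xb <- blocks[[ci]]$X[idx, , drop = FALSE]
        # project first, then resample rows: (Y[idx,] %*% v) == (Y %*% v)[idx,]
        sc <- (blocks[[ci]]$Y %*% v_a)[idx, , drop = FALSE]
        cor_draws[b, ci, , ] <- suppressWarnings(
          t(unclass(cor_cross(sc, Xb))))
      }
      b <- b + 1
    }
  })

  se <- sqrt(pmax((s2 - s1^2 / n_boot) / (n_boot - 1), 0))
  alpha <- (1 - ci_level) / 2
  ci_lo <- apply(cor_draws, c(2, 3, 4), quantile, probs = alpha,
                 na.rm = TRUE, names = FALSE)
  ci_hi <- apply(cor_draws, c(2, 3, 4), quantile, probs = 1 - alpha,
                 na.rm = TRUE, names = FALSE)
  dimnames(ci_lo) <- dimnames(ci_hi) <- dimnames(cor_obs)

  structure(list(
    salience_se = se,
    bsr = bootstrap_ratio(v_ref, se),
    original_salience = v_ref,
    correlation_observed = cor_obs,
    correlation_ci_lower = ci_lo,
    correlation_ci_upper = ci_hi,
    n_boot = n_boot, n_redrawn = n_redrawn, n_lv = k,
    ci_level = ci_level, seed = as.integer(seed),
    conditions = conditions, variables = vars,
    col_lag = datamat$col_lag, col_voxel = datamat$col_voxel,
    grid_shape = datamat$grid_shape, affine = datamat$affine,
    mask_idx = datamat$mask_idx, lag_count = datamat$lag_count
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("bootstrap_result: %d iterations, %d LV(s) tracked, ",
                     "%d redraw(s)\n"), x$n_boot, x$n_lv, x$n_redrawn))
  invisible(x)
}

#' Bootstrap ratios
#'
#' Elementwise ratio of the original saliences to their bootstrapped
#' standard errors. Cells with SE = 0 (no sampling variability) are
#' returned as `NA` and counted in `attr(, "n_unstable")`; they are
#' excluded from thresholding rather than reported as infinite.
#'
#' @param original_salience Numeric vector/matrix of saliences.
#' @param salience_se Matching non-negative standard errors.
#' @return Bootstrap ratio array of the same shape.
#' @export
bootstrap_ratio <- function(original_salience, salience_se) {
  if (!all(dim(as.matrix(original_salience)) ==
           dim(as.matrix(salience_se))))
    stop("salience and SE shapes do not match")
  if (any(salience_se < 0, na.rm = TRUE))
    stop("negative standard error: internal invariant violated")
  bsr <- original_salience / salience_se
  unstable <- salience_se == 0
  bsr[unstable & original_salience != 0] <- NA_real_
  bsr[unstable & original_salience == 0] <- 0
  structure(bsr, n_unstable = sum(unstable & original_salience != 0))
}
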