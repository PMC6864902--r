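# Core behavioural/seed PLS: the stacked condition-wise correlation matrix,
# its singular value decomposition, percent covariance, brain scores, and
# brain-score/variable correlations.

#' Build the stacked condition-wise correlation matrix
#'
#' For each condition `c` and variable `v`, row `(c, v)` holds the Pearson
#' correlation, across subjects, between the variable's values in
#' condition `c` and every (lag, voxel) datamat column in condition `c`.
#' Rows are stacked condition-major (all variables of condition 1, then
#' condition 2, ...). Although often called a covariance matrix, the
#' entries are Pearson correlations — the convention of behavioural PLS.
#'
#' Voxel-lag columns with zero variance within a condition are set to
#' r = 0 with a warning; a *variable* with zero variance within a
#' condition is an error.
#'
#' @param datamat A `trial_window_matrix`.
#' @param variables A `variable_block` over the same subjects, same order.
#' @return An object of class `stacked_corr`: `values` (rows =
#'   conditions x variables, columns = lags x voxels), `row_condition`,
#'   `row_variable`, plus the column geometry inherited from the datamat.
#' @export
build_stacked_correlation_matrix <- function(datamat, variables) {
  stopifnot(inherits(datamat, "trial_window_matrix"),
            inherits(variables, "variable_block"))
  if (!identical(datamat$subjects, variables$subjects))
    stop("datamat and variable block must share the same subjects ",
         "in the same order (see subset_subjects())")
  if (!identical(datamat$conditions, variables$conditions))
    stop("datamat and variable block disagree on conditions")
  n <- length(datamat$subjects)
  if (n < 3) stop("at least 3 subjects are required")
  conditions <- datamat$conditions
  vars <- variables$variable_order
  n_col <- dim(datamat$values)[3]
  R <- matrix(NA_real_, length(conditions) * length(vars), n_col)
  row_condition <- character(nrow(R))
  row_variable <- character(nrow(R))
  n_zero <- 0
  ri <- 1
  for (ci in seq_along(conditions)) {
    Y <- datamat$values[, ci, ]
    X <- variables$values[, ci, , drop = TRUE]
    X <- matrix(X, nrow = n, dimnames = list(NULL, vars))
    rc <- cor_cross(X, Y)
    bad <- which(is.na(rc[, 1]))
    if (length(bad))
      stop(sprintf("zero variance in variable %s within condition %s",
                   vars[bad[1]], conditions[ci]))
    n_zero <- n_zero + attr(rc, "n_zero_var")
    rows <- ri:(ri + length(vars) - 1)
    R[rows, ] <- rc
    row_condition[rows] <- conditions[ci]
    row_variable[rows] <- vars
    ri <- ri + length(vars)
  }
  if (n_zero > 0)
    warning(n_zero, " zero-variance voxel column(s) set to r = 0")
  structure(list(values = R, row_condition = row_condition,
                 row_variable = row_variable,
                 conditions = conditions, variables = vars,
                 col_lag = datamat$col_lag, col_voxel = datamat$col_voxel,
                 grid_shape = datamat$grid_shape, affine = datamat$affine,
                 mask_idx = datamat$mask_idx, lag_count = datamat$lag_count,
                 n_subjects = n),
            class = "stacked_corr")
}

#' @export
print.stacked_corr <- function(x, ...) {
  cat(sprintf(paste0("stacked_corr: %d rows (%d conditions x %d variables)",
                     " x %d voxel-lag columns, n = %d subjects\n"),
              nrow(x$values), length(x$conditions), length(x$variables),
              ncol(x$values), x$n_subjects))
  invisible(x)
}

#' Singular value decomposition into latent variables
#'
#' Decomposes the stacked correlation matrix `R = U diag(s) V'`. Each
#' latent variable (LV) pairs a task salience (column of `U`, one weight
#' per condition x variable cell) with a voxel salience (column of `V`,
#' one weight per lag x voxel cell) and a singular value. LVs are ordered
#' by descending singular value. The sign of each LV is fixed so that its
#' maximum-absolute task-salience entry is positive (the SVD sign is
#' arbitrary; pinning it makes resampling and reports reproducible).
#'
#' @param R A `stacked_corr`, or a bare numeric matrix.
#' @return An object of class `pls_decomposition`: `singular_values`,
#'   `task_salience` (rows x LVs), `voxel_salience` (columns x LVs),
#'   `pct_covariance`, row/column labels and geometry when available.
#' @export
svd_decompose <- function(R) {
  geom <- NULL
  if (inherits(R, "stacked_corr")) { geom <- R; R <- R$values }
  R <- as.matrix(R)
  if (!all(is.finite(R)))
    stop("correlation matrix contains non-finite entries")
  dec <- svd(R)
  if (max(dec$d) <= .Machine$double.eps * max(dim(R)))
    stop("degenerate matrix: all singular values are zero")
  k <- min(dim(R))
  u <- dec$u[, seq_len(k), drop = FALSE]
  v <- dec$v[, seq_len(k), drop = FALSE]
  d <- dec$d[seq_len(k)]
  for (i in seq_len(k)) {
    j <- which.max(abs(u[, i]))
    if (u[j, i] < 0) { u[, i] <- -u[, i]; v[, i] <- -v[, i] }
  }
  structure(list(
    singular_values = d,
    task_salience = u,
    voxel_salience = v,
    pct_covariance = percent_covariance(d),
    row_condition = geom$row_condition,
    row_variable = geom$row_variable,
    conditions = geom$conditions,
    variables = geom$variables,
    col_lag = geom$col_lag, col_voxel = geom$col_voxel,
    grid_shape = geom$grid_shape, affine = geom$affine,
    mask_idx = geom$mask_idx, lag_count = geom$lag_count
  ), class = "pls_decomposition")
}

#' @export
print.pls_decomposition <- function(x, ...) {
  k <- min(length(x$singular_values), 5)
  cat(sprintf("pls_decomposition: %d latent variables\n",
              length(x$singular_values)))
  for (i in seq_len(k))
    cat(sprintf("  LV%d: singular value %.4f, %.2f%% covariance\n",
                i, x$singular_values[i], x$pct_covariance[i]))
  if (length(x$singular_values) > k) cat("  ...\n")
  invisible(x)
}

#' Percent cross-block covariance accounted for per latent variable
#'
#' Uses the squared-singular-value convention:
#' \eqn{pct_i = 100 s_i^2 / \sum_j s_j^2}. The percentages sum to 100.
#'
#' @param singular_values Non-negative numeric vector with at least one
#'   positive entry.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' percent_covariance(c(3, 4))  # 36, 64
#' @export
percent_covariance <- function(singular_values) {
  if (!is.numeric(singular_values) || !length(singular_values))
    stop("singular_values must be a non-empty numeric vector")
  if (any(singular_values < 0))
    stop("singular values must be non-negative")
  tot <- sum(singular_values^2)
  if (tot == 0) stop("degenerate matrix: all singular values are zero")
  100 * singular_values^2 / tot
}

#' Per-subject, per-condition brain scores
#'
#' The brain score of a subject in a condition is the dot product of the
#' subject's condition datamat row with an LV's voxel salience: the degree
#' to which the subject expresses the LV's spatiotemporal pattern.
#'
#' @param datamat A `trial_window_matrix`.
#' @param lv A `pls_decomposition` (use LV `index`) or a numeric voxel
#'   salience vector of length matching the datamat columns.
#' @param index LV number when `lv` is a decomposition (default 1).
#' @return Matrix subjects x conditions of brain scores.
#' @export
compute_brain_scores <- function(datamat, lv, index = 1) {
  stopifnot(inherits(datamat, "trial_window_matrix"))
  v <- if (inherits(lv, "pls_decomposition"))
    lv$voxel_salience[, index] else as.numeric(lv)
  n_col <- dim(datamat$values)[3]
  if (length(v) != n_col)
    stop(sprintf("voxel salience length %d does not match datamat %d",
                 length(v), n_col))
  n_s <- dim(datamat$values)[1]; n_c <- dim(datamat$values)[2]
  flat <- matrix(datamat$values, n_s * n_c, n_col)
  out <- matrix(flat %*% v, n_s, n_c,
                dimnames = list(datamat$subjects, datamat$conditions))
  out
}

#' Correlate brain scores with the variable block per condition
#'
#' Pearson correlation across subjects, within each condition, between
#' the LV brain scores and each variable. Cells with zero variance are
#' returned as `NA` and flagged in `attr(, "flagged")` rather than
#' silently set to 0.
#'
#' @param scores Matrix subjects x conditions from
#'   [compute_brain_scores()].
#' @param variables A `variable_block` over the same subjects.
#' @return Matrix conditions x variables of Pearson r.
#' @export
correlate_brain_scores <- function(scores, variables) {
  stopifnot(inherits(variables, "variable_block"))
  if (nrow(scores) != length(variables$subjects))
    stop("scores and variable block disagree on subjects")
  if (nrow(scores) < 3) stop("at least 3 subjects are required")
  conditions <- variables$conditions
  vars <- variables$variable_order
  out <- matrix(NA_real_, length(conditions), length(vars),
                dimnames = list(conditions, vars))
  flagged <- NULL
  for (ci in seq_along(conditions)) {
    for (vi in seq_along(vars)) {
      x <- scores[, ci]
      y <- variables$values[, ci, vi]
      if (sd(x) == 0 || sd(y) == 0) {
        flagged <- rbind(flagged, data.frame(condition = conditions[ci],
                                             variable = vars[vi]))
        next
      }
      out[ci, vi] <- cor(x, y)
    }
  }
  structure(out, flagged = flagged)
}
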