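# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms from the package code:
# power iteration with deflation for the SVD, a scalar breadth-first
# search for cluster labelling, and stats::cor loops for the stacked
# correlation matrix.

# top-k singular values/vectors of R by power iteration on R'R with
# deflation; independent of both svd() and eigen()
power_svd_oracle <- function(R, k = min(dim(R)), tol = 1e-12,
                             max_iter = 5000, seed = 42) {
  Rm <- as.matrix(R)
  d <- numeric(k)
  V <- matrix(0, ncol(Rm), k)
  set.seed(seed)
  deflated <- Rm
  for (i in seq_len(k)) {
    v <- rnorm(ncol(Rm))
    v <- v / sqrt(sum(v^2))
    s_old <- 0
    for (it in seq_len(max_iter)) {
      w <- crossprod(deflated, deflated %*% v)   # R'R v
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      v <- as.vector(w / nw)
      s_new <- sqrt(nw)
      if (abs(s_new - s_old) < tol * max(1, s_new)) break
      s_old <- s_new
    }
    u <- deflated %*% v
    s <- sqrt(sum(u^2))
    d[i] <- s
    V[, i] <- v
    if (s > 0) deflated <- deflated - (u / s) %*% (s * t(v))
  }
  list(d = d, v = V)
}

# scalar breadth-first-search connected-component labelling
bfs_label_oracle <- function(x, connectivity = 26) {
  d <- dim(x)
  x <- as.logical(x)
  dim(x) <- d
  if (connectivity == 6) {
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
  }
  labels <- array(0L, d)
  lab <- 0L
  for (start in which(x)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- integer(sum(x))
    queue[1] <- start
    q_head <- 1L; q_tail <- 1L
    labels[start] <- lab
    while (q_head <= q_tail) {
      cur <- queue[q_head]
      q_head <- q_head + 1L
      k0 <- (cur - 1L) %/% (d[1] * d[2])
      j0 <- ((cur - 1L) %/% d[1]) %% d[2]
      i0 <- (cur - 1L) %% d[1]
      for (o in seq_len(nrow(offs))) {
        ii <- i0 + offs[o, 1]; jj <- j0 + offs[o, 2]; kk <- k0 + offs[o, 3]
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
            kk < 0 || kk >= d[3]) next
        nb <- ii + jj * d[1] + kk * d[1] * d[2] + 1L
        if (x[nb] && labels[nb] == 0L) {
          labels[nb] <- lab
          q_tail <- q_tail + 1L
          queue[q_tail] <- nb
        }
      }
    }
  }
  labels
}

# partitions equal up to label renaming
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  act <- which(a > 0)
  if (!length(act)) return(TRUE)
  key <- paste(a[act], b[act])
  length(unique(key)) == length(unique(a[act])) &&
    length(unique(key)) == length(unique(b[act]))
}

# stacked correlation matrix via stats::cor loops (small inputs only)
naive_stacked_cor <- function(datamat, variables) {
  conditions <- datamat$conditions
  vars <- variables$variable_order
  out <- NULL
  for (cc in seq_along(conditions)) {
    for (vv in seq_along(vars)) {
      x <- variables$values[, cc, vv]
      Y <- datamat$values[, cc, ]
      r <- apply(Y, 2, function(y) {
        if (sd(y) == 0) 0 else cor(x, y)
      })
      out <- rbind(out, r)
    }
  }
  unname(out)
}

# deterministic compact contiguous voxel set: the first `size` voxels of a
# bounding cube filled in column-major order (connected under 6- and
# 26-connectivity)
grow_blob_for_test <- function(grid, size, corner = 1) {
  b <- ceiling(size^(1 / 3)) + 1
  off <- if (corner == 1) c(1, 1, 1) else grid - b
  cube <- as.matrix(expand.grid(i = off[1]:(off[1] + b - 1),
                                j = off[2]:(off[2] + b - 1),
                                k = off[3]:(off[3] + b - 1)))
  idx <- (cube[, 3] - 1) * grid[1] * grid[2] +
    (cube[, 2] - 1) * grid[1] + cube[, 1]
  as.integer(idx[seq_len(size)])
}

# fabricate a trial_window_matrix directly from a values array (geometry
# for a full grid with identity-scaled affine)
fake_datamat <- function(values, lag_count, grid_shape,
                         conditions = dimnames(values)[[2]],
                         affine = NULL) {
  n_vox <- prod(grid_shape)
  stopifnot(dim(values)[3] == lag_count * n_vox)
  if (is.null(affine)) affine <- diag(4)
  structure(list(
    values = values,
    col_lag = rep(seq_len(lag_count) - 1L, each = n_vox),
    col_voxel = rep(seq_len(n_vox), lag_count),
    voxel_ijk = seedpls:::index_to_ijk(seq_len(n_vox), grid_shape),
    grid_shape = grid_shape, affine = affine, tr_s = 3,
    conditions = conditions, subjects = dimnames(values)[[1]],
    lag_count = lag_count, mask_idx = seq_len(n_vox)
  ), class = "trial_window_matrix")
}

fake_variable_block <- function(values) {
  structure(list(values = values,
                 variable_order = dimnames(values)[[3]],
                 conditions = dimnames(values)[[2]],
                 subjects = dimnames(values)[[1]],
                 dropped = data.frame(subject = character(0),
                                      reason = character(0))),
            class = "variable_block")
}
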