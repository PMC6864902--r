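# Small internal helpers shared across modules.

# linear (column-major, 1-based) index -> ijk matrix (n x 3, 1-based)
index_to_ijk <- function(idx, grid_shape) {
  idx0 <- idx - 1L
  i <- idx0 %% grid_shape[1]
  j <- (idx0 %/% grid_shape[1]) %% grid_shape[2]
  k <- idx0 %/% (grid_shape[1] * grid_shape[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

ijk_to_index <- function(ijk, grid_shape) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  as.integer((ijk[, 3] - 1L) * grid_shape[1] * grid_shape[2] +
               (ijk[, 2] - 1L) * grid_shape[1] + ijk[, 1])
}

# Fast Pearson correlation of each column of X (n x a) with each column of
# Y (n x q), optionally with integer observation weights (bootstrap
# multiplicities). Columns of Y with (weighted) zero variance yield r = 0;
# their count is returned in attr(, "n_zero_var"). Zero-variance columns of
# X yield NA (callers decide whether that is an error).
cor_cross <- function(X, Y, w = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(w)) {
    n <- nrow(X)
    sx <- colSums(X); sy <- colSums(Y)
    sxx <- colSums(X * X); syy <- colSums(Y * Y)
    sxy <- crossprod(X, Y)
  } else {
    n <- sum(w)
    wX <- X * w
    sx <- colSums(wX); sy <- crossprod(w, Y)[1, ]
    sxx <- colSums(wX * X); syy <- crossprod(w, Y * Y)[1, ]
    sxy <- crossprod(wX, Y)
  }
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  num <- sxy - outer(sx, sy) / n
  eps <- 1e-12
  vy_ok <- vy > eps * pmax(1, abs(syy))
  vx_ok <- vx > eps * pmax(1, abs(sxx))
  denom <- outer(sqrt(pmax(vx, 0)), sqrt(pmax(vy, 0)))
  r <- num / denom
  r[, !vy_ok] <- 0
  r[!vx_ok, ] <- NA_real_
  r[r > 1] <- 1
  r[r < -1] <- -1
  structure(r, n_zero_var = sum(!vy_ok))
}

# deterministic stage log used by the pipeline
stage_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# md5 of an object via its canonical JSON serialisation (base tools only)
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}
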