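# small fabricated blocks used across several tests
make_blocks <- function(n = 10, grid = c(3, 3, 3), lags = 2, seed = 1,
                        conds = c("AC", "AI", "HC", "HI"),
                        vars = c("seed", "fa_stria", "rt")) {
  set.seed(seed)
  q <- prod(grid) * lags
  dmv <- array(rnorm(n * length(conds) * q),
               dim = c(n, length(conds), q),
               dimnames = list(sprintf("s%02d", 1:n), conds, NULL))
  vbv <- array(rnorm(n * length(conds) * length(vars)),
               dim = c(n, length(conds), length(vars)),
               dimnames = list(sprintf("s%02d", 1:n), conds, vars))
  list(dm = fake_datamat(dmv, lags, grid), vb = fake_variable_block(vbv))
}

test_that("stacked correlation matrix matches a stats::cor oracle", {
  bl <- make_blocks()
  st <- build_stacked_correlation_matrix(bl$dm, bl$vb)
  expect_equal(nrow(st$values), 12)          # 4 conditions x 3 variables
  expect_true(all(abs(st$values) <= 1))
  expect_equal(st$values, naive_stacked_cor(bl$dm, bl$vb),
               tolerance = 1e-12)
  expect_identical(st$row_condition[1:3], rep("AC", 3))
  expect_identical(st$row_variable[1:3], c("seed", "fa_stria", "rt"))
})

test_that("a variable equal to a voxel-lag column correlates perfectly", {
  bl <- make_blocks()
  bl$vb$values[, , "seed"] <- bl$dm$values[, , 17]
  st <- build_stacked_correlation_matrix(bl$dm, bl$vb)
  seed_rows <- which(st$row_variable == "seed")
  expect_equal(unname(st$values[seed_rows, 17]), rep(1, 4),
               tolerance = 1e-12)
})

test_that("degenerate variance is an error for variables, r = 0 for voxels", {
  bl <- make_blocks()
  bl$vb$values[, 2, "rt"] <- 5
  expect_error(build_stacked_correlation_matrix(bl$dm, bl$vb),
               "zero variance in variable rt within condition AI")
  bl2 <- make_blocks()
  bl2$dm$values[, , 4] <- 2
  expect_warning(st <- build_stacked_correlation_matrix(bl2$dm, bl2$vb),
                 "zero-variance voxel column")
  expect_true(all(st$values[, 4] == 0))
})

test_that("null variables give correlations concentrated near zero", {
  set.seed(8)
  n <- 200
  bl <- make_blocks(n = n, grid = c(5, 5, 5), lags = 2, seed = 8)
  st <- build_stacked_correlation_matrix(bl$dm, bl$vb)
  expect_lt(abs(mean(st$values)), 0.05)
  expect_lt(max(abs(st$values)), 6 / sqrt(n))
})

test_that("SVD agrees with eigendecomposition and power-iteration oracles", {
  set.seed(3)
  R <- matrix(rnorm(12 * 500), 12, 500)
  dec <- svd_decompose(R)
  # eigenvalue oracle on R'R (nonzero spectrum)
  ev <- sort(sqrt(pmax(eigen(crossprod(R), symmetric = TRUE,
                             only.values = TRUE)$values[1:12], 0)),
             decreasing = TRUE)
  expect_equal(dec$singular_values, ev, tolerance = 1e-6)
  # power iteration + deflation, fully independent of LAPACK drivers
  R2 <- matrix(rnorm(12 * 200), 12, 200)
  d2 <- svd_decompose(R2)
  po <- power_svd_oracle(R2, k = 5)
  expect_equal(d2$singular_values[1:5], po$d, tolerance = 1e-5)
  for (i in 1:3)
    expect_gt(abs(sum(d2$voxel_salience[, i] * po$v[, i])), 1 - 1e-6)
})

test_that("decomposition satisfies orthonormality, energy and sign rules", {
  set.seed(4)
  R <- matrix(rnorm(12 * 300), 12, 300)
  dec <- svd_decompose(R)
  U <- dec$task_salience; V <- dec$voxel_salience
  expect_equal(crossprod(U), diag(12), tolerance = 1e-8)
  expect_equal(crossprod(V), diag(12), tolerance = 1e-8)
  expect_equal(sum(dec$singular_values^2), sum(R^2), tolerance = 1e-8)
  # reconstruction
  expect_equal(U %*% diag(dec$singular_values) %*% t(V), R,
               tolerance = 1e-8, ignore_attr = TRUE)
  # pinned sign: the largest-magnitude task salience entry is positive
  for (i in 1:12) expect_gt(U[which.max(abs(U[, i])), i], 0)
  # non-increasing singular values
  expect_true(all(diff(dec$singular_values) <= 1e-12))
  expect_error(svd_decompose(matrix(0, 3, 5)), "degenerate matrix")
  Rbad <- R; Rbad[1, 1] <- NaN
  expect_error(svd_decompose(Rbad), "non-finite")
})

test_that("percent covariance follows the squared-singular-value rule", {
  expect_equal(percent_covariance(c(3, 4)), c(36, 64))
  expect_equal(percent_covariance(5), 100)
  expect_equal(percent_covariance(rep(1, 4)), rep(25, 4))
  set.seed(5)
  s <- sort(abs(rnorm(7)), decreasing = TRUE)
  expect_equal(sum(percent_covariance(s)), 100, tolerance = 1e-9)
  expect_error(percent_covariance(c(0, 0)), "degenerate")
  expect_error(percent_covariance(c(-1, 2)), "non-negative")
})

test_that("noise-free planted data give a rank-1 decomposition", {
  nf <- shared_noisefree()
  dec <- svd_decompose(nf$stacked)
  expect_equal(dec$pct_covariance[1], 100, tolerance = 1e-8)
  expect_lt(dec$singular_values[2] / dec$singular_values[1], 1e-7)
})

test_that("brain scores are the datamat projection onto the salience", {
  bl <- make_blocks()
  q <- dim(bl$dm$values)[3]
  v <- rnorm(q); v <- v / sqrt(sum(v^2))
  bl$dm$values[3, 2, ] <- v                 # a row equal to the salience
  sc <- compute_brain_scores(bl$dm, v)
  expect_equal(unname(sc[3, 2]), 1, tolerance = 1e-12)
  # orthogonal row scores 0; doubling a row doubles its score
  w <- rnorm(q); w <- w - sum(w * v) / sum(v * v) * v
  bl$dm$values[4, 2, ] <- w
  sc <- compute_brain_scores(bl$dm, v)
  expect_equal(unname(sc[4, 2]), 0, tolerance = 1e-12)
  bl$dm$values[5, 1, ] <- 2 * bl$dm$values[6, 1, ]
  sc <- compute_brain_scores(bl$dm, v)
  expect_equal(unname(sc[5, 1]), 2 * unname(sc[6, 1]), tolerance = 1e-12)
  expect_error(compute_brain_scores(bl$dm, v[-1]), "does not match")
})

test_that("brain-score correlations respect labels, flags and geometry", {
  bl <- make_blocks()
  st <- build_stacked_correlation_matrix(bl$dm, bl$vb)
  dec <- svd_decompose(st)
  sc <- compute_brain_scores(bl$dm, dec, index = 1)
  r <- correlate_brain_scores(sc, bl$vb)
  expect_identical(dim(r), c(4L, 3L))
  # scores identical to a variable in one condition -> r = 1 there
  bl$vb$values[, 2, "rt"] <- sc[, 2]
  r2 <- correlate_brain_scores(sc, bl$vb)
  expect_equal(unname(r2[2, "rt"]), 1, tolerance = 1e-12)
  # zero-variance cells are flagged NA, not silently zeroed
  bl$vb$values[, 1, "seed"] <- 7
  r3 <- correlate_brain_scores(sc, bl$vb)
  expect_true(is.na(r3[1, "seed"]))
  expect_identical(attr(r3, "flagged")$variable, "seed")
  # n = 3 collinear points give |r| = 1
  sc3 <- sc[1:3, , drop = FALSE]
  vb3 <- bl$vb
  vb3$values <- bl$vb$values[1:3, , , drop = FALSE]
  vb3$subjects <- bl$vb$subjects[1:3]
  vb3$values[, 3, "rt"] <- 2 * sc3[, 3] + 1
  r4 <- correlate_brain_scores(sc3, vb3)
  expect_equal(unname(abs(r4[3, "rt"])), 1, tolerance = 1e-12)
})

test_that("in the rank-1 regime correlation profiles mirror task saliences", {
  nf <- shared_noisefree()
  dec <- svd_decompose(nf$stacked)
  sc <- compute_brain_scores(nf$dm, dec, index = 1)
  r <- correlate_brain_scores(sc, nf$vb)
  # flatten in row order (condition-major) to align with task salience
  prof <- as.vector(t(r))
  u <- dec$task_salience[, 1]
  cosine <- abs(sum(prof * u)) / (sqrt(sum(prof^2)) * sqrt(sum(u^2)))
  expect_gte(cosine, 0.99)
})
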