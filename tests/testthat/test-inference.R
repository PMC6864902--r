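test_that("permutation p-values obey the add-one estimator and contracts", {
  fx <- shared_planted()
  perm <- suppressWarnings(
    permutation_test(fx$dm_noseed, fx$vb, n_perm = 50, seed = 1))
  expect_true(all(perm$p_value >= 1 / 51))
  expect_true(all(perm$p_value <= 1))
  expect_identical(dim(perm$null_singular_values), c(50L, 12L))
  # reproducible under a fixed seed
  perm2 <- suppressWarnings(
    permutation_test(fx$dm_noseed, fx$vb, n_perm = 50, seed = 1))
  expect_identical(perm$p_value, perm2$p_value)
  expect_identical(perm$null_singular_values, perm2$null_singular_values)
  # coarse-resolution warning and the small-sample error
  expect_warning(permutation_test(fx$dm_noseed, fx$vb, n_perm = 5,
                                  seed = 1),
                 "coarse")
  dm3 <- subset_subjects(fx$dm_noseed, fx$dm_noseed$subjects[1:3])
  vb3 <- fx$vb
  vb3$values <- vb3$values[1:3, , , drop = FALSE]
  vb3$subjects <- vb3$subjects[1:3]
  expect_error(permutation_test(dm3, vb3, n_perm = 10),
               "at least 4 subjects")
})

test_that("the fast permutation path equals a naive rebuild-and-SVD", {
  bl_dm <- shared_planted()$dm_noseed
  bl_vb <- shared_planted()$vb
  n <- length(bl_dm$subjects)
  perm <- suppressWarnings(
    permutation_test(bl_dm, bl_vb, n_perm = 4, seed = 99))
  # replay the identical RNG stream and rebuild through the public API
  naive <- seedpls:::with_seed(99, {
    t(vapply(1:4, function(p) {
      orders <- lapply(seq_along(bl_dm$conditions),
                       function(ci) sample.int(n))
      vb_p <- bl_vb
      for (ci in seq_along(bl_dm$conditions))
        vb_p$values[, ci, ] <- bl_vb$values[orders[[ci]], ci, ]
      st <- suppressWarnings(
        build_stacked_correlation_matrix(bl_dm, vb_p))
      svd(st$values)$d
    }, numeric(12)))
  })
  expect_equal(perm$null_singular_values, naive, tolerance = 1e-8)
})

test_that("stronger planted coupling never weakens LV1 significance", {
  ps <- sapply(c(0, 0.4, 0.8), function(cp) {
    median(sapply(1:3, function(r) {
      tr <- make_ground_truth(grid_shape = c(10, 10, 10),
                              n_active_voxels = 120,
                              coupling_strength = cp, seed = r)
      ds <- simulate_dataset(tr, 16, 6, seed = 40 + r)
      dm <- extract_trial_windows(ds$bold, ds$events, ds$mask, 6,
                                  tr$conditions)
      sm <- extract_seed_signal(dm, ds$seed_spec)
      dm <- exclude_voxels(dm, attr(sm, "seed_voxels"))
      rt <- compute_condition_rt(ds$events, conditions = tr$conditions)
      vb <- assemble_variable_block(sm, ds$fa, rt, tracts = "stria")
      suppressWarnings(
        permutation_test(dm, vb, n_perm = 50, seed = 7))$p_value[1]
    }))
  })
  expect_true(all(diff(ps) <= 0))
})

test_that("Procrustes alignment undoes reflections and order swaps", {
  set.seed(12)
  ref <- qr.Q(qr(matrix(rnorm(40 * 2), 40, 2)))
  # pure reflection
  aligned <- procrustes_align(-ref, ref)
  expect_equal(unclass(aligned), ref, tolerance = 1e-10,
               ignore_attr = TRUE)
  # order swap: LV1 and LV2 exchanged by a permutation matrix
  P <- matrix(c(0, 1, 1, 0), 2, 2)
  aligned2 <- procrustes_align(ref %*% P, ref)
  expect_equal(unclass(aligned2), ref, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(attr(aligned2, "rotation"), P, tolerance = 1e-10)
  # fixed point
  aligned3 <- procrustes_align(ref, ref)
  expect_equal(attr(aligned3, "rotation"), diag(2), tolerance = 1e-10)
  # rank-deficient cross-product falls back to sign alignment
  ref0 <- cbind(ref[, 1], 0)
  aligned4 <- procrustes_align(cbind(-ref[, 1], 0), ref0)
  expect_true(attr(aligned4, "fallback"))
  expect_equal(aligned4[, 1], ref[, 1], tolerance = 1e-10)
  expect_error(procrustes_align(ref, ref[, 1, drop = FALSE]),
               "identical dimensions")
})

test_that("bootstrap results satisfy their structural invariants", {
  fx <- shared_planted()
  boot <- suppressWarnings(
    bootstrap_saliences(fx$dm_noseed, fx$vb, n_boot = 40, seed = 3,
                        n_lv = 2))
  expect_true(all(boot$salience_se >= 0))
  expect_true(all(boot$correlation_ci_lower <= boot$correlation_ci_upper))
  expect_true(all(is.finite(boot$bsr[boot$salience_se > 0])))
  expect_equal(boot$n_boot, 40)
  expect_equal(boot$n_lv, 2)
  # reproducibility
  boot2 <- suppressWarnings(
    bootstrap_saliences(fx$dm_noseed, fx$vb, n_boot = 40, seed = 3,
                        n_lv = 2))
  expect_identical(boot$salience_se, boot2$salience_se)
  expect_identical(boot$correlation_ci_lower, boot2$correlation_ci_lower)
  expect_error(bootstrap_saliences(fx$dm_noseed, fx$vb, n_boot = 1),
               "n_boot")
  # percentile CIs bracket the observed correlations for the lead LV
  obs <- boot$correlation_observed[, , 1]
  expect_true(mean(obs >= boot$correlation_ci_lower[, , 1] &
                     obs <= boot$correlation_ci_upper[, , 1]) > 0.9)
})

test_that("noise-free data give zero SEs and flagged bootstrap ratios", {
  nf <- shared_noisefree()
  boot <- suppressWarnings(
    bootstrap_saliences(nf$dm, nf$vb, n_boot = 20, seed = 2, n_lv = 1))
  act_cells <- abs(boot$original_salience[, 1]) > 1e-8
  expect_lt(max(boot$salience_se[act_cells, 1]), 1e-6)
  # SE exactly zero -> unstable-infinite, flagged and excluded (NA)
  zero_se <- boot$salience_se[, 1] == 0 & act_cells
  if (any(zero_se)) {
    expect_true(all(is.na(boot$bsr[zero_se, 1])))
    expect_gt(attr(boot$bsr, "n_unstable"), 0)
  }
})

test_that("bootstrap ratios divide salience by SE with guarded edges", {
  expect_equal(as.numeric(bootstrap_ratio(0.5, 0.1)), 5)
  expect_equal(as.numeric(bootstrap_ratio(0, 0.2)), 0)
  b <- bootstrap_ratio(c(0.5, 0, 0.3), c(0.1, 0.1, 0))
  expect_equal(unclass(b)[1:2], c(5, 0))
  expect_true(is.na(b[3]))
  expect_identical(attr(b, "n_unstable"), 1L)
  expect_error(bootstrap_ratio(c(1, 2), c(0.1, -0.1)), "negative")
  expect_error(bootstrap_ratio(c(1, 2), 0.1), "shapes")
})
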