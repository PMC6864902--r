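# helpers to build miniature single-voxel-of-interest volumes
mini_volume <- function(ts_list, grid = c(2, 2, 2), tr = 3) {
  # ts_list: named list voxel-linear-index -> time series; others constant 100
  n_scans <- length(ts_list[[1]])
  arr <- array(100, dim = c(grid, n_scans))
  flat <- matrix(arr, prod(grid), n_scans)
  for (nm in names(ts_list)) flat[as.integer(nm), ] <- ts_list[[nm]]
  volume_series(array(flat, dim = c(grid, n_scans)), affine = diag(4),
                tr_s = tr)
}

simple_events <- function(onset, condition = "A") {
  data.frame(onset = onset, duration = 3, condition = condition,
             accuracy = 1, rt = 1000)
}

test_that("constant series give zero percent signal change", {
  vol <- mini_volume(list(`1` = rep(100, 10)))
  ev <- simple_events(c(0, 9))
  dm <- extract_trial_windows(list(s1 = vol), list(s1 = ev),
                              array(TRUE, c(2, 2, 2)), lag_count = 3)
  expect_true(all(dm$values == 0))
})

test_that("a ramp converts to hand-computed percent signal change", {
  # onset scan value 100, then 101..105: lags are 0,1,2,3,4,5 percent
  vol <- mini_volume(list(`1` = c(100:105, rep(100, 2))))
  ev <- simple_events(0)
  dm <- extract_trial_windows(list(s1 = vol), list(s1 = ev),
                              array(TRUE, c(2, 2, 2)), lag_count = 6)
  v1_cols <- which(dm$col_voxel == 1)
  expect_equal(unname(dm$values[1, 1, v1_cols]), c(0, 1, 2, 3, 4, 5))
})

test_that("onsets map to the nearest scan at or before them", {
  # onset 3.5 s with TR 3 -> window starts at the scan covering 3 s
  vol <- mini_volume(list(`1` = c(100, 100, 110, 120, 100, 100)))
  ev <- simple_events(3.5)
  dm <- extract_trial_windows(list(s1 = vol), list(s1 = ev),
                              array(TRUE, c(2, 2, 2)), lag_count = 3)
  v1 <- dm$values[1, 1, which(dm$col_voxel == 1)]
  expect_equal(unname(v1), c(0, 10, 20))
})

test_that("datamat construction reports bad windows and conditions", {
  vol <- mini_volume(list(`1` = rep(100, 5)))
  expect_error(
    extract_trial_windows(list(s1 = vol),
                          list(s1 = simple_events(9)),
                          array(TRUE, c(2, 2, 2)), lag_count = 3),
    "overruns")
  expect_error(
    extract_trial_windows(list(s1 = vol),
                          list(s1 = simple_events(0, "A")),
                          array(TRUE, c(2, 2, 2)), lag_count = 3,
                          conditions = c("A", "B")),
    "condition B absent")
})

test_that("datamat is invariant to BOLD scaling and trial order", {
  fx <- shared_planted()
  ds <- fx$ds
  sub <- ds$subjects[1:3]
  bold <- ds$bold[sub]
  events <- ds$events[sub]
  mask <- ds$mask
  dm0 <- extract_trial_windows(bold, events, mask, 6,
                               fx$truth$conditions)
  # linearity: scaling all BOLD values leaves percent change unchanged
  bold_scaled <- lapply(bold, function(v) {
    v$data <- v$data * 2.5; v
  })
  dm1 <- extract_trial_windows(bold_scaled, events, mask, 6,
                               fx$truth$conditions)
  expect_equal(dm1$values, dm0$values, tolerance = 1e-9)
  # averaging is symmetric in trial order
  events_shuf <- lapply(events, function(ev) ev[rev(seq_len(nrow(ev))), ])
  dm2 <- extract_trial_windows(bold, events_shuf, mask, 6,
                               fx$truth$conditions)
  expect_equal(dm2$values, dm0$values, tolerance = 1e-12)
})

test_that("seed extraction averages the ROI and validates coordinates", {
  fx <- shared_planted()
  dm <- fx$dm
  # constant datamat -> seed mean equals the constant
  dm_const <- dm
  dm_const$values[] <- 1
  sm <- extract_seed_signal(dm_const, fx$ds$seed_spec)
  expect_true(all(sm == 1))
  # MNI spec resolves through the affine to the planted centre voxel
  sm2 <- extract_seed_signal(dm, list(mni = fx$ds$seed_spec$mni))
  ctr <- seedpls:::ijk_to_index(matrix(fx$truth$seed_center_ijk, ncol = 3),
                                dm$grid_shape)
  expect_true(ctr %in% attr(sm2, "seed_voxels"))
  # out-of-volume seed errors with both coordinate systems shown
  expect_error(extract_seed_signal(dm, list(mni = c(500, 0, 0))),
               "MNI")
  # planted dataset: seed mean tracks the latent score
  z <- fx$ds$latents[, , 1]
  for (ci in seq_along(fx$truth$conditions))
    expect_gt(cor(fx$seed_mean[, ci], z[, ci]), 0)
})

test_that("condition RTs average accurate trials only", {
  ev <- data.frame(onset = c(0, 10, 20), duration = 3, condition = "AC",
                   accuracy = c(1, 1, 0), rt = c(1000, 2000, 1500))
  rt <- compute_condition_rt(list(s1 = ev), conditions = "AC")
  expect_equal(unname(rt[1, 1]), 1500)
  # all trials inaccurate -> NA plus an exclusion flag, never imputed
  ev2 <- ev; ev2$accuracy <- 0; ev2$rt <- NA_real_
  rt2 <- compute_condition_rt(list(s1 = ev2), conditions = "AC")
  expect_true(is.na(rt2[1, 1]))
  expect_identical(attr(rt2, "flagged")$subject, "s1")
  # valid means respect the 3 s response ceiling
  fx <- shared_planted()
  expect_true(all(fx$rt <= 3000, na.rm = TRUE))
})

test_that("outlier screening uses per-condition z-scores", {
  mk_block <- function(vals) {
    n <- length(vals)
    v <- array(rep(vals, 4 * 2), dim = c(n, 4, 2),
               dimnames = list(sprintf("s%02d", seq_len(n)),
                               c("AC", "AI", "HC", "HI"),
                               c("seed", "rt")))
    fake_variable_block(v)
  }
  # n = 4 with one wild value: max |z| ~ 1.5, nobody removed
  res <- exclude_outliers(mk_block(c(0, 0, 0, 100)))
  expect_equal(nrow(res$excluded), 0)
  expect_length(res$block$subjects, 4)
  # zero-variance variable warns and removes nobody
  expect_warning(exclude_outliers(mk_block(rep(1, 5))), "zero variance")
  # a genuine outlier at larger n is removed with its trigger recorded
  vals <- c(rnorm(19, 0, 1), 50)
  res2 <- exclude_outliers(mk_block(vals))
  expect_identical(unique(res2$excluded$subject), "s20")
  expect_length(res2$block$subjects, 19)
  expect_true(all(abs(res2$excluded$z) > 3))
  # default threshold is |z| > 3
  expect_equal(formals(exclude_outliers)$z_threshold, 3)
  expect_error(exclude_outliers(mk_block(c(0, 0, 100)), z_threshold = 0.5),
               "fewer than 3")
})

test_that("variable-block assembly joins, drops and reports", {
  set.seed(46)
  n <- 46
  ids <- sprintf("p%02d", seq_len(n))
  conds <- c("AC", "AI", "HC", "HI")
  seed_mean <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, conds))
  rt <- matrix(1500 + rnorm(n * 4, 0, 10), n, 4,
               dimnames = list(ids, conds))
  fa <- data.frame(subject_id = rep(ids, 2),
                   tract = rep(c("stria", "ilf"), each = n),
                   fa = runif(2 * n, 0.3, 0.7))
  # eight subjects with indeterminable stria FA
  fa <- fa[!(fa$subject_id %in% ids[1:8] & fa$tract == "stria"), ]
  vb <- assemble_variable_block(seed_mean, fa, rt,
                                tracts = c("stria", "ilf"))
  expect_length(vb$subjects, 38)
  expect_identical(sort(vb$dropped$subject), ids[1:8])
  expect_identical(vb$variable_order, c("seed", "fa_stria", "fa_ilf", "rt"))
  # three outliers on top leaves 35 analysed
  vb$values[1:3, 1, 1] <- 1e6
  res <- exclude_outliers(vb)
  expect_length(res$block$subjects, 35)
  # FA is condition-invariant: replicated across condition slices
  expect_true(all(vb$values[, 1, "fa_stria"] == vb$values[, 3, "fa_stria"]))
  # one complete subject -> one row per condition
  vb1 <- assemble_variable_block(seed_mean[1, , drop = FALSE],
                                 fa[fa$subject_id == ids[1], ],
                                 rt[1, , drop = FALSE], tracts = "ilf")
  expect_equal(dim(vb1$values), c(1, 4, 3))
  # disjoint IDs error loudly
  rownames(seed_mean) <- paste0("x", ids)
  expect_error(assemble_variable_block(seed_mean, fa, rt,
                                       tracts = "ilf"),
               "no subjects shared")
})

test_that("datamat archives round-trip with a consistent manifest", {
  fx <- shared_planted()
  dir <- withr::local_tempdir()
  write_datamat(fx$dm_noseed, fx$vb, dir)
  back <- read_datamat(dir)
  expect_identical(back$datamat$values, fx$dm_noseed$values)
  expect_identical(back$variables$values, fx$vb$values)
  expect_identical(back$manifest$variable_order, fx$vb$variable_order)
  expect_error(read_datamat(file.path(dir, "nope")), "missing manifest")
})

test_that("voxel exclusion prunes columns consistently", {
  fx <- shared_planted()
  dm <- fx$dm
  drop <- dm$mask_idx[1:5]
  dm2 <- exclude_voxels(dm, drop)
  expect_equal(length(dm2$col_voxel), length(dm$col_voxel) - 5 * 6)
  expect_false(any(dm2$col_voxel %in% drop))
  expect_false(any(dm2$mask_idx %in% drop))
  expect_equal(dim(dm2$values)[3], length(dm2$col_voxel))
})
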