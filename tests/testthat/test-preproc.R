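make_run <- function(n_t = 20L, n_vox = 8L, tr_s = 2, data = NULL) {
  if (is.null(data)) data <- matrix(rnorm(n_t * n_vox), n_t)
  bold_from_series(data, dims = c(2L, 2L, 2L), tr_s = tr_s)
}

zero_motion <- function(n_t) {
  as.data.frame(matrix(0, n_t, 6,
                       dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                               "rot_x", "rot_y", "rot_z"))))
}

test_that("initial volumes are discarded jointly from BOLD and motion", {
  set.seed(1)
  bold <- make_run(200L)
  motion <- zero_motion(200L)
  out <- discard_initial(bold, motion, 10L)
  expect_equal(dim(out$bold$data)[4], 190L)
  expect_equal(nrow(out$motion), 190L)
  expect_equal(out$bold$data[, , , 1], bold$data[, , , 11])

  same <- discard_initial(bold, motion, 0L)
  expect_identical(same$bold$data, bold$data)
  expect_error(discard_initial(bold, motion, 200L), "discard")
})

test_that("framewise displacement follows the translation + arc-length formula", {
  m <- zero_motion(6L)
  expect_equal(framewise_displacement(m), rep(0, 6))

  m$trans_x[4:6] <- 0.1   # one 0.1 mm step at transition 4
  fd <- framewise_displacement(m)
  expect_equal(fd, c(0, 0, 0, 0.1, 0, 0))

  m2 <- zero_motion(4L)
  m2$rot_y[3:4] <- 0.004  # 0.004 rad at 50 mm radius -> 0.2 mm
  expect_equal(framewise_displacement(m2), c(0, 0, 0.2, 0))

  m2$rot_y[2] <- NA
  expect_error(framewise_displacement(m2), "finite")
})

test_that("scrubbing flags one back and two forward around each spike", {
  plan <- plan_scrubbing(c(0, 0, 0.25, 0, 0, 0))
  expect_equal(plan$flagged_volumes, 2:5)
  expect_equal(ncol(plan$spike_regressors), 4L)
  expect_true(all(colSums(plan$spike_regressors) == 1))

  quiet <- plan_scrubbing(rep(0.1, 10))
  expect_length(quiet$flagged_volumes, 0L)
  expect_equal(ncol(quiet$spike_regressors), 0L)

  # overlapping spikes: supra-threshold at volumes 4 and 6 flag 3..8 once
  fd <- rep(0, 10); fd[c(4, 6)] <- 0.3
  plan2 <- plan_scrubbing(fd)
  expect_equal(plan2$flagged_volumes, 3:8)
  expect_equal(ncol(plan2$spike_regressors), 6L)

  # clipping at the run start
  plan3 <- plan_scrubbing(c(0.5, 0, 0, 0))
  expect_equal(plan3$flagged_volumes, 1:3)
})

test_that("the Friston-24 expansion has the documented block structure", {
  m <- zero_motion(6L)
  expect_equal(dim(friston24(m)), c(6L, 24L))
  expect_true(all(friston24(m) == 0))

  m$trans_x <- 0:5
  f24 <- friston24(m)
  expect_equal(unname(f24[, "tx"]), 0:5)
  expect_equal(unname(f24[, "tx_lag"]), c(0, 0:4))
  expect_equal(unname(f24[, "tx_sq"]), (0:5)^2)
  expect_equal(unname(f24[, "tx_lag_sq"]), c(0, 0:4)^2)
})

test_that("nuisance regression produces residuals orthogonal to the design", {
  set.seed(2)
  n_t <- 30L
  motion <- zero_motion(n_t)
  motion[] <- rnorm(6 * n_t, sd = 0.01)
  design <- build_nuisance_design(motion)
  y <- matrix(rnorm(n_t * 8), n_t)
  y[, 1] <- design[, "tx"]            # a voxel equal to a design column
  bold <- make_run(n_t, data = y)
  mask <- array(TRUE, c(2, 2, 2))
  res <- nuisance_regression(bold, design, mask)
  resid <- bold_matrix(res, mask)
  expect_lt(max(abs(resid[, 1])), 1e-10)
  expect_lt(max(abs(crossprod(design, resid))), 1e-8)
})

test_that("intercept-only regression equals demeaning", {
  set.seed(3)
  y <- matrix(rnorm(3 * 8), 3)
  bold <- make_run(3L, data = y)
  mask <- array(TRUE, c(2, 2, 2))
  res <- nuisance_regression(bold, cbind(intercept = rep(1, 3)), mask)
  expect_equal(bold_matrix(res, mask), sweep(y, 2, colMeans(y)),
               tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected with the collinear labels", {
  design <- cbind(intercept = rep(1, 10), trend = 1:10, double_trend = 2 * (1:10))
  bold <- make_run(10L)
  expect_error(nuisance_regression(bold, design, array(TRUE, c(2, 2, 2))),
               "double_trend|trend")
})

test_that("spike regressors zero out the flagged volumes exactly", {
  set.seed(4)
  n_t <- 40L
  fd <- rep(0, n_t); fd[20] <- 0.5
  plan <- plan_scrubbing(fd)
  design <- build_nuisance_design(zero_motion(n_t), plan)
  design <- design[, colSums(design != 0) > 0, drop = FALSE]
  bold <- make_run(n_t)
  mask <- array(TRUE, c(2, 2, 2))
  res <- bold_matrix(nuisance_regression(bold, design, mask), mask)
  expect_lt(max(abs(res[plan$flagged_volumes, ])), 1e-10)
})

test_that("the ideal bandpass filter passes in-band and rejects out-of-band", {
  n_t <- 190L
  band <- band_spec(0.01, 0.08, 2)
  mask <- array(TRUE, c(2, 2, 2))

  inband <- on_bin_sinusoid(n_t, 2, 0.05)
  out <- bold_matrix(bandpass(make_run(n_t, data = matrix(inband, n_t, 8)),
                              band, mask), mask)
  expect_gt(stats::cor(out[, 1], inband), 0.999)

  fast <- on_bin_sinusoid(n_t, 2, 0.2)
  out2 <- bold_matrix(bandpass(make_run(n_t, data = matrix(fast, n_t, 8)),
                               band, mask), mask)
  expect_lt(stats::var(out2[, 1]), 1e-6 * stats::var(fast))

  flat <- make_run(n_t, data = matrix(5, n_t, 8))
  out3 <- bold_matrix(bandpass(flat, band, mask), mask)
  expect_lt(max(abs(out3)), 1e-10)
})

test_that("bandpass filtering is idempotent and flags the run as filtered", {
  set.seed(5)
  n_t <- 64L
  band <- band_spec(0.01, 0.08, 2)
  mask <- array(TRUE, c(2, 2, 2))
  bold <- make_run(n_t)
  once <- bandpass(bold, band, mask)
  twice <- bandpass(once, band, mask)
  expect_true(once$filtered)
  expect_lt(max(abs(once$data - twice$data)), 1e-10)
})

test_that("a regressed design column has no in-band energy left", {
  set.seed(6)
  n_t <- 60L
  band <- band_spec(0.01, 0.08, 2)
  mask <- array(TRUE, c(2, 2, 2))
  design <- cbind(intercept = 1, sig = rnorm(n_t))
  y <- matrix(design[, "sig"], n_t, 8) * rep(1:8, each = n_t)
  res <- nuisance_regression(make_run(n_t, data = y), design, mask)
  filt <- bold_matrix(bandpass(res, band, mask), mask)
  expect_lt(sum(filt^2), 1e-8 * sum(y^2))
})

test_that("compartment signals are in-mask means", {
  set.seed(7)
  y <- matrix(rnorm(10 * 8), 10)
  bold <- make_run(10L, data = y)
  one <- array(FALSE, c(2, 2, 2)); one[1] <- TRUE
  expect_equal(mean_compartment_signal(bold, one), y[, 1])
  two <- array(FALSE, c(2, 2, 2)); two[1:2] <- TRUE
  expect_equal(mean_compartment_signal(bold, two), (y[, 1] + y[, 2]) / 2)
  expect_error(mean_compartment_signal(bold, array(FALSE, c(2, 2, 2))),
               "empty")
})

test_that("the fused per-subject chain equals the composed operations", {
  cfg <- small_config(n_per_group = 1L, motion_spike_rate = 3)
  masks <- make_masks(cfg)
  coh <- generate_cohort(cfg, list(), seed = 31)
  s <- coh$subjects[[1]]
  band <- band_spec(tr_s = cfg$tr_s)

  pre <- preprocess_subject(s$bold, s$motion, masks, band)

  trimmed <- discard_initial(s$bold, s$motion, 10L)
  fd <- framewise_displacement(trimmed$motion)
  scrub <- plan_scrubbing(fd, threshold = 0.2)
  design <- build_nuisance_design(
    trimmed$motion, scrub,
    csf_signal = mean_compartment_signal(trimmed$bold, masks$csf),
    wm_signal = mean_compartment_signal(trimmed$bold, masks$wm))
  resid <- nuisance_regression(trimmed$bold, design, masks$brain)

  expect_equal(pre$residuals$data, resid$data, tolerance = 1e-10)
  expect_equal(pre$filtered$data, bandpass(resid, band, masks$brain)$data,
               tolerance = 1e-10)
  expect_equal(pre$scrub$flagged_volumes, scrub$flagged_volumes)
})
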