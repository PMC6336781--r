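test_that("identical configuration and seed reproduce the cohort bit for bit", {
  cfg <- small_config(n_per_group = 2L)
  ef <- list(effect_spec("amplitude", center = c(5, 5, 7), radius = 2,
                         effect_size = 2))
  a <- generate_cohort(cfg, ef, seed = 7)
  b <- generate_cohort(cfg, ef, seed = 7)
  expect_identical(a$subjects[[1]]$bold$data, b$subjects[[1]]$bold$data)
  expect_identical(a$subjects[[4]]$bold$data, b$subjects[[4]]$bold$data)
  expect_identical(a$subjects[[2]]$motion, b$subjects[[2]]$motion)
  expect_identical(a$participants, b$participants)
  c <- generate_cohort(cfg, ef, seed = 8)
  expect_false(identical(a$subjects[[1]]$bold$data, c$subjects[[1]]$bold$data))
})

test_that("tissue masks partition the brain", {
  masks <- make_masks(small_config())
  expect_identical(masks$gm | masks$wm | masks$csf, masks$brain)
  expect_false(any(masks$gm & masks$wm))
  expect_false(any(masks$gm & masks$csf))
  expect_false(any(masks$wm & masks$csf))
  expect_true(sum(masks$brain) > 0 && sum(masks$csf) > 0)
})

test_that("generated series are finite and zero outside the brain", {
  cfg <- small_config()
  masks <- make_masks(cfg)
  set.seed(1)
  bold <- generate_subject_bold(cfg, list(), "control", masks)
  expect_true(all(is.finite(bold$data)))
  outside <- bold_matrix(bold, !masks$brain)
  expect_true(all(outside == 0))
})

test_that("an effect sphere outside the brain mask is rejected by name", {
  cfg <- small_config()
  bad <- effect_spec("coherence", center = c(1, 1, 1), radius = 0.5,
                     effect_size = 0.5)
  expect_error(generate_cohort(cfg, list(bad), seed = 1), "coherence")
})

test_that("a unit amplitude effect produces no systematic group difference", {
  cfg <- small_config(n_per_group = 4L)
  masks <- make_masks(cfg)
  ef <- list(effect_spec("amplitude", center = c(5, 5, 7), radius = 2,
                         effect_size = 1))
  sphere <- effect_truth_mask(cfg, ef[[1]])
  band <- band_spec(tr_s = cfg$tr_s)
  diffs <- numeric(50)
  for (r in 1:50) {
    coh <- generate_cohort(cfg, ef, seed = 100 + r)
    means <- vapply(coh$subjects, function(s) {
      pre <- preprocess_subject(s$bold, s$motion, masks, band, filter = FALSE)
      mean(alff_map(pre$residuals, masks$brain, band)$values[sphere])
    }, numeric(1))
    grp <- vapply(coh$subjects, `[[`, "", "group") == "patient"
    diffs[r] <- mean(means[grp]) - mean(means[!grp])
  }
  pooled_diff <- mean(diffs)
  pooled_se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(pooled_diff), 2 * pooled_se + 1e-12)
})

test_that("amplitude effects scale in-band amplitude by the effect size", {
  cfg <- small_config(n_per_group = 6L, global_noise_sd = 0.05,
                      motion_spike_rate = 0)
  masks <- make_masks(cfg)
  ef <- list(effect_spec("amplitude", center = c(5, 5, 7), radius = 2,
                         effect_size = 2))
  sphere <- effect_truth_mask(cfg, ef[[1]])
  coh <- generate_cohort(cfg, ef, seed = 5)
  band <- band_spec(tr_s = cfg$tr_s)
  means <- vapply(coh$subjects, function(s) {
    pre <- preprocess_subject(s$bold, s$motion, masks, band, filter = FALSE)
    mean(alff_map(pre$residuals, masks$brain, band)$values[sphere])
  }, numeric(1))
  grp <- vapply(coh$subjects, `[[`, "", "group") == "patient"
  ratio <- mean(means[grp]) / mean(means[!grp])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("a strong coherence effect makes sphere series strongly correlated", {
  cfg <- small_config(n_per_group = 1L, n_volumes = 120L)
  masks <- make_masks(cfg)
  ef <- list(effect_spec("coherence", center = c(5, 5, 7), radius = 2,
                         effect_size = 0.9))
  coh <- generate_cohort(cfg, ef, seed = 3)
  sphere <- effect_truth_mask(cfg, ef[[1]])
  # measure on denoised series: the generator's shared CSF/WM nuisance
  # components would otherwise inflate raw within-compartment correlations
  get_mean_r <- function(s) {
    pre <- preprocess_subject(s$bold, s$motion, masks)
    cc <- stats::cor(bold_matrix(pre$filtered, sphere))
    mean(cc[upper.tri(cc)])
  }
  expect_gt(get_mean_r(coh$subjects[[1]]), 0.5)   # patient carries it
  expect_lt(get_mean_r(coh$subjects[[2]]), 0.45)  # control does not
})

test_that("hub effects correlate the hub sphere with its partner spheres", {
  cfg <- small_config(n_per_group = 1L, n_volumes = 120L)
  masks <- make_masks(cfg)
  ef <- effect_spec("hub", center = c(5, 5, 7), radius = 1.5,
                    effect_size = 0.7)
  coh <- generate_cohort(cfg, list(ef), seed = 3)
  hub <- effect_truth_mask(cfg, ef)
  partner_center <- rsmvpa:::hub_partners(ef, cfg$grid_shape)[[1]]
  partner <- sphere_mask(cfg$grid_shape, partner_center, 1.5) & masks$gm
  cross_cor <- function(s) {
    pre <- preprocess_subject(s$bold, s$motion, masks)
    mean(stats::cor(bold_matrix(pre$filtered, hub),
                    bold_matrix(pre$filtered, partner)))
  }
  expect_gt(cross_cor(coh$subjects[[1]]), 0.5)
  expect_lt(abs(cross_cor(coh$subjects[[2]])), 0.45)
})

test_that("motion traces respect the spike construction", {
  cfg_quiet <- small_config(motion_spike_rate = 0, n_volumes = 200L)
  set.seed(2)
  for (i in 1:5) {
    tr <- generate_motion_trace(cfg_quiet)
    expect_true(all(framewise_displacement(tr) < 0.2))
  }

  cfg_spiky <- small_config(motion_spike_rate = 3, n_volumes = 200L)
  set.seed(3)
  ratios <- replicate(40, {
    tr <- generate_motion_trace(cfg_spiky)
    k <- length(attr(tr, "spike_volumes"))
    if (k == 0) return(NA_real_)
    fd <- framewise_displacement(tr)
    length(plan_scrubbing(fd)$flagged_volumes) / k
  })
  ratios <- ratios[!is.na(ratios)]
  # each spike flags itself, one back and two forward (4 volumes) minus
  # boundary clipping and overlap
  expect_true(all(ratios <= 4))
  expect_gt(mean(ratios), 3.4)
})

test_that("degenerate motion requests error", {
  cfg <- small_config()
  cfg$n_volumes <- 0L
  expect_error(generate_motion_trace(cfg), "positive")
})

test_that("covariates match the cohort design", {
  cfg <- small_config(n_per_group = 10L)
  coh <- generate_cohort(cfg, seed = 9)
  p <- coh$participants
  expect_equal(nrow(p), 20L)
  expect_equal(sum(p$group == "patient"), 10L)
  pat <- p[p$group == "patient", ]
  expect_true(all(pat$ybocs_total == pat$ybocs_obsession + pat$ybocs_compulsive))
  expect_true(all(is.na(p$ybocs_total[p$group == "control"])))
  expect_true(all(p$age >= 18 & p$age <= 60))
})
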