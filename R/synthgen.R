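#' Simulation configuration for synthetic two-group BOLD cohorts
#'
#' Collects the acquisition geometry and noise model of a simulated
#' resting-state cohort. Defaults describe a desk-scale cohort: a 24^3 grid
#' of 3 mm voxels, TR = 2 s, 200 volumes per run and 20 subjects per group.
#' Larger, study-scale cohorts (e.g. 54 per group) are a configuration
#' choice, not a different code path.
#'
#' The baseline signal of every in-brain voxel is `global_noise_sd` worth of
#' white or AR(1) noise plus an independent band-limited (0.01-0.08 Hz)
#' fluctuation of standard deviation `inband_sd`; regional group effects
#' modulate that in-band component (see [effect_spec()]). Shared nuisance
#' sources emulate non-neuronal physiology: a slowly varying "CSF" signal and
#' a "WM" signal are injected into their tissue compartments and, attenuated
#' by `gm_nuisance_gain`, into gray matter; every voxel also carries a random
#' linear scanner drift. Head-motion spikes (Poisson count with mean
#' `motion_spike_rate` per run) displace the head persistently and add a
#' transient global intensity artifact of `spike_artifact_sd` signal units at
#' the affected volume.
#'
#' @param grid_shape integer 3-vector, voxels per axis.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param tr_s repetition time (s).
#' @param n_volumes volumes per run; must exceed 20 so that a usable
#'   spectrum survives discarding the first ten volumes.
#' @param n_per_group subjects per group.
#' @param noise_model `"white"` or `"ar1"` baseline voxel noise.
#' @param ar1_rho lag-one autocorrelation of AR(1) noise, in `[0, 1)`.
#' @param global_noise_sd stationary SD of the baseline noise (signal units).
#' @param inband_sd SD of each voxel's private band-limited fluctuation.
#' @param motion_spike_rate expected motion spikes per run.
#' @param baseline_mean mean signal level added to in-brain voxels.
#' @param csf_sd,wm_sd SD of the shared CSF / WM nuisance signals.
#' @param gm_nuisance_gain attenuation of CSF/WM signals leaking into GM.
#' @param drift_sd SD across voxels of the linear drift amplitude
#'   (full-run peak-to-peak excursion, signal units).
#' @param spike_artifact_sd amplitude of the global intensity artifact at
#'   motion-spike volumes.
#' @param seed integer seed stored with the configuration; identical
#'   configuration + seed reproduces a cohort bit for bit.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(24L, 24L, 24L),
                       voxel_size_mm = 3,
                       tr_s = 2,
                       n_volumes = 200L,
                       n_per_group = 20L,
                       noise_model = c("ar1", "white"),
                       ar1_rho = 0.3,
                       global_noise_sd = 1,
                       inband_sd = 1,
                       motion_spike_rate = 2,
                       baseline_mean = 1000,
                       csf_sd = 2,
                       wm_sd = 1.5,
                       gm_nuisance_gain = 0.3,
                       drift_sd = 1,
                       spike_artifact_sd = 3,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape <= 0L)) stop("grid_shape must be strictly positive")
  if (n_volumes <= 20L)
    stop("n_volumes must exceed 20 (ten discarded volumes plus a usable spectrum)")
  if (n_per_group < 1L) stop("n_per_group must be at least 1")
  if (ar1_rho < 0 || ar1_rho >= 1) stop("ar1_rho must lie in [0, 1)")
  if (global_noise_sd < 0 || inband_sd < 0) stop("noise SDs must be non-negative")
  if (motion_spike_rate < 0) stop("motion_spike_rate must be non-negative")
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
         n_volumes = as.integer(n_volumes), n_per_group = as.integer(n_per_group),
         noise_model = noise_model, ar1_rho = ar1_rho,
         global_noise_sd = global_noise_sd, inband_sd = inband_sd,
         motion_spike_rate = motion_spike_rate, baseline_mean = baseline_mean,
         csf_sd = csf_sd, wm_sd = wm_sd, gm_nuisance_gain = gm_nuisance_gain,
         drift_sd = drift_sd, spike_artifact_sd = spike_artifact_sd,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Regional group-effect specification
#'
#' Describes one spherical regional effect distinguishing the groups. An
#' effect acts on the gray-matter voxels inside its sphere (regional effects
#' model altered neural signal, which lives in gray matter). Three kinds are
#' supported, targeting the three families of parameter maps:
#'
#' * `"amplitude"`: the private in-band fluctuation of every voxel in the
#'   sphere is scaled by `effect_size` in the target group (patient/control
#'   in-band SD ratio). `effect_size = 1` is a null effect.
#' * `"coherence"`: one shared band-limited signal is added to every voxel of
#'   the sphere in the target group, sized so that it carries a fraction
#'   `effect_size` of the resulting voxel variance; the expected pairwise
#'   within-sphere correlation equals that fraction. `effect_size = 0` is a
#'   null effect.
#' * `"hub"`: one shared band-limited signal (variance share `effect_size`)
#'   is added to the sphere *and* to its long-range partner spheres, turning
#'   the region into a connectivity hub. Partners default to the reflections
#'   of `center` through the grid midpoint along each axis.
#'
#' @param kind `"amplitude"`, `"coherence"` or `"hub"`.
#' @param center numeric 3-vector, voxel coordinates of the sphere center.
#' @param radius sphere radius in voxels.
#' @param effect_size see above; unitless.
#' @param target_group `"patient"` or `"control"`.
#' @param partners for `"hub"`: list of partner-sphere centers (3-vectors),
#'   or `NULL` for the axis-reflection default.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(kind = c("amplitude", "coherence", "hub"),
                        center, radius, effect_size,
                        target_group = c("patient", "control"),
                        partners = NULL) {
  kind <- match.arg(kind)
  target_group <- match.arg(target_group)
  stopifnot(length(center) == 3L, radius > 0, is.finite(effect_size))
  if (kind == "amplitude" && effect_size < 0)
    stop("amplitude effect_size must be non-negative (an SD ratio)")
  if (kind %in% c("coherence", "hub") &&
      (effect_size < 0 || effect_size >= 1))
    stop(kind, " effect_size is a variance share and must lie in [0, 1)")
  structure(
    list(kind = kind, center = as.numeric(center), radius = radius,
         effect_size = effect_size, target_group = target_group,
         partners = partners),
    class = "effect_spec")
}

#' Tissue masks of the synthetic head
#'
#' Concentric compartments centred in the grid: a "CSF" core, a "WM" shell,
#' a "GM" rind, and their union as the brain mask. Radii scale with the grid
#' so that roughly a third of grid voxels are brain.
#'
#' @param config a [sim_config()].
#' @return named list of logical arrays: `brain`, `gm`, `wm`, `csf`.
#' @export
make_masks <- function(config) {
  d <- config$grid_shape
  ctr <- (d + 1) / 2
  r_brain <- min(d) / 2 - 1.5    # 10.5 voxels on the default 24^3 grid
  r_wm <- r_brain * 0.62
  r_csf <- r_brain * 0.29
  brain <- sphere_mask(d, ctr, r_brain)
  csf <- sphere_mask(d, ctr, r_csf)
  wm <- sphere_mask(d, ctr, r_wm) & !csf
  gm <- brain & !csf & !wm
  list(brain = brain, gm = gm, wm = wm, csf = csf)
}

# Band-limited Gaussian noise: synthesized directly on the in-band discrete
# Fourier basis with iid normal coefficients (the distribution of ideally
# bandpass-filtered white noise), each column rescaled to exactly `sd`.
band_limited_noise <- function(n_t, n_series, tr_s, low = 0.01, high = 0.08,
                               sd = 1) {
  k <- 1:(n_t %/% 2)
  k <- k[k / (n_t * tr_s) >= low & k / (n_t * tr_s) <= high]
  if (!length(k))
    stop("no frequency bins inside the band at resolution 1/(N*TR) = ",
         signif(1 / (n_t * tr_s), 3), " Hz")
  ang <- outer(0:(n_t - 1), 2 * pi * k / n_t)
  basis <- cbind(cos(ang), sin(ang))
  y <- basis %*% matrix(stats::rnorm(2 * length(k) * n_series),
                        ncol = n_series)
  s <- sqrt(colMeans(y^2) - colMeans(y)^2)
  sweep(y, 2L, ifelse(s > 0, sd / s, 0), `*`)
}

ar1_noise <- function(n_t, n_series, rho, sd) {
  e_sd <- sd * sqrt(1 - rho^2)
  x <- matrix(0, n_t, n_series)
  x[1, ] <- stats::rnorm(n_series, sd = sd)
  for (t in 2:n_t)
    x[t, ] <- rho * x[t - 1, ] + stats::rnorm(n_series, sd = e_sd)
  x
}

# Regional effects model altered *neural* signal, so they act on the
# gray-matter voxels of the sphere; this also keeps the WM/CSF nuisance
# compartments effect-free by construction.
effect_voxels <- function(effect, masks) {
  sel <- sphere_mask(dim(masks$brain), effect$center, effect$radius) & masks$gm
  if (!any(sel))
    stop(sprintf("%s effect sphere at (%s), radius %g, does not intersect gray matter",
                 effect$kind, paste(effect$center, collapse = ","), effect$radius))
  sel
}

#' Ground-truth voxel set of a regional effect
#'
#' The gray-matter voxels a given [effect_spec()] acts on (the hub sphere
#' only, for hub effects), used to score spatial recovery of injected
#' effects.
#'
#' @param config a [sim_config()].
#' @param effect an [effect_spec()].
#' @param masks optional mask list from [make_masks()].
#' @return logical 3D array.
#' @export
effect_truth_mask <- function(config, effect, masks = make_masks(config)) {
  effect_voxels(effect, masks)
}

hub_partners <- function(effect, dims) {
  if (!is.null(effect$partners)) return(effect$partners)
  ctr <- (dims + 1) / 2
  lapply(1:3, function(ax) {
    p <- effect$center
    p[ax] <- 2 * ctr[ax] - p[ax]
    p
  })
}

#' Generate one subject's synthetic BOLD run
#'
#' Assembles baseline noise, private band-limited fluctuations, regional
#' group effects, shared CSF/WM nuisance signals, per-voxel linear drift and
#' motion-spike intensity artifacts on the configured grid. Voxels outside
#' the brain mask are zero. Randomness comes from the current R RNG state;
#' seed it (or use [generate_cohort()]) for reproducibility.
#'
#' @param config a [sim_config()].
#' @param effects list of [effect_spec()] objects.
#' @param group `"patient"` or `"control"`; effects whose `target_group`
#'   differs are applied at their null value.
#' @param masks mask list from [make_masks()] (recomputed if omitted).
#' @param spike_volumes integer vector of volumes carrying a motion-spike
#'   intensity artifact (typically from [generate_motion_trace()]).
#' @return a [bold_run()].
#' @export
generate_subject_bold <- function(config, effects = list(),
                                  group = c("patient", "control"),
                                  masks = make_masks(config),
                                  spike_volumes = integer(0)) {
  group <- match.arg(group)
  d <- config$grid_shape
  n_t <- config$n_volumes
  brain_idx <- which(masks$brain)
  n_vox <- length(brain_idx)

  x <- if (config$noise_model == "white")
    matrix(stats::rnorm(n_t * n_vox, sd = config$global_noise_sd), n_t)
  else
    ar1_noise(n_t, n_vox, config$ar1_rho, config$global_noise_sd)

  # private in-band fluctuation, scaled inside amplitude-effect spheres
  inband <- band_limited_noise(n_t, n_vox, config$tr_s, sd = config$inband_sd)
  gain <- rep(1, n_vox)
  for (ef in effects) {
    if (ef$kind != "amplitude") next
    sel <- effect_voxels(ef, masks)
    if (ef$target_group == group)
      gain[match(which(sel), brain_idx)] <- ef$effect_size
  }
  x <- x + sweep(inband, 2L, gain, `*`)

  # shared regional signals for coherence and hub effects
  base_var <- config$global_noise_sd^2 + config$inband_sd^2
  for (ef in effects) {
    if (ef$kind == "amplitude") next
    sel <- effect_voxels(ef, masks)   # validate geometry for both groups
    if (ef$target_group != group || ef$effect_size == 0) next
    shared_sd <- sqrt(base_var * ef$effect_size / (1 - ef$effect_size))
    s <- band_limited_noise(n_t, 1L, config$tr_s, sd = shared_sd)[, 1L]
    targets <- sel
    if (ef$kind == "hub") {
      for (p in hub_partners(ef, d)) {
        psel <- sphere_mask(d, p, ef$radius) & masks$gm
        if (!any(psel))
          stop("hub partner sphere at (", paste(p, collapse = ","),
               ") does not intersect gray matter")
        targets <- targets | psel
      }
    }
    cols <- match(which(targets), brain_idx)
    x[, cols] <- x[, cols] + s
  }

  # shared nuisance signals: CSF and WM compartments, attenuated into GM
  csf_sig <- ar1_noise(n_t, 1L, 0.9, config$csf_sd)[, 1L]
  wm_sig <- ar1_noise(n_t, 1L, 0.9, config$wm_sd)[, 1L]
  in_csf <- masks$csf[brain_idx]
  in_wm <- masks$wm[brain_idx]
  in_gm <- masks$gm[brain_idx]
  x[, in_csf] <- x[, in_csf] + csf_sig
  x[, in_wm] <- x[, in_wm] + wm_sig
  leak <- config$gm_nuisance_gain * (csf_sig + wm_sig)
  x[, in_gm] <- x[, in_gm] + leak

  # per-voxel linear scanner drift and motion-spike intensity artifacts
  tt <- (seq_len(n_t) - (n_t + 1) / 2) / n_t
  x <- x + tt %o% stats::rnorm(n_vox, sd = config$drift_sd)
  spike_volumes <- spike_volumes[spike_volumes >= 1 & spike_volumes <= n_t]
  if (length(spike_volumes))
    x[spike_volumes, ] <- x[spike_volumes, ] + config$spike_artifact_sd
  x <- x + config$baseline_mean

  flat <- matrix(0, prod(d), n_t)
  flat[brain_idx, ] <- t(x)
  dim(flat) <- c(d, n_t)
  bold_run(flat, tr_s = config$tr_s,
           voxel_size_mm = config$voxel_size_mm, filtered = FALSE)
}

#' Generate a synthetic rigid-body motion trace
#'
#' Smooth low-amplitude drift (a clamped random walk whose per-transition
#' framewise displacement never reaches 0.2 mm) plus a Poisson number of
#' persistent head displacements ("spikes") large enough that the framewise
#' displacement at the spike transition exceeds 0.2 mm.
#'
#' @param config a [sim_config()]; uses `n_volumes` and `motion_spike_rate`.
#' @return a data frame with columns `trans_x`, `trans_y`, `trans_z` (mm) and
#'   `rot_x`, `rot_y`, `rot_z` (rad), one row per volume, with the spike
#'   volumes in attribute `"spike_volumes"`.
#' @export
generate_motion_trace <- function(config) {
  n_t <- config$n_volumes
  if (n_t < 1L) stop("n_volumes must be positive")
  steps <- cbind(matrix(stats::rnorm(3 * n_t, sd = 0.01), ncol = 3),
                 matrix(stats::rnorm(3 * n_t, sd = 2e-4), ncol = 3))
  steps[1, ] <- 0
  # clamp drift so its own FD stays strictly below the 0.2 mm threshold
  fd_step <- rowSums(abs(steps[, 1:3, drop = FALSE])) +
    50 * rowSums(abs(steps[, 4:6, drop = FALSE]))
  over <- fd_step > 0.15
  steps[over, ] <- steps[over, ] * (0.15 / fd_step[over])

  n_spikes <- stats::rpois(1L, config$motion_spike_rate)
  spike_volumes <- integer(0)
  if (n_spikes > 0 && n_t >= 3L) {
    spike_volumes <- sort(sample(2:(n_t - 1L), min(n_spikes, n_t - 2L)))
    for (v in spike_volumes) {
      ax <- sample(3L, 1L)
      steps[v, ax] <- steps[v, ax] +
        sample(c(-1, 1), 1L) * stats::runif(1L, 0.4, 0.8)
    }
  }
  trace <- apply(steps, 2L, cumsum)
  if (n_t == 1L) trace <- matrix(trace, nrow = 1L)
  trace <- as.data.frame(trace)
  names(trace) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  attr(trace, "spike_volumes") <- spike_volumes
  trace
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Covariates drawn from truncated normals matched to the study population's
# moments (age ~30/28 y, illness duration ~8 y, moderate-to-severe
# obsessive-compulsive symptom scores, mild anxiety/depression scores).
draw_covariates <- function(group, n) {
  n_male <- round(n * 34 / 54)
  sex <- rep(c("M", "F"), c(n_male, n - n_male))
  if (group == "patient") {
    obs <- round(rtrunc_norm(n, 10.67, 3.60, 0, 20), 1)
    comp <- round(rtrunc_norm(n, 10.06, 4.44, 0, 20), 1)
    data.frame(
      group = "patient", sex = sex,
      age = round(rtrunc_norm(n, 30.41, 8.07, 18, 60), 1),
      duration_years = round(rtrunc_norm(n, 8.15, 5.69, 0.2, 40), 1),
      ybocs_obsession = obs, ybocs_compulsive = comp,
      ybocs_total = obs + comp,
      hamd = round(rtrunc_norm(n, 8.19, 5.87, 0, 52), 1),
      hama = round(rtrunc_norm(n, 9.24, 5.15, 0, 56), 1))
  } else {
    data.frame(
      group = "control", sex = sex,
      age = round(rtrunc_norm(n, 28.39, 11.22, 18, 60), 1),
      duration_years = NA_real_, ybocs_obsession = NA_real_,
      ybocs_compulsive = NA_real_, ybocs_total = NA_real_,
      hamd = NA_real_, hama = NA_real_)
  }
}

subject_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
}

#' Generate a full synthetic cohort
#'
#' Draws `n_per_group` patients and controls with motion traces, BOLD runs
#' carrying the requested regional effects, and covariates. Fully
#' deterministic given `config` and `seed`: each subject consumes its own
#' derived RNG substream, so cohorts are reproducible subject by subject.
#'
#' @param config a [sim_config()].
#' @param effects list of [effect_spec()] objects.
#' @param seed integer; defaults to `config$seed`.
#' @return an object of class `cohort`: list with `subjects` (each holding
#'   `subject_id`, `group`, `bold`, `motion`, covariates row), `participants`
#'   (data frame), `masks`, `config`, `effects`, `seed`.
#' @export
generate_cohort <- function(config, effects = list(), seed = config$seed) {
  masks <- make_masks(config)
  for (ef in effects) effect_voxels(ef, masks)  # fail fast on bad geometry
  n <- config$n_per_group
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)

  set.seed(subject_seed(seed, 0L))
  covs <- rbind(draw_covariates("patient", n), draw_covariates("control", n))
  covs$participant_id <- sprintf("sub-%02d", seq_len(2 * n))
  covs <- covs[, c("participant_id", setdiff(names(covs), "participant_id"))]

  subjects <- vector("list", 2 * n)
  for (i in seq_len(2 * n)) {
    group <- if (i <= n) "patient" else "control"
    set.seed(subject_seed(seed, i))
    motion <- generate_motion_trace(config)
    bold <- generate_subject_bold(config, effects, group, masks,
                                  spike_volumes = attr(motion, "spike_volumes"))
    subjects[[i]] <- list(subject_id = covs$participant_id[i], group = group,
                          bold = bold, motion = motion,
                          covariates = covs[i, ])
  }
  structure(list(subjects = subjects, participants = covs, masks = masks,
                 config = config, effects = effects, seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients + %d controls, grid %s, %d volumes, seed %d\n",
              sum(x$participants$group == "patient"),
              sum(x$participants$group == "control"),
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_volumes, x$seed))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
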