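#' Discard initial volumes
#'
#' Drops the first `n` volumes jointly from a BOLD run and its motion trace,
#' the usual guard against pre-steady-state signal at the start of a run.
#'
#' @param bold a [bold_run()].
#' @param motion motion data frame (6 columns, one row per volume).
#' @param n number of leading volumes to discard.
#' @return list with shortened `bold` and `motion`.
#' @export
discard_initial <- function(bold, motion, n = 10L) {
  stopifnot(inherits(bold, "bold_run"))
  n_t <- n_volumes(bold)
  if (nrow(motion) != n_t)
    stop("motion trace has ", nrow(motion), " rows but BOLD has ", n_t, " volumes")
  if (n < 0 || n >= n_t)
    stop("cannot discard ", n, " of ", n_t, " volumes")
  if (n == 0L) return(list(bold = bold, motion = motion))
  keep <- (n + 1L):n_t
  out <- bold_run(bold$data[, , , keep, drop = FALSE], tr_s = bold$tr_s,
                  voxel_size_mm = bold$voxel_size_mm, filtered = bold$filtered)
  list(bold = out, motion = motion[keep, , drop = FALSE])
}

#' Framewise displacement
#'
#' Power-style framewise displacement: the sum of absolute volume-to-volume
#' changes of the three translations (mm) plus the three rotations converted
#' to arc length at a `head_radius_mm` sphere. The first volume has FD 0.
#'
#' @param motion motion data frame: 3 translation columns (mm) then 3
#'   rotation columns (rad).
#' @param head_radius_mm rotation-to-displacement conversion radius.
#' @return numeric vector of per-volume FD (mm).
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L) stop("motion must have 6 columns")
  if (!all(is.finite(m))) stop("motion parameters must be finite")
  if (nrow(m) < 2L) stop("framewise displacement needs at least 2 volumes")
  d <- abs(diff(m))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Plan motion scrubbing
#'
#' Flags every volume whose framewise displacement exceeds `threshold`,
#' together with one volume back and two forward (clipped at run
#' boundaries), and builds one 0/1 spike regressor per flagged volume so the
#' flagged volumes can be censored within the nuisance regression.
#'
#' @param fd_series per-volume FD from [framewise_displacement()].
#' @param threshold FD threshold in mm.
#' @param back,forward neighbours flagged around each supra-threshold volume.
#' @return a `scrub_plan`: list with `fd_series`, `fd_threshold_mm`,
#'   `flagged_volumes` (sorted indices) and `spike_regressors`
#'   (volumes x flagged indicator matrix; zero columns if nothing flagged).
#' @export
plan_scrubbing <- function(fd_series, threshold = 0.2, back = 1L, forward = 2L) {
  if (!all(is.finite(fd_series))) stop("fd_series must be finite")
  n_t <- length(fd_series)
  over <- which(fd_series > threshold)
  flagged <- sort(unique(unlist(lapply(over, function(v)
    max(1L, v - back):min(n_t, v + forward)))))
  spikes <- matrix(0, nrow = n_t, ncol = length(flagged))
  if (length(flagged)) {
    spikes[cbind(flagged, seq_along(flagged))] <- 1
    colnames(spikes) <- sprintf("spike_%03d", flagged)
  }
  structure(list(fd_series = fd_series, fd_threshold_mm = threshold,
                 flagged_volumes = flagged, spike_regressors = spikes),
            class = "scrub_plan")
}

#' Friston 24-parameter motion regressor block
#'
#' Expands 6 rigid-body parameters into 24 regressors: the parameters, their
#' one-volume backshifts (first row zero-padded), and the squares of both.
#'
#' @param motion motion data frame (6 columns).
#' @return numeric matrix with 24 labelled columns.
#' @export
friston24 <- function(motion) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L) stop("motion must have 6 columns")
  if (nrow(m) < 2L) stop("need at least 2 volumes")
  lagged <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, lagged, m^2, lagged^2)
  p <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(p, paste0(p, "_lag"), paste0(p, "_sq"), paste0(p, "_lag_sq"))
  out
}

#' Assemble the combined nuisance design
#'
#' One design matrix holding everything removed from the voxel series in a
#' single regression: intercept, linear trend, the Friston-24 motion block,
#' per-volume spike regressors from a [plan_scrubbing()] plan, and the mean
#' CSF and WM compartment signals.
#'
#' @param motion motion data frame (post-discard).
#' @param scrub a `scrub_plan`, or `NULL` to omit spike regressors.
#' @param csf_signal,wm_signal compartment mean time series, or `NULL`.
#' @return numeric matrix with labelled columns, one row per volume.
#' @export
build_nuisance_design <- function(motion, scrub = NULL,
                                  csf_signal = NULL, wm_signal = NULL) {
  n_t <- nrow(motion)
  design <- cbind(intercept = rep(1, n_t),
                  trend = seq_len(n_t) - (n_t + 1) / 2,
                  friston24(motion))
  if (!is.null(scrub) && ncol(scrub$spike_regressors) > 0) {
    stopifnot(nrow(scrub$spike_regressors) == n_t)
    design <- cbind(design, scrub$spike_regressors)
  }
  if (!is.null(csf_signal)) design <- cbind(design, csf = csf_signal)
  if (!is.null(wm_signal)) design <- cbind(design, wm = wm_signal)
  design
}

#' Mean compartment signal
#'
#' Per-volume mean of the in-mask voxel time series, used to summarize CSF
#' and WM compartments as nuisance covariates.
#'
#' @param bold a [bold_run()].
#' @param mask logical 3D array.
#' @return numeric vector, one value per volume.
#' @export
mean_compartment_signal <- function(bold, mask) {
  check_mask(mask, grid_dim(bold))
  if (!any(mask)) stop("compartment mask is empty")
  rowMeans(bold_matrix(bold, mask))
}

#' Nuisance regression
#'
#' Regresses every in-mask voxel time series on the columns of `design` and
#' keeps the least-squares residuals (zero-mean; the voxel mean is *not*
#' re-added). Exactly duplicated and all-zero columns are pruned before
#' fitting; a design still rank-deficient after pruning is an error naming
#' the collinear columns. Volumes carrying their own spike indicator have
#' residuals exactly zero, which is what makes regressor-based scrubbing
#' equivalent to censoring.
#'
#' @param bold a [bold_run()].
#' @param design numeric matrix, rows = volumes.
#' @param mask logical 3D array of voxels to process (others are zeroed).
#' @return a [bold_run()] of residuals.
#' @export
nuisance_regression <- function(bold, design, mask) {
  stopifnot(inherits(bold, "bold_run"))
  n_t <- n_volumes(bold)
  if (nrow(design) != n_t)
    stop("design has ", nrow(design), " rows but run has ", n_t, " volumes")
  if (is.null(colnames(design)))
    colnames(design) <- paste0("c", seq_len(ncol(design)))

  keep <- !duplicated(t(design)) & colSums(design != 0) > 0
  pruned <- design[, keep, drop = FALSE]
  qr_d <- qr(pruned)
  if (qr_d$rank < ncol(pruned)) {
    dropped <- colnames(pruned)[qr_d$pivot[(qr_d$rank + 1):ncol(pruned)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  y <- bold_matrix(bold, mask)
  resid <- qr.resid(qr_d, y)
  matrix_to_bold(resid, bold, mask, filtered = bold$filtered)
}

#' Bandpass specification
#'
#' @param low_hz,high_hz passband edges in Hz.
#' @param tr_s sampling interval in seconds.
#' @return a `band_spec` list.
#' @export
band_spec <- function(low_hz = 0.01, high_hz = 0.08, tr_s = 2) {
  nyquist <- 1 / (2 * tr_s)
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyquist))
    stop(sprintf("band must satisfy 0 < low < high < Nyquist = %.4g Hz", nyquist))
  structure(list(low_hz = low_hz, high_hz = high_hz, tr_s = tr_s),
            class = "band_spec")
}

# Indices (1-based, DC = 1) of FFT bins whose frequency lies inside the band,
# first-half bins only.
band_bins <- function(n_t, band) {
  k <- 1:(n_t %/% 2)
  f <- k / (n_t * band$tr_s)
  k[f >= band$low_hz & f <= band$high_hz] + 1L
}

#' Ideal bandpass filter
#'
#' Brick-wall filtering in the discrete frequency domain: spectral
#' coefficients with frequency inside `[low_hz, high_hz]` (bounds inclusive
#' on the discrete grid) are retained, everything else — including the DC
#' component — is zeroed, and the series is transformed back. The output is
#' exactly real and the operation is idempotent.
#'
#' @param bold a [bold_run()].
#' @param band a [band_spec()].
#' @param mask logical 3D array of voxels to filter.
#' @return a filtered [bold_run()] (its `filtered` flag set).
#' @export
bandpass <- function(bold, band, mask) {
  stopifnot(inherits(bold, "bold_run"), inherits(band, "band_spec"))
  n_t <- n_volumes(bold)
  bins <- band_bins(n_t, band)
  if (!length(bins))
    stop("no frequency bins inside the band at resolution 1/(N*TR) = ",
         signif(1 / (n_t * band$tr_s), 3), " Hz")
  keep <- rep(FALSE, n_t)
  keep[bins] <- TRUE
  keep[n_t + 2L - bins] <- TRUE        # conjugate-symmetric partners
  y <- bold_matrix(bold, mask)
  yf <- stats::mvfft(y)
  yf[!keep, ] <- 0
  out <- Re(stats::mvfft(yf, inverse = TRUE)) / n_t
  matrix_to_bold(out, bold, mask, filtered = TRUE)
}

#' Run the full denoising chain for one subject
#'
#' Applies, in order: initial-volume discarding, framewise-displacement
#' scrubbing planning, a single combined nuisance regression (intercept,
#' linear trend, Friston-24 motion block, spike regressors, mean CSF and WM
#' signals), and — optionally deferred — ideal bandpass filtering. The
#' unfiltered residuals are returned alongside the filtered series because
#' the spectral amplitude maps are defined on residuals *before* band
#' limiting, while regional-homogeneity and connectivity maps consume the
#' filtered series.
#'
#' @param bold a [bold_run()] as acquired.
#' @param motion motion data frame matching `bold`.
#' @param masks tissue mask list (`brain`, `gm`, `wm`, `csf`).
#' @param band a [band_spec()] (defaults to 0.01-0.08 Hz at the run's TR).
#' @param n_discard leading volumes to drop.
#' @param fd_threshold_mm scrubbing threshold.
#' @param filter logical; also compute the bandpass-filtered series?
#' @return list with `residuals` (unfiltered [bold_run()]), `filtered`
#'   ([bold_run()] or `NULL`), `scrub` (the [plan_scrubbing()] plan),
#'   `design` (nuisance matrix) and `motion` (post-discard trace).
#' @export
preprocess_subject <- function(bold, motion, masks,
                               band = band_spec(tr_s = bold$tr_s),
                               n_discard = 10L, fd_threshold_mm = 0.2,
                               filter = TRUE) {
  n_t <- n_volumes(bold)
  if (nrow(motion) != n_t)
    stop("motion trace has ", nrow(motion), " rows but BOLD has ", n_t, " volumes")
  if (n_discard < 0 || n_discard >= n_t)
    stop("cannot discard ", n_discard, " of ", n_t, " volumes")
  keep <- (n_discard + 1L):n_t
  # single masked extraction; equivalent to composing discard_initial,
  # mean_compartment_signal and nuisance_regression on full runs
  y <- bold_matrix(bold, masks$brain)[keep, , drop = FALSE]
  motion <- motion[keep, , drop = FALSE]
  in_brain <- which(masks$brain)
  fd <- framewise_displacement(motion)
  scrub <- plan_scrubbing(fd, threshold = fd_threshold_mm)
  design <- build_nuisance_design(
    motion, scrub,
    csf_signal = rowMeans(y[, match(which(masks$csf), in_brain), drop = FALSE]),
    wm_signal = rowMeans(y[, match(which(masks$wm), in_brain), drop = FALSE]))
  if (is.null(colnames(design)))
    colnames(design) <- paste0("c", seq_len(ncol(design)))
  pruned <- design[, !duplicated(t(design)) & colSums(design != 0) > 0,
                   drop = FALSE]
  qr_d <- qr(pruned)
  if (qr_d$rank < ncol(pruned)) {
    dropped <- colnames(pruned)[qr_d$pivot[(qr_d$rank + 1):ncol(pruned)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  resid <- bold_from_matrix(qr.resid(qr_d, y), grid_dim(bold), bold$tr_s,
                            bold$voxel_size_mm, masks$brain, filtered = FALSE)
  filtered <- if (filter) bandpass(resid, band, masks$brain) else NULL
  list(residuals = resid, filtered = filtered, scrub = scrub,
       design = design, motion = motion)
}
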