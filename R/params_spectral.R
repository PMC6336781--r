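#' Single-sided amplitude spectrum
#'
#' Amplitude per discrete frequency bin of one time series:
#' `amplitude(k) = sqrt(|X(k)|^2 * 2 / N)` for `k = 1 .. floor(N/2)`, with
#' `X` the discrete Fourier transform. The DC bin is excluded; frequencies
#' are `k / (N * tr_s)` Hz.
#'
#' @param series numeric vector (length >= 4, finite).
#' @param tr_s sampling interval in seconds.
#' @return data frame with columns `freq_hz` and `amplitude`.
#' @export
amplitude_spectrum <- function(series, tr_s) {
  if (length(series) < 4L) stop("series must have at least 4 points")
  if (!all(is.finite(series))) stop("series must be finite")
  n <- length(series)
  k <- 1:(n %/% 2)
  xf <- stats::fft(series)[k + 1L]
  data.frame(freq_hz = k / (n * tr_s),
             amplitude = sqrt(Mod(xf)^2 * 2 / n))
}

# Amplitudes for all in-mask voxels at once: bins x voxels matrix. When only
# a few bins are needed, the DFT coefficients are evaluated directly on the
# cos/sin basis, which is cheaper than a full transform.
amplitude_matrix <- function(y, k = NULL) {
  n <- nrow(y)
  if (is.null(k)) k <- 1:(n %/% 2)
  if (2L * length(k) >= n)
    return(sqrt(Mod(stats::mvfft(y)[k + 1L, , drop = FALSE])^2 * 2 / n))
  ang <- outer(0:(n - 1), 2 * pi * k / n)
  re <- crossprod(cos(ang), y)
  im <- crossprod(sin(ang), y)
  sqrt((re^2 + im^2) * 2 / n)
}

assert_unfiltered <- function(bold, what) {
  if (isTRUE(bold$filtered))
    stop(what, " is defined on nuisance-regressed but *unfiltered* series; ",
         "got a bandpass-filtered run")
}

assert_filtered <- function(bold, what) {
  if (!isTRUE(bold$filtered))
    stop(what, " is defined on bandpass-filtered series; ",
         "got an unfiltered run")
}

#' Low-frequency fluctuation amplitude map
#'
#' Mean single-sided spectral amplitude over the frequency bins inside the
#' low-frequency band, per in-mask voxel. Defined on nuisance-regressed,
#' detrended but *not* bandpass-filtered series — the band enters through
#' the spectral sum itself (filtering first would make the fractional
#' variant's whole-spectrum denominator degenerate).
#'
#' @param bold an unfiltered [bold_run()] of residuals.
#' @param mask logical 3D analysis mask.
#' @param band a [band_spec()].
#' @return a raw-state [parameter_map()] of kind `"alff"`.
#' @export
alff_map <- function(bold, mask, band = band_spec(tr_s = bold$tr_s)) {
  assert_unfiltered(bold, "the low-frequency amplitude map")
  bins <- band_bins(n_volumes(bold), band) - 1L    # bin numbers k = 1..N/2
  if (!length(bins)) stop("no frequency bins fall inside the band")
  amp <- amplitude_matrix(bold_matrix(bold, mask), k = bins)
  vals <- colMeans(amp)
  to_map(vals, mask, "alff",
         provenance = list(low_hz = band$low_hz, high_hz = band$high_hz,
                           tr_s = band$tr_s))
}

#' Fractional low-frequency fluctuation amplitude map
#'
#' Ratio of the in-band amplitude sum to the amplitude sum over all
#' available frequencies (DC excluded), per in-mask voxel; voxels with zero
#' total amplitude get 0. Bounded in `[0, 1]`.
#'
#' @inheritParams alff_map
#' @return a raw-state [parameter_map()] of kind `"falff"`.
#' @export
falff_map <- function(bold, mask, band = band_spec(tr_s = bold$tr_s)) {
  assert_unfiltered(bold, "the fractional amplitude map")
  amp <- amplitude_matrix(bold_matrix(bold, mask))
  bins <- band_bins(n_volumes(bold), band) - 1L
  if (!length(bins)) stop("no frequency bins fall inside the band")
  denom <- colSums(amp)
  num <- colSums(amp[bins, , drop = FALSE])
  vals <- ifelse(denom > 0, num / denom, 0)
  to_map(vals, mask, "falff",
         provenance = list(low_hz = band$low_hz, high_hz = band$high_hz,
                           tr_s = band$tr_s))
}

to_map <- function(vals, mask, kind, provenance = list()) {
  grid <- array(0, dim = dim(mask))
  grid[mask] <- vals
  parameter_map(grid, kind, "raw", mask, provenance)
}
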