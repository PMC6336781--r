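#' Functional connectivity strength specification
#'
#' @param r_threshold correlations at or below this value are discarded
#'   before summation (removes weak, noise-attributable connections).
#' @param gm_probability_threshold threshold applied when binarizing a
#'   probabilistic gray-matter map into the analysis mask.
#' @param clip_r correlations are clipped below 1 at this value so the
#'   Fisher transform stays finite for (numerically) perfect correlations.
#' @return an `fcs_spec` list.
#' @export
fcs_spec <- function(r_threshold = 0.2, gm_probability_threshold = 0.2,
                     clip_r = 1 - 1e-7) {
  if (!(r_threshold > 0 && r_threshold < 1))
    stop("r_threshold must lie in (0, 1)")
  structure(list(r_threshold = r_threshold,
                 gm_probability_threshold = gm_probability_threshold,
                 clip_r = clip_r),
            class = "fcs_spec")
}

#' Binarize a gray-matter probability map
#'
#' @param prob_map numeric 3D array of tissue probabilities.
#' @param threshold probability cutoff (voxels strictly above are kept).
#' @return logical 3D array.
#' @export
threshold_gm <- function(prob_map, threshold = 0.2) {
  array(prob_map > threshold, dim = dim(prob_map))
}

#' Functional connectivity strength (degree centrality) map
#'
#' For every gray-matter voxel, the sum of Fisher r-to-z transformed
#' *positive* correlations exceeding `r_threshold` between its
#' bandpass-filtered time series and every other gray-matter voxel's.
#' Self-correlations are excluded, correlations are clipped below 1 before
#' the `atanh` transform, and zero-variance voxels get strength 0.
#'
#' @param bold a bandpass-filtered [bold_run()].
#' @param gm_mask logical 3D gray-matter mask.
#' @param spec an [fcs_spec()].
#' @return a raw-state [parameter_map()] of kind `"fcs"`.
#' @export
fcs_map <- function(bold, gm_mask, spec = fcs_spec()) {
  assert_filtered(bold, "functional connectivity strength")
  check_mask(gm_mask, grid_dim(bold))
  y <- bold_matrix(bold, gm_mask)
  if (ncol(y) < 2L) stop("need at least 2 gray-matter voxels")
  yc <- sweep(y, 2L, colMeans(y))
  nrm <- sqrt(colSums(yc^2))
  ok <- nrm > 0
  if (sum(ok) < 2L) stop("need at least 2 gray-matter voxels with nonzero variance")
  z <- sweep(yc[, ok, drop = FALSE], 2L, nrm[ok], `/`)
  r <- crossprod(z)
  zt <- atanh(pmin(r, spec$clip_r))
  zt[r <= spec$r_threshold] <- 0
  diag(zt) <- 0
  vals <- numeric(ncol(y))
  vals[ok] <- colSums(zt)
  to_map(vals, gm_mask, "fcs",
         provenance = list(r_threshold = spec$r_threshold,
                           clip_r = spec$clip_r))
}
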