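#' Voxelwise parameter map
#'
#' A 3D scalar map of one intrinsic-activity parameter, tagged with its kind
#' (`alff`, `falff`, `reho`, `fcs`) and processing state (`raw`,
#' `normalized`, `smoothed`). Values are defined inside the mask and stored
#' as 0 outside it; provenance records the band, thresholds and smoothing
#' that produced the map.
#'
#' @param values numeric 3D array.
#' @param kind one of `"alff"`, `"falff"`, `"reho"`, `"fcs"`.
#' @param state one of `"raw"`, `"normalized"`, `"smoothed"`.
#' @param mask logical 3D array the map is defined on.
#' @param provenance named list of processing parameters.
#' @return an object of class `parameter_map`.
#' @export
parameter_map <- function(values, kind, state = "raw", mask,
                          provenance = list()) {
  kind <- match.arg(kind, c("alff", "falff", "reho", "fcs"))
  state <- match.arg(state, c("raw", "normalized", "smoothed"))
  stopifnot(length(dim(values)) == 3L)
  check_mask(mask, dim(values))
  if (!all(is.finite(values[mask])))
    stop("parameter map has non-finite in-mask values")
  values[!mask] <- 0
  structure(list(values = values, kind = kind, state = state, mask = mask,
                 provenance = provenance),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %s (%s), grid %s, %d in-mask voxels\n",
              x$kind, x$state, paste(dim(x$values), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Normalize a map by its in-mask mean
#'
#' Divides every value by the mean over the mask, so the in-mask mean of the
#' result is exactly 1. This is the within-brain standardization applied to
#' amplitude and regional-homogeneity maps before smoothing.
#'
#' @param map a [parameter_map()].
#' @param mask logical array; defaults to the map's own mask.
#' @return a [parameter_map()] in state `"normalized"`.
#' @export
normalize_by_mask_mean <- function(map, mask = map$mask) {
  mu <- mean(map$values[mask])
  if (!is.finite(mu) || mu <= 0)
    stop("in-mask mean must be positive to normalize (got ", signif(mu, 4), ")")
  parameter_map(map$values / mu, map$kind, "normalized", map$mask,
                c(map$provenance, list(norm = "mask_mean")))
}

#' Standardize a map to z-scores
#'
#' Centers and scales by the in-mask mean and population standard deviation
#' (divisor `n`), the standardization applied to connectivity-strength maps
#' after smoothing.
#'
#' @inheritParams normalize_by_mask_mean
#' @return a [parameter_map()] in state `"normalized"`.
#' @export
zscore_map <- function(map, mask = map$mask) {
  v <- map$values[mask]
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv <= 0) stop("in-mask standard deviation is zero; cannot z-score")
  out <- map$values
  out[mask] <- (v - mu) / sdv
  out[!mask] <- 0
  parameter_map(out, map$kind, "normalized", map$mask,
                c(map$provenance, list(norm = "zscore")))
}

#' Smoothing specification
#'
#' @param fwhm_mm Gaussian kernel full width at half maximum (mm).
#' @param voxel_size_mm isotropic voxel size (mm).
#' @return a `smooth_spec` list with the implied `sigma_voxels`.
#' @export
smooth_spec <- function(fwhm_mm = 8, voxel_size_mm = 3) {
  if (fwhm_mm <= 0 || voxel_size_mm <= 0)
    stop("fwhm_mm and voxel_size_mm must be positive")
  structure(list(fwhm_mm = fwhm_mm, voxel_size_mm = voxel_size_mm,
                 sigma_voxels = (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))),
            class = "smooth_spec")
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable 1D convolution along one array axis with zero padding, done as a
# banded-matrix product.
conv_axis <- function(arr, g, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(g) - 1L) / 2L
  band <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    i <- seq_len(n)
    ok <- i + j >= 1L & i + j <= n
    band[cbind(i[ok], (i + j)[ok])] <- g[j + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dim(x) <- c(n, prod(d[-axis]))
  x <- band %*% x
  dim(x) <- d[perm]
  aperm(x, order(perm))
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing with `sigma = FWHM / (2 sqrt(2 ln 2))`
#' voxels, applied to the full grid with zero-padded boundaries and then
#' re-masked (values outside the map's mask are zeroed afterwards), the
#' behaviour of volume-wide smoothing in standard neuroimaging pipelines.
#'
#' @param map a [parameter_map()].
#' @param spec a [smooth_spec()].
#' @return a [parameter_map()] in state `"smoothed"`.
#' @export
gaussian_smooth <- function(map, spec = smooth_spec(voxel_size_mm = map$provenance$voxel_size_mm %||% 3)) {
  stopifnot(inherits(spec, "smooth_spec"))
  g <- gaussian_kernel_1d(spec$sigma_voxels)
  v <- map$values
  for (axis in 1:3) v <- conv_axis(v, g, axis)
  v[!map$mask] <- 0
  parameter_map(v, map$kind, "smoothed", map$mask,
                c(map$provenance, list(fwhm_mm = spec$fwhm_mm,
                                       sigma_voxels = spec$sigma_voxels)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
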