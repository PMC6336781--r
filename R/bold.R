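#' BOLD run container
#'
#' A `bold_run` holds one subject's 4D voxel time series together with its
#' acquisition geometry. Data are stored as an `x * y * z * t` array in
#' arbitrary signal units; `tr_s` is the sampling interval (volume-to-volume
#' repetition time, seconds) and `voxel_size_mm` the isotropic voxel edge
#' length in millimetres. The `filtered` flag records whether the series has
#' been bandpass filtered, so downstream spectral operations can assert that
#' they receive data in the processing state they are defined on.
#'
#' @param data numeric 4D array (x, y, z, t).
#' @param tr_s repetition time in seconds.
#' @param voxel_size_mm isotropic voxel size in millimetres.
#' @param filtered logical; has a bandpass filter been applied?
#' @return an object of class `bold_run`.
#' @export
bold_run <- function(data, tr_s, voxel_size_mm = 3, filtered = FALSE) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("`tr_s` must be a positive scalar")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be positive")
  structure(
    list(data = data, tr_s = tr_s, voxel_size_mm = voxel_size_mm,
         filtered = isTRUE(filtered)),
    class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d voxels, %d volumes, TR %.3g s, %s\n",
              d[1], d[2], d[3], d[4], x$tr_s,
              if (x$filtered) "bandpass filtered" else "unfiltered"))
  invisible(x)
}

n_volumes <- function(bold) dim(bold$data)[4L]

grid_dim <- function(bold) dim(bold$data)[1:3]

#' Extract in-mask voxel time series as a matrix
#'
#' Returns a `t * v` matrix whose columns are the time series of the voxels
#' selected by `mask`, in the array-storage (column-major) order of the mask.
#'
#' @param bold a [bold_run()].
#' @param mask logical 3D array matching the spatial grid.
#' @return numeric matrix, volumes in rows, in-mask voxels in columns.
#' @export
bold_matrix <- function(bold, mask) {
  stopifnot(inherits(bold, "bold_run"))
  check_mask(mask, grid_dim(bold))
  d <- dim(bold$data)
  n_vox <- prod(d[1:3])
  idx <- outer(seq_len(d[4L]) - 1L, which(mask),
               function(t, v) t * n_vox + v)
  out <- bold$data[as.vector(idx)]     # linear indexing, never coordinate rows
  dim(out) <- c(d[4L], sum(mask))
  out
}

#' Write in-mask voxel time series back into a BOLD run
#'
#' Inverse of [bold_matrix()]: replaces the in-mask series of `bold` with the
#' columns of `mat` (voxels outside the mask are zeroed).
#'
#' @inheritParams bold_matrix
#' @param mat `t * v` matrix as produced by [bold_matrix()].
#' @param filtered logical; filtered-state flag for the result.
#' @return a [bold_run()].
#' @export
matrix_to_bold <- function(mat, bold, mask, filtered = bold$filtered) {
  bold_from_matrix(mat, grid_dim(bold), bold$tr_s, bold$voxel_size_mm,
                   mask, filtered)
}

bold_from_matrix <- function(mat, dims, tr_s, voxel_size_mm, mask, filtered) {
  stopifnot(ncol(mat) == sum(mask))
  flat <- matrix(0, nrow = prod(dims), ncol = nrow(mat))
  flat[as.vector(mask), ] <- t(mat)
  dim(flat) <- c(dims, nrow(mat))
  bold_run(flat, tr_s = tr_s, voxel_size_mm = voxel_size_mm,
           filtered = filtered)
}

check_mask <- function(mask, dims) {
  if (!is.logical(mask) || !identical(dim(mask), as.integer(dims)))
    stop("mask must be a logical array with dim ", paste(dims, collapse = "x"))
  invisible(TRUE)
}

#' Spherical voxel set
#'
#' Logical mask of voxels within `radius` (in voxel units, Euclidean) of
#' `center` on a grid of size `dims`.
#'
#' @param dims integer 3-vector of grid extents.
#' @param center numeric 3-vector, voxel coordinates (1-based).
#' @param radius radius in voxels.
#' @return logical 3D array.
#' @export
sphere_mask <- function(dims, center, radius) {
  stopifnot(length(dims) == 3L, length(center) == 3L, radius >= 0)
  dx <- (seq_len(dims[1]) - center[1])^2
  dy <- (seq_len(dims[2]) - center[2])^2
  dz <- (seq_len(dims[3]) - center[3])^2
  r2 <- outer(outer(dx, dy, `+`), dz, `+`)
  array(r2 <= radius^2, dim = dims)
}
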