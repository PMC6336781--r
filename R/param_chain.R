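#' Compute one subject's parameter maps in their canonical chains
#'
#' Runs the per-kind processing chains on a preprocessed subject:
#' amplitude maps (`alff`, `falff`) are computed from the unfiltered
#' residuals, then normalized by the within-mask mean and smoothed;
#' regional homogeneity (`reho`) is computed from the filtered series, then
#' mean-normalized and smoothed; connectivity strength (`fcs`) is computed
#' from the filtered series on the gray-matter mask, then smoothed and
#' z-scored.
#'
#' @param pre result of [preprocess_subject()].
#' @param masks tissue mask list.
#' @param kinds subset of `c("alff", "falff", "reho", "fcs")`.
#' @param band a [band_spec()].
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @param fcs an [fcs_spec()].
#' @param neighbourhood regional-homogeneity neighbourhood (7, 19 or 27).
#' @return named list of final-state [parameter_map()]s.
#' @export
subject_parameter_maps <- function(pre, masks,
                                   kinds = c("alff", "falff", "reho", "fcs"),
                                   band = band_spec(tr_s = pre$residuals$tr_s),
                                   fwhm_mm = 8, fcs = fcs_spec(),
                                   neighbourhood = 27L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  spec <- smooth_spec(fwhm_mm, pre$residuals$voxel_size_mm)
  out <- list()
  for (kind in kinds) {
    out[[kind]] <- switch(
      kind,
      alff = gaussian_smooth(normalize_by_mask_mean(
        alff_map(pre$residuals, masks$brain, band)), spec),
      falff = gaussian_smooth(normalize_by_mask_mean(
        falff_map(pre$residuals, masks$brain, band)), spec),
      reho = gaussian_smooth(normalize_by_mask_mean(
        reho_map(pre$filtered, masks$brain, neighbourhood)), spec),
      fcs = zscore_map(gaussian_smooth(
        fcs_map(pre$filtered, masks$gm, fcs), spec)))
  }
  out
}

#' Assemble a subjects-by-voxels feature matrix
#'
#' Stacks one parameter kind's final maps into the subjects x in-mask-voxels
#' matrix consumed by both the univariate and the multivariate arm. Labels
#' are +1 for patients and -1 for controls.
#'
#' @param maps list of [parameter_map()]s, one per subject, same kind,
#'   state and grid.
#' @param groups character vector, `"patient"` / `"control"` per subject.
#' @param ids subject identifiers.
#' @return an object of class `cohort_features`: list with `x` (matrix),
#'   `labels` (+1/-1), `ids`, `kind`, `state`, `mask`, `voxel_index`
#'   (grid indices of the columns).
#' @export
cohort_features <- function(maps, groups, ids = names(maps)) {
  stopifnot(length(maps) >= 2L, length(groups) == length(maps))
  ref <- maps[[1L]]
  for (m in maps) {
    stopifnot(inherits(m, "parameter_map"))
    if (m$kind != ref$kind || m$state != ref$state ||
        !identical(m$mask, ref$mask))
      stop("all maps must share kind, state and mask")
  }
  if (!all(groups %in% c("patient", "control")))
    stop("groups must be 'patient' or 'control'")
  x <- t(vapply(maps, function(m) m$values[m$mask], numeric(sum(ref$mask))))
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values")
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_along(maps))
  structure(list(x = x, labels = ifelse(groups == "patient", 1L, -1L),
                 ids = ids, kind = ref$kind, state = ref$state,
                 mask = ref$mask, voxel_index = which(ref$mask)),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf("<cohort_features> %s (%s): %d subjects (%d patients) x %d voxels\n",
              x$kind, x$state, nrow(x$x), sum(x$labels == 1), ncol(x$x)))
  invisible(x)
}
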