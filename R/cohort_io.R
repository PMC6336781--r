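#' Write a synthetic cohort to disk
#'
#' Lays out a cohort in a BIDS-flavoured directory: one gzipped 4D NIfTI-1
#' and one whitespace-delimited motion file per subject, one NIfTI mask per
#' tissue compartment, a `participants.tsv`, and a JSON `manifest.json`
#' recording the configuration, effects and seed. The manifest makes the
#' directory self-describing: [read_cohort()] restores the cohort, and
#' [regenerate_cohort()] rebuilds it from the manifest alone.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if absent).
#' @param overwrite logical; refuse to clobber an existing manifest unless
#'   `TRUE`.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists at ", manifest_path,
         "; use overwrite = TRUE to replace the cohort")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  vox <- cohort$config$voxel_size_mm
  write_nii <- function(arr, path, with_time = FALSE) {
    img <- RNifti::asNifti(arr * 1)       # masks stored as 0/1 float
    RNifti::pixdim(img) <- c(vox, vox, vox,
                             if (with_time) cohort$config$tr_s else NULL)
    RNifti::sform(img) <- structure(diag(c(vox, vox, vox, 1)), code = 2L)
    RNifti::writeNifti(img, path)
  }
  for (tissue in names(cohort$masks))
    write_nii(cohort$masks[[tissue]],
              file.path(out_dir, sprintf("mask_%s.nii.gz", tissue)))

  files <- lapply(cohort$subjects, function(s) {
    bold_file <- sprintf("%s_bold.nii.gz", s$subject_id)
    motion_file <- sprintf("%s_motion.tsv", s$subject_id)
    write_nii(s$bold$data, file.path(out_dir, bold_file), with_time = TRUE)
    utils::write.table(s$motion, file.path(out_dir, motion_file),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(subject_id = s$subject_id, group = s$group,
         bold = bold_file, motion = motion_file)
  })
  utils::write.table(cohort$participants, file.path(out_dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "n/a")

  manifest <- list(
    format = "rsmvpa-cohort-1",
    seed = cohort$seed,
    config = unclass(cohort$config),
    effects = lapply(cohort$effects, unclass),
    subjects = files)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

read_manifest <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(m$format, "rsmvpa-cohort-1"))
    stop("unrecognized cohort manifest format: ", m$format)
  m
}

manifest_config <- function(m) {
  cfg <- m$config
  cfg$grid_shape <- as.integer(cfg$grid_shape)
  do.call(sim_config, cfg)
}

manifest_effects <- function(m) {
  lapply(m$effects, function(e)
    effect_spec(kind = e$kind, center = as.numeric(e$center),
                radius = e$radius, effect_size = e$effect_size,
                target_group = e$target_group, partners = e$partners))
}

#' Read a cohort from disk
#'
#' Restores a directory written by [write_cohort()] into the same in-memory
#' `cohort` structure, reading NIfTI volumes, motion files and the
#' participants table.
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return a `cohort` object.
#' @export
read_cohort <- function(dir) {
  m <- read_manifest(dir)
  config <- manifest_config(m)
  effects <- manifest_effects(m)
  masks <- lapply(c(brain = "brain", gm = "gm", wm = "wm", csf = "csf"),
                  function(t) {
                    arr <- RNifti::readNifti(file.path(dir, sprintf("mask_%s.nii.gz", t)))
                    array(as.vector(arr) > 0.5, dim = dim(arr))
                  })
  participants <- utils::read.delim(file.path(dir, "participants.tsv"),
                                    na.strings = "n/a")
  subjects <- lapply(m$subjects, function(s) {
    arr <- RNifti::readNifti(file.path(dir, s$bold))
    bold <- bold_run(array(as.vector(arr), dim = dim(arr)),
                     tr_s = config$tr_s, voxel_size_mm = config$voxel_size_mm)
    motion <- utils::read.delim(file.path(dir, s$motion))
    list(subject_id = s$subject_id, group = s$group, bold = bold,
         motion = motion,
         covariates = participants[participants$participant_id == s$subject_id, ])
  })
  structure(list(subjects = subjects, participants = participants,
                 masks = masks, config = config, effects = effects,
                 seed = as.integer(m$seed)),
            class = "cohort")
}

#' Regenerate a cohort from its manifest
#'
#' Re-runs [generate_cohort()] with the configuration, effects and seed
#' recorded in a cohort directory's manifest; the result is bit-identical to
#' the cohort originally written there.
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return a `cohort` object.
#' @export
regenerate_cohort <- function(dir) {
  m <- read_manifest(dir)
  generate_cohort(manifest_config(m), manifest_effects(m), seed = m$seed)
}
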