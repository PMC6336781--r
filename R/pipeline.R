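#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end pipeline. The defaults
#' are the canonical analysis constants: a 0.01-0.08 Hz passband, a 0.2 mm
#' framewise-displacement scrubbing threshold, ten discarded volumes, an
#' 8 mm FWHM smoothing kernel, a connectivity threshold of r = 0.2, C = 1,
#' 1000 label permutations, a 30% discrimination-map display threshold and
#' FDR control at q = 0.05.
#'
#' @param simulate,preprocess,maps,univariate,mvpa stage toggles.
#' @param kinds parameter kinds to analyse.
#' @param sim a [sim_config()] for the simulation stage.
#' @param effects list of [effect_spec()]s for the simulation stage.
#' @param in_dir cohort directory to read when `simulate = FALSE`.
#' @param out_dir where to write the report (optional; `NULL` keeps the run
#'   in memory).
#' @param low_hz,high_hz bandpass edges (Hz).
#' @param fd_threshold_mm scrubbing threshold (mm).
#' @param n_discard initial volumes to drop.
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @param r_threshold connectivity-strength correlation threshold.
#' @param neighbourhood regional-homogeneity neighbourhood (7, 19, 27).
#' @param C soft-margin cost.
#' @param n_perm label permutations for classifier significance.
#' @param perm_stat permutation statistic, `"accuracy"` or `"joint"`.
#' @param q FDR level for the univariate arm.
#' @param threshold_fraction discrimination-map display threshold.
#' @param seed master seed; per-stage substreams are derived from it.
#' @return a validated `run_config` list.
#' @export
run_config <- function(simulate = TRUE, preprocess = TRUE, maps = TRUE,
                       univariate = TRUE, mvpa = TRUE,
                       kinds = c("alff", "falff", "reho", "fcs"),
                       sim = sim_config(), effects = list(),
                       in_dir = NULL, out_dir = NULL,
                       low_hz = 0.01, high_hz = 0.08,
                       fd_threshold_mm = 0.2, n_discard = 10L,
                       fwhm_mm = 8, r_threshold = 0.2, neighbourhood = 27L,
                       C = 1, n_perm = 1000L,
                       perm_stat = c("accuracy", "joint"),
                       q = 0.05, threshold_fraction = 0.30, seed = 1L) {
  cfg <- list(simulate = simulate, preprocess = preprocess, maps = maps,
              univariate = univariate, mvpa = mvpa, kinds = kinds,
              sim = sim, effects = effects, in_dir = in_dir,
              out_dir = out_dir, low_hz = low_hz, high_hz = high_hz,
              fd_threshold_mm = fd_threshold_mm,
              n_discard = as.integer(n_discard), fwhm_mm = fwhm_mm,
              r_threshold = r_threshold,
              neighbourhood = as.integer(neighbourhood), C = C,
              n_perm = as.integer(n_perm),
              perm_stat = match.arg(perm_stat), q = q,
              threshold_fraction = threshold_fraction,
              seed = as.integer(seed))
  validate_config(cfg)
}

#' Validate and normalize a run configuration
#'
#' Checks every cross-field constraint (band against TR, thresholds in
#' range, known parameter kinds, no unknown keys) and returns the
#' normalized configuration, or stops with all problems listed.
#'
#' @param config a `run_config`-shaped list.
#' @return the validated configuration, classed `run_config`.
#' @export
validate_config <- function(config) {
  known <- c("simulate", "preprocess", "maps", "univariate", "mvpa",
             "kinds", "sim", "effects", "in_dir", "out_dir", "low_hz",
             "high_hz", "fd_threshold_mm", "n_discard", "fwhm_mm",
             "r_threshold", "neighbourhood", "C", "n_perm", "perm_stat",
             "q", "threshold_fraction", "seed")
  errs <- character(0)
  extra <- setdiff(names(config), known)
  if (length(extra))
    errs <- c(errs, paste("unknown configuration keys:",
                          paste(extra, collapse = ", ")))
  missing <- setdiff(known, names(config))
  if (length(missing))
    errs <- c(errs, paste("missing configuration keys:",
                          paste(missing, collapse = ", ")))
  if (!length(errs)) {
    if (!inherits(config$sim, "sim_config"))
      errs <- c(errs, "sim must be a sim_config object")
    else {
      nyq <- 1 / (2 * config$sim$tr_s)
      if (!(0 < config$low_hz && config$low_hz < config$high_hz &&
            config$high_hz < nyq))
        errs <- c(errs, sprintf(
          "band [low_hz, high_hz] = [%g, %g] must satisfy 0 < low < high < Nyquist = %g",
          config$low_hz, config$high_hz, nyq))
      if (config$n_discard < 0 || config$n_discard >= config$sim$n_volumes)
        errs <- c(errs, "n_discard must be in [0, n_volumes)")
    }
    if (!all(config$kinds %in% c("alff", "falff", "reho", "fcs")))
      errs <- c(errs, "kinds must be a subset of alff, falff, reho, fcs")
    if (!length(config$kinds)) errs <- c(errs, "kinds must be nonempty")
    if (config$fd_threshold_mm <= 0)
      errs <- c(errs, "fd_threshold_mm must be positive")
    if (!(config$threshold_fraction > 0 && config$threshold_fraction <= 1))
      errs <- c(errs, "threshold_fraction must lie in (0, 1]")
    if (!(config$q > 0 && config$q < 1)) errs <- c(errs, "q must lie in (0, 1)")
    if (!(config$r_threshold > 0 && config$r_threshold < 1))
      errs <- c(errs, "r_threshold must lie in (0, 1)")
    if (config$C <= 0) errs <- c(errs, "C must be positive")
    if (config$n_perm < 1) errs <- c(errs, "n_perm must be at least 1")
    if (!config$neighbourhood %in% c(7L, 19L, 27L))
      errs <- c(errs, "neighbourhood must be 7, 19 or 27")
    if (!config$simulate && is.null(config$in_dir))
      errs <- c(errs, "in_dir is required when the simulate stage is disabled")
  }
  if (length(errs))
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(config, class = "run_config")
}

# One master seed fans out into fixed per-stage substreams, so toggling a
# stage cannot perturb another stage's draws.
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + sum(utf8ToInt(stage)) * 69621) %% 2147483647
}

config_digest <- function(config) {
  keep <- config[setdiff(names(config), c("in_dir", "out_dir"))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load a cohort),
#' preprocess, parameter maps, univariate statistics, multivariate
#' classification — and assembles a per-kind report comparing the parameter
#' kinds side by side. Re-running with the same configuration and seed
#' reproduces every numeric output.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report`: `per_kind` (named list with
#'   `cv` reports, `univariate` summaries and thresholded discrimination
#'   maps), `features`, `cohort`, `summary` (data frame, one row per kind),
#'   `config`, `config_digest`, `seed`, and per-stage wall-clock seconds in
#'   `timing`.
#' @export
run_all <- function(config) {
  config <- validate_config(config)
  timing <- list()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  cohort <- if (config$simulate)
    generate_cohort(config$sim, config$effects,
                    seed = stage_seed(config$seed, "simulate"))
  else read_cohort(config$in_dir)
  timing$simulate <- tic() - t0

  if (!config$preprocess && (config$maps || config$univariate || config$mvpa))
    stop("stage 'preprocess' is required by the downstream stages enabled")

  features <- NULL
  if (config$maps) {
    t0 <- tic()
    band <- band_spec(config$low_hz, config$high_hz, cohort$config$tr_s)
    need_filter <- any(config$kinds %in% c("reho", "fcs"))
    fspec <- fcs_spec(r_threshold = config$r_threshold)
    per_subject <- lapply(cohort$subjects, function(s) {
      pre <- preprocess_subject(s$bold, s$motion, cohort$masks, band,
                                n_discard = config$n_discard,
                                fd_threshold_mm = config$fd_threshold_mm,
                                filter = need_filter)
      subject_parameter_maps(pre, cohort$masks, kinds = config$kinds,
                             band = band, fwhm_mm = config$fwhm_mm,
                             fcs = fspec,
                             neighbourhood = config$neighbourhood)
    })
    groups <- vapply(cohort$subjects, `[[`, "", "group")
    ids <- vapply(cohort$subjects, `[[`, "", "subject_id")
    features <- lapply(stats::setNames(config$kinds, config$kinds),
                       function(kind)
                         cohort_features(lapply(per_subject, `[[`, kind),
                                         groups, ids))
    timing$maps <- tic() - t0
  }

  per_kind <- list()
  if (config$univariate || config$mvpa) {
    if (is.null(features))
      stop("stage 'maps' is required by the univariate and mvpa stages")
    for (kind in config$kinds) {
      res <- list()
      if (config$univariate) {
        t0 <- tic()
        sm <- voxelwise_ttest(features[[kind]])
        fdr <- fdr_bh(sm$p, q = config$q)
        res$univariate <- list(stat_map = sm, fdr = fdr,
                               n_significant = sum(fdr$reject),
                               cutoff = fdr$cutoff)
        timing[[paste0("univariate_", kind)]] <- tic() - t0
      }
      if (config$mvpa) {
        t0 <- tic()
        cv <- permutation_test(features[[kind]], C = config$C,
                               n_perm = config$n_perm,
                               seed = stage_seed(config$seed,
                                                 paste0("mvpa_", kind)),
                               statistic = config$perm_stat)
        full <- train_svm(linear_kernel(features[[kind]]),
                          features[[kind]]$labels, C = config$C)
        dmap <- discrimination_map(full, features[[kind]])
        res$cv <- cv
        res$discrimination <- dmap
        res$discrimination_thresholded <-
          threshold_map(dmap, config$threshold_fraction)
        timing[[paste0("mvpa_", kind)]] <- tic() - t0
      }
      per_kind[[kind]] <- res
    }
  }

  summary <- do.call(rbind, lapply(config$kinds, function(kind) {
    res <- per_kind[[kind]]
    data.frame(
      kind = kind,
      accuracy = if (!is.null(res$cv)) res$cv$accuracy else NA_real_,
      sensitivity = if (!is.null(res$cv)) res$cv$sensitivity else NA_real_,
      specificity = if (!is.null(res$cv)) res$cv$specificity else NA_real_,
      auc = if (!is.null(res$cv)) res$cv$auc else NA_real_,
      perm_p = if (!is.null(res$cv)) res$cv$p_value else NA_real_,
      n_significant_voxels = if (!is.null(res$univariate))
        res$univariate$n_significant else NA_integer_)
  }))

  report <- structure(
    list(per_kind = per_kind, features = features, cohort = cohort,
         summary = summary, config = config,
         config_digest = config_digest(config), seed = config$seed,
         timing = timing),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "config", x$config_digest, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a run report to disk
#'
#' Serializes the per-kind summary as JSON (machine-comparable; no
#' timestamps, so identical runs produce identical bytes) and as a flat
#' TSV.
#'
#' @param report a [run_all()] report.
#' @param out_dir output directory.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(seed = report$seed, config_digest = report$config_digest,
               summary = report$summary)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.table(report$summary, file.path(out_dir, "report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
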