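#' Voxelwise two-sample t-test
#'
#' Pooled-variance two-sample t per in-mask voxel between patients and
#' controls, with `df = n1 + n2 - 2` and two-sided p-values. Voxels with
#' zero pooled variance are reported as `t = 0, p = 1`.
#'
#' @param features a [cohort_features()] object, or a subjects x voxels
#'   matrix with `labels` supplied.
#' @param labels +1 / -1 group labels.
#' @return an object of class `stat_map`: vectors `t` and `p` over feature
#'   columns, `df`, grid arrays `t_map` / `p_map` when a mask is available,
#'   and the mask.
#' @export
voxelwise_ttest <- function(features, labels = NULL) {
  x <- if (inherits(features, "cohort_features")) features$x else features
  if (is.null(labels) && inherits(features, "cohort_features"))
    labels <- features$labels
  g1 <- x[labels == 1, , drop = FALSE]
  g2 <- x[labels == -1, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- colSums(sweep(g1, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(g2, 2L, m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tv <- ifelse(se > 0, (m1 - m2) / se, 0)
  pv <- ifelse(se > 0, 2 * stats::pt(-abs(tv), df), 1)
  out <- list(t = tv, p = pv, df = df, n1 = n1, n2 = n2)
  if (inherits(features, "cohort_features")) {
    tm <- pm <- array(0, dim = dim(features$mask))
    tm[features$voxel_index] <- tv
    pm[!features$mask] <- 1
    pm[features$voxel_index] <- pv
    out$t_map <- tm; out$p_map <- pm; out$mask <- features$mask
    out$voxel_index <- features$voxel_index
  }
  structure(out, class = "stat_map")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR over a family of p-values (the in-mask voxels of one map
#' kind): rejects all hypotheses with BH-adjusted p at most `q` and reports
#' the realized adaptive p cutoff (the largest sorted p-value under the
#' step-up line, or 0 when nothing is rejected).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate.
#' @return list with `reject` (logical), `cutoff`, `p_adjusted`, `q`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  reject <- adj <= q
  cutoff <- if (any(reject)) max(p_values[reject]) else 0
  list(reject = reject, cutoff = cutoff, p_adjusted = adj, q = q)
}

#' Two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1 first group's mean, SD and size.
#' @param mean2,sd2,n2 second group's mean, SD and size.
#' @param variance_mode `"welch"` (Welch-Satterthwaite df) or `"pooled"`.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (variance_mode == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    a <- sd1^2 / n1; b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  tv <- (mean1 - mean2) / se
  list(t = tv, df = df, p = 2 * stats::pt(-abs(tv), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, `df = 1`. The table is
#' `rbind(c(a, b), c(c, d))` with groups in rows.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), nrow = 2L)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all table margins must be positive")
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Partial correlation with nuisance covariates
#'
#' Residualizes both variables on the covariates (plus intercept) and
#' correlates the residuals; the two-sided p-value is t-based with
#' `df = n - k - 2` for `k` covariates. With no covariates this reduces to
#' the plain Pearson correlation.
#'
#' @param values numeric vector (e.g. regional parameter means).
#' @param scores numeric vector (e.g. symptom-severity scores).
#' @param covariates numeric matrix or data frame of covariates, or `NULL`.
#' @return list with `r`, `df`, `p`.
#' @export
partial_correlation <- function(values, scores, covariates = NULL) {
  n <- length(values)
  stopifnot(length(scores) == n)
  k <- 0L
  if (!is.null(covariates)) {
    z <- as.matrix(as.data.frame(covariates))
    storage.mode(z) <- "double"
    stopifnot(nrow(z) == n)
    k <- ncol(z)
    qr_z <- qr(cbind(1, z))
    if (qr_z$rank < k + 1L)
      stop("covariate matrix is rank deficient")
    values <- qr.resid(qr_z, values)
    scores <- qr.resid(qr_z, scores)
  } else {
    values <- values - mean(values)
    scores <- scores - mean(scores)
  }
  if (n <= k + 2L) stop("need n > k + 2 observations")
  r <- sum(values * scores) / sqrt(sum(values^2) * sum(scores^2))
  df <- n - k - 2L
  tv <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tv), df))
}

#' Mean parameter value in a region, per subject
#'
#' @param features a [cohort_features()] object, or list of
#'   [parameter_map()]s (one per subject).
#' @param region_mask logical 3D array; must be nonempty and lie inside the
#'   analysis mask.
#' @return numeric vector, one mean per subject.
#' @export
extract_region_means <- function(features, region_mask) {
  if (inherits(features, "cohort_features")) {
    check_mask(region_mask, dim(features$mask))
    if (!any(region_mask)) stop("region mask is empty")
    if (any(region_mask & !features$mask))
      stop("region mask extends outside the analysis mask")
    cols <- match(which(region_mask), features$voxel_index)
    rowMeans(features$x[, cols, drop = FALSE])
  } else {
    vapply(features, function(m) {
      check_mask(region_mask, dim(m$values))
      if (!any(region_mask)) stop("region mask is empty")
      if (any(region_mask & !m$mask))
        stop("region mask extends outside the analysis mask")
      mean(m$values[region_mask])
    }, numeric(1))
  }
}
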