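#' Recover confusion counts from printed sensitivity/specificity
#'
#' Published classifier performance is usually reported as percentages
#' rounded to two decimals. With known group sizes the underlying integer
#' confusion counts are recoverable whenever exactly one count rounds to
#' the printed rate; this permits arithmetic-consistency checks of a
#' reported (accuracy, sensitivity, specificity) triplet.
#'
#' @param sensitivity_pct,specificity_pct printed rates in percent.
#' @param n_patients,n_controls group sizes.
#' @return list with `tp`, `fn`, `tn`, `fp`; errors if a rate is not
#'   consistent with any (or with more than one) integer count.
#' @export
confusion_from_rates <- function(sensitivity_pct, specificity_pct,
                                 n_patients, n_controls = n_patients) {
  pick <- function(rate, n, what) {
    k <- which(round(100 * (0:n) / n, 2) == round(rate, 2)) - 1L
    if (length(k) == 0L)
      stop(sprintf("%s %.2f%% matches no integer count out of %d", what, rate, n))
    if (length(k) > 1L)
      stop(sprintf("%s %.2f%% is ambiguous at n = %d", what, rate, n))
    k
  }
  tp <- pick(sensitivity_pct, n_patients, "sensitivity")
  tn <- pick(specificity_pct, n_controls, "specificity")
  list(tp = tp, fn = n_patients - tp, tn = tn, fp = n_controls - tn)
}

#' Score a classifier from recovered confusion counts
#'
#' Convenience wrapper: recovers the integer counts with
#' [confusion_from_rates()], expands them into per-subject labels and
#' predictions, and recomputes all metrics with [score()].
#'
#' @inheritParams confusion_from_rates
#' @return the [score()] list for the recovered counts.
#' @export
score_from_rates <- function(sensitivity_pct, specificity_pct,
                             n_patients, n_controls = n_patients) {
  cc <- confusion_from_rates(sensitivity_pct, specificity_pct,
                             n_patients, n_controls)
  labels <- rep(c(1L, -1L), c(n_patients, n_controls))
  predictions <- c(rep(c(1L, -1L), c(cc$tp, cc$fn)),
                   rep(c(-1L, 1L), c(cc$tn, cc$fp)))
  score(predictions, labels)
}
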