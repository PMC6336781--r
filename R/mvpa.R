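#' Linear kernel (Gram) matrix
#'
#' Inner products between all pairs of subject feature rows — the
#' precomputed similarity matrix supplied to the classifier. Symmetric and
#' positive semidefinite by construction.
#'
#' @param features a [cohort_features()] object or a numeric matrix
#'   (subjects in rows).
#' @return numeric `n x n` matrix.
#' @export
linear_kernel <- function(features) {
  x <- if (inherits(features, "cohort_features")) features$x else features
  if (!is.matrix(x)) stop("features must be a matrix or cohort_features")
  if (!all(is.finite(x))) stop("features contain non-finite values")
  tcrossprod(x)
}

#' Train a soft-margin linear-kernel SVM on a precomputed Gram matrix
#'
#' Solves the C-SVC dual on the supplied kernel and returns the dual
#' solution in a fixed orientation: `decision(x) = sum_i alpha_i K(x_i, x)
#' + b` with `alpha_i = y_i * a_i`, `0 <= a_i <= C`, `sum_i alpha_i = 0`,
#' and positive decisions meaning the +1 (patient) class. The quadratic
#' program is delegated to libsvm after factoring the Gram matrix into an
#' equivalent Euclidean embedding (eigendecomposition with negative
#' eigenvalues clipped at zero), which leaves the dual solution unchanged.
#'
#' @param kernel `n x n` Gram matrix from [linear_kernel()].
#' @param labels vector of +1 / -1 class labels.
#' @param C soft-margin cost.
#' @return an object of class `svm_model`: `alpha` (signed dual
#'   coefficients over support vectors), `sv_index`, `b`, `C`, `labels`.
#' @export
train_svm <- function(kernel, labels, C = 1) {
  n <- length(labels)
  stopifnot(is.matrix(kernel), nrow(kernel) == n, ncol(kernel) == n)
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1 / -1")
  if (length(unique(labels)) < 2L)
    stop("training requires both classes to be present")

  eig <- eigen(kernel, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  embed <- eig$vectors %*% diag(sqrt(lambda), n)
  y <- factor(labels, levels = c(-1L, 1L))
  fit <- e1071::svm(embed, y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  alpha <- as.vector(fit$coefs)        # libsvm's y_i * a_i, internal sign
  sv <- fit$index
  dec_internal <- as.vector(kernel[, sv, drop = FALSE] %*% alpha) - fit$rho
  pred <- as.integer(as.character(predict(fit, embed)))
  s <- if (sum(sign(dec_internal) * pred) >= 0) 1 else -1
  structure(list(alpha = s * alpha, sv_index = sv, b = -s * fit$rho,
                 C = C, labels = labels, n = n),
            class = "svm_model")
}

#' Decision values for new samples from their kernel rows
#'
#' @param model an [train_svm()] model.
#' @param k_new `m x n_train` matrix of kernel values between new samples
#'   and the training samples (a row subset of the full Gram matrix).
#' @return numeric decision values; positive means the +1 class.
#' @export
svm_decision <- function(model, k_new) {
  stopifnot(inherits(model, "svm_model"))
  if (is.vector(k_new)) k_new <- matrix(k_new, nrow = 1L)
  stopifnot(ncol(k_new) == model$n)
  as.vector(k_new[, model$sv_index, drop = FALSE] %*% model$alpha) + model$b
}

#' Voxelwise SVM discrimination map
#'
#' Maps the primal weight vector `w = sum_i alpha_i x_i` of a trained
#' linear-kernel model back onto the brain grid. Positive weights push the
#' decision towards the patient class, negative towards controls; the map
#' is a spatial representation of the decision boundary.
#'
#' @param model an [train_svm()] model trained on `features`.
#' @param features the [cohort_features()] the model was trained on.
#' @return an object of class `discrimination_map`: `values` (3D array),
#'   `w` (vector over feature columns), `mask`, `kind`.
#' @export
discrimination_map <- function(model, features) {
  stopifnot(inherits(model, "svm_model"),
            inherits(features, "cohort_features"),
            model$n == nrow(features$x))
  w <- as.vector(crossprod(features$x[model$sv_index, , drop = FALSE],
                           model$alpha))
  grid <- array(0, dim = dim(features$mask))
  grid[features$voxel_index] <- w
  structure(list(values = grid, w = w, mask = features$mask,
                 kind = features$kind),
            class = "discrimination_map")
}

#' Threshold a discrimination map at a fraction of its maximum
#'
#' Retains voxels whose absolute weight strictly exceeds
#' `fraction * max(|w|)`; signs are preserved in the thresholded values.
#' This is the display convention that suppresses noise components and
#' highlights the most discriminating regions.
#'
#' @param map a [discrimination_map()].
#' @param fraction threshold fraction of the maximum absolute weight.
#' @return list with `retained` (logical 3D array), `values` (thresholded
#'   signed weights), `fraction`, `cutoff`.
#' @export
threshold_map <- function(map, fraction = 0.30) {
  stopifnot(inherits(map, "discrimination_map"), fraction > 0, fraction <= 1)
  mx <- max(abs(map$w))
  if (mx == 0) stop("discrimination map is identically zero")
  cutoff <- fraction * mx
  retained <- abs(map$values) > cutoff & map$mask
  vals <- map$values
  vals[!retained] <- 0
  list(retained = retained, values = vals, fraction = fraction,
       cutoff = cutoff)
}

#' Classification performance from per-subject predictions
#'
#' Confusion counts and percentage metrics over patients (+1) and controls
#' (-1): sensitivity is the patient recall `TP / (TP + FN)`, specificity the
#' control recall `TN / (TN + FP)`, accuracy their case-weighted average.
#'
#' @param predictions vector of +1 / -1 predicted labels.
#' @param labels vector of +1 / -1 true labels.
#' @return list with `tp`, `fn`, `tn`, `fp` and `accuracy`, `sensitivity`,
#'   `specificity` in percent (exact values; round to 2 decimals for
#'   reporting).
#' @export
score <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels),
            all(predictions %in% c(-1L, 1L)), all(labels %in% c(-1L, 1L)))
  tp <- sum(predictions == 1 & labels == 1)
  fn <- sum(predictions == -1 & labels == 1)
  tn <- sum(predictions == -1 & labels == -1)
  fp <- sum(predictions == 1 & labels == -1)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Area under the ROC curve from decision values
#'
#' Mann-Whitney formulation: the probability that a random patient's
#' decision value exceeds a random control's, ties counted one half.
#'
#' @param decision_values numeric vector.
#' @param labels +1 / -1 true labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(decision_values, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(decision_values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

default_pairing <- function(labels) {
  pat <- which(labels == 1)
  ctl <- which(labels == -1)
  if (length(pat) != length(ctl))
    stop("leave-one-pair-out needs equal group sizes, or an explicit pairing")
  cbind(patient = pat, control = ctl)
}

# LOOCV over subject pairs on a precomputed kernel; the kernel is computed
# once and sub-indexed per fold.
loocv_kernel <- function(kernel, labels, C = 1, pairing = default_pairing(labels)) {
  n <- length(labels)
  predictions <- integer(n)
  decisions <- numeric(n)
  for (f in seq_len(nrow(pairing))) {
    test <- pairing[f, ]
    train <- setdiff(seq_len(n), test)
    model <- train_svm(kernel[train, train, drop = FALSE], labels[train], C)
    d <- svm_decision(model, kernel[test, train, drop = FALSE])
    decisions[test] <- d
    predictions[test] <- ifelse(d >= 0, 1L, -1L)
  }
  list(predictions = predictions, decisions = decisions, pairing = pairing)
}

#' Leave-one-pair-out cross-validation
#'
#' Excludes one subject from each group per fold, trains the linear-kernel
#' SVM on the remaining subjects and predicts the held-out pair, so every
#' subject is predicted exactly once. Pairing defaults to the i-th patient
#' with the i-th control in cohort order; under exchangeable subjects the
#' choice is immaterial, and an explicit pairing can be supplied.
#'
#' @param features a [cohort_features()] object (or numeric matrix).
#' @param labels +1 / -1 labels (taken from `features` when available).
#' @param C soft-margin cost.
#' @param pairing optional 2-column matrix of (patient, control) index
#'   pairs covering each group exactly once.
#' @return an object of class `cv_report`: per-subject `predictions` and
#'   `decision_values`, confusion counts and percentage metrics from
#'   [score()], `auc`, `n_folds`, `C`, ids and labels.
#' @export
loocv_pairs <- function(features, labels = NULL, C = 1, pairing = NULL) {
  x <- if (inherits(features, "cohort_features")) features$x else features
  if (is.null(labels) && inherits(features, "cohort_features"))
    labels <- features$labels
  labels <- as.integer(labels)
  if (is.null(pairing)) pairing <- default_pairing(labels)
  kernel <- linear_kernel(x)
  cv <- loocv_kernel(kernel, labels, C, pairing)
  metrics <- score(cv$predictions, labels)
  structure(c(list(predictions = cv$predictions,
                   decision_values = cv$decisions,
                   labels = labels,
                   ids = if (inherits(features, "cohort_features"))
                     features$ids else NULL,
                   auc = roc_auc(cv$decisions, labels),
                   n_folds = nrow(pairing), C = C),
              metrics),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report> %d folds: accuracy %.2f%%, sensitivity %.2f%%, ",
                     "specificity %.2f%%, AUC %.3f\n"),
              x$n_folds, x$accuracy, x$sensitivity, x$specificity, x$auc))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  invisible(x)
}

#' Permutation test of classifier significance
#'
#' Repeats the full leave-one-pair-out procedure under random permutations
#' of the group labels and compares the permuted performance with the
#' observed one. With `statistic = "accuracy"` a permutation counts against
#' the observed result when its accuracy is at least as high; with
#' `"joint"` it must reach both the observed sensitivity and the observed
#' specificity. The p-value uses the add-one estimator
#' `(1 + #better) / (1 + n_perm)`.
#'
#' @inheritParams loocv_pairs
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @param statistic `"accuracy"` or `"joint"`.
#' @return the observed `cv_report` with `p_value`, `n_permutations`,
#'   `perm_statistic` and `seed` fields added.
#' @export
permutation_test <- function(features, labels = NULL, C = 1, n_perm = 1000,
                             seed = 1L, statistic = c("accuracy", "joint"),
                             pairing = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1)
  x <- if (inherits(features, "cohort_features")) features$x else features
  if (is.null(labels) && inherits(features, "cohort_features"))
    labels <- features$labels
  labels <- as.integer(labels)
  if (is.null(pairing)) pairing <- default_pairing(labels)
  kernel <- linear_kernel(x)

  observed <- loocv_pairs(features, labels, C, pairing)
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    perm_pairing <- default_pairing(perm)
    cv <- loocv_kernel(kernel, perm, C, perm_pairing)
    m <- score(cv$predictions, perm)
    hit <- if (statistic == "accuracy") m$accuracy >= observed$accuracy
           else m$sensitivity >= observed$sensitivity &&
                m$specificity >= observed$specificity
    if (isTRUE(hit)) count <- count + 1L
  }
  observed$p_value <- (1 + count) / (1 + n_perm)
  observed$n_permutations <- as.integer(n_perm)
  observed$perm_statistic <- statistic
  observed$seed <- as.integer(seed)
  observed
}
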