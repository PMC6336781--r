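test_that("the linear kernel is the Gram matrix of subject rows", {
  x <- rbind(c(1, 0), c(0, 2))
  expect_equal(linear_kernel(x), matrix(c(1, 0, 0, 4), 2))

  set.seed(20)
  x2 <- matrix(rnorm(8 * 5), 8)
  x2[3, ] <- x2[1, ]
  k <- linear_kernel(x2)
  expect_equal(k, t(k))
  expect_equal(k[1, ], k[3, ])
  expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8 * sum(diag(k)))

  x2[1, 1] <- NA
  expect_error(linear_kernel(x2), "finite")
})

test_that("the dual solution satisfies its constraints and separates separable data", {
  x <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  labels <- c(-1L, -1L, 1L, 1L)
  model <- train_svm(linear_kernel(x), labels, C = 1e4)
  dec <- svm_decision(model, linear_kernel(x))
  expect_true(all(sign(dec) == labels))
  expect_lt(abs(sum(model$alpha)), 1e-6)                 # sum alpha_i y_i = 0
  a <- model$alpha * model$labels[model$sv_index]         # raw multipliers
  expect_true(all(a >= -1e-8 & a <= 1e4 + 1e-8))
  expect_error(train_svm(linear_kernel(x), rep(1L, 4)), "both classes")
})

test_that("kernel decisions equal primal decisions through the weight map", {
  set.seed(21)
  for (i in 1:10) {
    gf <- gaussian_features(6, 12, shift = 3)
    k <- linear_kernel(gf$x)
    model <- train_svm(k, gf$labels, C = 1)
    w <- as.vector(crossprod(gf$x[model$sv_index, , drop = FALSE],
                             model$alpha))
    primal <- as.vector(gf$x %*% w) + model$b
    expect_lt(max(abs(primal - svm_decision(model, k))), 1e-8)
  }
})

test_that("flipping all labels flips the decision values", {
  set.seed(22)
  gf <- gaussian_features(5, 8, shift = 2)
  k <- linear_kernel(gf$x)
  d1 <- svm_decision(train_svm(k, gf$labels), k)
  d2 <- svm_decision(train_svm(k, -gf$labels), k)
  expect_equal(d1, -d2, tolerance = 1e-6)
})

test_that("the dual solution agrees with an independent kernel solver", {
  skip_if_not_installed("kernlab")
  set.seed(23)
  gf <- gaussian_features(8, 10, shift = 2.5)
  k <- linear_kernel(gf$x)
  model <- train_svm(k, gf$labels, C = 1)
  ours <- svm_decision(model, k)
  ref <- kernlab::ksvm(kernlab::as.kernelMatrix(k),
                       factor(gf$labels, levels = c(-1, 1)),
                       type = "C-svc", C = 1, scaled = FALSE)
  theirs <- kernlab::predict(
    ref, kernlab::as.kernelMatrix(k[, kernlab::SVindex(ref), drop = FALSE]),
    type = "decision")[, 1]
  if (stats::cor(ours, theirs) < 0) theirs <- -theirs   # solver's internal sign
  expect_gt(stats::cor(ours, theirs), 0.999)
  expect_true(all(sign(ours) == sign(theirs)))
})

test_that("leave-one-pair-out predicts every subject exactly once", {
  set.seed(24)
  gf <- gaussian_features(7, 15, shift = 2)
  cv <- loocv_pairs(gf$x, gf$labels)
  expect_equal(cv$n_folds, 7L)
  expect_length(cv$predictions, 14L)
  expect_true(all(cv$predictions %in% c(-1L, 1L)))
  expect_equal(cv$tp + cv$fn + cv$tn + cv$fp, 14)
  expect_error(loocv_pairs(gf$x[1:13, ], gf$labels[1:13]), "equal group")
})

test_that("a strongly separated cohort is classified perfectly", {
  set.seed(25)
  gf <- gaussian_features(10, 20, shift = 4)
  cv <- loocv_pairs(gf$x, gf$labels)
  expect_equal(cv$accuracy, 100)
  expect_equal(cv$auc, 1)
})

test_that("metrics recover printed performance triplets from counts", {
  all_right <- score(rep(c(1L, -1L), each = 5), rep(c(1L, -1L), each = 5))
  expect_equal(all_right$accuracy, 100)
  expect_equal(all_right$sensitivity, 100)
  expect_equal(all_right$specificity, 100)

  labels <- rep(c(1L, -1L), each = 54)
  pred <- c(rep(1L, 52), rep(-1L, 2), rep(-1L, 51), rep(1L, 3))
  m <- score(pred, labels)
  expect_equal(round(m$sensitivity, 2), 96.30)
  expect_equal(round(m$specificity, 2), 94.44)
  expect_equal(round(m$accuracy, 2), 95.37)

  pred2 <- c(rep(1L, 40), rep(-1L, 14), rep(-1L, 40), rep(1L, 14))
  m2 <- score(pred2, labels)
  expect_equal(round(m2$accuracy, 2), 74.07)
  expect_equal(round(m2$sensitivity, 2), 74.07)
  expect_equal(round(m2$specificity, 2), 74.07)
})

test_that("accuracy is the case-weighted average of sensitivity and specificity", {
  set.seed(26)
  for (i in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    labels <- rep(c(1L, -1L), c(n1, n2))
    pred <- sample(c(-1L, 1L), n1 + n2, replace = TRUE)
    m <- score(pred, labels)
    expect_equal(m$accuracy,
                 (m$sensitivity * n1 + m$specificity * n2) / (n1 + n2),
                 tolerance = 1e-12)
  }
})

test_that("AUC follows the Mann-Whitney convention with ties at one half", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, -1, -1)), 1)
  expect_equal(roc_auc(c(0, 1, 2, 3), c(1, 1, -1, -1)), 0)
  expect_equal(roc_auc(c(2, 0, 1, -1), c(1, 1, -1, -1)), 0.75)
  expect_equal(roc_auc(c(1, 1, 1, 1), c(1, 1, -1, -1)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC matches an independent implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(27)
  labels <- rep(c(1L, -1L), each = 20)
  dec <- round(rnorm(40) + labels, 1)    # rounding forces some ties
  ours <- roc_auc(dec, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, dec, quiet = TRUE,
                                        direction = "<", levels = c(-1, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(roc_auc(exp(dec), labels), ours, tolerance = 1e-12)
})

test_that("permutation p-values behave at the extremes and reproduce bit-exactly", {
  set.seed(28)
  gf <- gaussian_features(6, 10, shift = 5)
  r1 <- permutation_test(gf$x, gf$labels, n_perm = 49, seed = 99)
  r2 <- permutation_test(gf$x, gf$labels, n_perm = 49, seed = 99)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$accuracy, 100)
  # the observed labelling beats every permutation except structural ties:
  # sampling the label complement reproduces 100% accuracy exactly
  expect_gte(r1$p_value, 1 / 50)
  expect_lte(r1$p_value, 5 / 50)

  const <- matrix(1, 8, 4)              # no signal at all: every labelling ties
  labels <- rep(c(1L, -1L), each = 4)
  r3 <- permutation_test(const + 1e-9 * rnorm(32), labels, n_perm = 19,
                         seed = 1)
  expect_gte(r3$p_value, 0.5)
})

test_that("the joint sensitivity-and-specificity statistic is supported", {
  set.seed(29)
  gf <- gaussian_features(6, 10, shift = 4)
  r <- permutation_test(gf$x, gf$labels, n_perm = 19, seed = 5,
                        statistic = "joint")
  expect_equal(r$perm_statistic, "joint")
  expect_lte(r$p_value, 0.1)
})

test_that("discrimination maps recover informative voxels and respect identities", {
  set.seed(30)
  dims <- c(3, 3, 2)
  mask <- array(TRUE, dims)
  n <- 8
  maps <- vector("list", 2 * n)
  groups <- rep(c("patient", "control"), each = n)
  for (i in seq_len(2 * n)) {
    v <- array(rnorm(prod(dims), sd = 0.1), dims)
    if (groups[i] == "patient") v[2, 2, 1] <- v[2, 2, 1] + 3
    maps[[i]] <- parameter_map(v, "alff", "smoothed", mask)
  }
  feats <- cohort_features(maps, groups)
  model <- train_svm(linear_kernel(feats), feats$labels, C = 1)
  dmap <- discrimination_map(model, feats)
  informative <- which(as.vector(mask))[
    (2 - 1) + (2 - 1) * 3 + (1 - 1) * 9 + 1]
  expect_equal(which.max(abs(dmap$values)), informative)
  expect_gt(dmap$values[2, 2, 1], 0)    # patient-directed weight is positive

  k <- linear_kernel(feats)
  expect_lt(max(abs(as.vector(feats$x %*% dmap$w) + model$b -
                      svm_decision(model, k))), 1e-8)
})

test_that("identical features with opposite labels cancel in the weight map", {
  x <- matrix(rep(c(1, 2, 3, 4), 4), 4, byrow = TRUE)
  labels <- c(1L, 1L, -1L, -1L)
  model <- train_svm(linear_kernel(x), labels, C = 1)
  w <- crossprod(x[model$sv_index, , drop = FALSE], model$alpha)
  expect_lt(max(abs(w)), 1e-8)
})

test_that("map thresholding keeps strict suprathreshold weights with sign", {
  dims <- c(4, 1, 1)
  mask <- array(TRUE, dims)
  dmap <- structure(list(values = array(c(10, 4, -5, 2), dims),
                         w = c(10, 4, -5, 2), mask = mask, kind = "alff"),
                    class = "discrimination_map")
  th <- threshold_map(dmap, 0.30)
  expect_identical(as.vector(th$retained), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(as.vector(th$values), c(10, 4, -5, 0))

  flat <- structure(list(values = array(2, dims), w = rep(2, 4), mask = mask,
                         kind = "alff"), class = "discrimination_map")
  expect_true(all(threshold_map(flat, 0.30)$retained))
  expect_false(any(threshold_map(flat, 1)$retained))   # strict inequality

  zero <- structure(list(values = array(0, dims), w = rep(0, 4), mask = mask,
                         kind = "alff"), class = "discrimination_map")
  expect_error(threshold_map(zero), "zero")
})
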