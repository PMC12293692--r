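test_that("rank-1 data put all variance on the first component and reconstruct exactly", {
  grid <- seq(1300, 1318, by = 2)
  shape <- gaussian_spectrum(grid, 1310, sigma = 4)
  mat <- outer(c(1, 2, 3, 5), shape)
  p <- fit_pca(mean_center(spectra_from_matrix(mat, grid)))
  expect_equal(p$explained_variance_ratio[1], 1, tolerance = 1e-10)
  # SVD identity: full reconstruction of the centered matrix
  centered <- sweep(mat, 2, colMeans(mat))
  expect_equal(p$scores %*% t(p$loadings), centered,
               ignore_attr = TRUE, tolerance = 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("explained-variance ratios match an exactly known covariance", {
  # four points whose sample covariance is diag(2, 1) * 2/3:
  # eigen ratios 2/3 and 1/3 exactly
  mat <- rbind(c(sqrt(2), 0), c(-sqrt(2), 0), c(0, 1), c(0, -1))
  p <- fit_pca(mean_center(spectra_from_matrix(mat, c(1300, 1302))))
  expect_equal(p$explained_variance_ratio, c(2 / 3, 1 / 3),
               tolerance = 1e-10)
})

test_that("SVD variance ratios agree with brute-force covariance eigenvalues", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    p_dim <- sample(2:20, 1)
    mat <- matrix(rnorm(n * p_dim), n, p_dim)
    grid <- seq(1300, by = 2, length.out = p_dim)
    model <- fit_pca(mean_center(spectra_from_matrix(mat, grid)))
    ev <- eigen(stats::cov(mat), symmetric = TRUE)$values
    ratios <- ev[ev > 1e-12] / sum(ev)
    k <- length(model$explained_variance_ratio)
    expect_equal(model$explained_variance_ratio[seq_len(min(k, length(ratios)))],
                 ratios[seq_len(min(k, length(ratios)))], tolerance = 1e-8)
  }
})

test_that("component counting by cumulative variance and its failure modes", {
  fake <- structure(list(explained_variance_ratio = c(0.74, 0.15, 0.11)),
                    class = "pca_model")
  expect_equal(n_components_for_variance(fake, 0.85), 2)
  expect_equal(n_components_for_variance(fake, 0.74), 1)
  expect_equal(n_components_for_variance(fake, 1.0), 3)
  one <- structure(list(explained_variance_ratio = 1.0), class = "pca_model")
  expect_equal(n_components_for_variance(one, 0.9999), 1)
  partial <- structure(list(explained_variance_ratio = c(0.5, 0.3)),
                       class = "pca_model")
  expect_error(n_components_for_variance(partial, 0.9), "unreachable")
  expect_error(n_components_for_variance(fake, 0), "in \\(0, 1]")
})

test_that("degenerate all-identical data refuse a PCA", {
  mat <- matrix(1, nrow = 4, ncol = 3)
  s <- spectra_from_matrix(mat, c(1300, 1302, 1304))
  expect_error(fit_pca(mean_center(s)), "variance is zero")
})

test_that("duplicating a wavelength only adds its own contribution to score geometry", {
  set.seed(7)
  mat <- matrix(rnorm(40), 8, 5)
  grid <- seq(1300, 1308, by = 2)
  p0 <- fit_pca(mean_center(spectra_from_matrix(mat, grid)))
  # all-component scores preserve pairwise distances of centered rows
  centered <- sweep(mat, 2, colMeans(mat))
  expect_equal(as.matrix(dist(p0$scores)), as.matrix(dist(centered)),
               ignore_attr = TRUE, tolerance = 1e-8)
  # duplicated column: squared distances grow by exactly that column's part
  dup <- cbind(mat, mat[, 5])
  p1 <- fit_pca(mean_center(spectra_from_matrix(dup, c(grid, 1310))))
  d0 <- as.matrix(dist(p0$scores))^2
  d1 <- as.matrix(dist(p1$scores))^2
  extra <- as.matrix(dist(centered[, 5, drop = FALSE]))^2
  expect_equal(d1, d0 + extra, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("LDA matches the closed-form pooled-covariance solution and MASS", {
  skip_if_not_installed("MASS")
  set.seed(21)
  n <- 60
  sigma <- matrix(c(1, 0.4, 0.4, 2), 2)
  ch <- chol(sigma)
  x1 <- matrix(rnorm(2 * n), n) %*% ch
  x2 <- sweep(matrix(rnorm(2 * n), n) %*% ch, 2, c(-2, 1.5), `+`)
  scores <- rbind(x1, x2)
  labels <- rep(c("Passed", "Failed"), each = n)

  model <- fit_lda(scores, labels)
  # closed form computed independently in the test
  mu_p <- colMeans(x1); mu_f <- colMeans(x2)
  pooled <- (crossprod(sweep(x1, 2, mu_p)) + crossprod(sweep(x2, 2, mu_f))) /
    (2 * n - 2)
  w_closed <- solve(pooled, mu_p - mu_f)
  w_model <- model$pooled_inverse %*% (model$class_means["Passed", ] -
                                         model$class_means["Failed", ])
  expect_equal(as.numeric(w_model), as.numeric(w_closed), tolerance = 1e-6)
  expect_equal(model$priors, c(0.5, 0.5))
  expect_true(isSymmetric(model$pooled_covariance))
  expect_true(all(eigen(model$pooled_covariance)$values > 0))

  # independent oracle: MASS::lda predicts the same labels
  mass_fit <- MASS::lda(scores, grouping = labels)
  mass_pred <- as.character(predict(mass_fit, scores)$class)
  expect_equal(predict_lda(model, scores), mass_pred)
})

test_that("separable clouds classify perfectly; identical clouds follow the prior", {
  scores <- matrix(c(rnorm(20, -5, 0.1), rnorm(20, 5, 0.1)), ncol = 1)
  labels <- rep(c("Failed", "Passed"), each = 20)
  model <- fit_lda(scores, labels)
  expect_equal(predict_lda(model, scores), labels)
  # training centroids map to their own class
  expect_equal(predict_lda(model, model$class_means), model$classes)

  # uninformative features: identical class distributions collapse the
  # discriminant to the prior, so everything goes to the larger class
  v <- seq(-1, 1, length.out = 10)
  same <- matrix(c(v, v, v), ncol = 1)
  lab2 <- rep(c("Passed", "Failed"), c(20, 10))
  m2 <- fit_lda(same, lab2)
  expect_true(all(predict_lda(m2, matrix(seq(-3, 3, 0.5), ncol = 1)) ==
                    "Passed"))

  expect_error(fit_lda(matrix(rnorm(3), ncol = 1), c("A", "B", "B")),
               "fewer than two")
})

test_that("midpoint ties break to the lexicographically smaller label", {
  scores <- matrix(c(-1, -1.5, -0.5, 1, 1.5, 0.5), ncol = 1)
  labels <- rep(c("Failed", "Passed"), each = 3)
  model <- fit_lda(scores, labels)  # equal priors, symmetric clouds
  expect_equal(predict_lda(model, matrix(0, 1, 1)), "Failed")
})

test_that("LDA predictions are invariant to a shared invertible affine map", {
  set.seed(13)
  train <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 2), 20))
  labels <- rep(c("Failed", "Passed"), each = 20)
  test <- matrix(rnorm(30, 1), ncol = 2)
  a <- matrix(c(2, 0.5, -1, 1.5), 2)
  b <- c(3, -7)
  f <- function(x) sweep(x %*% t(a), 2, b, `+`)
  p0 <- predict_lda(fit_lda(train, labels), test)
  p1 <- predict_lda(fit_lda(f(train), labels), f(test))
  expect_equal(p1, p0)
})

test_that("predict_lda validates the score dimension", {
  model <- fit_lda(matrix(rnorm(20), ncol = 2),
                   rep(c("A", "B"), each = 5))
  expect_error(predict_lda(model, matrix(1, 1, 3)), "features")
})

test_that("cross-validation keeps samples whole, conserves counts and separates a clean design", {
  cfg <- small_cfg(n_passed = 8, n_failed = 8, seed = 2L)
  s <- average_replicates(simulate_sp_spectra(cfg))
  cm <- cross_validate_pca_lda(s, folds = 4, seed = 1)
  expect_equal(sum(cm), 16)
  # strongly planted effects: perfect separation off the diagonal
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0)
  # replicate-level rows: all replicates of a sample share a fold
  s_rep <- simulate_sp_spectra(cfg)
  cm_rep <- cross_validate_pca_lda(s_rep, folds = 4, seed = 1)
  preds <- attr(cm_rep, "predictions")
  fold_per_sample <- dplyr::summarise(
    dplyr::group_by(preds, sample_id),
    n_folds = dplyr::n_distinct(fold), .groups = "drop")
  expect_true(all(fold_per_sample$n_folds == 1))
  expect_equal(sum(cm_rep), 16 * cfg$replicates_per_sample)
})

test_that("held-out rows cannot influence the trained models", {
  cfg <- small_cfg(n_passed = 6, n_failed = 6, seed = 8L)
  s <- average_replicates(simulate_sp_spectra(cfg))
  cm0 <- cross_validate_pca_lda(s, folds = 2, seed = 3)
  # poison one sample's spectrum with an enormous outlier: its co-fold
  # samples are predicted by a model trained without it, so their
  # predictions must not move (in the other fold it is training data)
  poisoned <- s
  victim <- "P01"
  poisoned$value[poisoned$sample_id == victim] <- 1e6
  cm1 <- cross_validate_pca_lda(poisoned, folds = 2, seed = 3)
  p0 <- attr(cm0, "predictions")
  p1 <- attr(cm1, "predictions")
  victim_fold <- p0$fold[p0$sample_id == victim][1]
  cofold <- p0$sample_id[p0$fold == victim_fold & p0$sample_id != victim]
  keep0 <- dplyr::arrange(dplyr::filter(p0, sample_id %in% cofold), sample_id)
  keep1 <- dplyr::arrange(dplyr::filter(p1, sample_id %in% cofold), sample_id)
  expect_gt(length(cofold), 0)
  expect_equal(keep1, keep0)
})

test_that("permuted labels drop accuracy to the majority-class rate", {
  cfg <- small_cfg(n_passed = 8, n_failed = 8, replicates_per_sample = 1,
                   seed = 6L)
  s <- average_replicates(simulate_sp_spectra(cfg))
  samples <- dplyr::distinct(s[c("sample_id", "group")])
  acc <- vapply(1:20, function(i) {
    set.seed(100 + i)
    relabel <- setNames(sample(samples$group), samples$sample_id)
    s_perm <- dplyr::mutate(s, group = unname(relabel[sample_id]))
    cm <- cross_validate_pca_lda(s_perm, folds = 4, seed = i)
    confusion_metrics(cm)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(acc) - 50), 15)
})

test_that("cross-validation errors when a training fold loses a class", {
  cfg <- small_cfg(n_passed = 6, n_failed = 2, replicates_per_sample = 1)
  s <- average_replicates(simulate_sp_spectra(cfg))
  # 2 folds over 8 samples: the Failed samples land together in one fold
  # (training fold empty of the class) or split 1/1 (too few to fit)
  expect_error(
    cross_validate_pca_lda(s, folds = 2, seed = 5),
    "missing a class|fewer than two")
})

test_that("confusion metrics follow their defining formulas", {
  cm <- aquasem:::new_confusion_matrix(
    truth = c(rep("Passed", 33), rep("Failed", 31)),
    pred = c(rep("Passed", 31), rep("Failed", 2),
             rep("Failed", 28), rep("Passed", 3)))
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy, 100 * 59 / 64)          # 92.1875
  expect_equal(m$sensitivity, 93.94, tolerance = 1e-3)
  expect_equal(m$specificity, 90.32, tolerance = 1e-3)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(31, 2, 28, 3))

  perfect <- aquasem:::new_confusion_matrix(
    rep(c("Passed", "Failed"), each = 10),
    rep(c("Passed", "Failed"), each = 10))
  mp <- confusion_metrics(perfect)
  expect_equal(c(mp$accuracy, mp$sensitivity, mp$specificity),
               c(100, 100, 100))

  # no positives at all: sensitivity undefined, not zero
  none <- aquasem:::new_confusion_matrix(
    rep("Failed", 5), rep(c("Failed", "Passed"), c(4, 1)))
  expect_true(is.na(confusion_metrics(none)$sensitivity))
})

test_that("tidiers expose model summaries as tibbles", {
  cfg <- small_cfg(seed = 15L)
  s <- average_replicates(simulate_sp_spectra(cfg))
  p <- fit_pca(mean_center(s))
  td <- tidy(p)
  expect_equal(td$cumulative_variance, cumsum(td$explained_variance_ratio))
  expect_equal(glance(p)$n_obs, 12)
  cm <- cross_validate_pca_lda(s, folds = 4, seed = 2)
  expect_equal(sum(tidy(cm)$n), sum(cm))
  expect_equal(glance(cm)$accuracy, confusion_metrics(cm)$accuracy)
})
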