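#' Principal component analysis of a centered spectra matrix
#'
#' PCA by singular value decomposition of the mean-centered matrix.
#' Components are ordered by decreasing singular value and the sign of
#' each loading vector is fixed so that its largest-magnitude element is
#' positive, which makes scores and loading plots reproducible.
#'
#' @param m A `centered_spectra` object from [mean_center()].
#' @param max_components Maximum number of components to retain; must not
#'   exceed `min(rows - 1, cols)`. Default keeps all.
#' @return An object of class `pca_model` with `loadings` (wavelengths x
#'   components), `scores` (observations x components),
#'   `explained_variance_ratio`, `column_means`, `row_labels` and `grid`.
#' @examples
#' s <- simulate_sp_spectra(sim_config(n_passed = 4, n_failed = 4,
#'                                     replicates_per_sample = 1))
#' p <- fit_pca(mean_center(s))
#' glance(p)
#' @export
fit_pca <- function(m, max_components = NULL) {
  stopifnot(inherits(m, "centered_spectra"))
  x <- m$matrix
  limit <- min(nrow(x) - 1L, ncol(x))
  if (is.null(max_components)) max_components <- limit
  if (max_components < 1 || max_components > limit) {
    abort(sprintf("max_components must be in [1, %d] for %d x %d data",
                  limit, nrow(x), ncol(x)))
  }
  sv <- svd(x, nu = max_components, nv = max_components)
  d <- sv$d
  total <- sum(d^2)
  if (total <= 0) {
    abort("all observations are identical: spectral variance is zero")
  }
  k <- max_components
  loadings <- sv$v
  scores <- sv$u %*% diag(d[seq_len(k)], nrow = k)
  # sign convention: largest-magnitude loading element positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  structure(list(
    loadings = loadings,
    scores = scores,
    explained_variance_ratio = d[seq_len(k)]^2 / total,
    column_means = m$column_means,
    row_labels = m$row_labels,
    grid = m$grid
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- length(x$explained_variance_ratio)
  cat(sprintf("<pca_model: %d components; PC1 %.1f%%, PC2 %s of variance>\n",
              k, 100 * x$explained_variance_ratio[1],
              if (k > 1) sprintf("%.1f%%", 100 * x$explained_variance_ratio[2])
              else "-"))
  invisible(x)
}

#' Smallest number of components reaching a cumulative variance threshold
#'
#' @param p A `pca_model`.
#' @param threshold Cumulative explained-variance fraction in (0, 1].
#' @return The smallest `k` whose first `k` components explain at least
#'   `threshold` of the variance.
#' @export
n_components_for_variance <- function(p, threshold) {
  stopifnot(inherits(p, "pca_model"))
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  cum <- cumsum(p$explained_variance_ratio)
  k <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k)) {
    abort(sprintf(
      "threshold %g unreachable: %d available components explain %.6f",
      threshold, length(cum), cum[length(cum)]))
  }
  k
}

# project new observations into an existing PCA space using the training
# column means (no refitting, no leakage)
project_pca <- function(p, mat, k = NULL) {
  stopifnot(inherits(p, "pca_model"))
  if (is.null(k)) k <- ncol(p$loadings)
  sweep(mat, 2, p$column_means) %*% p$loadings[, seq_len(k), drop = FALSE]
}

#' Linear discriminant analysis with pooled within-class covariance
#'
#' Classic LDA: class centroids, a pooled (shared) within-class covariance
#' estimate and empirical class priors. If the pooled covariance is
#' numerically singular a small ridge (`1e-8 * trace / dim`) is added to
#' its diagonal and a warning is issued.
#'
#' @param scores Numeric matrix of observations by features (typically PCA
#'   scores).
#' @param labels Class label per observation; at least two classes with at
#'   least two observations each.
#' @return An object of class `lda_model` with `class_means`,
#'   `pooled_covariance`, `priors` and `classes` (sorted label set).
#' @export
fit_lda <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (nrow(scores) != length(labels)) {
    abort("scores and labels must have matching length")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("LDA requires at least two classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) {
    abort(sprintf("class '%s' has fewer than two observations",
                  names(counts)[which(counts < 2)[1]]))
  }
  k <- ncol(scores)
  class_means <- matrix(0, length(classes), k,
                        dimnames = list(classes, colnames(scores)))
  for (cl in classes) {
    class_means[cl, ] <- colMeans(scores[labels == cl, , drop = FALSE])
  }
  pooled <- matrix(0, k, k)
  for (cl in classes) {
    xc <- scores[labels == cl, , drop = FALSE]
    xc <- sweep(xc, 2, class_means[cl, ])
    pooled <- pooled + crossprod(xc)
  }
  pooled <- pooled / (nrow(scores) - length(classes))
  inv <- tryCatch(solve(pooled), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    ridge <- 1e-8 * sum(diag(pooled)) / k
    warn(sprintf(
      "pooled covariance singular; adding ridge %.3g to the diagonal", ridge),
      class = "aquasem_ridge")
    pooled <- pooled + diag(ridge, k)
    inv <- solve(pooled)
  }
  structure(list(
    class_means = class_means,
    pooled_covariance = pooled,
    pooled_inverse = inv,
    priors = as.numeric(counts) / length(labels),
    classes = classes
  ), class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model: classes %s; priors %s; %d features>\n",
              paste(x$classes, collapse = "/"),
              paste(sprintf("%.3f", x$priors), collapse = "/"),
              ncol(x$class_means)))
  invisible(x)
}

#' Predict class labels from a fitted LDA model
#'
#' Assigns each observation to the class with the maximal linear
#' discriminant value; exact ties go to the lexicographically smaller
#' label.
#'
#' @param model An `lda_model`.
#' @param scores Matrix of observations by features, matching the model's
#'   feature dimension.
#' @return Character vector of predicted labels.
#' @export
predict_lda <- function(model, scores) {
  stopifnot(inherits(model, "lda_model"))
  scores <- as.matrix(scores)
  if (ncol(scores) != ncol(model$class_means)) {
    abort(sprintf("model has %d features but scores have %d",
                  ncol(model$class_means), ncol(scores)))
  }
  inv <- model$pooled_inverse
  disc <- vapply(seq_along(model$classes), function(g) {
    mu <- model$class_means[g, ]
    w <- inv %*% mu
    drop(scores %*% w) - 0.5 * drop(crossprod(mu, w)) + log(model$priors[g])
  }, numeric(nrow(scores)))
  disc <- matrix(disc, nrow = nrow(scores))
  # classes are sorted, so the first maximal column is the tie-break label
  model$classes[apply(disc, 1, which.max)]
}

#' Cross-validated PCA-LDA classification of spectra
#'
#' Random k-fold cross-validation with folds grouped by `sample_id`, so
#' that all replicate scans of one sample fall into the same fold. Inside
#' each fold the held-out rows touch nothing: centering, PCA, the
#' component count (smallest number of PCs reaching
#' `variance_threshold` cumulative explained variance) and the LDA are all
#' derived from the training rows only. Default is leave-one-sample-out
#' ("full" cross-validation).
#'
#' @param s A spectra tibble in absorbance mode with groups Passed/Failed
#'   (any two class labels work).
#' @param folds Number of folds; default = number of samples
#'   (leave-one-sample-out).
#' @param variance_threshold Cumulative explained-variance fraction used
#'   to pick the number of PCs inside each training fold (default 0.9999).
#' @param seed Integer seed for the random fold assignment.
#' @param positive_class Label treated as positive when deriving
#'   sensitivity (default `"Passed"`).
#' @return A `confusion_matrix` object: 2x2 integer counts
#'   (true class x predicted class) with attributes `positive_class`,
#'   `fold_k` (components used per fold) and `seed`.
#' @examples
#' s <- simulate_sp_spectra(sim_config(n_passed = 8, n_failed = 8,
#'                                     replicates_per_sample = 2))
#' cm <- cross_validate_pca_lda(average_replicates(s), folds = 4, seed = 1)
#' confusion_metrics(cm)
#' @export
cross_validate_pca_lda <- function(s, folds = NULL,
                                   variance_threshold = 0.9999,
                                   seed = 1L,
                                   positive_class = "Passed") {
  sm <- spectra_matrix(s)
  samples <- dplyr::distinct(sm$meta[c("sample_id", "group")])
  n_samples <- nrow(samples)
  classes <- sort(unique(samples$group))
  if (length(classes) != 2) {
    abort("cross-validation requires exactly two classes")
  }
  if (is.null(folds)) folds <- n_samples
  if (folds < 2 || folds > n_samples) {
    abort(sprintf("folds must be in [2, %d]", n_samples))
  }
  set.seed(seed)
  fold_of <- setNames(sample(rep_len(seq_len(folds), n_samples)),
                      samples$sample_id)

  truth <- character(0)
  pred <- character(0)
  pred_rows <- list()
  fold_k <- integer(folds)
  ridge_folds <- integer(0)
  for (f in seq_len(folds)) {
    test_samples <- names(fold_of)[fold_of == f]
    in_test <- sm$meta$sample_id %in% test_samples
    train_meta <- sm$meta[!in_test, ]
    if (length(unique(train_meta$group)) < 2) {
      abort(sprintf("training fold %d is missing a class", f))
    }
    train <- structure(list(matrix = sm$matrix[!in_test, , drop = FALSE],
                            meta = train_meta, grid = sm$grid), class = "list")
    mu <- colMeans(train$matrix)
    centered <- structure(list(
      matrix = sweep(train$matrix, 2, mu),
      column_means = mu, row_labels = train_meta, grid = sm$grid),
      class = "centered_spectra")
    p <- fit_pca(centered)
    k <- n_components_for_variance(p, variance_threshold)
    fold_k[f] <- k
    # at a 99.99% threshold k routinely exceeds the pooled-covariance
    # degrees of freedom; collect the per-fold ridge notices into one
    lda <- withCallingHandlers(
      fit_lda(p$scores[, seq_len(k), drop = FALSE], train_meta$group),
      aquasem_ridge = function(w) {
        ridge_folds <<- c(ridge_folds, f)
        invokeRestart("muffleWarning")
      })
    test_scores <- project_pca(p, sm$matrix[in_test, , drop = FALSE], k)
    fold_pred <- predict_lda(lda, test_scores)
    truth <- c(truth, sm$meta$group[in_test])
    pred <- c(pred, fold_pred)
    pred_rows[[f]] <- tibble::tibble(
      sample_id = sm$meta$sample_id[in_test],
      replicate = sm$meta$replicate[in_test],
      truth = sm$meta$group[in_test],
      predicted = fold_pred, fold = f)
  }
  if (length(ridge_folds)) {
    warn(sprintf(
      "pooled covariance was singular in %d of %d folds; ridge applied",
      length(ridge_folds), folds), class = "aquasem_ridge")
  }
  cm <- new_confusion_matrix(truth, pred, positive_class = positive_class,
                             fold_k = fold_k, seed = seed)
  attr(cm, "predictions") <- dplyr::bind_rows(pred_rows)
  cm
}

# counts with the positive class first on both margins
new_confusion_matrix <- function(truth, pred, positive_class = "Passed",
                                 fold_k = NULL, seed = NULL) {
  classes <- sort(unique(c(truth, pred)))
  if (positive_class %in% classes) {
    classes <- c(positive_class, setdiff(classes, positive_class))
  }
  counts <- table(factor(truth, levels = classes),
                  factor(pred, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  structure(counts, class = "confusion_matrix",
            positive_class = positive_class, fold_k = fold_k, seed = seed)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted); positive class:",
      attr(x, "positive_class"), "\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Accuracy is the percentage of correctly classified observations;
#' sensitivity the true-positive rate for the positive class (Passed by
#' default); specificity the true-negative rate. A metric whose
#' denominator is zero (e.g. no positive observations) is reported as
#' `NA`, never as 0.
#'
#' @param c A `confusion_matrix`.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`
#'   in percent, plus the raw `tp`, `fn`, `tn`, `fp` counts.
#' @export
confusion_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_matrix"))
  counts <- unclass(c)
  total <- sum(counts)
  if (total == 0) abort("confusion matrix is empty")
  pos <- attr(c, "positive_class")
  if (!pos %in% rownames(counts)) {
    abort(sprintf("positive class '%s' absent from the matrix", pos))
  }
  tp <- counts[pos, pos]
  fn <- sum(counts[pos, ]) - tp
  fp <- sum(counts[, pos]) - tp
  tn <- total - tp - fn - fp
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    accuracy = 100 * sum(diag(counts)) / total,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}
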