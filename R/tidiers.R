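#' Tidy a PCA model into a per-component tibble
#'
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return A tibble with `component`, `explained_variance_ratio` and
#'   `cumulative_variance`.
#' @exportS3Method generics::tidy
#' @export
tidy.pca_model <- function(x, ...) {
  r <- x$explained_variance_ratio
  tibble::tibble(
    component = seq_along(r),
    explained_variance_ratio = r,
    cumulative_variance = cumsum(r)
  )
}

#' One-row summary of a PCA model
#'
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return A tibble with the observation/wavelength counts, the number of
#'   components kept and the variance explained by PC1 and PC2.
#' @exportS3Method generics::glance
#' @export
glance.pca_model <- function(x, ...) {
  r <- x$explained_variance_ratio
  tibble::tibble(
    n_obs = nrow(x$scores),
    n_wavelengths = nrow(x$loadings),
    n_components = length(r),
    pc1_variance = r[1],
    pc2_variance = if (length(r) > 1) r[2] else NA_real_
  )
}

#' Tidy an LDA model into a class-by-feature tibble of centroids
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return A tibble with `class`, `prior`, `feature` and `mean`.
#' @exportS3Method generics::tidy
#' @export
tidy.lda_model <- function(x, ...) {
  k <- ncol(x$class_means)
  features <- colnames(x$class_means) %||% paste0("PC", seq_len(k))
  tibble::tibble(
    class = rep(x$classes, each = k),
    prior = rep(x$priors, each = k),
    feature = rep(features, length(x$classes)),
    mean = as.numeric(t(x$class_means))
  )
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with `truth`, `predicted`, `n`.
#' @exportS3Method generics::tidy
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tab <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  tibble::tibble(truth = tab$true, predicted = tab$predicted, n = tab$Freq)
}

#' One-row metric summary of a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return The [confusion_metrics()] tibble.
#' @exportS3Method generics::glance
#' @export
glance.confusion_matrix <- function(x, ...) confusion_metrics(x)

#' Partition counts of a proteome partition
#'
#' @param x A `proteome_partition`.
#' @param ... Unused.
#' @return A tibble with `n_passed`, `n_failed`, `n_shared`,
#'   `n_unique_passed`, `n_unique_failed`.
#' @exportS3Method generics::glance
#' @export
glance.proteome_partition <- function(x, ...) {
  tibble::tibble(
    n_passed = attr(x, "n_passed"),
    n_failed = attr(x, "n_failed"),
    n_shared = sum(x$status == "shared"),
    n_unique_passed = sum(x$status == "unique_passed"),
    n_unique_failed = sum(x$status == "unique_failed")
  )
}

#' One-row summary of a differential-protein result
#'
#' @param x A `dep_result`.
#' @param ... Unused.
#' @return A tibble with the number of proteins tested, the number
#'   called at the result's alpha, the alpha and the test used.
#' @exportS3Method generics::glance
#' @export
glance.dep_result <- function(x, ...) {
  tibble::tibble(
    n_tested = attr(x, "n_tested"),
    n_called = nrow(x),
    alpha = attr(x, "alpha"),
    method = attr(x, "method")
  )
}
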