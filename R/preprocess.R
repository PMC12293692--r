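#' Convert transmittance spectra to absorbance
#'
#' Applies the Beer-Lambert convention `A = -log10(T)`. The inverse,
#' `T = 10^(-A)`, recovers transmittance exactly, so the conversion is a
#' bijection on positive transmittance.
#'
#' @param s A spectra tibble in transmittance mode with all values > 0.
#' @return The same tibble with `value = -log10(value)` and
#'   `mode = "absorbance"`.
#' @examples
#' s <- simulate_sp_spectra(sim_config(n_passed = 1, n_failed = 1,
#'                                     replicates_per_sample = 1))
#' t <- dplyr::mutate(s, value = 10^(-value), mode = "transmittance")
#' a <- to_absorbance(t)
#' all.equal(a$value, s$value)
#' @export
to_absorbance <- function(s) {
  s <- validate_spectra(s)
  if (s$mode[1] != "transmittance") {
    abort("to_absorbance() expects spectra in transmittance mode")
  }
  bad <- s$value <= 0
  if (any(bad)) {
    abort(sprintf("non-positive transmittance at %g nm cannot be converted",
                  s$wavelength_nm[which(bad)[1]]))
  }
  dplyr::mutate(s, value = -log10(.data$value), mode = "absorbance")
}

#' Resample spectra onto a target wavelength grid
#'
#' Linear interpolation of every scan onto `grid`. Extrapolation is
#' refused: the target grid must lie within the source range.
#'
#' @param s A spectra tibble.
#' @param grid Target wavelengths in nm, strictly increasing.
#' @return The spectra resampled onto `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  s <- validate_spectra(s)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) abort("target grid must be strictly increasing")
  src <- spectra_grid(s)
  if (min(grid) < min(src) || max(grid) > max(src)) {
    abort(sprintf(
      "target grid [%g, %g] extends beyond source range [%g, %g]",
      min(grid), max(grid), min(src), max(src)))
  }
  out <- dplyr::reframe(
    dplyr::group_by(s, .data$sample_id, .data$group, .data$replicate,
                    .data$mode),
    value = stats::approx(.data$wavelength_nm, .data$value,
                          xout = grid, method = "linear")$y,
    wavelength_nm = grid)
  validate_spectra(out[spectra_cols])
}

#' Restrict spectra to a wavelength region
#'
#' Keeps grid points in the closed interval `[lo_nm, hi_nm]`. The default
#' region is the first overtone of the O-H stretch, 1300-1600 nm, the
#' aquaphotomics analysis window.
#'
#' @param s A spectra tibble.
#' @param lo_nm,hi_nm Region bounds in nm, `lo_nm < hi_nm`.
#' @return The trimmed spectra tibble.
#' @export
trim_region <- function(s, lo_nm = 1300, hi_nm = 1600) {
  s <- validate_spectra(s)
  if (lo_nm >= hi_nm) abort("trim region requires lo_nm < hi_nm")
  out <- dplyr::filter(s, .data$wavelength_nm >= lo_nm,
                       .data$wavelength_nm <= hi_nm)
  if (nrow(out) == 0) {
    abort(sprintf("no grid points inside [%g, %g] nm", lo_nm, hi_nm))
  }
  out
}

#' Average replicate scans within each sample
#'
#' Collapses the table to one spectrum per `sample_id` by the arithmetic
#' mean of its replicates at each wavelength; the group label is
#' preserved. Averaging before classification prevents replicate scans of
#' one sample from appearing on both sides of a cross-validation split.
#'
#' @param s A spectra tibble.
#' @return A spectra tibble with one scan (replicate 1) per sample.
#' @export
average_replicates <- function(s) {
  s <- validate_spectra(s)
  out <- dplyr::summarise(
    dplyr::group_by(s, .data$sample_id, .data$group, .data$mode,
                    .data$wavelength_nm),
    value = mean(.data$value), .groups = "drop")
  out$replicate <- 1L
  dplyr::arrange(out[spectra_cols], .data$group, .data$sample_id,
                 .data$wavelength_nm)
}

#' Standard normal variate scatter correction
#'
#' Centers and scales each scan across wavelengths:
#' `(A - mean(A)) / sd(A)` per spectrum. Off by default throughout the
#' pipeline (no scatter correction is part of the reference workflow);
#' enable it via the preprocessing config when multiplicative scatter is
#' suspected.
#'
#' @param s A spectra tibble.
#' @return The scatter-corrected spectra tibble.
#' @export
snv_correct <- function(s) {
  s <- validate_spectra(s)
  out <- dplyr::mutate(
    dplyr::group_by(s, .data$sample_id, .data$replicate),
    value = (.data$value - mean(.data$value)) / sd(.data$value))
  dplyr::ungroup(out)[spectra_cols]
}

#' Mean-center a spectra set into an observations-by-wavelengths matrix
#'
#' Builds the scans-by-wavelengths matrix and removes the per-wavelength
#' mean. The removed column means are stored so that new observations
#' (e.g. held-out cross-validation rows) can be projected consistently.
#'
#' @param s A spectra tibble with at least two scans.
#' @return An object of class `centered_spectra`: a list with `matrix`
#'   (centered, rows = scans), `column_means`, `row_labels` (tibble of
#'   `sample_id`, `group`, `replicate`) and `grid`.
#' @export
mean_center <- function(s) {
  sm <- spectra_matrix(s)
  if (nrow(sm$matrix) < 2) {
    abort("mean-centering requires at least two observations")
  }
  mu <- colMeans(sm$matrix)
  structure(list(
    matrix = sweep(sm$matrix, 2, mu),
    column_means = mu,
    row_labels = sm$meta,
    grid = sm$grid
  ), class = "centered_spectra")
}

#' @export
print.centered_spectra <- function(x, ...) {
  cat(sprintf("<centered_spectra: %d observations x %d wavelengths (%g-%g nm)>\n",
              nrow(x$matrix), ncol(x$matrix), min(x$grid), max(x$grid)))
  invisible(x)
}
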