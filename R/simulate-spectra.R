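#' Simulation settings for synthetic seminal-plasma spectra
#'
#' Builds the full parameterisation of the spectral simulator. A simulated
#' absorbance spectrum is a smooth water continuum (low-order polynomial in
#' wavelength) plus one Gaussian band per WAMACS coordinate, with
#' group-specific band centres and amplitudes, a per-sample biological
#' effect (a constant absorbance offset, as produced by concentration and
#' effective path-length differences between cuvette fillings), and
#' independent per-wavelength replicate noise.
#'
#' The defaults emulate the study design the package targets: 33 Passed and
#' 31 Failed samples, 10 replicate scans per sample on a 2-nm grid over
#' 1300-1600 nm, and group differences planted only in bands C1, C5 and
#' C12 (Passed peaks at 1348, 1404 and 1507 nm against Failed peaks at
#' 1344, 1398 and 1518 nm).
#'
#' @param n_passed,n_failed Number of samples per group.
#' @param replicates_per_sample Replicate scans per sample (default 10).
#' @param grid Wavelength grid in nm (default 1300-1600 nm, 2 nm step).
#' @param band_centers Named list with one numeric vector per group
#'   (`Passed`, `Failed`), each named by band id, giving Gaussian centres
#'   in nm.
#' @param band_amplitudes Same shape as `band_centers`; amplitudes in
#'   absorbance units.
#' @param band_widths Named numeric vector of Gaussian sigmas in nm.
#' @param baseline Water-continuum polynomial coefficients `c(b0, b1, b2, ...)`
#'   evaluated in the scaled coordinate `x = (lambda - 1450) / 150`.
#' @param noise_sd Replicate noise standard deviation (absorbance units).
#' @param sample_sd Between-sample standard deviation of the per-sample
#'   absorbance offset (absorbance units).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param bands WAMACS registry, see [wamacs_bands()].
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_passed = 4, n_failed = 4, replicates_per_sample = 2)
#' spectra <- simulate_sp_spectra(cfg)
#' @export
sim_config <- function(n_passed = 33L,
                       n_failed = 31L,
                       replicates_per_sample = 10L,
                       grid = seq(1300, 1600, by = 2),
                       band_centers = NULL,
                       band_amplitudes = NULL,
                       band_widths = NULL,
                       baseline = c(0.60, 0.05, -0.25),
                       noise_sd = 0.002,
                       sample_sd = 0.004,
                       seed = 42L,
                       bands = wamacs_bands()) {
  mid <- wamacs_midpoints(bands)
  if (is.null(band_centers)) {
    centers_passed <- mid
    centers_passed[c("C1", "C5", "C12")] <- c(1348, 1404, 1507)
    centers_failed <- mid
    centers_failed[c("C1", "C5", "C12")] <- c(1344, 1398, 1518)
    band_centers <- list(Passed = centers_passed, Failed = centers_failed)
  }
  if (is.null(band_amplitudes)) {
    amp <- setNames(rep(0.02, nrow(bands)), bands$band)
    band_amplitudes <- list(Passed = amp, Failed = amp)
  }
  if (is.null(band_widths)) {
    band_widths <- setNames(rep(5, nrow(bands)), bands$band)
  }

  cfg <- structure(list(
    n_passed = check_count(n_passed, "n_passed"),
    n_failed = check_count(n_failed, "n_failed"),
    replicates_per_sample = check_count(replicates_per_sample,
                                        "replicates_per_sample"),
    grid = sort(as.numeric(grid)),
    band_centers = band_centers,
    band_amplitudes = band_amplitudes,
    band_widths = band_widths,
    baseline = as.numeric(baseline),
    noise_sd = noise_sd,
    sample_sd = sample_sd,
    seed = check_count(seed, "seed", min = 0L),
    bands = bands
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$noise_sd < 0 || cfg$sample_sd < 0) {
    abort("noise_sd and sample_sd must be non-negative")
  }
  known <- cfg$bands$band
  bad_width <- setdiff(names(cfg$band_widths), known)
  if (length(bad_width)) {
    abort(paste0("band_widths references unknown band(s): ",
                 paste(bad_width, collapse = ", ")))
  }
  for (grp in c("Passed", "Failed")) {
    for (field in c("band_centers", "band_amplitudes")) {
      ids <- names(cfg[[field]][[grp]])
      bad <- setdiff(ids, known)
      if (length(bad)) {
        abort(sprintf("%s for group %s references unknown band(s): %s",
                      field, grp, paste(bad, collapse = ", ")))
      }
      no_width <- setdiff(ids, names(cfg$band_widths))
      if (length(no_width)) {
        abort(paste0("band(s) without a configured width: ",
                     paste(no_width, collapse = ", ")))
      }
    }
  }
  cfg
}

# water continuum: polynomial in x = (lambda - 1450) / 150
water_continuum <- function(wavelength_nm, baseline) {
  x <- (wavelength_nm - 1450) / 150
  drop(outer(x, seq_along(baseline) - 1, `^`) %*% baseline)
}

# sum of Gaussian bands with the given per-band amplitudes
band_mixture <- function(wavelength_nm, centers, amplitudes, widths) {
  out <- numeric(length(wavelength_nm))
  for (id in names(centers)) {
    out <- out + amplitudes[[id]] *
      exp(-(wavelength_nm - centers[[id]])^2 / (2 * widths[[id]]^2))
  }
  out
}

# the noise-free group-mean spectrum implied by a config (used in tests
# and by the reference simulator)
clean_group_spectrum <- function(cfg, group) {
  water_continuum(cfg$grid, cfg$baseline) +
    band_mixture(cfg$grid, cfg$band_centers[[group]],
                 cfg$band_amplitudes[[group]], cfg$band_widths)
}

check_grid_covers <- function(cfg) {
  rng <- range(cfg$grid)
  for (grp in names(cfg$band_centers)) {
    centers <- cfg$band_centers[[grp]]
    off <- names(centers)[centers < rng[1] | centers > rng[2]]
    if (length(off)) {
      abort(sprintf(
        "wavelength grid [%g, %g] does not cover band(s) %s (group %s)",
        rng[1], rng[2], paste(off, collapse = ", "), grp))
    }
  }
  invisible(cfg)
}

#' Simulate seminal-plasma NIR absorbance spectra
#'
#' Draws `(n_passed + n_failed) * replicates_per_sample` absorbance spectra
#' on the configured grid. Each sample receives a biological effect (a
#' constant absorbance offset drawn with sd `sample_sd`); each replicate
#' scan adds independent per-wavelength noise (sd `noise_sd`). Output is
#' deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A long-format tibble with columns `sample_id`, `group`,
#'   `replicate`, `mode` (`"absorbance"`), `wavelength_nm`, `value`.
#'   The seed used is recorded in the `sim_seed` attribute.
#' @examples
#' s <- simulate_sp_spectra(sim_config(n_passed = 2, n_failed = 2,
#'                                     replicates_per_sample = 2))
#' dplyr::count(s, group)
#' @export
simulate_sp_spectra <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  check_grid_covers(config)
  grid <- config$grid
  set.seed(config$seed)

  plan <- tibble::tibble(
    group = rep(c("Passed", "Failed"), c(config$n_passed, config$n_failed)),
    sample_id = c(sprintf("P%02d", seq_len(config$n_passed)),
                  sprintf("F%02d", seq_len(config$n_failed)))
  )
  n_samples <- nrow(plan)
  n_rep <- config$replicates_per_sample
  n_wl <- length(grid)
  clean <- list(Passed = clean_group_spectrum(config, "Passed"),
                Failed = clean_group_spectrum(config, "Failed"))
  sample_offset <- rnorm(n_samples, 0, config$sample_sd)
  noise <- rnorm(n_samples * n_rep * n_wl, 0, config$noise_sd)

  base <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    matrix(clean[[plan$group[i]]] + sample_offset[i],
           nrow = n_rep, ncol = n_wl, byrow = TRUE)
  }))
  values <- base + matrix(noise, nrow = n_samples * n_rep, byrow = TRUE)

  res <- tibble::tibble(
    sample_id = rep(plan$sample_id, each = n_rep * n_wl),
    group = rep(plan$group, each = n_rep * n_wl),
    replicate = rep(rep(seq_len(n_rep), each = n_wl), n_samples),
    mode = "absorbance",
    wavelength_nm = rep(grid, n_samples * n_rep),
    value = as.numeric(t(values))
  )
  attr(res, "sim_seed") <- config$seed
  res
}

#' Simulate distilled-water reference scans
#'
#' Scans of the bare water continuum (no solute bands) plus replicate
#' noise, labelled with group `"Reference"`. These play the role of the
#' distilled sterile water reference used to normalise sample spectra.
#'
#' @param config A [sim_config()]; only its grid, baseline, noise and seed
#'   are used.
#' @param n_scans Number of reference scans (>= 1).
#' @return A long-format spectra tibble (see [simulate_sp_spectra()]).
#' @export
simulate_water_reference <- function(config, n_scans = 10L) {
  stopifnot(inherits(config, "sim_config"))
  n_scans <- check_count(n_scans, "n_scans")
  check_grid_covers(config)
  grid <- config$grid
  continuum <- water_continuum(grid, config$baseline)
  set.seed(config$seed)
  noise <- rnorm(n_scans * length(grid), 0, config$noise_sd)
  res <- tibble::tibble(
    sample_id = "water", group = "Reference",
    replicate = rep(seq_len(n_scans), each = length(grid)),
    mode = "absorbance",
    wavelength_nm = rep(grid, n_scans),
    value = rep(continuum, n_scans) + noise
  )
  attr(res, "sim_seed") <- config$seed
  res
}
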