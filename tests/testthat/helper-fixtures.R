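# small-footprint fixtures shared across test files; everything is built
# in code so the suite ships no data files

# a small but fully structured simulation (same planted band effects as
# the default, fewer samples/replicates)
small_cfg <- function(seed = 11L, ...) {
  args <- modifyList(list(n_passed = 6L, n_failed = 6L,
                          replicates_per_sample = 3L, seed = seed),
                     list(...))
  do.call(sim_config, args)
}

# long spectra tibble from a scans-by-wavelengths matrix
spectra_from_matrix <- function(mat, grid,
                                groups = rep("Passed", nrow(mat)),
                                mode = "absorbance") {
  sample_ids <- sprintf("S%02d", seq_len(nrow(mat)))
  dplyr::bind_rows(lapply(seq_len(nrow(mat)), function(i) {
    tibble::tibble(sample_id = sample_ids[i], group = groups[i],
                   replicate = 1L, mode = mode,
                   wavelength_nm = grid, value = as.numeric(mat[i, ]))
  }))
}

# a single analytic Gaussian band on a flat baseline
gaussian_spectrum <- function(grid, center, sigma = 5, amplitude = 1,
                              baseline = 0) {
  baseline + amplitude * exp(-(grid - center)^2 / (2 * sigma^2))
}

# protein config with no planted effects, for null-calibration tests
null_protein_cfg <- function(n = 100L, seed = 1L, noise = 0.2) {
  protein_sim_config(n_shared = n, n_unique_passed = 0L,
                     n_unique_failed = 0L, planted_deps = NULL,
                     empai_noise_sd = noise, seed = seed)
}
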