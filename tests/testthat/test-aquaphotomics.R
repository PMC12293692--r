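test_that("a spectrum equal to the water mean normalizes to zero everywhere", {
  grid <- seq(1300, 1310, by = 2)
  water_vals <- gaussian_spectrum(grid, 1304, 3, 0.5, baseline = 0.4)
  water <- spectra_from_matrix(rbind(water_vals, water_vals + 0.01),
                               grid, groups = rep("Reference", 2))
  # group of two samples straddling the water mean
  wm <- colMeans(rbind(water_vals, water_vals + 0.01))
  s <- spectra_from_matrix(rbind(wm, wm + 0.2, wm - 0.2), grid,
                           groups = rep("Passed", 3))
  norm <- normalize_reference(s, water)
  expect_equal(norm$value[norm$sample_id == "S01"], rep(0, length(grid)),
               tolerance = 1e-12)
})

test_that("symmetric deviations normalize to +/- 1/sqrt(2) under the n-1 SD convention", {
  grid <- seq(1300, 1310, by = 2)
  water_vals <- rep(0.5, length(grid))
  water <- spectra_from_matrix(rbind(water_vals, water_vals), grid,
                               groups = rep("Reference", 2))
  delta <- 0.05
  s <- spectra_from_matrix(rbind(water_vals + delta, water_vals - delta),
                           grid, groups = rep("Passed", 2))
  norm <- normalize_reference(s, water)
  # sample SD of {+d, -d} is d * sqrt(2), so values are +/- 1/sqrt(2)
  expect_equal(unique(round(norm$value[norm$sample_id == "S01"], 10)),
               round(1 / sqrt(2), 10))
  expect_equal(unique(round(norm$value[norm$sample_id == "S02"], 10)),
               round(-1 / sqrt(2), 10))
})

test_that("normalization is invariant to a consistent doubling of all absorbances", {
  cfg <- small_cfg(seed = 31L)
  s <- simulate_sp_spectra(cfg)
  w <- simulate_water_reference(cfg, 5)
  n1 <- normalize_reference(s, w)
  s2 <- dplyr::mutate(s, value = 2 * value)
  w2 <- dplyr::mutate(w, value = 2 * value)
  n2 <- normalize_reference(s2, w2)
  expect_equal(n2$value, n1$value, tolerance = 1e-10)
})

test_that("zero within-group spread with a nonzero deviation is a degenerate category", {
  grid <- c(1300, 1302)
  water <- spectra_from_matrix(rbind(c(0.5, 0.5), c(0.5, 0.5)), grid,
                               groups = rep("Reference", 2))
  s <- spectra_from_matrix(rbind(c(0.6, 0.6), c(0.6, 0.6)), grid,
                           groups = rep("Passed", 2))
  expect_error(normalize_reference(s, water), "1300")
})

test_that("WABS detection is grid-argmax with a lower-wavelength tie rule", {
  bands <- wamacs_bands()
  grid <- seq(1300, 1600, by = 2)
  # Gaussian centered at 1412 inside C6's limits
  gm <- tibble::tibble(group = "Passed", wavelength_nm = grid,
                       value = gaussian_spectrum(grid, 1412, 4))
  wabs <- detect_wabs(gm, bands)
  expect_equal(nrow(wabs), 12)
  expect_true(all(wabs$wavelength_nm >= bands$lo_nm &
                    wabs$wavelength_nm <= bands$hi_nm))
  # the peaked band finds the center; C5 rises monotonically toward its
  # upper limit there, so its WABS pins to the limit
  expect_equal(wabs$wavelength_nm[wabs$band == "C6"], 1412)
  expect_equal(wabs$wavelength_nm[wabs$band == "C5"], 1406)
  # flat spectrum: every band reports its lower limit
  flat <- tibble::tibble(group = "Passed", wavelength_nm = grid, value = 1)
  wabs_flat <- detect_wabs(flat, bands)
  expect_equal(wabs_flat$wavelength_nm,
               vapply(bands$lo_nm, function(lo) min(grid[grid >= lo]),
                      numeric(1)))
})

test_that("shifting all band centers shifts every WABS by the same amount", {
  grid <- seq(1300, 1600, by = 2)
  bands <- wamacs_bands()
  mid <- wamacs_midpoints(bands)
  delta <- 4  # a multiple of the grid step
  centers <- lapply(list(0, delta), function(d) {
    vals <- numeric(length(grid))
    for (b in names(mid)) {
      vals <- vals + gaussian_spectrum(grid, mid[[b]] + d, 3, 0.5)
    }
    tibble::tibble(group = "Passed", wavelength_nm = grid, value = vals)
  })
  w0 <- detect_wabs(centers[[1]], bands)
  w1 <- detect_wabs(centers[[2]], bands)
  inner <- !(w0$wavelength_nm + delta > bands$hi_nm)  # shift stays in band
  expect_equal(w1$wavelength_nm[inner], w0$wavelength_nm[inner] + delta)
})

test_that("barcode aligns groups per band and reports Failed - Passed shifts", {
  grid <- seq(1300, 1600, by = 1)  # 1-nm grid contains 1507 and 1518
  cfg <- small_cfg(noise_sd = 0, sample_sd = 0, grid = grid)
  s <- simulate_sp_spectra(cfg)
  # subtract the water continuum (the reference step): band peaks then
  # sit exactly at their planted centers
  w <- simulate_water_reference(cfg, 2)
  water_mean <- dplyr::summarise(dplyr::group_by(w, wavelength_nm),
                                 water = mean(value), .groups = "drop")
  means <- dplyr::summarise(dplyr::group_by(s, group, wavelength_nm),
                            value = mean(value), .groups = "drop")
  means <- dplyr::mutate(
    dplyr::left_join(means, water_mean, by = "wavelength_nm"),
    value = value - water)
  wabs <- dplyr::bind_rows(lapply(split(means, means$group), detect_wabs))
  bc <- build_barcode(wabs)
  expect_equal(bc$band, paste0("C", 1:12))
  expect_equal(bc$shift_nm[bc$band == "C12"], 11)
  expect_equal(bc$wabs_Passed[bc$band == "C12"], 1507)
  expect_equal(bc$wabs_Failed[bc$band == "C12"], 1518)

  # identical groups: all shifts zero
  same <- dplyr::mutate(wabs[wabs$group == "Passed", ], group = "Failed")
  bc0 <- build_barcode(dplyr::bind_rows(wabs[wabs$group == "Passed", ], same))
  expect_true(all(bc0$shift_nm == 0))

  # one group still builds (no shift column)
  bc1 <- build_barcode(wabs[wabs$group == "Passed", ])
  expect_false("shift_nm" %in% names(bc1))
  expect_error(build_barcode(wabs[wabs$band != "C3", ]), "C3")
})

test_that("aquagram equals the normalized group mean sampled at the WABS wavelengths", {
  cfg <- small_cfg(seed = 17L)
  s <- simulate_sp_spectra(cfg)
  w <- simulate_water_reference(cfg, 10)
  norm <- normalize_reference(dplyr::bind_rows(s, w), w)
  ag <- compute_aquagram(norm)
  expect_equal(nrow(ag), 36)  # 3 groups x 12 bands
  means <- aquasem:::group_mean_spectra(norm)
  for (i in seq_len(nrow(ag))) {
    expect_equal(
      ag$value[i],
      means$value[means$group == ag$group[i] &
                    means$wavelength_nm == ag$wavelength_nm[i]])
  }
})

test_that("groups differing only in C12 amplitude differ only at C12", {
  # analytic construction: within-group spread comes from a symmetric
  # sample offset, so per-wavelength SD is identical across groups
  grid <- seq(1300, 1600, by = 2)
  bands <- wamacs_bands()
  mid <- wamacs_midpoints(bands)
  base <- numeric(length(grid))
  for (b in names(mid)) base <- base + gaussian_spectrum(grid, mid[[b]], 4, 0.02)
  bump <- gaussian_spectrum(grid, mid[["C12"]], 3, 0.03)
  water <- spectra_from_matrix(rbind(rep(0.4, length(grid)),
                                     rep(0.4, length(grid))),
                               grid, groups = rep("Reference", 2))
  offset <- 0.01
  mat <- rbind(0.4 + base + offset, 0.4 + base - offset,
               0.4 + base + bump + offset, 0.4 + base + bump - offset)
  s <- spectra_from_matrix(mat, grid,
                           groups = rep(c("Passed", "Failed"), each = 2))
  ag <- compute_aquagram(normalize_reference(s, water), bands,
                         at = tibble::tibble(
                           band = bands$band,
                           wavelength_nm = 2 * round(unname(mid) / 2)))
  wide <- tidyr::pivot_wider(tibble::as_tibble(ag)[c("band", "group", "value")],
                             names_from = group, values_from = value)
  differs <- abs(wide$Passed - wide$Failed) > 1e-9
  expect_true(differs[wide$band == "C12"])
  expect_equal(sum(differs), 1)
})

test_that("planted C12 peaks are recovered within one grid step under noise", {
  hits <- 0L
  n_runs <- 25
  for (i in seq_len(n_runs)) {
    cfg <- sim_config(n_passed = 10, n_failed = 10,
                      replicates_per_sample = 3, seed = 500L + i)
    s <- simulate_sp_spectra(cfg)
    w <- simulate_water_reference(cfg, 5)
    wabs <- aquasem:::detect_wabs_by_group(
      normalize_reference(dplyr::bind_rows(s, w), w))
    c12 <- wabs[wabs$band == "C12", ]
    hit <- abs(c12$wavelength_nm[c12$group == "Passed"] - 1507) <= 2 &&
      abs(c12$wavelength_nm[c12$group == "Failed"] - 1518) <= 2
    hits <- hits + as.integer(hit)
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("parabolic refinement locates an off-grid peak to sub-grid precision", {
  grid <- seq(1300, 1600, by = 2)
  gm <- tibble::tibble(group = "Passed", wavelength_nm = grid,
                       value = gaussian_spectrum(grid, 1411, 5))
  coarse <- detect_wabs(gm)
  fine <- detect_wabs(gm, refine = TRUE)
  expect_equal(coarse$wavelength_nm[coarse$band == "C6"], 1410)
  expect_lt(abs(fine$wavelength_nm[fine$band == "C6"] - 1411), 0.1)
})
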