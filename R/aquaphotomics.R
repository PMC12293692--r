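#' Normalize absorbance spectra against a distilled-water reference
#'
#' For each wavelength and each sample category (group) `g`, the
#' normalized absorbance is
#' `A'(lambda) = (A(lambda) - mean_water(lambda)) / SD_g(lambda)`,
#' where `mean_water` is the mean absorbance of the water reference scans
#' and `SD_g` is the per-wavelength sample standard deviation (n - 1
#' denominator) over the spectra of group `g`. Wavelengths where a group
#' has zero spread but already equals the water mean normalize to 0 (the
#' limit); zero spread with a nonzero numerator is a degenerate category
#' and raises an error naming the wavelength.
#'
#' @param s Absorbance spectra tibble (any groups, including Reference).
#' @param water Absorbance spectra of the water reference on the same
#'   grid.
#' @return The spectra tibble with `value` replaced by the normalized
#'   absorbance and `mode = "normalized"`.
#' @export
normalize_reference <- function(s, water) {
  s <- validate_spectra(s)
  water <- validate_spectra(water)
  if (!identical(spectra_grid(s), spectra_grid(water))) {
    abort("sample and water grids differ; resample first")
  }
  if (s$mode[1] != "absorbance" || water$mode[1] != "absorbance") {
    abort("normalization expects absorbance spectra")
  }
  water_mean <- dplyr::summarise(
    dplyr::group_by(water, .data$wavelength_nm),
    water_mean = mean(.data$value), .groups = "drop")

  out <- dplyr::left_join(s, water_mean, by = "wavelength_nm")
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$group, .data$wavelength_nm),
    .num = .data$value - .data$water_mean,
    .sd = sd(.data$value))
  out <- dplyr::ungroup(out)

  degenerate <- out$.sd == 0 & abs(out$.num) > 0
  if (any(degenerate)) {
    i <- which(degenerate)[1]
    abort(sprintf(
      "group '%s' has zero standard deviation at %g nm: cannot normalize",
      out$group[i], out$wavelength_nm[i]))
  }
  out$value <- ifelse(out$.sd == 0, 0, out$.num / out$.sd)
  out$mode <- "normalized"
  out[spectra_cols]
}

# per-group mean spectrum of a (normalized) spectra table
group_mean_spectra <- function(s) {
  dplyr::summarise(
    dplyr::group_by(s, .data$group, .data$wavelength_nm),
    value = mean(.data$value), .groups = "drop")
}

#' Locate water absorbance bands (WABS) within the WAMACS coordinates
#'
#' For each WAMACS band, finds the grid wavelength at which the spectrum
#' is maximal within the band's closed limits. Ties (including flat
#' spectra) resolve to the lower wavelength.
#'
#' @param group_mean A single spectrum as a tibble with `wavelength_nm`
#'   and `value` columns (typically a normalized group-mean spectrum; a
#'   `group` column, if present, is carried through).
#' @param bands WAMACS registry, see [wamacs_bands()].
#' @param refine When `TRUE`, refine each interior peak to sub-grid
#'   precision by fitting a parabola through the three points around the
#'   argmax. Off by default: reported peaks are whole grid wavelengths.
#' @return A tibble with one row per band: `band`, `wavelength_nm` (the
#'   WABS), `value` at the peak, and `group` if supplied.
#' @export
detect_wabs <- function(group_mean, bands = wamacs_bands(), refine = FALSE) {
  if (dplyr::n_distinct(group_mean$group %||% "x") > 1) {
    abort("detect_wabs() expects a single group's mean spectrum")
  }
  grid <- sort(unique(group_mean$wavelength_nm))
  res <- purrr::pmap(bands[c("band", "lo_nm", "hi_nm")],
                     function(band, lo_nm, hi_nm) {
    inside <- dplyr::filter(group_mean, .data$wavelength_nm >= lo_nm,
                            .data$wavelength_nm <= hi_nm)
    if (nrow(inside) == 0) {
      abort(sprintf("band %s [%g, %g] has no grid points in the spectrum",
                    band, lo_nm, hi_nm))
    }
    inside <- dplyr::arrange(inside, .data$wavelength_nm)
    i <- which.max(inside$value)  # first maximum = lower-wavelength tie rule
    peak_wl <- inside$wavelength_nm[i]
    peak_val <- inside$value[i]
    if (refine && i > 1 && i < nrow(inside)) {
      # parabola through the three points straddling the argmax
      y <- inside$value[(i - 1):(i + 1)]
      denom <- y[1] - 2 * y[2] + y[3]
      if (denom < 0) {
        h <- inside$wavelength_nm[i + 1] - inside$wavelength_nm[i]
        delta <- 0.5 * (y[1] - y[3]) / denom * h
        peak_wl <- min(max(peak_wl + delta, lo_nm), hi_nm)
        peak_val <- y[2] - 0.25 * (y[1] - y[3]) * delta / h
      }
    }
    tibble::tibble(band = band, wavelength_nm = peak_wl, value = peak_val)
  })
  res <- dplyr::bind_rows(res)
  if ("group" %in% names(group_mean)) res$group <- group_mean$group[1]
  res
}

# WABS per group from a normalized spectra table
detect_wabs_by_group <- function(normalized, bands = wamacs_bands()) {
  means <- group_mean_spectra(normalized)
  dplyr::bind_rows(purrr::map(split(means, means$group), detect_wabs,
                              bands = bands))
}

#' Build a WAMACS barcode from per-group WABS tables
#'
#' Aligns each group's twelve WABS wavelengths per band so chemical
#' shifts are directly readable. When both Passed and Failed are present
#' the column `shift_nm` holds `Failed - Passed` in nm (e.g. +11 nm at
#' C12 when Failed peaks at 1518 nm and Passed at 1507 nm).
#'
#' @param wabs_by_group A tibble of WABS rows for one or more groups, as
#'   returned by [detect_wabs()] with a `group` column.
#' @param bands WAMACS registry used to order and check the bands.
#' @return A tibble of class `wamacs_barcode`: `band`, one wavelength
#'   column per group (`wabs_<group>`), and `shift_nm` when both Passed
#'   and Failed are present.
#' @export
build_barcode <- function(wabs_by_group, bands = wamacs_bands()) {
  need <- setdiff(c("band", "wavelength_nm", "group"),
                  names(wabs_by_group))
  if (length(need)) {
    abort(paste0("WABS table lacks column(s): ", paste(need, collapse = ", ")))
  }
  for (g in unique(wabs_by_group$group)) {
    got <- wabs_by_group$band[wabs_by_group$group == g]
    missing <- setdiff(bands$band, got)
    if (length(missing)) {
      abort(sprintf("group '%s' is missing WABS for band(s): %s",
                    g, paste(missing, collapse = ", ")))
    }
  }
  wide <- tidyr::pivot_wider(
    wabs_by_group[c("band", "group", "wavelength_nm")],
    names_from = "group", values_from = "wavelength_nm",
    names_prefix = "wabs_")
  wide <- wide[match(bands$band, wide$band), ]
  if (all(c("wabs_Passed", "wabs_Failed") %in% names(wide))) {
    wide$shift_nm <- wide$wabs_Failed - wide$wabs_Passed
  }
  structure(wide, class = c("wamacs_barcode", class(wide)))
}

#' Compute aquagrams (water spectral patterns) per group
#'
#' For each group and WAMACS band, the aquagram value is the group-mean
#' normalized absorbance evaluated at that group's own WABS wavelength
#' (the band peak found at baseline). Supplying `at` evaluates every
#' group at a common fixed wavelength per band instead, which trades the
#' per-group peak definition for cross-group comparability.
#'
#' @param normalized Normalized spectra tibble from
#'   [normalize_reference()], with group labels.
#' @param bands WAMACS registry.
#' @param at Optional tibble with columns `band` and `wavelength_nm`
#'   fixing a common evaluation wavelength per band.
#' @return A tibble of class `aquagram`: `group`, `band`,
#'   `wavelength_nm`, `value`, in band order C1-C12 within group.
#' @export
compute_aquagram <- function(normalized, bands = wamacs_bands(), at = NULL) {
  normalized <- validate_spectra(normalized)
  means <- group_mean_spectra(normalized)
  groups <- unique(means$group)
  res <- purrr::map(groups, function(g) {
    gm <- dplyr::filter(means, .data$group == g)
    if (is.null(at)) {
      wabs <- detect_wabs(gm, bands = bands)
    } else {
      wabs <- dplyr::left_join(at[c("band", "wavelength_nm")],
                               gm[c("wavelength_nm", "value")],
                               by = "wavelength_nm")
      if (any(is.na(wabs$value))) {
        abort("`at` wavelengths must lie on the spectra grid")
      }
    }
    wabs$group <- g
    wabs[c("group", "band", "wavelength_nm", "value")]
  })
  res <- dplyr::bind_rows(res)
  res <- res[order(match(res$group, spectra_groups),
                   match(res$band, bands$band)), ]
  structure(res, class = c("aquagram", class(res)))
}
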