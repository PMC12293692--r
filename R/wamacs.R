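#' WAMACS water matrix coordinates for the first overtone
#'
#' The water matrix coordinates (WAMACS) are twelve spectral bands, C1-C12,
#' in the first overtone of the O-H stretch (1300-1600 nm). Each band is
#' attributed to a water species (dimers, free water, hydration shells of
#' kosmotropic or chaotropic solutes, bulk water, ...). Published band
#' limits vary by a few nanometres between studies; this registry ships
#' literature-standard limits widened where needed so that the wavelengths
#' reported for seminal plasma (1348 nm in C1; 1398 and 1404 nm in C5;
#' 1507 and 1518 nm in C12) fall inside their bands. The `reported_nm`
#' column records every peak wavelength reported for this system, including
#' an ambiguous 1398 nm listed alongside C1, without asserting band
#' membership beyond the enforced containment.
#'
#' @param bands Optional tibble to validate and use in place of the default
#'   registry. Must carry columns `band`, `lo_nm`, `hi_nm`, `species`.
#' @return A tibble with one row per band: `band` (`"C1"`..`"C12"`),
#'   `lo_nm`, `hi_nm` (band limits, nm), `species` (water species label)
#'   and `reported_nm` (list column of reported peak wavelengths).
#' @examples
#' wamacs_bands()
#' @export
wamacs_bands <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- tibble::tibble(
      band = paste0("C", 1:12),
      lo_nm = c(1336, 1356, 1368, 1378, 1390, 1408, 1422, 1446,
                1456, 1470, 1482, 1502),
      hi_nm = c(1354, 1366, 1376, 1388, 1406, 1420, 1444, 1454,
                1468, 1480, 1494, 1520),
      species = c(
        "water dimers / nu3 shoulder",
        "water solvation shell (OH-(H2O)1,2,4)",
        "symmetric + asymmetric stretch (nu1 + nu3)",
        "water solvation shell (OH-(H2O)1,4)",
        "free water molecules (S0)",
        "hydration band / H-OH bend and O...O",
        "water molecules with one H bond (S1)",
        "water solvation shell (O2-(H2O)4)",
        "water molecules with two H bonds (S2)",
        "water molecules with three H bonds (S3)",
        "water molecules with four H bonds (S4, bulk)",
        "strongly bound water / kosmotropic solutes (nu1, nu2)"
      ),
      reported_nm = list(c(1348, 1398), numeric(), numeric(), numeric(),
                         c(1398, 1404), numeric(), numeric(), numeric(),
                         numeric(), numeric(), numeric(),
                         c(1507, 1518))
    )
  }
  validate_wamacs(bands)
}

# enforces the registry invariants: 12 ordered, non-overlapping bands inside
# [1300, 1600] nm, with the seminal-plasma peaks contained where required
validate_wamacs <- function(bands) {
  required <- c("band", "lo_nm", "hi_nm", "species")
  missing <- setdiff(required, names(bands))
  if (length(missing)) {
    abort(paste0("band registry lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bands <- tibble::as_tibble(bands)
  if (!identical(bands$band, paste0("C", 1:12))) {
    abort("band registry must contain exactly the 12 bands C1..C12, in order")
  }
  if (any(bands$lo_nm >= bands$hi_nm)) {
    abort("each band must satisfy lo_nm < hi_nm")
  }
  if (any(bands$lo_nm < 1300) || any(bands$hi_nm > 1600)) {
    abort("all bands must lie within [1300, 1600] nm")
  }
  if (any(diff(as.vector(rbind(bands$lo_nm, bands$hi_nm))) < 0)) {
    abort("bands must be ordered and non-overlapping")
  }
  containment <- list(C1 = 1348, C5 = c(1398, 1404), C12 = c(1507, 1518))
  for (id in names(containment)) {
    row <- bands[bands$band == id, ]
    wl <- containment[[id]]
    if (any(wl < row$lo_nm | wl > row$hi_nm)) {
      abort(sprintf(
        "band %s [%g, %g] must contain the reported wavelength(s) %s nm",
        id, row$lo_nm, row$hi_nm, paste(wl, collapse = ", ")))
    }
  }
  bands
}

# midpoint of each band; used as the default simulated band centre
wamacs_midpoints <- function(bands = wamacs_bands()) {
  setNames((bands$lo_nm + bands$hi_nm) / 2, bands$band)
}
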