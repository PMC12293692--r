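#' Read spectra from the wide CSV dialect
#'
#' The wide dialect has a first column `wavelength_nm` and one column per
#' scan, with headers `sampleid|group|replicate`. An optional leading
#' comment line `# mode: transmittance` (or `absorbance`) declares the
#' measurement mode; absorbance is assumed when absent.
#'
#' @param path Path to a CSV file.
#' @return A long-format spectra tibble with columns `sample_id`, `group`,
#'   `replicate`, `mode`, `wavelength_nm`, `value`.
#' @seealso [write_spectra_csv()], [read_spectra_tsv()]
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  mode <- "absorbance"
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("#\\s*mode:\\s*(\\w+)", first))[[1]]
    if (length(m) == 2L) mode <- m[2]
  }
  if (!mode %in% c("absorbance", "transmittance")) {
    abort(paste0("unknown spectra mode in header: ", mode))
  }
  wide <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal")
  probs <- readr::problems(wide)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed spectra CSV at line %d: %s",
                  probs$row[1] + 1L, probs$expected[1]))
  }
  if (names(wide)[1] != "wavelength_nm") {
    abort("first column must be named 'wavelength_nm'")
  }
  scan_cols <- names(wide)[-1]
  bad <- scan_cols[!grepl("^[^|]+\\|[^|]+\\|[^|]+$", scan_cols)]
  if (length(bad)) {
    abort(paste0("scan column header(s) not in 'sampleid|group|replicate' ",
                 "form: ", paste(head(bad, 3), collapse = ", ")))
  }
  if (anyDuplicated(scan_cols)) {
    abort(paste0("duplicated (sample, replicate) scan column: ",
                 scan_cols[duplicated(scan_cols)][1]))
  }
  wl <- wide$wavelength_nm
  if (any(!is.finite(wl)) || any(diff(wl) <= 0)) {
    bad_row <- which(!is.finite(wl) | c(FALSE, diff(wl) <= 0))[1]
    abort(sprintf("wavelengths must be finite and strictly increasing (line %d)",
                  bad_row + 1L))
  }
  long <- tidyr::pivot_longer(wide, -"wavelength_nm",
                              names_to = "scan", values_to = "value")
  if (any(!is.finite(long$value))) {
    abort("spectra contain missing or non-finite values")
  }
  long <- tidyr::separate_wider_delim(
    long, "scan", delim = "|",
    names = c("sample_id", "group", "replicate"))
  long$replicate <- as.integer(long$replicate)
  long$mode <- mode
  validate_spectra(dplyr::arrange(
    long[spectra_cols], .data$group, .data$sample_id, .data$replicate,
    .data$wavelength_nm))
}

#' Write spectra to the wide CSV dialect
#'
#' Emits the same dialect [read_spectra_csv()] consumes, with fixed
#' 6-decimal formatting so files are byte-stable across platforms.
#'
#' @param s A long-format spectra tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  s <- validate_spectra(s)
  mode <- s$mode[1]
  wide <- tidyr::pivot_wider(
    dplyr::mutate(s, scan = paste(.data$sample_id, .data$group,
                                  .data$replicate, sep = "|")),
    id_cols = "wavelength_nm", names_from = "scan", values_from = "value")
  lines <- c(
    paste0("# mode: ", mode),
    paste(names(wide), collapse = ","),
    apply(wide, 1, function(row) {
      paste(sprintf("%.6f", as.numeric(row)), collapse = ",")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read spectra from the long TSV layout
#'
#' Columns: `wavelength` (or `wavelength_nm`), `value`, `sample_id`,
#' `group`, `replicate`, and optionally `mode`.
#'
#' @param path Path to a TSV file.
#' @return A long-format spectra tibble.
#' @export
read_spectra_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("wavelength" %in% names(long) && !"wavelength_nm" %in% names(long)) {
    long <- dplyr::rename(long, wavelength_nm = "wavelength")
  }
  if (!"mode" %in% names(long)) long$mode <- "absorbance"
  need <- setdiff(spectra_cols, names(long))
  if (length(need)) {
    abort(paste0("long-form spectra TSV lacks column(s): ",
                 paste(need, collapse = ", ")))
  }
  long$replicate <- as.integer(long$replicate)
  validate_spectra(long[spectra_cols])
}

# invariant checks shared by readers, writers and preprocessing:
# one common strictly-increasing grid, finite values, one mode,
# unique (sample_id, replicate) scans, one group per sample
validate_spectra <- function(s) {
  s <- tibble::as_tibble(s)
  need <- setdiff(spectra_cols, names(s))
  if (length(need)) {
    abort(paste0("spectra table lacks column(s): ",
                 paste(need, collapse = ", ")))
  }
  if (nrow(s) == 0) abort("spectra table is empty")
  if (any(!is.finite(s$value))) abort("spectra values must be finite")
  if (length(unique(s$mode)) != 1L) {
    abort("spectra table mixes absorbance and transmittance scans")
  }
  grids <- dplyr::summarise(
    dplyr::group_by(s, .data$sample_id, .data$replicate),
    grid = paste(.data$wavelength_nm, collapse = ","), .groups = "drop")
  if (length(unique(grids$grid)) != 1L) {
    abort("all scans must share one wavelength grid")
  }
  grid <- spectra_grid(s)
  if (any(diff(grid) <= 0)) {
    abort("wavelengths must be strictly increasing within each scan")
  }
  mixed <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(s, .data$sample_id),
                     n_groups = dplyr::n_distinct(.data$group),
                     .groups = "drop"),
    .data$n_groups > 1)
  if (nrow(mixed)) {
    abort(paste0("sample(s) assigned to more than one group: ",
                 paste(mixed$sample_id, collapse = ", ")))
  }
  s
}

# the common wavelength grid of a spectra table
spectra_grid <- function(s) {
  sort(unique(s$wavelength_nm))
}

# scans x wavelengths matrix plus row metadata, the interface between the
# long tables and the linear algebra
spectra_matrix <- function(s) {
  s <- validate_spectra(s)
  grid <- spectra_grid(s)
  wide <- tidyr::pivot_wider(
    s, id_cols = c("sample_id", "group", "replicate"),
    names_from = "wavelength_nm", values_from = "value")
  meta <- wide[c("sample_id", "group", "replicate")]
  mat <- as.matrix(wide[as.character(grid)])
  rownames(mat) <- paste(meta$sample_id, meta$replicate, sep = "|")
  colnames(mat) <- as.character(grid)
  list(matrix = mat, grid = grid, meta = meta)
}

# inverse of spectra_matrix for internal round trips
matrix_to_spectra <- function(mat, grid, meta, mode = "absorbance") {
  purrr::list_rbind(purrr::map(seq_len(nrow(mat)), function(i) {
    tibble::tibble(
      sample_id = meta$sample_id[i], group = meta$group[i],
      replicate = meta$replicate[i], mode = mode,
      wavelength_nm = grid, value = as.numeric(mat[i, ]))
  }))
}
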