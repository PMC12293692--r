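#' Read a protein emPAI table from TSV
#'
#' Expected columns: `accession`, `gene_id`, `name`, optionally
#' `n_observed` and `n_observable`, then one emPAI column per sample with
#' header `group|sample` (e.g. `Passed|P01`). When the peptide-count
#' columns are present, emPAI is recomputed from them and any sample
#' column must agree with the recomputed value within 1e-9; with no
#' sample columns the recomputed emPAI becomes a single column.
#'
#' @param path Path to a TSV file.
#' @return A long protein tibble: `accession`, `gene_id`, `name`,
#'   `group`, `sample_id`, `empai` (plus `n_observed`/`n_observable` when
#'   supplied).
#' @export
read_protein_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- setdiff(c("accession", "gene_id", "name"), names(wide))
  if (length(need)) {
    abort(paste0("protein TSV lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(wide$accession)) {
    abort(paste0("duplicated accession: ",
                 wide$accession[duplicated(wide$accession)][1]))
  }
  counts_present <- all(c("n_observed", "n_observable") %in% names(wide))
  sample_cols <- grep("^[^|]+\\|[^|]+$", names(wide), value = TRUE)
  if (!counts_present && length(sample_cols) == 0) {
    abort("protein TSV needs 'group|sample' emPAI columns or peptide counts")
  }
  if (counts_present) {
    recomputed <- compute_empai(wide$n_observed, wide$n_observable)
    for (col in sample_cols) {
      off <- abs(wide[[col]] - recomputed) > 1e-9
      if (any(off)) {
        abort(sprintf(
          "emPAI column '%s' inconsistent with peptide counts for %s",
          col, wide$accession[which(off)[1]]))
      }
    }
    if (length(sample_cols) == 0) {
      grp <- "Unknown"
      wide[[paste0(grp, "|s1")]] <- recomputed
      sample_cols <- paste0(grp, "|s1")
    }
  }
  id_cols <- intersect(c("accession", "gene_id", "name",
                         "n_observed", "n_observable"), names(wide))
  long <- tidyr::pivot_longer(wide[c(id_cols, sample_cols)],
                              dplyr::all_of(sample_cols),
                              names_to = "scan", values_to = "empai")
  long <- tidyr::separate_wider_delim(long, "scan", delim = "|",
                                      names = c("group", "sample_id"))
  if (any(!is.finite(long$empai)) || any(long$empai < 0)) {
    abort("emPAI values must be finite and non-negative")
  }
  long[c("accession", "gene_id", "name", "group", "sample_id", "empai",
         setdiff(id_cols, c("accession", "gene_id", "name")))]
}

#' Write a protein emPAI table to TSV
#'
#' Emits the wide dialect [read_protein_tsv()] consumes, one
#' `group|sample` column per sample, with stable 6-decimal formatting.
#'
#' @param t A long protein tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_tsv <- function(t, path) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(t, scan = paste(.data$group, .data$sample_id, sep = "|")),
    id_cols = c("accession", "gene_id", "name"),
    names_from = "scan", values_from = "empai")
  num_cols <- setdiff(names(wide), c("accession", "gene_id", "name"))
  for (col in num_cols) wide[[col]] <- sprintf("%.6f", wide[[col]])
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
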