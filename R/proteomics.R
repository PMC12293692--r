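#' Exponentially modified protein abundance index (emPAI)
#'
#' `emPAI = 10^(n_observed / n_observable) - 1`, the label-free relative
#' abundance estimate derived from the fraction of a protein's observable
#' tryptic peptides that were actually observed.
#'
#' @param n_observed Number of observed peptides (>= 0); vectorised.
#' @param n_observable Number of observable peptides (>= 1); vectorised.
#' @return Numeric emPAI scores.
#' @examples
#' compute_empai(3, 6)  # 10^0.5 - 1
#' @export
compute_empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1)) {
    abort("n_observable must be at least 1")
  }
  if (any(n_observed < 0)) {
    abort("n_observed must be non-negative")
  }
  10^(n_observed / n_observable) - 1
}

#' Partition two protein tables into shared and group-unique sets
#'
#' Set partition by accession: proteins present in both tables are
#' shared; the rest are unique to their group. The three sets are
#' pairwise disjoint and satisfy `|shared| + |unique_passed| = |passed|`
#' and `|shared| + |unique_failed| = |failed|` exactly.
#'
#' @param passed,failed Long protein tibbles with an `accession` column
#'   (e.g. from [simulate_empai_table()] or [read_protein_tsv()]).
#' @return A tibble of class `proteome_partition` with columns
#'   `accession` and `status` (shared / unique_passed / unique_failed);
#'   [glance()] returns the partition counts.
#' @examples
#' sim <- simulate_empai_table(protein_sim_config(seed = 1))
#' glance(partition_proteins(sim$passed, sim$failed))
#' @export
partition_proteins <- function(passed, failed) {
  acc_p <- unique(passed$accession)
  acc_f <- unique(failed$accession)
  shared <- intersect(acc_p, acc_f)
  res <- tibble::tibble(
    accession = c(shared, setdiff(acc_p, shared), setdiff(acc_f, shared)),
    status = rep(c("shared", "unique_passed", "unique_failed"),
                 c(length(shared), length(acc_p) - length(shared),
                   length(acc_f) - length(shared)))
  )
  structure(res, class = c("proteome_partition", class(res)),
            n_passed = length(acc_p), n_failed = length(acc_f))
}

#' Fraction of total abundance carried by the top-n proteins
#'
#' Ranks proteins by mean emPAI across a table's samples and returns the
#' summed abundance of the `n` most abundant proteins divided by the
#' table's total. Ties at rank `n` break deterministically by accession
#' order.
#'
#' @param t A long protein tibble with `accession` and `empai` columns.
#' @param n Number of top proteins (default 20).
#' @return A single fraction in (0, 1].
#' @export
top_n_fraction <- function(t, n = 20L) {
  if (nrow(t) == 0) abort("protein table is empty")
  ab <- dplyr::summarise(dplyr::group_by(t, .data$accession),
                         abundance = mean(.data$empai), .groups = "drop")
  if (n < 1 || n > nrow(ab)) {
    abort(sprintf("n must be in [1, %d]", nrow(ab)))
  }
  ab <- ab[order(-ab$abundance, ab$accession), ]
  sum(ab$abundance[seq_len(n)]) / sum(ab$abundance)
}

#' Differential-protein calling between Passed and Failed tables
#'
#' Tests only the proteins shared by both tables (group-unique proteins
#' are presence/absence findings with no variance estimate on the absent
#' side). Per shared protein, a two-sided Welch t-test (or Wilcoxon
#' rank-sum test) compares `log10(emPAI + epsilon)` between the groups;
#' `epsilon` defaults to one tenth of the smallest nonzero emPAI across
#' both tables. Direction is the sign of the mean log10 ratio
#' Passed/Failed. P-values are raw by default; Benjamini-Hochberg
#' adjustment is available via `p_adjust = "BH"`.
#'
#' @param passed,failed Long protein tibbles with `accession`,
#'   `sample_id` and `empai` columns and at least two samples per group.
#' @param alpha Significance level (default 0.05); proteins with
#'   `p <= alpha` are returned.
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @param p_adjust Multiple-testing adjustment passed to
#'   [stats::p.adjust()]; `"none"` by default.
#' @param epsilon Offset added inside the log10; computed from the data
#'   when `NULL`.
#' @return A tibble of class `dep_result` with `accession`, `gene_id`,
#'   `name`, `direction` (`up_in_passed` / `down_in_passed`), `p_value`
#'   and `effect` (mean log10 emPAI ratio Passed/Failed), sorted by
#'   p-value. The number of proteins tested is in attribute `n_tested`.
#' @export
test_differential <- function(passed, failed, alpha = 0.05,
                              method = c("welch", "wilcoxon"),
                              p_adjust = "none", epsilon = NULL) {
  method <- match.arg(method)
  shared <- intersect(unique(passed$accession), unique(failed$accession))
  if (is.null(epsilon)) {
    nz <- c(passed$empai[passed$empai > 0], failed$empai[failed$empai > 0])
    epsilon <- if (length(nz)) min(nz) / 10 else 1e-6
  }
  meta <- dplyr::distinct(
    dplyr::bind_rows(passed, failed)[c("accession", "gene_id", "name")])

  rows <- purrr::map(shared, function(acc) {
    x <- log10(passed$empai[passed$accession == acc] + epsilon)
    y <- log10(failed$empai[failed$accession == acc] + epsilon)
    if (length(x) < 2 || length(y) < 2) {
      warn(sprintf("protein %s skipped: fewer than two replicates per group",
                   acc))
      return(NULL)
    }
    effect <- mean(x) - mean(y)
    p <- if (sd(x) == 0 && sd(y) == 0) {
      # degenerate but well-defined: identical constants are a non-call,
      # distinct constants an unambiguous call
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else if (method == "welch") {
      t.test(x, y, var.equal = FALSE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    }
    tibble::tibble(
      accession = acc,
      direction = if (effect >= 0) "up_in_passed" else "down_in_passed",
      p_value = p, effect = effect)
  })
  res <- dplyr::bind_rows(rows)
  n_tested <- nrow(res)
  if (n_tested > 0) {
    res$p_value <- p.adjust(res$p_value, method = p_adjust)
    res <- dplyr::left_join(res, meta, by = "accession")
    res <- res[res$p_value <= alpha,
               c("accession", "gene_id", "name", "direction",
                 "p_value", "effect")]
    res <- res[order(res$p_value, res$accession), ]
  }
  structure(res, class = c("dep_result", class(res)),
            n_tested = n_tested, alpha = alpha, method = method,
            epsilon = epsilon)
}
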