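#' Simulation settings for synthetic SP-EV protein tables
#'
#' Parameterises the emPAI-table generator. Shared proteins receive one
#' baseline log10-emPAI drawn from a common distribution and appear in
#' both groups; unique proteins draw from the same distribution but
#' appear in one group only (presence/absence, not abundance, encodes
#' uniqueness). Planted differential proteins add their full effect size
#' to the baseline of the favoured group.
#'
#' The defaults emulate the proteome structure the package targets: 69
#' shared proteins, 149 unique to Passed and 169 unique to Failed (tables
#' of 218 and 238 proteins), with three planted differential proteins
#' mirroring the reported calls - LGALS3BP down in Passed, nexin-1 (PN-1)
#' and seminal plasma protein pB1 (BSP1) up in Passed.
#'
#' @param n_shared,n_unique_passed,n_unique_failed Protein counts per
#'   partition class.
#' @param planted_deps Tibble with columns `accession`, `gene_id`,
#'   `name`, `direction` (`"up_in_passed"` or `"down_in_passed"`) and
#'   `effect` (log10-emPAI offset). Planted accessions are assigned to
#'   the shared set and must be distinct.
#' @param samples_per_group Replicate emPAI columns per group (default 9).
#' @param empai_noise_sd Per-sample noise sd on log10-emPAI (default 0.2).
#' @param base_mean,base_sd Distribution of baseline log10-emPAI across
#'   proteins.
#' @param seed Integer seed.
#' @return An object of class `protein_sim_config`.
#' @export
protein_sim_config <- function(n_shared = 69L,
                               n_unique_passed = 149L,
                               n_unique_failed = 169L,
                               planted_deps = default_planted_deps(),
                               samples_per_group = 9L,
                               empai_noise_sd = 0.2,
                               base_mean = 0,
                               base_sd = 0.5,
                               seed = 7L) {
  n_shared <- check_count(n_shared, "n_shared", min = 0L)
  n_unique_passed <- check_count(n_unique_passed, "n_unique_passed", min = 0L)
  n_unique_failed <- check_count(n_unique_failed, "n_unique_failed", min = 0L)
  if (!is.null(planted_deps) && nrow(planted_deps)) {
    planted_deps <- tibble::as_tibble(planted_deps)
    if (anyDuplicated(planted_deps$accession)) {
      abort("planted accessions must be distinct")
    }
    if (!all(is.finite(planted_deps$effect))) {
      abort("planted effect sizes must be finite")
    }
    if (!all(planted_deps$direction %in%
             c("up_in_passed", "down_in_passed"))) {
      abort("planted direction must be 'up_in_passed' or 'down_in_passed'")
    }
    if (nrow(planted_deps) > n_shared) {
      abort("cannot plant more differential proteins than shared proteins")
    }
  } else {
    planted_deps <- default_planted_deps()[0, ]
  }
  if (empai_noise_sd < 0) abort("empai_noise_sd must be non-negative")
  structure(list(
    n_shared = n_shared,
    n_unique_passed = n_unique_passed,
    n_unique_failed = n_unique_failed,
    planted_deps = planted_deps,
    samples_per_group = check_count(samples_per_group, "samples_per_group"),
    empai_noise_sd = empai_noise_sd,
    base_mean = base_mean,
    base_sd = base_sd,
    seed = check_count(seed, "seed", min = 0L)
  ), class = "protein_sim_config")
}

#' Default planted differential SP-EV proteins
#'
#' The three differential proteins and directions the analysis is
#' benchmarked against: LGALS3BP down-regulated in Passed relative to
#' Failed; nexin-1 and seminal plasma protein pB1 up-regulated in Passed.
#' Effects are +1 on the log10-emPAI scale (a tenfold abundance ratio).
#'
#' @return A tibble with columns `accession`, `gene_id`, `name`,
#'   `direction`, `effect`.
#' @export
default_planted_deps <- function() {
  tibble::tibble(
    accession = c("gi|456752927", "gi|28435507", "gi|3599989"),
    gene_id = c("LGALS3BP", "PN-1", "BSP1"),
    name = c("Lectin, galactoside-binding, soluble, 3 binding protein",
             "Nexin-1",
             "Seminal plasma protein pB1 precursor"),
    direction = c("down_in_passed", "up_in_passed", "up_in_passed"),
    effect = c(1, 1, 1)
  )
}

#' Simulate paired emPAI protein tables for Passed and Failed groups
#'
#' @param config A [protein_sim_config()].
#' @return A list with `passed` and `failed` (long protein tibbles with
#'   columns `accession`, `gene_id`, `name`, `group`, `sample_id`,
#'   `empai`) and `truth`, a tibble of ground-truth labels per accession
#'   (`status` in shared / unique_passed / unique_failed, `is_dep`,
#'   `direction`, `effect`).
#' @examples
#' sim <- simulate_empai_table(protein_sim_config(seed = 1))
#' dplyr::n_distinct(sim$passed$accession)
#' @export
simulate_empai_table <- function(config) {
  stopifnot(inherits(config, "protein_sim_config"))
  set.seed(config$seed)
  planted <- config$planted_deps
  n_extra_shared <- config$n_shared - nrow(planted)

  shared_acc <- c(planted$accession,
                  sprintf("gi|SH%04d", seq_len(n_extra_shared)))
  up_acc <- sprintf("gi|UP%04d", seq_len(config$n_unique_passed))
  uf_acc <- sprintf("gi|UF%04d", seq_len(config$n_unique_failed))

  truth <- tibble::tibble(
    accession = c(shared_acc, up_acc, uf_acc),
    gene_id = c(planted$gene_id,
                sprintf("SHARED%04d", seq_len(n_extra_shared)),
                sprintf("UNIQP%04d", seq_len(config$n_unique_passed)),
                sprintf("UNIQF%04d", seq_len(config$n_unique_failed))),
    name = c(planted$name,
             sprintf("Shared SP-EV protein %d", seq_len(n_extra_shared)),
             sprintf("Passed-unique SP-EV protein %d",
                     seq_len(config$n_unique_passed)),
             sprintf("Failed-unique SP-EV protein %d",
                     seq_len(config$n_unique_failed))),
    status = rep(c("shared", "unique_passed", "unique_failed"),
                 c(config$n_shared, config$n_unique_passed,
                   config$n_unique_failed)),
    is_dep = c(rep(TRUE, nrow(planted)),
               rep(FALSE, n_extra_shared + config$n_unique_passed +
                     config$n_unique_failed)),
    direction = c(planted$direction,
                  rep(NA_character_, n_extra_shared +
                        config$n_unique_passed + config$n_unique_failed)),
    effect = c(planted$effect,
               rep(NA_real_, n_extra_shared + config$n_unique_passed +
                     config$n_unique_failed))
  )

  # one baseline log10-emPAI per protein, common to both groups
  base <- rnorm(nrow(truth), config$base_mean, config$base_sd)
  offset_passed <- ifelse(!is.na(truth$direction) &
                            truth$direction == "up_in_passed",
                          truth$effect, 0)
  offset_failed <- ifelse(!is.na(truth$direction) &
                            truth$direction == "down_in_passed",
                          truth$effect, 0)
  offset_passed[is.na(offset_passed)] <- 0
  offset_failed[is.na(offset_failed)] <- 0

  make_table <- function(keep, group, offset) {
    n_prot <- sum(keep)
    n_samp <- config$samples_per_group
    prefix <- if (group == "Passed") "P" else "F"
    log_empai <- rep(base[keep] + offset[keep], each = n_samp) +
      rnorm(n_prot * n_samp, 0, config$empai_noise_sd)
    tibble::tibble(
      accession = rep(truth$accession[keep], each = n_samp),
      gene_id = rep(truth$gene_id[keep], each = n_samp),
      name = rep(truth$name[keep], each = n_samp),
      group = group,
      sample_id = rep(sprintf("%s%02d", prefix, seq_len(n_samp)), n_prot),
      empai = 10^log_empai
    )
  }
  passed <- make_table(truth$status %in% c("shared", "unique_passed"),
                       "Passed", offset_passed)
  failed <- make_table(truth$status %in% c("shared", "unique_failed"),
                       "Failed", offset_failed)
  list(passed = passed, failed = failed, truth = truth)
}
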