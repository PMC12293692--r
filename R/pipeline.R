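#' Assemble a pipeline configuration
#'
#' One configuration drives the whole analysis: simulate (or read)
#' spectra, a water reference and protein tables; preprocess; classify by
#' cross-validated PCA-LDA; build aquaphotomics summaries; call
#' differential proteins. Stages whose section is `NULL` are skipped, so
#' partial configs run partial pipelines. The single `seed` fans out to
#' fixed per-stage seeds (`seed + 1009` spectra, `+ 2003` water, `+ 3001`
#' proteins, `+ 4001` cross-validation) so each stage is independently
#' reproducible.
#'
#' @param seed Master seed for the run.
#' @param simulate List with any of `spectra` (arguments to
#'   [sim_config()]), `water_scans` (count) and `proteins` (arguments to
#'   [protein_sim_config()]); set an element to `NULL` to skip it.
#' @param spectra_csv,water_csv,passed_tsv,failed_tsv Optional input
#'   files, used instead of simulation when given.
#' @param preprocess List: `lo_nm`, `hi_nm` (trim region),
#'   `average_replicates` (replicate policy; `TRUE` collapses the
#'   replicates of each sample to its mean spectrum before modeling) and
#'   `scatter_correction` (`TRUE` applies SNV per scan; off by default).
#' @param classify List (`folds`, `variance_threshold`) or `NULL` to
#'   skip classification.
#' @param aquagram `TRUE`/`FALSE`: build WABS, barcode and aquagram.
#' @param proteomics List (`alpha`, `method`, `top_n`) or `NULL` to skip.
#' @param output_dir Optional directory; when set, the run report is
#'   written there as `report.json`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            simulate = list(spectra = list(),
                                            water_scans = 10L,
                                            proteins = list()),
                            spectra_csv = NULL,
                            water_csv = NULL,
                            passed_tsv = NULL,
                            failed_tsv = NULL,
                            preprocess = list(lo_nm = 1300, hi_nm = 1600,
                                              average_replicates = TRUE),
                            classify = list(folds = NULL,
                                            variance_threshold = 0.9999),
                            aquagram = TRUE,
                            proteomics = list(alpha = 0.05,
                                              method = "welch",
                                              top_n = 20L),
                            output_dir = NULL) {
  for (f in c(spectra_csv, water_csv, passed_tsv, failed_tsv)) {
    if (!is.null(f) && !file.exists(f)) {
      abort(paste0("configured input file does not exist: ", f))
    }
  }
  structure(list(
    seed = check_count(seed, "seed", min = 0L),
    simulate = simulate,
    spectra_csv = spectra_csv, water_csv = water_csv,
    passed_tsv = passed_tsv, failed_tsv = failed_tsv,
    preprocess = preprocess, classify = classify,
    aquagram = isTRUE(aquagram), proteomics = proteomics,
    output_dir = output_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  defaults <- formals(pipeline_config)
  args <- modifyList(lapply(defaults[setdiff(known, names(raw))], eval),
                     raw)
  do.call(pipeline_config, args)
}

stage_seeds <- function(seed) {
  c(spectra = seed + 1009L, water = seed + 2003L,
    proteins = seed + 3001L, cv = seed + 4001L)
}

run_stage <- function(stage, report, config, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(config$output_dir)) write_run_report(report, config)
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full seminal-plasma analysis pipeline
#'
#' Executes the configured stages in order - inputs (simulation or
#' files), preprocessing, PCA-LDA classification, aquaphotomics,
#' EV proteomics - and assembles a consolidated run report. A stage
#' error aborts with the stage name and cause; sections already computed
#' are still written to `output_dir` when one is configured. Re-running
#' with an identical config reproduces the report payload bit-identically
#' (no wall-clock values enter the payload).
#'
#' @param config A [pipeline_config()], or a path to a YAML config file.
#' @return A list of class `run_report` with sections `classification`
#'   (metrics, counts, per-fold components), `aquaphotomics` (WABS,
#'   barcode, aquagram), `proteomics` (partition counts, top-n fractions,
#'   differential proteins), plus `config`, `seed`, `stage_seeds`,
#'   `version` and a `decisions` log of the defaults actually applied.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 1, simulate = list(
#'   spectra = list(n_passed = 6, n_failed = 6, replicates_per_sample = 2),
#'   water_scans = 4, proteins = list(n_shared = 10, n_unique_passed = 5,
#'                                    n_unique_failed = 5)))
#' rep <- run_pipeline(cfg)
#' rep$classification$metrics
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed)
  report <- list(
    version = as.character(utils::packageVersion("aquasem")),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    config = config_echo(config),
    decisions = list()
  )
  note <- function(msg) report$decisions <<- c(report$decisions, msg)

  # --- inputs -------------------------------------------------------------
  spectra <- water <- passed <- failed <- NULL
  inputs <- run_stage("inputs", report, config, {
    if (!is.null(config$spectra_csv)) {
      spectra <- read_spectra_csv(config$spectra_csv)
    } else if (!is.null(config$simulate$spectra)) {
      sim_args <- modifyList(list(seed = unname(seeds["spectra"])),
                             config$simulate$spectra)
      spectra <- simulate_sp_spectra(do.call(sim_config, sim_args))
    }
    if (!is.null(config$water_csv)) {
      water <- read_spectra_csv(config$water_csv)
    } else if (!is.null(spectra) && !is.null(config$simulate$water_scans)) {
      w_args <- modifyList(list(seed = unname(seeds["water"])),
                           config$simulate$spectra %||% list())
      water <- simulate_water_reference(do.call(sim_config, w_args),
                                        n_scans = config$simulate$water_scans)
    }
    if (!is.null(config$passed_tsv) && !is.null(config$failed_tsv)) {
      passed <- read_protein_tsv(config$passed_tsv)
      failed <- read_protein_tsv(config$failed_tsv)
    } else if (!is.null(config$simulate$proteins)) {
      p_args <- modifyList(list(seed = unname(seeds["proteins"])),
                           config$simulate$proteins)
      sim <- simulate_empai_table(do.call(protein_sim_config, p_args))
      passed <- sim$passed
      failed <- sim$failed
    }
    list(spectra = spectra, water = water, passed = passed, failed = failed)
  })
  spectra <- inputs$spectra; water <- inputs$water
  passed <- inputs$passed; failed <- inputs$failed

  # --- preprocessing ------------------------------------------------------
  if (!is.null(spectra)) {
    pp <- config$preprocess
    trimmed <- run_stage("preprocess", report, config, {
      if (spectra$mode[1] == "transmittance") {
        spectra <- to_absorbance(spectra)
      }
      spectra <- trim_region(spectra, pp$lo_nm %||% 1300,
                             pp$hi_nm %||% 1600)
      if (!is.null(water)) {
        water <- trim_region(water, pp$lo_nm %||% 1300, pp$hi_nm %||% 1600)
      }
      if (isTRUE(pp$scatter_correction)) {
        spectra <- snv_correct(spectra)
        if (!is.null(water)) water <- snv_correct(water)
      }
      list(spectra = spectra, water = water)
    })
    spectra <- trimmed$spectra
    water <- trimmed$water
    note(sprintf("trim region [%g, %g] nm", pp$lo_nm %||% 1300,
                 pp$hi_nm %||% 1600))
    note(sprintf("replicate policy: %s",
                 if (isTRUE(pp$average_replicates %||% TRUE))
                   "sample means (replicates averaged before modeling)"
                 else "replicate-level rows with sample-grouped folds"))
  }

  # --- classification -----------------------------------------------------
  if (!is.null(config$classify) && !is.null(spectra)) {
    cls <- config$classify
    classification <- run_stage("classify", report, config, {
      model_input <- if (isTRUE(config$preprocess$average_replicates %||%
                               TRUE)) {
        average_replicates(spectra)
      } else spectra
      cm <- cross_validate_pca_lda(
        model_input, folds = cls$folds,
        variance_threshold = cls$variance_threshold %||% 0.9999,
        seed = unname(seeds["cv"]))
      list(
        counts = as.list(as.data.frame(as.table(unclass(cm)))),
        metrics = as.list(confusion_metrics(cm)[
          c("accuracy", "sensitivity", "specificity")]),
        per_fold_components = as.integer(attr(cm, "fold_k")),
        positive_class = attr(cm, "positive_class"),
        folds = length(attr(cm, "fold_k")),
        variance_threshold = cls$variance_threshold %||% 0.9999
      )
    })
    report$classification <- classification
    note("classification: per-fold PCA and component re-selection (no leakage)")
  }

  # --- aquaphotomics ------------------------------------------------------
  if (isTRUE(config$aquagram) && !is.null(spectra) && !is.null(water)) {
    aqua <- run_stage("aquagram", report, config, {
      normalized <- normalize_reference(dplyr::bind_rows(spectra, water),
                                        water)
      bands <- wamacs_bands()
      wabs <- detect_wabs_by_group(normalized, bands)
      barcode <- build_barcode(wabs, bands)
      ag <- compute_aquagram(normalized, bands)
      list(wabs = as.list(wabs),
           barcode = as.list(tibble::as_tibble(barcode)),
           aquagram = as.list(tibble::as_tibble(ag)))
    })
    report$aquaphotomics <- aqua
    note("normalization: water-mean subtraction / per-category SD (n-1)")
    note("aquagram evaluated at each group's own WABS wavelength")
  }

  # --- proteomics ---------------------------------------------------------
  if (!is.null(config$proteomics) && !is.null(passed) && !is.null(failed)) {
    prt <- config$proteomics
    proteomics <- run_stage("proteomics", report, config, {
      part <- partition_proteins(passed, failed)
      deps <- test_differential(passed, failed,
                                alpha = prt$alpha %||% 0.05,
                                method = prt$method %||% "welch")
      top_n <- min(prt$top_n %||% 20L,
                   dplyr::n_distinct(passed$accession),
                   dplyr::n_distinct(failed$accession))
      list(
        partition = as.list(glance(part)),
        top_n = top_n,
        top_n_fraction_passed = top_n_fraction(passed, top_n),
        top_n_fraction_failed = top_n_fraction(failed, top_n),
        n_tested = attr(deps, "n_tested"),
        alpha = prt$alpha %||% 0.05,
        deps = as.list(tibble::as_tibble(deps))
      )
    })
    report$proteomics <- proteomics
    note(sprintf("differential test: %s on log10(emPAI + eps), raw p-values",
                 prt$method %||% "welch"))
  }

  report <- structure(report, class = "run_report")
  if (!is.null(config$output_dir)) write_run_report(report, config)
  report
}

# config echo with file paths and plain options; functions never enter it
config_echo <- function(config) {
  echo <- unclass(config)
  echo$output_dir <- NULL
  echo
}

#' Serialize a run report to JSON
#'
#' The payload contains no wall-clock values, so identical runs produce
#' byte-identical files.
#'
#' @param report A `run_report`.
#' @param config The `pipeline_config` of the run (for `output_dir`), or
#'   a directory path.
#' @return The path of the written file, invisibly.
#' @export
write_run_report <- function(report, config) {
  dir <- if (is.character(config)) config else config$output_dir
  if (is.null(dir)) abort("no output directory configured")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  seed:", x$seed, " version:", x$version, "\n")
  if (!is.null(x$classification)) {
    m <- x$classification$metrics
    cat(sprintf("  classification: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
                m$accuracy, m$sensitivity, m$specificity))
  }
  if (!is.null(x$aquaphotomics)) {
    cat("  aquaphotomics: WABS, barcode and aquagram for",
        length(unique(x$aquaphotomics$wabs$group)), "groups\n")
  }
  if (!is.null(x$proteomics)) {
    p <- x$proteomics$partition
    cat(sprintf("  proteomics: %d vs %d proteins, %d shared, %d differential\n",
                p$n_passed, p$n_failed, p$n_shared,
                length(x$proteomics$deps$accession)))
  }
  invisible(x)
}
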