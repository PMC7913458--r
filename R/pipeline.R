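## End-to-end study pipeline: (generate | ingest) -> match -> cohort ->
## models -> report, with a run manifest that records every seed and
## per-stage row count so a run can be reproduced exactly.

#' Run the full inpatient outcome study
#'
#' Executes the whole analysis in the order of the patient-flow diagram:
#' eligibility filtering (adults with at least one diagnosis), stay-history
#' annotation against the full history, random selection of one stay per
#' patient, exposure classification against the catalogue, per-outcome
#' cohort construction, the baseline table, unadjusted 2x2 mortality odds
#' ratios, the five adjusted models, sex-subgroup mortality models, and the
#' three sensitivity analyses.
#'
#' Input is either a synthetic configuration (`config`) or observed tables
#' (`stays` + `diagnoses` + `cat`, as data frames or file paths). When
#' `out_dir` is given, the tidy results, the baseline table, the flow report
#' and the manifest (plus generated data, for synthetic runs) are written
#' there.
#'
#' @param config a `rd_config`; used when `stays` is `NULL`.
#' @param stays,diagnoses observed tables (data frames or CSV/TSV paths).
#' @param cat catalogue (a `rd_catalogue` or a file path); required with
#'   `stays`.
#' @param out_dir optional output directory.
#' @param seed top-level seed; per-stage seeds are derived from it
#'   deterministically. Defaults to the config seed.
#' @return Invisibly, a list with `results` (tidy effect estimates),
#'   `baseline`, `flow`, `manifest`, and `data` (the selected-cohort model
#'   data).
#' @export
run_study <- function(config = synthetic_config(), stays = NULL,
                      diagnoses = NULL, cat = NULL, out_dir = NULL,
                      seed = NULL) {
  t0 <- Sys.time()
  synthetic <- is.null(stays)
  seed <- as.integer(seed %||% config$seed)
  flow <- list()
  dataset <- NULL
  if (synthetic) {
    config$seed <- seed
    dataset <- generate_population(config)
    stays <- dataset$stays
    diagnoses <- dataset$diagnoses
    cat <- dataset$catalogue
  } else {
    if (is.character(stays)) stays <- read_stays(stays)
    if (is.character(diagnoses)) diagnoses <- read_diagnoses(diagnoses)
    stop_if(is.null(cat), "a catalogue is required when observed tables are supplied")
    if (is.character(cat)) cat <- read_catalogue(cat)
    stays <- annotate_stay_history(stays)
  }
  validate_stays(stays)
  flow$stays_total <- nrow(stays)
  flow$patients_total <- length(unique(stays$patient_id))

  elig <- filter_eligible(stays, diagnoses)
  flow$removed_underage <- unname(elig$removed["underage"])
  flow$removed_no_diagnosis <- unname(elig$removed["no_diagnosis"])
  flow$stays_eligible <- elig$n_out

  selected <- select_one_stay_per_patient(elig$stays, seed = seed + 7L)
  flow$patients_selected <- nrow(selected)

  expo <- summarize_exposure(
    diagnoses[diagnoses$stay_id %in% selected$stay_id, , drop = FALSE], cat)
  data <- prepare_model_data(selected, expo)
  flow$exposure_groups <- as.list(table(data$rare_group))

  cohorts <- lapply(setNames(nm = names(OUTCOME_COLUMNS)), function(oc) {
    build_outcome_cohort(data, oc)
  })
  for (oc in names(cohorts)) {
    stop_if(nrow(cohorts[[oc]]$cohort) == 0L,
            sprintf("empty cohort for outcome %s", oc))
  }
  flow$cohort_sizes <- lapply(cohorts, function(co) nrow(co$cohort))
  flow$cohort_exclusions <- lapply(cohorts, function(co) as.list(co$excluded))

  baseline <- baseline_table(data)

  ## unadjusted mortality ORs from the 2x2 tables (each exposed group vs 0)
  deaths <- tapply(data$died_in_hospital, data$rare_group, sum)
  sizes <- table(data$rare_group)
  unadj <- do.call(rbind, lapply(c("1", ">1"), function(gr) {
    t <- two_by_two(deaths[[gr]], sizes[[gr]] - deaths[[gr]],
                    deaths[["0"]], sizes[["0"]] - deaths[["0"]])
    est <- or_from_table(t)
    data.frame(model = paste0("mortality_unadjusted_", gr),
               term = paste0("rare_group", gr), est[-1L],
               stringsAsFactors = FALSE)
  }))

  fits <- list(
    unadj,
    fit_logistic(cohorts$mortality$cohort, model_spec("mortality")),
    fit_logistic(cohorts$icu_admission$cohort, model_spec("icu_admission")),
    fit_log_linear(cohorts$los$cohort, model_spec("los")),
    fit_log_linear(cohorts$icu_los$cohort, model_spec("icu_los")),
    fit_logistic(cohorts$readmission_30d$cohort, model_spec("readmission_30d")),
    fit_logistic(cohorts$mortality$cohort, model_spec("mortality", subgroup_sex = "F")),
    fit_logistic(cohorts$mortality$cohort, model_spec("mortality", subgroup_sex = "M")),
    run_sensitivity("stay-count-adjusted", cohorts$mortality$cohort),
    run_sensitivity("rare-by-nonrare-interaction", cohorts$mortality$cohort),
    run_sensitivity("rare-by-unit-interaction", cohorts$mortality$cohort))
  results <- do.call(rbind, fits)
  rownames(results) <- NULL

  manifest <- list(
    package = "raredx",
    version = as.character(packageVersion("raredx")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    input = if (synthetic) "synthetic" else "observed",
    seed = seed,
    selection_seed = seed + 7L,
    config = if (synthetic) unclass(config),
    flow = flow,
    n_results = nrow(results))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (synthetic) write_dataset(dataset, file.path(out_dir, "data"))
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    write.csv(baseline, file.path(out_dir, "baseline.csv"), row.names = FALSE)
    write.table(format_baseline_table(baseline),
                file.path(out_dir, "baseline_formatted.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    jsonlite::write_json(flow, file.path(out_dir, "flow.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$output_dir <- normalizePath(out_dir)
  }
  invisible(list(results = results, baseline = baseline, flow = flow,
                 manifest = manifest, data = data, cohorts = cohorts))
}
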