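# Cohort CSV schema, validation, and run manifests.
#
# On-disk layout of a cohort directory:
#   patients.csv, stays.csv, observations.csv, truth.csv, manifest.yml
# Times are hours from ICU admission (real numbers); categorical fields use
# the fixed literals "pre"/"post"/"crossover" and
# "White"/"Black"/"Latinx"/"Other".

COHORT_SCHEMA <- list(
  patients = c("patient_id", "ethnicity", "age_years", "sex", "weight_kg",
               "ckd", "chf", "hypertension", "diabetes", "copd", "afib",
               "cad", "stroke", "liver_disease", "cancer", "obesity"),
  stays = c("stay_id", "patient_id", "icu_admit_time", "icu_discharge_time",
            "hospital_discharge_time", "emr_epoch", "readmission_time"),
  observations = c("stay_id", "time_h", "channel", "value", "units"),
  truth = c("stay_id", "true_aki_stage", "true_readmission_gap_h")
)

schema_error <- function(...) {
  stop(structure(class = c("icushift_schema_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

#' Write a cohort to a directory of CSV files
#'
#' @param cohort a `generated_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in c("patients", "stays", "observations", "truth"))
    data.table::fwrite(cohort[[tb]], file.path(dir, paste0(tb, ".csv")))
  manifest <- cohort$manifest
  manifest$config$ethnicity_mix <- as.list(manifest$config$ethnicity_mix)
  manifest$config$epoch_mix <- as.list(manifest$config$epoch_mix)
  manifest$config$stage_mix <- as.list(manifest$config$stage_mix)
  manifest$config$obs_cadence <- as.list(manifest$config$obs_cadence)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' Read and validate a cohort directory
#'
#' Checks required columns, categorical literals, referential integrity
#' (observations and truth reference known stays, stays reference known
#' patients) and value ranges, reporting offending row numbers.
#'
#' @param dir a directory written by [write_cohort()] (or conforming CSVs).
#' @return a `generated_cohort`.
#' @export
read_cohort <- function(dir) {
  tabs <- list()
  for (tb in names(COHORT_SCHEMA)) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) schema_error("missing table file: %s", path)
    x <- data.table::fread(path)
    missing_cols <- setdiff(COHORT_SCHEMA[[tb]], names(x))
    if (length(missing_cols))
      schema_error("%s.csv lacks required column(s): %s", tb,
                   paste(missing_cols, collapse = ", "))
    tabs[[tb]] <- x
  }
  validate_cohort_tables(tabs)
  manifest <- NULL
  mpath <- file.path(dir, "manifest.yml")
  if (file.exists(mpath)) manifest <- yaml::read_yaml(mpath)
  structure(c(tabs, list(manifest = manifest)), class = "generated_cohort")
}

validate_cohort_tables <- function(tabs) {
  bad_rows <- function(flag) paste(utils::head(which(flag), 5), collapse = ", ")
  p <- tabs$patients; s <- tabs$stays; o <- tabs$observations; tr <- tabs$truth
  bad <- !p$ethnicity %in% c("White", "Black", "Latinx", "Other")
  if (any(bad))
    schema_error("patients.csv: unknown ethnicity literal at row(s) %s",
                 bad_rows(bad))
  bad <- !s$emr_epoch %in% c("pre", "post", "crossover")
  if (any(bad))
    schema_error("stays.csv: unknown emr_epoch literal at row(s) %s",
                 bad_rows(bad))
  bad <- !s$patient_id %in% p$patient_id
  if (any(bad))
    schema_error("stays.csv: stay references missing patient at row(s) %s",
                 bad_rows(bad))
  bad <- !(s$icu_admit_time < s$icu_discharge_time)
  if (any(bad))
    schema_error("stays.csv: icu_admit_time >= icu_discharge_time at row(s) %s",
                 bad_rows(bad))
  for (tb in c("observations", "truth")) {
    ids <- tabs[[tb]]$stay_id
    bad <- !ids %in% s$stay_id
    if (any(bad))
      schema_error("%s.csv: unknown stay_id at row(s) %s", tb, bad_rows(bad))
  }
  bad <- o$channel %in% c("urine_output", "creatinine") & o$value < 0
  if (any(bad))
    schema_error("observations.csv: negative value at row(s) %s",
                 bad_rows(bad))
  bad <- !tr$true_aki_stage %in% 0:3
  if (any(bad))
    schema_error("truth.csv: true_aki_stage outside 0..3 at row(s) %s",
                 bad_rows(bad))
  invisible(TRUE)
}

#' Write a run manifest
#'
#' Every pipeline entry point records its configuration snapshot, seeds,
#' input file fingerprints and per-stage row counts, sufficient to re-run
#' the step bit-identically.
#' @param path output YAML path.
#' @param step step name.
#' @param config configuration snapshot (list).
#' @param seeds integer seeds used.
#' @param counts named list of row counts per stage.
#' @param inputs character vector of input paths (fingerprinted).
#' @export
write_run_manifest <- function(path, step, config = list(), seeds = integer(0),
                               counts = list(), inputs = character(0)) {
  fp <- vapply(inputs, function(f)
    if (file.exists(f)) sprintf("%s:%d", basename(f), file.size(f))
    else sprintf("%s:missing", basename(f)), character(1))
  yaml::write_yaml(list(
    artifact_version = as.character(utils::packageVersion("icushift")),
    step = step, config = config, seeds = as.integer(seeds),
    input_fingerprints = as.list(unname(fp)), row_counts = counts
  ), path)
  invisible(path)
}
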