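#' Configuration for the synthetic ICU cohort generator
#'
#' Bundles every knob of the generator: cohort size, category mixtures,
#' outcome rates, and the two shift magnitudes used by the deployment
#' scenarios. Defaults reproduce the reference cohort composition used
#' throughout the package's experiments:
#' \itemize{
#'   \item AKI-stage mixture (0.399, 0.179, 0.321, 0.103) for stages 0--3,
#'     i.e. roughly 60\% of stays develop some stage of AKI within 7 days;
#'   \item EMR-epoch mixture (0.500, 0.386, 0.114) over pre/post/crossover,
#'     modelling a hospital that switched record systems, with crossover
#'     stays appearing in both systems;
#'   \item ethnicity mixture with 71.6\% White;
#'   \item a 6.5\% rate of ICU readmission within 72 hours of discharge.
#' }
#'
#' @param n_stays positive integer, number of ICU stays to simulate.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full configuration including this seed.
#' @param ethnicity_mix named proportions over White/Black/Latinx/Other.
#' @param epoch_mix named proportions over pre/post/crossover EMR epochs.
#' @param stage_mix named proportions over AKI stages "0".."3".
#' @param readmission_rate_72h fraction of stays readmitted to the ICU
#'   within 72 h of ICU discharge.
#' @param drift_magnitude non-negative scalar (delta). 0 means the
#'   feature-to-risk relation is identical in both EMR epochs; larger values
#'   rotate the post-epoch risk coefficients further from the pre-epoch ones.
#' @param subgroup_effect non-negative scalar (eta). 0 means the relation is
#'   identical across ethnicity groups; larger values rotate the non-White
#'   risk coefficients away from the White ones.
#' @param urine_available logical; when FALSE no urine-output channel is
#'   charted (the feature-change scenarios toggle this).
#' @param noise_sd positive scalar multiplying all per-observation channel
#'   noise (1 = calibrated default).
#' @param obs_cadence named numeric vector of sampling intervals in hours
#'   for the creatinine, urine, vitals and labs channel groups.
#' @param aki_prevalence_preset `"icu_cohort"` (default; stage mixture as
#'   above) or `"hospital_wide"`, an alternative preset with 6\% total AKI
#'   prevalence reflecting hospital-wide rather than ICU rates.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_stays = 200, seed = 1)
#' cfg$stage_mix
cohort_config <- function(n_stays,
                          seed = 1L,
                          ethnicity_mix = c(White = 0.716, Black = 0.075,
                                            Latinx = 0.034, Other = 0.175),
                          epoch_mix = c(pre = 0.500, post = 0.386,
                                        crossover = 0.114),
                          stage_mix = c(`0` = 16837, `1` = 7558,
                                        `2` = 13535, `3` = 4321) / 42251,
                          readmission_rate_72h = 0.065,
                          drift_magnitude = 0.6,
                          subgroup_effect = 0.5,
                          urine_available = TRUE,
                          noise_sd = 1,
                          obs_cadence = c(creatinine = 12, urine = 1,
                                          vitals = 1, labs = 24),
                          aki_prevalence_preset = c("icu_cohort",
                                                    "hospital_wide")) {
  aki_prevalence_preset <- match.arg(aki_prevalence_preset)
  if (aki_prevalence_preset == "hospital_wide" && missing(stage_mix))
    stage_mix <- c(`0` = 0.94, `1` = 0.030, `2` = 0.020, `3` = 0.010)
  if (!is.numeric(n_stays) || length(n_stays) != 1 || is.na(n_stays) ||
      n_stays < 1 || n_stays != floor(n_stays))
    stop_input("n_stays must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_input("seed must be a single integer")
  ethnicity_mix <- check_prob_vector(ethnicity_mix, "ethnicity_mix",
                                     c("White", "Black", "Latinx", "Other"))
  epoch_mix <- check_prob_vector(epoch_mix, "epoch_mix",
                                 c("pre", "post", "crossover"))
  stage_mix <- check_prob_vector(stage_mix, "stage_mix",
                                 c("0", "1", "2", "3"))
  for (nm in c("readmission_rate_72h", "drift_magnitude", "subgroup_effect",
               "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop_input("%s must be a finite scalar", nm)
  }
  if (readmission_rate_72h < 0 || readmission_rate_72h > 1)
    stop_input("readmission_rate_72h must lie in [0, 1]")
  if (drift_magnitude < 0 || subgroup_effect < 0)
    stop_input("drift_magnitude and subgroup_effect must be >= 0")
  if (noise_sd <= 0) stop_input("noise_sd must be > 0")
  if (!is.logical(urine_available) || length(urine_available) != 1)
    stop_input("urine_available must be TRUE or FALSE")
  cadence <- check_cadence(obs_cadence)

  structure(list(
    n_stays = as.integer(n_stays),
    seed = as.integer(seed),
    ethnicity_mix = ethnicity_mix,
    epoch_mix = epoch_mix,
    stage_mix = stage_mix,
    readmission_rate_72h = readmission_rate_72h,
    drift_magnitude = drift_magnitude,
    subgroup_effect = subgroup_effect,
    urine_available = urine_available,
    noise_sd = noise_sd,
    obs_cadence = cadence,
    aki_prevalence_preset = aki_prevalence_preset
  ), class = "cohort_config")
}

check_cadence <- function(obs_cadence) {
  want <- c("creatinine", "urine", "vitals", "labs")
  if (!is.numeric(obs_cadence) || is.null(names(obs_cadence)) ||
      !all(want %in% names(obs_cadence)))
    stop_input("obs_cadence must be a named numeric vector with entries {%s}",
               paste(want, collapse = ", "))
  v <- obs_cadence[want]
  if (any(!is.finite(v)) || any(v <= 0))
    stop_input("obs_cadence entries must be positive and finite")
  # bounds that keep the label round-trip exact: urine charting must stay
  # inside the 2 h KDIGO gap tolerance (with 20% jitter), creatinine must
  # chart the 24 h peak plateau, and every channel needs a first-day value
  if (v[["urine"]] > 1.6)
    stop_input("urine cadence must be <= 1.6 h for KDIGO span coverage")
  if (v[["creatinine"]] > 16)
    stop_input("creatinine cadence must be <= 16 h")
  if (v[["vitals"]] > 24 || v[["labs"]] > 48)
    stop_input("vitals cadence must be <= 24 h and labs cadence <= 48 h")
  v
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_stays:", x$n_stays, " seed:", x$seed, "\n")
  cat("  stage mix:", paste(sprintf("%s=%.3f", names(x$stage_mix),
                                    x$stage_mix), collapse = " "), "\n")
  cat("  epoch mix:", paste(sprintf("%s=%.3f", names(x$epoch_mix),
                                    x$epoch_mix), collapse = " "), "\n")
  cat("  ethnicity:", paste(sprintf("%s=%.3f", names(x$ethnicity_mix),
                                    x$ethnicity_mix), collapse = " "), "\n")
  cat(sprintf("  drift delta=%.2f subgroup eta=%.2f urine=%s noise_sd=%.2f\n",
              x$drift_magnitude, x$subgroup_effect, x$urine_available,
              x$noise_sd))
  invisible(x)
}
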