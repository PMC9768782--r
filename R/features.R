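# Cohort extraction, the 83-column AKI feature matrix, and readmission
# window labels.
#
# The documented feature list (83 names with the urine group included):
#   4 demographics + 10 comorbidity flags
#   + 13 vitals/labs channels x 4 first-24h summaries (mean, min, max, last)
#   + 3 urine features + 1 minimum eGFR + 13 creatinine/eGFR-derived
# Prediction-time window: the first 24 h of the stay; labels cover days
# 0-7, so features precede most onsets.

#' Estimated glomerular filtration rate (MDRD-4)
#'
#' `175 * SCr^-1.154 * age^-0.203 * 0.742[female] * 1.212[Black]` in
#' mL/min/1.73 m^2.
#'
#' @param creatinine serum creatinine in mg/dL (> 0).
#' @param age_years age in years (>= 18).
#' @param sex "M" or "F".
#' @param ethnicity ethnicity group; the 1.212 factor applies to "Black".
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' egfr(1.0, 40, "M", "White")  # ~82.8
egfr <- function(creatinine, age_years, sex, ethnicity) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop_input("creatinine must be > 0")
  if (any(age_years < 18)) stop_input("age_years must be >= 18")
  v <- 175 * creatinine^(-1.154) * age_years^(-0.203)
  v <- v * ifelse(sex == "F", 0.742, 1)
  v * ifelse(ethnicity == "Black", 1.212, 1)
}

#' Apply cohort exclusions
#'
#' Removes stays with age < 18, a chronic-kidney-disease flag, AKI already
#' present in the first 24 h of the stay (admission AKI), or creatinine
#' series too sparse to compute a KDIGO baseline.
#'
#' @param cohort a `generated_cohort` (or list with the same tables).
#' @param labels optional precomputed [label_cohort()] output; computed
#'   (with dropped-baseline handling) when NULL.
#' @return list with `stay_ids` (eligible), `exclusions` (stay_id, reason)
#'   and `labels` (KDIGO labels of eligible stays).
#' @export
extract_cohort <- function(cohort, labels = NULL) {
  stays <- data.table::as.data.table(cohort$stays)
  patients <- data.table::as.data.table(cohort$patients)
  if (!nrow(stays))
    return(list(stay_ids = integer(0),
                exclusions = data.table::data.table(
                  stay_id = integer(0), reason = character(0)),
                labels = NULL))
  if (is.null(labels)) labels <- label_cohort(cohort, "drop")
  info <- merge(stays[, c("stay_id", "patient_id")],
                patients[, c("patient_id", "age_years", "ckd")],
                by = "patient_id")
  info <- merge(info, labels, by = "stay_id", all.x = TRUE)
  reason <- rep(NA_character_, nrow(info))
  reason[is.na(reason) & info$age_years < 18] <- "age_under_18"
  reason[is.na(reason) & info$ckd] <- "chronic_kidney_disease"
  reason[is.na(reason) &
           (is.na(info$stage) |
              (!is.na(info$criterion) &
                 info$criterion == "missing_baseline"))] <- "missing_baseline"
  reason[is.na(reason) & info$stage >= 1 &
           info$onset_time_h <= 24] <- "admission_aki"
  excl <- data.table::data.table(stay_id = info$stay_id, reason = reason)
  list(
    stay_ids = sort(info$stay_id[is.na(reason)]),
    exclusions = excl[!is.na(reason)][order(stay_id)],
    labels = labels[labels$stay_id %in% info$stay_id[is.na(reason)], ]
  )
}

#' The fixed feature-name order
#' @param include_urine logical; whether the urine feature group is present.
#' @return character vector of feature names (83 with the urine group).
#' @export
feature_names_aki <- function(include_urine = TRUE) {
  cat <- channel_catalog()
  ch <- as.vector(t(outer(cat$channel, c("mean", "min", "max", "last"),
                          paste, sep = "_")))
  nm <- c(
    "age_years", "sex_male", "weight_kg", "ethnicity_nonwhite",
    "chf", "hypertension", "diabetes", "copd", "afib", "cad", "stroke",
    "liver_disease", "cancer", "obesity",
    ch,
    if (include_urine) urine_feature_group(),
    "egfr_min",
    "creat_mean", "creat_min", "creat_max", "creat_last", "creat_first",
    "creat_sd", "creat_n", "creat_slope_per_h", "creat_delta",
    "creat_ratio_max_min", "creat_range", "egfr_mean", "egfr_last"
  )
  nm
}

#' @rdname feature_names_aki
#' @export
urine_feature_group <- function() {
  c("urine_mean_rate", "urine_min_rate", "urine_hours_below_0.5")
}

#' Build the per-stay AKI feature matrix
#'
#' Summarizes each eligible stay's first `window_h` hours into the fixed
#' 83-column feature layout (or 80 columns without the urine group). Raw
#' summaries never depend on any train/test flagging; normalization and
#' imputation are fitted separately via [normalize_features()].
#'
#' @param cohort a `generated_cohort`.
#' @param include_urine include the urine feature group?
#' @param stay_ids stays to featurize (default: all stays in the cohort;
#'   normally the eligible set from [extract_cohort()]).
#' @param window_h prediction-time window in hours (default 24).
#' @return object of class `feature_matrix`: list(stay_ids, feature_names,
#'   values, urine_group).
#' @export
build_features <- function(cohort, include_urine = TRUE, stay_ids = NULL,
                           window_h = 24) {
  obs <- data.table::as.data.table(cohort$observations)
  stays <- data.table::as.data.table(cohort$stays)
  patients <- data.table::as.data.table(cohort$patients)
  if (is.null(stay_ids)) stay_ids <- sort(stays$stay_id)
  stay_ids <- sort(stay_ids)
  dem <- merge(stays[stay_id %in% stay_ids,
                     c("stay_id", "patient_id")], patients,
               by = "patient_id")
  data.table::setkey(dem, stay_id)

  known <- c(channel_catalog()$channel, "creatinine", "urine_output")
  unknown <- setdiff(unique(obs$channel), known)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown channel(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    obs <- obs[!channel %in% unknown]
  }
  w <- obs[stay_id %in% stay_ids & time_h <= window_h]

  n <- length(stay_ids)
  nm <- feature_names_aki(include_urine)
  m <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))

  idx <- match(dem$stay_id, stay_ids)
  m[idx, "age_years"] <- dem$age_years
  m[idx, "sex_male"] <- as.numeric(dem$sex == "M")
  m[idx, "weight_kg"] <- dem$weight_kg
  m[idx, "ethnicity_nonwhite"] <- as.numeric(dem$ethnicity != "White")
  for (f in c("chf", "hypertension", "diabetes", "copd", "afib", "cad",
              "stroke", "liver_disease", "cancer", "obesity"))
    m[idx, f] <- as.numeric(dem[[f]])

  smry <- w[channel != "urine_output",
            .(mean = mean(value), min = min(value), max = max(value),
              last = value[which.max(time_h)]),
            by = .(stay_id, channel)]
  for (stat in c("mean", "min", "max", "last")) {
    wide <- data.table::dcast(smry, stay_id ~ channel, value.var = stat)
    ridx <- match(wide$stay_id, stay_ids)
    for (ch in setdiff(names(wide), "stay_id")) {
      col <- paste0(if (ch == "creatinine") "creat" else ch, "_", stat)
      if (ch == "creatinine" && stat == "last") col <- "creat_last"
      m[ridx, col] <- wide[[ch]]
    }
  }

  cr <- w[channel == "creatinine"][order(stay_id, time_h)]
  crs <- cr[, .(first = value[1], sd = if (.N > 1) stats::sd(value) else 0,
                n = as.numeric(.N),
                slope = if (.N > 1)
                  stats::cov(time_h, value) / stats::var(time_h) else 0,
                delta = value[.N] - value[1],
                ratio = max(value) / min(value),
                range = max(value) - min(value)),
            by = stay_id]
  ridx <- match(crs$stay_id, stay_ids)
  m[ridx, "creat_first"] <- crs$first
  m[ridx, "creat_sd"] <- crs$sd
  m[ridx, "creat_n"] <- crs$n
  m[ridx, "creat_slope_per_h"] <- crs$slope
  m[ridx, "creat_delta"] <- crs$delta
  m[ridx, "creat_ratio_max_min"] <- crs$ratio
  m[ridx, "creat_range"] <- crs$range

  dem_g <- dem[match(cr$stay_id, dem$stay_id)]
  cr[, egfr_v := egfr(pmax(value, 0.1), dem_g$age_years, dem_g$sex,
                      dem_g$ethnicity)]
  ge <- cr[, .(emin = min(egfr_v), emean = mean(egfr_v),
               elast = egfr_v[which.max(time_h)]), by = stay_id]
  ridx <- match(ge$stay_id, stay_ids)
  m[ridx, "egfr_min"] <- ge$emin
  m[ridx, "egfr_mean"] <- ge$emean
  m[ridx, "egfr_last"] <- ge$elast

  if (include_urine) {
    ur <- w[channel == "urine_output"]
    if (nrow(ur)) {
      wmap <- stats::setNames(dem$weight_kg, dem$stay_id)
      ur[, rate := value / wmap[as.character(stay_id)]]
      us <- ur[order(stay_id, time_h),
               .(mean_rate = mean(rate), min_rate = min(rate),
                 below = {
                   if (.N > 1) {
                     len <- diff(time_h)
                     sum(len[rate[-1] < 0.5])
                   } else 0
                 }), by = stay_id]
      ridx <- match(us$stay_id, stay_ids)
      m[ridx, "urine_mean_rate"] <- us$mean_rate
      m[ridx, "urine_min_rate"] <- us$min_rate
      m[ridx, "urine_hours_below_0.5"] <- us$below
    }
  }

  structure(list(stay_ids = stay_ids, feature_names = nm, values = m,
                 urine_group = if (include_urine) urine_feature_group()
                               else character(0)),
            class = "feature_matrix")
}

#' Fit and apply train-only normalization and imputation
#'
#' Per-feature (mean, sd) standardization and median imputation, with every
#' parameter estimated exclusively from the rows flagged as training.
#' Constant training columns get sd 1 so they standardize to 0.
#'
#' @param fm a [build_features()] result.
#' @param train_mask logical vector over `fm$stay_ids`, TRUE for training
#'   rows.
#' @return `fm` with `$normalized` (matrix, no missing values) and
#'   `$normalization` (per-feature mean/sd/median) attached.
#' @export
normalize_features <- function(fm, train_mask) {
  stopifnot(inherits(fm, "feature_matrix"),
            length(train_mask) == length(fm$stay_ids))
  if (!any(train_mask)) stop_input("train_mask selects no rows")
  tr <- fm$values[train_mask, , drop = FALSE]
  med <- apply(tr, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  v <- fm$values
  for (j in seq_len(ncol(v))) v[is.na(v[, j]), j] <- med[j]
  trv <- v[train_mask, , drop = FALSE]
  mu <- colMeans(trv)
  sdv <- apply(trv, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  fm$normalized <- sweep(sweep(v, 2, mu), 2, sdv, `/`)
  fm$normalization <- list(mean = mu, sd = sdv, median = med)
  fm
}

#' Readmission window labels
#'
#' Derives the seven binary readmission labels of each stay from its single
#' readmission gap: windows 24 h, 48 h, 72 h, 24-72 h, 7 days and 30 days
#' label 1 iff `gap <= window` (24-72 h iff `24 < gap <= 72`), and
#' bounce-back labels a return to the ICU before hospital discharge. No
#' readmission means all labels 0.
#'
#' @param stays the cohort `stays` table.
#' @return `data.table` with stay_id and one 0/1 column per window.
#' @export
readmission_labels <- function(stays) {
  s <- data.table::as.data.table(stays)
  gap <- s$readmission_time - s$icu_discharge_time
  if (any(!is.na(gap) & gap <= 0))
    stop_input("readmission before ICU discharge")
  has <- !is.na(gap)
  lab <- function(cut) as.integer(has & gap <= cut)
  data.table::data.table(
    stay_id = s$stay_id,
    w24h = lab(24), w48h = lab(48), w72h = lab(72),
    w24_72h = as.integer(has & gap > 24 & gap <= 72),
    w7d = lab(168), w30d = lab(720),
    bounce_back = as.integer(has &
      s$readmission_time < s$hospital_discharge_time))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d stays x %d features (%s urine group)\n",
              length(x$stay_ids), length(x$feature_names),
              if (length(x$urine_group)) "with" else "without"))
  invisible(x)
}
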