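# Cohort exclusions, eGFR, the 83-feature matrix, normalization and
# readmission window labels.

test_that("MDRD-4 eGFR matches hand evaluation", {
  expect_equal(egfr(1.0, 40, "M", "White"), 175 * 40^(-0.203),
               tolerance = 1e-12)
  expect_equal(round(egfr(1.0, 40, "M", "White"), 1), 82.8)
  # doubling creatinine multiplies by 2^-1.154
  expect_equal(egfr(2.0, 40, "M", "White") / egfr(1.0, 40, "M", "White"),
               2^(-1.154), tolerance = 1e-12)
  expect_equal(egfr(1.0, 40, "F", "White"),
               egfr(1.0, 40, "M", "White") * 0.742)
  expect_equal(egfr(1.0, 40, "M", "Black"),
               egfr(1.0, 40, "M", "White") * 1.212)
  expect_error(egfr(0, 40, "M", "White"), "> 0")
})

make_toy_cohort <- function() {
  mk_obs <- function(sid, times, values, channel = "creatinine") {
    data.frame(stay_id = sid, time_h = times, channel = channel,
               value = values, units = "mg/dL")
  }
  clean <- function(sid) mk_obs(sid, c(2, 30, 60), c(1.0, 1.05, 1.0))
  obs <- rbind(
    clean(1), clean(2),
    clean(3),                                     # will be under-age
    clean(4),                                     # will carry CKD
    mk_obs(5, c(1, 6, 20), c(1.0, 2.4, 2.3)))    # stage 2 onset at 6 h
  patients <- data.frame(
    patient_id = 1:5, ethnicity = "White",
    age_years = c(40, 55, 16, 60, 45), sex = "M", weight_kg = 80,
    ckd = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    chf = FALSE, hypertension = FALSE, diabetes = FALSE, copd = FALSE,
    afib = FALSE, cad = FALSE, stroke = FALSE, liver_disease = FALSE,
    cancer = FALSE, obesity = FALSE)
  stays <- data.frame(
    stay_id = 1:5, patient_id = 1:5, icu_admit_time = 0,
    icu_discharge_time = 200, hospital_discharge_time = 300,
    emr_epoch = "pre", readmission_time = NA_real_)
  list(patients = patients, stays = stays, observations = obs,
       truth = data.frame(stay_id = 1:5, true_aki_stage = 0,
                          true_readmission_gap_h = NA_real_))
}

test_that("cohort exclusions remove each ineligible stay with its reason", {
  co <- make_toy_cohort()
  ex <- extract_cohort(co)
  expect_setequal(ex$stay_ids, c(1, 2))
  expect_equal(ex$exclusions$reason[ex$exclusions$stay_id == 3],
               "age_under_18")
  expect_equal(ex$exclusions$reason[ex$exclusions$stay_id == 4],
               "chronic_kidney_disease")
  expect_equal(ex$exclusions$reason[ex$exclusions$stay_id == 5],
               "admission_aki")
})

test_that("a stay without first-day creatinine is dropped, not fatal", {
  co <- make_toy_cohort()
  co$observations <- rbind(
    co$observations,
    data.frame(stay_id = 6, time_h = c(30, 50), channel = "creatinine",
               value = c(1, 1.1), units = "mg/dL"))
  co$patients <- rbind(co$patients, transform(co$patients[1, ],
                                              patient_id = 6))
  co$stays <- rbind(co$stays, transform(co$stays[1, ], stay_id = 6,
                                        patient_id = 6))
  ex <- extract_cohort(co)
  expect_equal(ex$exclusions$reason[ex$exclusions$stay_id == 6],
               "missing_baseline")
  expect_setequal(ex$stay_ids, c(1, 2))
})

test_that("empty input yields empty output without error", {
  co <- make_toy_cohort()
  co$stays <- co$stays[0, ]; co$patients <- co$patients[0, ]
  co$observations <- co$observations[0, ]; co$truth <- co$truth[0, ]
  ex <- extract_cohort(co)
  expect_length(ex$stay_ids, 0)
  expect_equal(nrow(ex$exclusions), 0)
})

test_that("feature layout is fixed at 83 names with the urine group", {
  nm <- feature_names_aki(TRUE)
  expect_length(nm, 83)
  expect_length(feature_names_aki(FALSE), 80)
  expect_identical(setdiff(nm, feature_names_aki(FALSE)),
                   urine_feature_group())
  expect_identical(nm, feature_names_aki(TRUE))  # stable across calls
})

test_that("summaries, the urine toggle and imputation behave as specified", {
  co <- make_toy_cohort()
  co$observations <- rbind(
    co$observations,
    data.frame(stay_id = 1, time_h = 1:10, channel = "heart_rate",
               value = 80, units = "bpm"),
    data.frame(stay_id = 1, time_h = 1:10, channel = "urine_output",
               value = 70, units = "mL/h"),
    data.frame(stay_id = 2, time_h = c(3, 9), channel = "hemoglobin",
               value = c(10.0, 10.4), units = "g/dL"))
  fm <- build_features(co, include_urine = TRUE, stay_ids = c(1, 2))
  i1 <- which(fm$stay_ids == 1)
  expect_equal(unname(fm$values[i1, c("heart_rate_mean", "heart_rate_min",
                                      "heart_rate_max", "heart_rate_last")]),
               rep(80, 4))
  expect_equal(unname(fm$values[i1, "urine_mean_rate"]), 70 / 80)
  # toggling urine off removes exactly the urine columns
  fm0 <- build_features(co, include_urine = FALSE, stay_ids = c(1, 2))
  expect_identical(fm0$feature_names, setdiff(fm$feature_names,
                                              urine_feature_group()))
  expect_equal(fm0$values, fm$values[, fm0$feature_names])
  # stay 1 has no hemoglobin: imputed by the training median (10.2)
  expect_true(is.na(fm$values[i1, "hemoglobin_mean"]))
  nf <- normalize_features(fm, c(TRUE, TRUE))
  expect_equal(unname(nf$normalization$median["hemoglobin_mean"]), 10.2)
  expect_false(anyNA(nf$normalized))
  # raw summaries are independent of the train flagging
  nf2 <- normalize_features(fm, c(FALSE, TRUE))
  expect_identical(fm$values, nf2$values)
})

test_that("unknown channels are ignored with a warning", {
  co <- make_toy_cohort()
  co$observations <- rbind(
    co$observations,
    data.frame(stay_id = 1, time_h = 1, channel = "lactate", value = 2,
               units = "mmol/L"))
  expect_warning(build_features(co, stay_ids = c(1, 2)), "lactate")
})

test_that("readmission windows derive from the gap with nesting", {
  stays <- data.frame(
    stay_id = 1:3, patient_id = 1:3, icu_admit_time = 0,
    icu_discharge_time = 100, hospital_discharge_time = 150,
    emr_epoch = "pre",
    readmission_time = c(130, NA, 120))  # gaps 30 h, none, 20 h
  rl <- readmission_labels(stays)
  expect_equal(unlist(rl[1, -1]),
               c(w24h = 0L, w48h = 1L, w72h = 1L, w24_72h = 1L, w7d = 1L,
                 w30d = 1L, bounce_back = 1L))
  expect_equal(sum(unlist(rl[2, -1])), 0)
  expect_equal(unlist(rl[3, -1]),
               c(w24h = 1L, w48h = 1L, w72h = 1L, w24_72h = 0L, w7d = 1L,
                 w30d = 1L, bounce_back = 1L))
  stays$readmission_time[2] <- 90  # before ICU discharge
  expect_error(readmission_labels(stays), "before ICU discharge")
})
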