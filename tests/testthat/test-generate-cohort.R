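# Synthetic cohort generator: determinism, relational invariants, the
# ground-truth risk model, and stage-to-trajectory construction.

test_that("configuration validation catches bad inputs", {
  expect_error(cohort_config(0), "positive integer")
  expect_error(cohort_config(10, stage_mix = c(`0` = 0.5, `1` = 0.5,
                                               `2` = 0.2, `3` = -0.2)),
               "non-negative")
  expect_error(cohort_config(10, epoch_mix = c(pre = 0.6, post = 0.6,
                                               crossover = 0.1)), "sum to 1")
  expect_error(cohort_config(10, noise_sd = 0), "noise_sd")
  expect_error(cohort_config(10, obs_cadence = c(creatinine = 12, urine = 3,
                                                 vitals = 1, labs = 24)),
               "urine cadence")
  expect_silent(cohort_config(10, aki_prevalence_preset = "hospital_wide"))
})

test_that("identical configuration yields byte-identical cohorts", {
  c1 <- generate_cohort(cohort_config(100, seed = 7))
  c2 <- generate_cohort(cohort_config(100, seed = 7))
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$stays, c2$stays)
  expect_identical(c1$observations, c2$observations)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(cohort_config(100, seed = 8))
  expect_false(identical(c1$truth, c3$truth))
})

test_that("generated tables satisfy the relational invariants", {
  co <- test_cohort(400, 42)
  expect_true(all(co$observations$stay_id %in% co$stays$stay_id))
  expect_true(all(co$truth$stay_id %in% co$stays$stay_id))
  expect_true(all(co$stays$patient_id %in% co$patients$patient_id))
  expect_true(all(co$stays$icu_admit_time < co$stays$icu_discharge_time))
  rt <- co$stays$readmission_time
  expect_true(all(is.na(rt) | rt > co$stays$icu_discharge_time))
  expect_true(all(co$patients$age_years >= 18))
  # fixed units per channel
  u <- unique(co$observations[, c("channel", "units")])
  expect_equal(nrow(u), length(unique(u$channel)))
  expect_equal(u$units[u$channel == "creatinine"], "mg/dL")
  expect_equal(u$units[u$channel == "urine_output"], "mL/h")
  # times strictly increasing within stay x channel
  bad <- co$observations[, .(ok = !is.unsorted(time_h, strictly = TRUE)),
                         by = .(stay_id, channel)]
  expect_true(all(bad$ok))
})

test_that("urine_available = FALSE drops the urine channel only", {
  co <- generate_cohort(cohort_config(60, seed = 5, urine_available = FALSE))
  expect_false("urine_output" %in% co$observations$channel)
  expect_true("creatinine" %in% co$observations$channel)
})

test_that("tiny cohorts warn about empty strata instead of failing", {
  w <- capture_warnings(co <- generate_cohort(cohort_config(3, seed = 1)))
  expect_true(any(grepl("empty stratum", w)))
  expect_equal(nrow(co$stays), 3)
})

test_that("latent risk follows the documented logistic form", {
  cfg0 <- cohort_config(10, drift_magnitude = 0, subgroup_effect = 0)
  x <- c(0.5, -1, 0.3, 2, -0.4)
  # null shift: identical risk across epochs and groups
  expect_equal(latent_risk(x, "pre", "White", cfg0),
               latent_risk(x, "post", "White", cfg0))
  expect_equal(latent_risk(x, "pre", "White", cfg0),
               latent_risk(x, "pre", "Black", cfg0))
  # logistic(0) at the origin
  expect_equal(latent_risk(rep(0, 5), "pre", "White", cfg0), 0.5)
  # hand evaluation of the formula for delta = 1 with gamma.x > 0
  cfg1 <- cohort_config(10, drift_magnitude = 1, subgroup_effect = 0)
  co <- icushift:::risk_coefficients()
  xt <- icushift:::expand_basis(x)
  expect_equal(latent_risk(x, "post", "White", cfg1),
               plogis(drop(xt %*% co$beta) + drop(xt %*% co$gamma)))
  if (drop(xt %*% co$gamma) > 0)
    expect_gt(latent_risk(x, "post", "White", cfg1),
              latent_risk(x, "pre", "White", cfg1))
  expect_error(latent_risk(c(1, NA, 0, 0, 0), "pre", "White", cfg0),
               "finite")
})

test_that("increasing drift cannot shrink the pre-post risk divergence", {
  set.seed(31)
  grid <- matrix(rnorm(200 * 5), 200, 5)
  div <- sapply(c(0, 0.5, 1, 1.5), function(d) {
    cfg <- cohort_config(10, drift_magnitude = d, subgroup_effect = 0)
    mean(abs(latent_risk(grid, "post", "White", cfg) -
               latent_risk(grid, "pre", "White", cfg)))
  })
  expect_true(all(diff(div) >= 0))
})

test_that("trajectories realize the intended stage with safe margins", {
  # stage 0: flat creatinine, urine never below 0.5 mL/kg/h
  tr <- trajectory_from_stage(0, 70, TRUE, seed = 3)
  cr <- tr[channel == "creatinine"]
  expect_lt(max(cr$value) / min(cr$value), 1.5)
  ur <- tr[channel == "urine_output"]
  expect_true(all(ur$value / 70 >= 0.5))
  expect_equal(kdigo_stage(tr, 70)$stage, 0L)
  # stage 3 without urine: creatinine alone must reach >= 3x baseline
  tr <- trajectory_from_stage(3, 70, FALSE, seed = 3)
  cr <- tr[channel == "creatinine"]
  bl <- baseline_creatinine(cr$time_h, cr$value)
  expect_gte(max(cr$value[cr$time_h <= 168]) / bl, 3)
  expect_equal(kdigo_stage(tr, 70)$stage, 3L)
  # nuisance channels present
  expect_true(all(c("heart_rate", "sbp", "resp_rate", "bun", "hemoglobin",
                    "wbc") %in% tr$channel))
})

test_that("labeler recovers the intended stage across stages and seeds", {
  for (seed in 1:25) {
    stage <- seed %% 4
    w <- 55 + 7 * (seed %% 8)
    tr <- trajectory_from_stage(stage, w, urine_available = seed %% 2 == 0,
                                seed = seed)
    expect_equal(kdigo_stage(tr, w)$stage, stage,
                 info = sprintf("stage %d seed %d", stage, seed))
  }
})
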