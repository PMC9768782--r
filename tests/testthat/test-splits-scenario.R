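# Split builders, the scenario engine's bookkeeping, learning curves,
# crossover fractions and the confounding cross-tabulation.

test_that("baseline split is stratified 80/20 and seed-deterministic", {
  ids <- 1:100
  y <- rep(c(1, 0), c(30, 70))
  sp <- split_baseline(ids, y, seed = 4)
  expect_equal(sum(sp$role == "train"), 80)
  expect_equal(sum(sp$role == "test"), 20)
  prev_tr <- mean(y[sp$stay_id[sp$role == "train"]])
  prev_te <- mean(y[sp$stay_id[sp$role == "test"]])
  expect_lte(abs(prev_tr - 0.3) * 80, 1)   # within one stay of 30%
  expect_lte(abs(prev_te - 0.3) * 20, 1)
  expect_identical(sp, split_baseline(ids, y, seed = 4))
  expect_false(identical(sp, split_baseline(ids, y, seed = 5)))
  expect_error(split_baseline(1:3, c(0, 1, 0), 1), "fewer than 5")
})

test_that("drift split partitions by epoch and excludes cross-over stays", {
  stays <- data.frame(stay_id = 1:10,
                      emr_epoch = c(rep("pre", 5), rep("post", 4),
                                    "crossover"))
  sp <- split_drift(stays)
  expect_equal(sum(sp$role == "train"), 5)
  expect_equal(sum(sp$role == "test"), 4)
  expect_equal(sp$role[10], "excluded")
  expect_equal(sp$note[10], "crossover")
  stays$emr_epoch <- "pre"
  expect_error(split_drift(stays), "infeasible")
})

test_that("population split trains on one group and tests on another", {
  co <- list(
    patients = data.frame(patient_id = 1:10,
                          ethnicity = rep(c("White", "Black", "Other"),
                                          c(6, 3, 1))),
    stays = data.frame(stay_id = 1:10, patient_id = 1:10))
  sp <- split_population(co, "White", "Black")
  expect_equal(sum(sp$role == "train"), 6)
  expect_equal(sum(sp$role == "test"), 3)
  expect_equal(sum(sp$role == "excluded"), 1)
  expect_error(split_population(co, "White", "White"), "degenerate")
  expect_error(split_population(co, "White", "Latinx"), "infeasible")
})

test_that("crossover fraction is the first grid point reaching the reference", {
  curve <- data.frame(fraction = c(0.1, 0.2, 0.3),
                      mean_auroc = c(0.70, 0.74, 0.76))
  expect_equal(crossover_fraction(curve, 0.75), 0.3)
  expect_equal(crossover_fraction(curve, 0.60), 0.1)
  expect_true(is.na(crossover_fraction(curve, 0.80)))
})

test_that("confounding percentages match hand tabulation", {
  co <- list(
    patients = data.frame(patient_id = 1:10,
                          ethnicity = rep("White", 10)),
    stays = data.frame(stay_id = 1:10, patient_id = 1:10,
                       emr_epoch = "pre"))
  a <- rep(c("x", "y"), c(6, 4))
  b <- c(rep("p", 4), rep("q", 2), rep("p", 2), rep("q", 2))
  ct <- confounding_table(co, a, b)
  expect_equal(ct[[2]][ct$partition == "x"], 100 * 4 / 6, tolerance = 1e-9)
  expect_equal(ct[[3]][ct$partition == "x"], 100 * 2 / 6, tolerance = 1e-9)
  expect_equal(ct[[2]][ct$partition == "y"], 50)
  expect_equal(ct[[2]][ct$partition == "whole"], 60)
  # a partition against itself is diagonal
  ct2 <- confounding_table(co, a, a)
  expect_equal(ct2$x[ct2$partition == "x"], 100)
  expect_equal(ct2$y[ct2$partition == "x"], 0)
  # omitted B levels absorb the remainder (listed cells sum below 100)
  ct3 <- confounding_table(co, a, b, b_levels = "p")
  expect_lt(ct3$p[ct3$partition == "whole"], 100)
})

test_that("independent generator partitions cross-tabulate near-uniformly", {
  co <- test_cohort(4000, 42)
  ct <- confounding_table(co, "ethnicity_binary", "drift",
                          b_levels = c("pre", "post"))
  whole_pre <- ct$pre[ct$partition == "whole"]
  expect_true(all(abs(ct$pre - whole_pre) <= 3))
  # crossover absorbs the remainder
  expect_lt(ct$pre[1] + ct$post[1], 100)
})

test_that("scenario bookkeeping records sizes and seeds per row", {
  co <- test_cohort(500, 42, delta = 0, eta = 0)
  ex <- extract_cohort(co)
  r <- run_scenario(scenario_spec("scarcity", seeds = 1:2,
                                  fractions = c(0.3, 0.6)),
                    co, model_spec(hidden = c(8), max_epochs = 15),
                    extraction = ex)
  expect_equal(nrow(r), 4)
  expect_equal(r$n_train + r$n_test, rep(length(ex$stay_ids), 4))
  expect_true(all(diff(r[r$seed == 1]$n_train) > 0))
  lc <- learning_curve(r)
  expect_equal(lc$fraction, c(0.3, 0.6))
  expect_true(all(lc$sd_auroc >= 0))
})

test_that("the nonlinear planted risk rewards model capacity", {
  # the generator's interaction terms give the MLP an edge a linear
  # scorer cannot match
  co <- test_cohort(4000, 4242, delta = 0, eta = 0)
  ex <- extract_cohort(co)
  ids <- ex$stay_ids
  y <- as.integer(ex$labels$stage[match(ids, ex$labels$stay_id)] >= 1)
  fm <- build_features(co, stay_ids = ids)
  diffs <- sapply(1:3, function(seed) {
    sp <- split_baseline(ids, y, seed)
    trm <- ids %in% sp$stay_id[sp$role == "train"]; tem <- !trm
    nf <- normalize_features(fm, trm)
    mlp <- train(nf$normalized[trm, ], y[trm], model_spec(seed = seed))
    lin <- train(nf$normalized[trm, ], y[trm],
                 model_spec(hidden = integer(0), seed = seed))
    auroc(predict_proba(mlp, nf$normalized[tem, ]), y[tem])$value -
      auroc(predict_proba(lin, nf$normalized[tem, ]), y[tem])$value
  })
  expect_gt(mean(diffs), 0)
})

test_that("the fraction grid is validated", {
  expect_error(scenario_spec("scarcity", fractions = c(0, 0.5)),
               "fractions")
  expect_error(scenario_spec("scarcity", fractions = c(0.5, 0.3)),
               "strictly increasing")
  expect_error(scenario_spec("baseline", seeds = integer(0)), "seeds")
})
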