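# MLP training, prediction contracts, hyperparameter search and the
# layer-freezing transfer procedure.

toy_xy <- function(n = 400, seed = 1, kind = c("separable", "noise",
                                               "xor")) {
  kind <- match.arg(kind)
  set.seed(seed)
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- switch(kind,
              separable = as.integer(X[, 1] + X[, 2] > 0),
              noise = sample(0:1, n, replace = TRUE),
              xor = as.integer(X[, 1] * X[, 2] > 0))
  list(X = X, y = y)
}

test_that("a separable toy task is fit to near-perfect training AUROC", {
  d <- toy_xy(400, 1, "separable")
  m <- train(d$X, d$y, model_spec(hidden = c(8, 8), seed = 2,
                                  val_fraction = 0))
  p <- predict_proba(m, d$X)
  expect_gte(auroc(p, d$y)$value, 0.99)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("label-independent features give chance-level held-out AUROC", {
  d <- toy_xy(3000, 3, "noise")
  tr <- 1:1500; te <- 1501:3000
  m <- train(d$X[tr, ], d$y[tr], model_spec(hidden = c(8), seed = 4))
  a <- auroc(predict_proba(m, d$X[te, ]), d$y[te])$value
  expect_gte(a, 0.45); expect_lte(a, 0.55)
})

test_that("training is deterministic for a fixed (data, spec, seed)", {
  d <- toy_xy(300, 5, "separable")
  m1 <- train(d$X, d$y, model_spec(hidden = c(6, 4), seed = 7))
  m2 <- train(d$X, d$y, model_spec(hidden = c(6, 4), seed = 7))
  expect_identical(m1$par, m2$par)
  m3 <- train(d$X, d$y, model_spec(hidden = c(6, 4), seed = 8))
  expect_false(identical(m1$par, m3$par))
})

test_that("prediction refuses mismatched or reordered columns", {
  d <- toy_xy(200, 6, "separable")
  m <- train(d$X, d$y, model_spec(hidden = c(4), seed = 1))
  expect_error(predict_proba(m, d$X[, c("f2", "f1")]), "do not match")
  X2 <- d$X; colnames(X2) <- c("f1", "other")
  expect_error(predict_proba(m, X2), "do not match")
  expect_silent(predict_proba(m, d$X[7, , drop = FALSE]))
})

test_that("single-class training labels are a degenerate-task error", {
  d <- toy_xy(100, 2, "separable")
  expect_error(train(d$X, rep(1, 100), model_spec(seed = 1)),
               "single class")
})

test_that("class probabilities sum to one in the multiclass mode", {
  set.seed(9)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- pmin(3, pmax(0, round(X[, 1] + rnorm(200, 0, 0.5) + 1.5)))
  m <- train(X, y, model_spec(hidden = c(8), task = "aki_stage", seed = 1))
  P <- predict_proba(m, X)
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-6)
  expect_true(all(P >= 0 & P <= 1))
})

test_that("grid search returns the spec with the best cross-validated AUROC", {
  d <- toy_xy(600, 11, "xor")
  grid <- list(model_spec(hidden = integer(0), seed = 1),
               model_spec(hidden = c(16, 8, 4, 4), seed = 1,
                          max_epochs = 80))
  hs <- hyperparameter_search(d$X, d$y, grid, k_folds = 3, seed = 5)
  # a linear scorer cannot solve XOR; the deeper net must win
  expect_identical(hs$best_spec$hidden, grid[[2]]$hidden)
  expect_gt(hs$cv_table$mean_auroc[2], hs$cv_table$mean_auroc[1] + 0.2)
  # singleton grid returns its only member
  hs1 <- hyperparameter_search(d$X, d$y, grid[1], k_folds = 2, seed = 5)
  expect_identical(hs1$best_spec, grid[[1]])
  # fold assignment reproducible per seed
  hs2 <- hyperparameter_search(d$X, d$y, grid[1], k_folds = 2, seed = 5)
  expect_identical(hs1$folds, hs2$folds)
  expect_error(hyperparameter_search(d$X, d$y, list(), 3, 1), "non-empty")
})

test_that("transfer widening is exact: zero epochs reproduce the old model", {
  d <- toy_xy(400, 13, "separable")
  m <- train(d$X, d$y, model_spec(hidden = c(8, 6, 4), seed = 3))
  Xw <- cbind(d$X, extra = rnorm(400))
  tsp <- transfer_spec(default_frozen_layers(3), "extra",
                       fine_tune_epochs = 0)
  tm <- transfer_train(m, Xw, d$y, tsp)
  expect_equal(predict_proba(tm, Xw), predict_proba(m, d$X),
               tolerance = 1e-12)
})

test_that("frozen layers are bitwise invariant under fine-tuning", {
  d <- toy_xy(400, 14, "separable")
  m <- train(d$X, d$y, model_spec(hidden = c(8, 6, 4), seed = 3))
  Xw <- cbind(d$X, extra = as.numeric(d$y) + rnorm(400, 0, 0.3))
  tsp <- transfer_spec(2L, "extra", fine_tune_epochs = 10)
  tm <- transfer_train(m, Xw, d$y, tsp)
  expect_identical(tm$par$W[[2]], m$par$W[[2]])
  expect_identical(tm$par$b[[2]], m$par$b[[2]])
  expect_false(identical(tm$par$W[[3]], m$par$W[[3]]))
  expect_false(identical(tm$par$W[[1]][1:2, ], m$par$W[[1]]))
  # overlap between old and new feature names is rejected
  expect_error(transfer_train(m, Xw, d$y, transfer_spec(2L, "f1")),
               "overlap")
  # frozen set must be a strict subset of the hidden layers
  expect_error(transfer_train(m, Xw, d$y,
                              transfer_spec(1:3, "extra")), "strict subset")
})

test_that("default frozen set keeps the input and output layers adaptive", {
  expect_identical(default_frozen_layers(3), 2L)
  expect_identical(default_frozen_layers(5), 2:4)
  expect_error(default_frozen_layers(1), "depth >= 2")
})

test_that("the deep tapering preset has 15 hidden layers", {
  sp <- aki_deep_spec(seed = 2)
  expect_length(sp$hidden, 15)
  expect_true(all(diff(sp$hidden) <= 0))
})
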