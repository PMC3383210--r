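table2_metrics <- function() {
  act <- load_activity_table("table1")
  op <- load_observed_predicted("table2")
  train_mean <- mean(act$pic50[!act$id %in% op$id])
  external_metrics(op$observed, op$predicted, train_mean)
}

test_that("external validation reproduces the printed test-set statistics", {
  ext <- table2_metrics()
  expect_equal(ext$r2pred, 0.641, tolerance = 2e-3 / 0.641)
  expect_equal(ext$sep, 0.325, tolerance = 2e-3 / 0.325)
  expect_equal(ext$k, 1.017, tolerance = 2e-3)
  expect_equal(ext$kprime, 0.981, tolerance = 2e-3)
  expect_equal(ext$abs_diff, 0.004, tolerance = 2e-3 / 0.004)
  expect_true(ext$pass_r2pred && ext$pass_k && ext$pass_kprime && ext$pass_diff)
})

test_that("external metrics behave at the exact-prediction and mean-prediction limits", {
  obs <- c(6.2, 6.9, 7.4, 8.1)
  perfect <- external_metrics(obs, obs, y_train_mean = 7)
  expect_equal(perfect$r2pred, 1)
  expect_equal(perfect$sep, 0)
  expect_equal(perfect$k, 1)
  expect_equal(perfect$kprime, 1)
  expect_equal(perfect$abs_diff, 0)

  ## predicting the training mean everywhere gives R2pred = 0
  mean_pred <- external_metrics(obs, rep(7, 4) + c(1e-9, -1e-9, 1e-9, -1e-9),
                                y_train_mean = 7)
  expect_equal(mean_pred$r2pred, 0, tolerance = 1e-6)
})

test_that("slope metrics obey their exchange and scaling laws", {
  set.seed(19)
  obs <- runif(8, 6, 8); pred <- obs + rnorm(8, 0, 0.3)
  a <- external_metrics(obs, pred, mean(obs))
  b <- external_metrics(pred, obs, mean(pred))
  expect_equal(a$k, b$kprime, tolerance = 1e-12)
  expect_equal(a$kprime, b$k, tolerance = 1e-12)
  expect_equal(a$sep^2 * a$n, a$press_test, tolerance = 1e-12)
  for (c0 in c(0.5, 2)) {
    sc <- external_metrics(obs, pred * c0, mean(obs))
    expect_equal(sc$k * c0, a$k, tolerance = 1e-12)
  }
  expect_error(external_metrics(obs, rep(0, 8), mean(obs)), "pred")
  expect_error(external_metrics(obs, pred, y_train_mean = NA), "degenerate|missing")
})

test_that("fixed-list split reproduces the study's training/test sizes", {
  act <- load_activity_table("table1")
  sp <- fixed_split(act$id, c("A0", "B5", "C2", "C4", "C9"))
  expect_length(sp$train_ids, 26)
  expect_length(sp$test_ids, 5)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), act$id)
  expect_error(fixed_split(act$id, character(0)), "non-empty")
  expect_error(fixed_split(act$id, "ZZ"), "unknown")
})

test_that("HCA split is representative: strata covered, extremes kept for training", {
  ## two well-separated blobs: one test compound from each
  set.seed(4)
  X <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
             matrix(rnorm(20, 8, 0.3), 10, 2))
  y <- c(rnorm(10, 6.5, 0.2), rnorm(10, 7.5, 0.2))
  rownames(X) <- paste0("S", 1:20)
  sp <- hca_split(X, y, n_test = 2, seed = 3)
  blob <- rep(1:2, each = 10)
  expect_setequal(blob[match(sp$test_ids, rownames(X))], 1:2)
  ## activity extremes never leave the training set
  extremes <- rownames(X)[c(which.min(y), which.max(y))]
  expect_true(all(extremes %in% sp$train_ids))
  expect_setequal(c(sp$train_ids, sp$test_ids), rownames(X))
  expect_error(hca_split(X, y, n_test = 0), "n_test")
  ## deterministic under a fixed seed
  expect_identical(sp$test_ids, hca_split(X, y, n_test = 2, seed = 3)$test_ids)
})
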