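test_that("activity sums of squares reproduce the printed values", {
  act <- load_activity_table("table1")
  expect_equal(ssy(act$pic50), 9.491, tolerance = 2e-3)
  test_ids <- load_observed_predicted("table2")$id
  expect_equal(ssy(act$pic50[!act$id %in% test_ids]), 8.026, tolerance = 2e-3)
  expect_equal(ssy(rep(4.2, 10)), 0)
  expect_error(ssy(1), "two values")
})

test_that("calibration statistics satisfy their algebraic identities", {
  pr <- random_problem(n = 31, m = 5, seed = 2)
  fit <- fit_pls(pr$X, pr$y, 3)
  fs <- fit_statistics(pr$y, fitted(fit), p = 3)
  expect_equal(fs$r2, 1 - fs$rss / fs$ssy, tolerance = 1e-10)
  expect_equal(fs$sec, sqrt(fs$rss / (fs$n - fs$p - 1)), tolerance = 1e-12)
  expect_equal(fs$f_value, (fs$r2 / fs$p) / ((1 - fs$r2) / (fs$n - fs$p - 1)),
               tolerance = 1e-12)
  ## exact fit: unbounded F is flagged, not fabricated
  ex <- fit_statistics(pr$y, pr$y, p = 3)
  expect_true(ex$overflow)
  expect_equal(ex$r2, 1)
  expect_equal(ex$sec, 0)
  expect_error(fit_statistics(pr$y[1:4], pr$y[1:4], p = 3), "n > p")
})

test_that("the F critical value at the study design matches the printed one", {
  fs <- fit_statistics(rnorm(31), rnorm(31), p = 3, alpha = 0.05)
  expect_equal(fs$f_crit, 2.960, tolerance = 1e-3)
})

test_that("printed statistic blocks are internally consistent", {
  for (block in c("eq1_stats", "eq2_stats")) {
    cons <- stats_block_consistency(block)
    tol <- c(sec = 1e-3, f_value = 0.1, f_crit = 1e-3, q2_loo = 1e-3,
             sev = 1e-3)
    for (i in seq_len(nrow(cons)))
      expect_equal(cons$derived[i], cons$printed[i],
                   tolerance = tol[[cons$statistic[i]]] / max(abs(cons$printed[i]), 1),
                   label = paste(block, cons$statistic[i]))
  }
})

test_that("streamlined LOO equals the brute-force refit loop", {
  pr <- random_problem(n = 15, m = 5, seed = 17)
  cv <- loo_cv(pr$X, pr$y, ncomp = 3)
  expect_equal(cv$predictions, loo_brute(pr$X, pr$y, 3), tolerance = 1e-10)
  expect_equal(cv$press, sum((pr$y - cv$predictions)^2), tolerance = 1e-10)
  expect_equal(cv$q2, 1 - cv$press / ssy(pr$y), tolerance = 1e-12)
  expect_equal(cv$sev, sqrt(cv$press / 15), tolerance = 1e-12)
})

test_that("LOO predicts noiseless linear activities perfectly", {
  pr <- random_problem(n = 16, m = 4, seed = 23, noise = 0)
  cv <- loo_cv(pr$X, pr$y, ncomp = 4)
  expect_gt(cv$q2, 1 - 1e-6)
  expect_lte(cv$q2, 1)
})

test_that("leave-N-out with N = 1 is exactly leave-one-out", {
  pr <- random_problem(n = 14, m = 4, seed = 29)
  loo <- loo_cv(pr$X, pr$y, 2)
  lno <- lno_cv(pr$X, pr$y, 2, n_max = 1, replicates = 3, seed = 77)
  expect_equal(lno$trials$q2, rep(loo$q2, 3), tolerance = 1e-12)
})

test_that("leave-N-out is stable on planted-signal data and collapses on scrambled y", {
  d <- synth_paperlike(101)
  xsel <- d$X[, d$truth$descriptor]
  loo <- loo_cv(xsel, d$y, 3)
  lno <- lno_cv(xsel, d$y, 3, n_max = 7, replicates = 6, seed = 101)
  expect_true(all(abs(lno$summary$mean_q2 - loo$q2) <= 0.1))
  expect_true(all(lno$summary$sd_q2 <= 0.1))
  expect_equal(nrow(lno$trials), 42)

  yperm <- with_seed_perm(d$y, 999)
  lno0 <- lno_cv(xsel, yperm, 3, n_max = 3, replicates = 3, seed = 5)
  expect_lt(mean(lno0$trials$q2), 0)
})

test_that("y-randomization separates real models from chance correlation", {
  d <- synth_paperlike(202)
  xsel <- d$X[, d$truth$descriptor]
  yr <- y_randomization(xsel, d$y, 3, n_scrambles = 10, seed = 202)
  expect_lt(yr$intercept_r2, 0.3)
  expect_lt(yr$intercept_q2, 0.05)
  expect_true(yr$pass_r2 && yr$pass_q2)
  expect_true(all(yr$scrambles$abs_r >= 0 & yr$scrambles$abs_r <= 1))
  ## intercepts recomputable from the recorded points plus the anchor
  pts_x <- c(yr$scrambles$abs_r, 1)
  int <- unname(coef(lm(c(yr$scrambles$r2, yr$original_r2) ~ pts_x))[1])
  expect_equal(yr$intercept_r2, int, tolerance = 1e-12)
  ## determinism
  yr2 <- y_randomization(xsel, d$y, 3, n_scrambles = 10, seed = 202)
  expect_equal(yr$scrambles, yr2$scrambles)
  expect_error(y_randomization(xsel, d$y, 3, n_scrambles = 1), "2 scrambles")
})
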