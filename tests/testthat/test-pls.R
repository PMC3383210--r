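test_that("PLS1 with a single descriptor reproduces the least-squares line", {
  set.seed(3)
  x <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "x"))
  y <- 2 + 0.7 * x[, 1] + rnorm(25, 0, 0.3)
  fit <- fit_pls(x, y, ncomp = 1)
  ls <- lm(y ~ x[, 1])
  expect_equal(unname(fit$fitted.values), unname(fitted(ls)), tolerance = 1e-8)
  expect_equal(unname(coef(fit)), unname(coef(ls)), tolerance = 1e-8)
})

test_that("full-component PLS equals ordinary least squares", {
  for (seed in 1:3) {
    pr <- random_problem(n = 20, m = 6, seed = seed)
    fit <- fit_pls(pr$X, pr$y, ncomp = 6)
    expect_equal(fit$fitted.values, ols_fitted(pr$X, pr$y), tolerance = 1e-6)
  }
})

test_that("scores are orthogonal and the latent decomposition matches the coefficients", {
  pr <- random_problem(n = 24, m = 8, seed = 5)
  fit <- fit_pls(pr$X, pr$y, ncomp = 4)
  G <- crossprod(fit$scores)
  offdiag <- abs(G - diag(diag(G)))
  expect_true(all(offdiag <= 1e-8 * sqrt(outer(diag(G), diag(G)))))
  ## score-space prediction route equals the coefficient route
  expect_equal(opsqsar:::predict_via_scores(fit, pr$X),
               predict(fit, pr$X), tolerance = 1e-9)
})

test_that("prediction behaves at the centre and recovers noiseless signals", {
  pr <- random_problem(n = 20, m = 5, seed = 9, noise = 0)
  fit <- fit_pls(pr$X, pr$y, ncomp = 5)
  expect_equal(unname(predict(fit, matrix(colMeans(pr$X), 1))),
               mean(pr$y), tolerance = 1e-8)
  expect_equal(unname(predict(fit, pr$X)), pr$y, tolerance = 1e-6)
  ## self-consistency: R2 of training predictions equals the fit statistic
  fs <- fit_statistics(pr$y, fitted(fit), p = fit$ncomp)
  expect_equal(fs$r2, 1, tolerance = 1e-8)
})

test_that("training R2 is non-decreasing in the number of latent variables", {
  pr <- random_problem(n = 25, m = 7, seed = 13)
  r2 <- vapply(1:6, function(a) {
    f <- fit_pls(pr$X, pr$y, a)
    fit_statistics(pr$y, fitted(f), a)$r2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("NIPALS agrees with the independent Krylov-space PLS1 oracle", {
  for (seed in 1:4) {
    pr <- random_problem(n = 20, m = 8, seed = 100 + seed)
    for (a in c(1, 3, 5)) {
      fit <- fit_pls(pr$X, pr$y, ncomp = a)
      kry <- pls1_krylov(pr$X, pr$y, ncomp = a)
      expect_equal(fit$fitted.values, kry$fitted, tolerance = 1e-8)
    }
  }
})

test_that("deflation exhausts the descriptor block at full rank", {
  pr <- random_problem(n = 15, m = 6, seed = 21)
  sc <- autoscale(pr$X)
  eng <- opsqsar:::pls1_engine(sc$X, pr$y - mean(pr$y), ncomp = 6)
  expect_lt(norm(eng$X_residual, "F"), 1e-8)
})

test_that("explained X variance is non-negative, bounded and exact on orthogonal designs", {
  pr <- random_problem(n = 22, m = 6, seed = 31)
  fit <- fit_pls(pr$X, pr$y, ncomp = 5)
  expv <- explained_variance(fit)
  expect_true(all(expv >= 0))
  expect_lte(sum(expv), 100 + 1e-6)
  full <- fit_pls(pr$X, pr$y, ncomp = 6)
  expect_equal(sum(explained_variance(full)), 100, tolerance = 1e-6)

  ## orthogonal design, equal y loadings: LV1 captures exactly 1/m
  set.seed(8)
  m <- 4
  Q <- qr.Q(qr(scale(matrix(rnorm(48), 12, m), center = TRUE, scale = FALSE)))
  Xo <- Q                     # orthogonal, mean-zero columns
  y <- drop(Xo %*% rep(1, m))
  f1 <- fit_pls(Xo, y, ncomp = 1)
  expect_equal(explained_variance(f1), 100 / m, tolerance = 1e-8)
})

test_that("Wold rule flags descriptors at half the largest standardized coefficient", {
  b <- c(EEig02r = -0.549, SOFT = 0.545, alpha_xx = 0.377,
         q10NBO = 0.238, q2NBO = 0.250, SsssN_oth = -0.314)
  rep <- standardized_coefficients(b)
  expect_equal(attr(rep, "threshold"), 0.2745)
  expect_equal(sum(rep$significant), 4)
  expect_setequal(rep$descriptor[!rep$significant], c("q10NBO", "q2NBO"))

  expect_true(standardized_coefficients(c(a = 0.2))$significant)
  expect_true(all(standardized_coefficients(c(a = 0.3, b = -0.3))$significant))
})

test_that("model validation guards reject infeasible inputs", {
  pr <- random_problem(n = 10, m = 4, seed = 41)
  expect_error(fit_pls(pr$X, pr$y, ncomp = 5), "ncomp")
  expect_error(fit_pls(pr$X, rep(1, 10), 1), "zero-variance")
  fit <- fit_pls(pr$X, pr$y, 2)
  expect_error(predict(fit, pr$X[, 1:3]), "columns")
})

test_that("simulate draws reproducible noise around the fitted values", {
  pr <- random_problem(n = 18, m = 4, seed = 51)
  fit <- fit_pls(pr$X, pr$y, 2)
  s1 <- simulate(fit, nsim = 3, seed = 99)
  s2 <- simulate(fit, nsim = 3, seed = 99)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(18L, 3L))
})
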