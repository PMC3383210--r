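#' Sum of squares of an activity vector about its mean
#'
#' @param y numeric vector, length >= 2.
#' @return `sum((y - mean(y))^2)`.
#' @export
ssy <- function(y) {
  if (length(y) < 2) stop("need at least two values", call. = FALSE)
  sum((y - mean(y))^2)
}

#' Calibration statistics of a fitted model
#'
#' Computes the internal quality statistics used for PLS-QSAR models:
#' coefficient of determination R2, standard error of calibration
#' `SEC = sqrt(RSS / (n - p - 1))`, and the F ratio
#' `(R2/p) / ((1 - R2)/(n - p - 1))` with its upper-alpha critical value
#' on (p, n - p - 1) degrees of freedom, where `p` is the number of
#' latent variables.
#'
#' @param y observed activities.
#' @param fitted fitted activities (same length).
#' @param p number of latent variables.
#' @param alpha significance level for the F critical value; default 0.05.
#' @return list of class `"fit_stats"`: `r2`, `sec`, `rss`, `ssy`,
#'   `f_value`, `f_crit`, `n`, `p`, `alpha`, and `overflow` (`TRUE` when
#'   the fit is exact and F is unbounded).
#' @export
fit_statistics <- function(y, fitted, p, alpha = 0.05) {
  n <- length(y)
  if (length(fitted) != n) stop("length mismatch", call. = FALSE)
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  ss <- ssy(y)
  if (ss == 0) stop("zero-variance activity vector", call. = FALSE)
  rss <- sum((y - fitted)^2)
  r2 <- 1 - rss / ss
  sec <- sqrt(rss / (n - p - 1))
  overflow <- rss == 0
  f_value <- if (overflow) Inf else (r2 / p) / ((1 - r2) / (n - p - 1))
  structure(list(r2 = r2, sec = sec, rss = rss, ssy = ss,
                 f_value = f_value,
                 f_crit = stats::qf(1 - alpha, p, n - p - 1),
                 n = n, p = p, alpha = alpha, overflow = overflow),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d;  R2 = %.3f;  SEC = %.3f;  F(%d,%d) = %s (crit %.3f)\n",
    x$n, x$r2, x$sec, x$p, x$n - x$p - 1,
    if (x$overflow) "Inf" else sprintf("%.3f", x$f_value), x$f_crit))
  invisible(x)
}

## Internal: cross-validation statistics container.
cv_stats <- function(press, ss, n, predictions = NULL) {
  structure(list(press = press, q2 = 1 - press / ss,
                 sev = sqrt(press / n), ssy = ss, n = n,
                 predictions = predictions),
            class = "cv_stats")
}

#' @export
print.cv_stats <- function(x, ...) {
  cat(sprintf("Q2 = %.3f;  SEV = %.3f;  PRESS = %.3f (SSy = %.3f; n = %d)\n",
              x$q2, x$sev, x$press, x$ssy, x$n))
  invisible(x)
}

#' Leave-one-out cross validation of a PLS model
#'
#' Each compound is removed in turn, the model refitted on the rest, and
#' the held-out activity predicted; `PRESS` is the sum of the squared
#' prediction errors, `Q2 = 1 - PRESS/SSy` and `SEV = sqrt(PRESS/n)`.
#' Q2 can be negative (prediction worse than the mean); values above 0.5
#' are conventionally required for a predictive QSAR model.
#'
#' @param x descriptor matrix (original units).
#' @param y activity vector.
#' @param ncomp number of latent variables.
#' @param refit_scaling recompute the autoscaling inside every fold
#'   (leakage-safe, default) or reuse the full-data scaling.
#' @return object of class `"cv_stats"` with `press`, `q2`, `sev`, `ssy`,
#'   `n` and the per-compound `predictions`.
#' @export
loo_cv <- function(x, y, ncomp, refit_scaling = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 compounds", call. = FALSE)
  if (ncomp > min(n - 2, ncol(x)))
    stop("ncomp infeasible after removing one compound", call. = FALSE)
  pred <- cv_predict(x, y, ncomp, folds = as.list(seq_len(n)),
                     refit_scaling = refit_scaling)
  cv_stats(sum((y - pred)^2), ssy(y), n, predictions = pred)
}

## Internal: block cross-validation prediction engine shared by LOO/LNO.
## folds: list of integer vectors of row indices to hold out.
cv_predict <- function(x, y, ncomp, folds, refit_scaling = TRUE) {
  n <- nrow(x)
  pred <- numeric(n)
  if (!refit_scaling) sc_full <- autoscale(x)
  for (idx in folds) {
    xtr <- x[-idx, , drop = FALSE]; ytr <- y[-idx]
    if (refit_scaling) {
      sc <- autoscale(xtr)
      Xs <- sc$X
      ctr <- sc$scaling$center; sds <- sc$scaling$scale
    } else {
      ctr <- sc_full$scaling$center; sds <- sc_full$scaling$scale
      Xs <- sweep(sweep(xtr, 2, ctr, "-"), 2, sds, "/")
    }
    ym <- mean(ytr)
    eng <- pls1_engine(Xs, ytr - ym, ncomp)
    xte <- sweep(sweep(x[idx, , drop = FALSE], 2, ctr, "-"), 2, sds, "/")
    pred[idx] <- drop(xte %*% eng$b) + ym
  }
  pred
}

#' Leave-N-out cross validation
#'
#' Robustness check: for each block size `N`, the rows of the data are
#' jointly permuted, partitioned into consecutive blocks of `N`
#' compounds (the last block possibly smaller), and each block is left
#' out once; `Q2_LNO = 1 - PRESS/SSy` with SSy of the full activity
#' vector. Repeated `replicates` times per `N` with fresh permutations.
#' A robust model keeps mean Q2_LNO close to Q2_LOO with small spread.
#'
#' @param x descriptor matrix.
#' @param y activity vector.
#' @param ncomp number of latent variables.
#' @param n_max largest block size (default 7).
#' @param replicates permutation replicates per block size (default 6).
#' @param seed integer seed for the permutations (local RNG).
#' @param refit_scaling as in [loo_cv()].
#' @return object of class `"lno_result"`: data frame `trials`
#'   (`N`, `replicate`, `q2`) plus a `summary` data frame with mean and
#'   sample sd per `N`.
#' @export
lno_cv <- function(x, y, ncomp, n_max = 7, replicates = 6, seed = 1,
                   refit_scaling = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_max < 1 || n_max >= n) stop("infeasible n_max", call. = FALSE)
  if (replicates < 1) stop("need replicates >= 1", call. = FALSE)
  ss <- ssy(y)
  trials <- with_local_seed(seed, {
    do.call(rbind, lapply(seq_len(n_max), function(N) {
      q2 <- vapply(seq_len(replicates), function(r) {
        perm <- sample.int(n)
        folds <- split(perm, ceiling(seq_len(n) / N))
        pred <- cv_predict(x, y, ncomp, folds, refit_scaling = refit_scaling)
        1 - sum((y - pred)^2) / ss
      }, numeric(1))
      data.frame(N = N, replicate = seq_len(replicates), q2 = q2)
    }))
  })
  smry <- do.call(rbind, lapply(split(trials, trials$N), function(d)
    data.frame(N = d$N[1], mean_q2 = mean(d$q2),
               sd_q2 = if (nrow(d) > 1) stats::sd(d$q2) else 0)))
  rownames(smry) <- NULL
  structure(list(trials = trials, summary = smry, replicates = replicates,
                 seed = seed, ncomp = ncomp),
            class = "lno_result")
}

#' @export
print.lno_result <- function(x, ...) {
  cat("Leave-N-out cross validation (", x$replicates,
      " replicates per N, seed ", x$seed, ")\n", sep = "")
  print(transform(x$summary, mean_q2 = round(mean_q2, 3),
                  sd_q2 = round(sd_q2, 3)), row.names = FALSE)
  cat("Overall mean Q2_LNO =", round(mean(x$trials$q2), 3), "\n")
  invisible(x)
}

#' y-randomization (chance correlation) test
#'
#' The activity vector is scrambled `n_scrambles` times and the PLS model
#' refitted on the fixed descriptor subset each time, recording the
#' absolute correlation of the scrambled with the original activities
#' together with the resulting R2 and Q2_LOO. Following Eriksson's
#' approach, straight lines are fitted to the (|r|, R2) and (|r|, Q2)
#' points — anchored by the original model at |r| = 1 — and the model is
#' free of chance correlation when the intercepts fall below 0.3 (R2)
#' and 0.05 (Q2).
#'
#' @param x descriptor matrix of the selected subset.
#' @param y activity vector.
#' @param ncomp number of latent variables.
#' @param n_scrambles number of permutations (default 10).
#' @param seed integer seed (local RNG).
#' @param include_original anchor the regression lines with the original
#'   model's point at |r| = 1 (default `TRUE`).
#' @param r2_limit,q2_limit intercept pass limits (defaults 0.3, 0.05).
#' @return object of class `"yrand_result"`: data frame `scrambles`
#'   (`abs_r`, `r2`, `q2` per permutation), `intercept_r2`,
#'   `intercept_q2`, pass flags, and the original model's `r2`/`q2`.
#' @export
y_randomization <- function(x, y, ncomp, n_scrambles = 10, seed = 1,
                            include_original = TRUE,
                            r2_limit = 0.3, q2_limit = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_scrambles < 2) stop("need at least 2 scrambles", call. = FALSE)
  orig_fit <- fit_pls(x, y, ncomp)
  orig_r2 <- fit_statistics(y, orig_fit$fitted.values, p = orig_fit$ncomp)$r2
  orig_q2 <- loo_cv(x, y, ncomp)$q2
  scrambles <- with_local_seed(seed, {
    do.call(rbind, lapply(seq_len(n_scrambles), function(k) {
      yp <- y[sample.int(n)]
      fit <- fit_pls(x, yp, ncomp)
      data.frame(
        abs_r = abs(stats::cor(yp, y)),
        r2 = fit_statistics(yp, fit$fitted.values, p = fit$ncomp)$r2,
        q2 = loo_cv(x, yp, ncomp)$q2)
    }))
  })
  xs <- scrambles$abs_r; r2s <- scrambles$r2; q2s <- scrambles$q2
  if (include_original) {
    xs <- c(xs, 1); r2s <- c(r2s, orig_r2); q2s <- c(q2s, orig_q2)
  }
  int_r2 <- unname(stats::coef(stats::lm(r2s ~ xs))[1])
  int_q2 <- unname(stats::coef(stats::lm(q2s ~ xs))[1])
  structure(list(scrambles = scrambles,
                 intercept_r2 = int_r2, intercept_q2 = int_q2,
                 pass_r2 = int_r2 < r2_limit, pass_q2 = int_q2 < q2_limit,
                 original_r2 = orig_r2, original_q2 = orig_q2,
                 r2_limit = r2_limit, q2_limit = q2_limit,
                 seed = seed, ncomp = ncomp),
            class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat("y-randomization (", nrow(x$scrambles), " scrambles, seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  intercept R2 = %.3f (< %.2f: %s)\n", x$intercept_r2,
              x$r2_limit, if (x$pass_r2) "pass" else "FAIL"))
  cat(sprintf("  intercept Q2 = %.3f (< %.2f: %s)\n", x$intercept_q2,
              x$q2_limit, if (x$pass_q2) "pass" else "FAIL"))
  invisible(x)
}
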