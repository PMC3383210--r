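## NIPALS PLS1. For a single response no iteration is needed: at each
## deflation step the weight vector is the normalized covariance X'y, which
## makes the fit fully deterministic.

## Lean engine on preprocessed data (X autoscaled, y centered). No checks;
## used in cross-validation loops.
pls1_engine <- function(X, y, ncomp) {
  n <- nrow(X); m <- ncol(X)
  W <- matrix(0, m, ncomp); P <- matrix(0, m, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xa <- X; ya <- y
  a <- 0L
  while (a < ncomp) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12) break          # response fully deflated
    w <- w / nw
    tt <- Xa %*% w
    t2 <- sum(tt * tt)
    if (t2 < 1e-24) break
    p <- crossprod(Xa, tt) / t2
    qa <- sum(ya * tt) / t2
    Xa <- Xa - tcrossprod(tt, p)
    ya <- ya - qa * tt
    a <- a + 1L
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt; q[a] <- qa
  }
  if (a < ncomp) {
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    Tm <- Tm[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  }
  ## coefficients on the preprocessed scale: b = W (P'W)^{-1} q
  b <- if (a > 0) drop(W %*% solve(crossprod(P, W), q)) else numeric(m)
  list(W = W, P = P, T = Tm, q = q, b = b, ncomp = a, X_residual = Xa)
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Fits a partial-least-squares regression of a single activity on a
#' descriptor matrix. Descriptors are autoscaled (mean-centered, unit
#' sample variance) and the activity mean-centered internally; coefficients
#' are reported both on the original descriptor units and in standardized
#' form. Latent variables maximize the covariance between descriptor
#' projections and the activity.
#'
#' @param x numeric descriptor matrix (compounds x descriptors), original
#'   units.
#' @param y numeric activity vector (e.g. pIC50).
#' @param ncomp number of latent variables; must satisfy
#'   `ncomp <= min(n - 1, m)`.
#' @param scale_y also scale the activity to unit variance internally
#'   (predictions are invariant to this choice); default `FALSE`.
#' @return an object of class `"pls_model"` with components including
#'   `weights`, `x_loadings`, `y_loadings`, `scores`, `coefficients`
#'   (raw scale), `intercept`, `b_std` (standardized coefficients),
#'   `explained_x_variance` (per-LV percentages), `fitted.values`,
#'   `residuals`, and the scaling parameters needed for prediction.
#' @seealso [predict.pls_model()], [standardized_coefficients()],
#'   [loo_cv()], [fit_statistics()]
#' @examples
#' d <- synth_generate(synthetic_spec(n = 20, m = 5, k_true = 2, seed = 1))
#' m <- fit_pls(d$X, d$y, ncomp = 2)
#' summary(m)
#' @export
fit_pls <- function(x, y, ncomp, scale_y = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); m <- ncol(x)
  if (length(y) != n) stop("x rows and y length differ", call. = FALSE)
  if (stats::sd(y) == 0) stop("zero-variance activity vector", call. = FALSE)
  if (ncomp < 1 || ncomp > min(n - 1, m))
    stop("ncomp must be in 1..min(n-1, m) = ", min(n - 1, m), call. = FALSE)
  sc <- autoscale(x)
  y_center <- mean(y)
  y_scale <- if (scale_y) stats::sd(y) else 1
  ys <- (y - y_center) / y_scale
  eng <- pls1_engine(sc$X, ys, ncomp)
  ## back-transform coefficients to original descriptor/activity units
  b_raw <- eng$b * y_scale / sc$scaling$scale
  intercept <- y_center - sum(b_raw * sc$scaling$center)
  b_std <- eng$b * y_scale / stats::sd(y)     # autoscaled x, autoscaled y
  fitted <- drop(x %*% b_raw) + intercept
  ## per-LV explained variance of the autoscaled X block
  ssx <- sum(sc$X^2)
  expv <- 100 * colSums(eng$T^2) * colSums(eng$P^2) / ssx
  structure(list(
    ncomp = eng$ncomp,
    weights = eng$W, x_loadings = eng$P, y_loadings = eng$q,
    scores = eng$T,
    coefficients = stats::setNames(b_raw, colnames(x)),
    intercept = intercept,
    b_std = stats::setNames(b_std, colnames(x)),
    explained_x_variance = expv,
    scaling = sc$scaling, y_center = y_center, y_scale = y_scale,
    y = y, fitted.values = fitted, residuals = y - fitted,
    descriptors = colnames(x), n = n,
    call = match.call()
  ), class = "pls_model")
}

#' Predict activities from a fitted PLS model
#'
#' @param object a `"pls_model"`.
#' @param newdata descriptor matrix in original units; columns must match
#'   (by name when named) the training descriptors. Missing `newdata`
#'   returns the training fitted values.
#' @param ... unused.
#' @return numeric vector of predicted activities.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (missing(newdata) || is.null(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$descriptors))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$descriptors), call. = FALSE)
  if (!is.null(colnames(newdata))) {
    if (!setequal(colnames(newdata), object$descriptors))
      stop("newdata descriptor names do not match the model", call. = FALSE)
    newdata <- newdata[, object$descriptors, drop = FALSE]
  }
  drop(newdata %*% object$coefficients) + object$intercept
}

## Prediction through the latent-variable route (scores from W, P, q);
## algebraically identical to the coefficient route, kept as an internal
## cross-check of the decomposition.
predict_via_scores <- function(object, newdata) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$scaling$center, "-"),
              2, object$scaling$scale, "/")
  R <- object$weights %*% solve(crossprod(object$x_loadings, object$weights))
  Tn <- Xs %*% R
  drop(Tn %*% object$y_loadings) * object$y_scale + object$y_center
}

#' Standardized coefficients and the Wold significance rule
#'
#' Standardized coefficients refer to autoscaled descriptors and activity
#' (`b_std_j = b_raw_j * sd(x_j) / sd(y)`); they are directly comparable
#' across descriptors. Wold's rule of thumb flags a descriptor as
#' significant when its |standardized coefficient| reaches half the
#' largest one.
#'
#' @param model a `"pls_model"`, or a plain numeric vector of standardized
#'   coefficients.
#' @param y_sd optional activity standard deviation overriding the one
#'   stored in the model (ignored for vector input).
#' @return a data frame of class `"coef_report"` with columns
#'   `descriptor`, `b_std`, `significant`, and attribute `threshold`
#'   (= 0.5 * max |b_std|).
#' @export
standardized_coefficients <- function(model, y_sd = NULL) {
  if (inherits(model, "pls_model")) {
    b <- model$b_std
    if (!is.null(y_sd)) {
      stopifnot(y_sd > 0)
      b <- model$coefficients * model$scaling$scale / y_sd
    }
  } else b <- model
  if (is.null(names(b))) names(b) <- paste0("x", seq_along(b))
  thr <- 0.5 * max(abs(b))
  out <- data.frame(descriptor = names(b), b_std = as.numeric(b),
                    significant = abs(b) >= thr, row.names = NULL)
  attr(out, "threshold") <- thr
  class(out) <- c("coef_report", "data.frame")
  out
}

#' @export
print.coef_report <- function(x, digits = 3, ...) {
  cat("Standardized PLS coefficients (Wold threshold ",
      format(round(attr(x, "threshold"), digits)), ")\n", sep = "")
  df <- data.frame(descriptor = x$descriptor,
                   b_std = round(x$b_std, digits),
                   significant = ifelse(x$significant, "*", ""))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Per-latent-variable explained X variance
#'
#' Percentage of the autoscaled descriptor block's total sum of squares
#' captured by each latent variable's rank-one reconstruction.
#'
#' @param model a `"pls_model"`.
#' @return numeric vector of percentages, one per latent variable.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  model$explained_x_variance
}

#' @export
print.pls_model <- function(x, digits = 3, ...) {
  cat("PLS1 regression model (NIPALS): ", x$n, " compounds, ",
      length(x$descriptors), " descriptors, ", x$ncomp, " latent variable(s)\n",
      sep = "")
  cat("Explained X variance (%):",
      paste(format(round(x$explained_x_variance, 3)), collapse = " + "),
      "=", format(round(sum(x$explained_x_variance), 3)), "\n")
  cat("Coefficients (original units):\n")
  print(round(c(x$coefficients, `(Intercept)` = x$intercept), digits))
  invisible(x)
}

#' @export
summary.pls_model <- function(object, alpha = 0.05, ...) {
  fs <- fit_statistics(object$y, object$fitted.values, p = object$ncomp,
                       alpha = alpha)
  out <- list(model = object, fit = fs,
              coef_report = standardized_coefficients(object))
  class(out) <- "summary.pls_model"
  out
}

#' @export
print.summary.pls_model <- function(x, ...) {
  print(x$model)
  f <- x$fit
  cat(sprintf("R2 = %.3f   SEC = %.3f   F(%d,%d) = %.3f (crit %.3f)\n",
              f$r2, f$sec, f$p, f$n - f$p - 1,
              f$f_value, f$f_crit))
  print(x$coef_report)
  invisible(x)
}

#' @export
coef.pls_model <- function(object, intercept = TRUE, ...) {
  if (intercept) c(`(Intercept)` = object$intercept, object$coefficients)
  else object$coefficients
}

#' @export
fitted.pls_model <- function(object, ...) object$fitted.values

#' @export
residuals.pls_model <- function(object, ...) object$residuals

#' Simulate activities from a fitted PLS model
#'
#' Draws new activity vectors as fitted values plus Gaussian noise with
#' standard deviation equal to the model's standard error of calibration.
#'
#' @param object a `"pls_model"`.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed (local RNG; global state untouched).
#' @param ... unused.
#' @return data frame with `nsim` columns.
#' @export
simulate.pls_model <- function(object, nsim = 1, seed = NULL, ...) {
  fs <- fit_statistics(object$y, object$fitted.values, p = object$ncomp)
  s <- fs$sec
  with_local_seed(seed, {
    out <- as.data.frame(replicate(
      nsim, object$fitted.values + stats::rnorm(object$n, 0, s)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Diagnostic plots for a PLS model
#'
#' `type = "fit"` plots observed versus fitted activities;
#' `type = "williams"` plots studentized residuals against leverage with
#' the conventional cutoff lines (outlier/applicability view).
#'
#' @param x a `"pls_model"`.
#' @param type `"fit"` or `"williams"`.
#' @param residual_threshold,leverage_factor cutoffs for the Williams
#'   view; see [outlier_report()].
#' @param ... passed to [plot()].
#' @export
plot.pls_model <- function(x, type = c("fit", "williams"),
                           residual_threshold = 2.5, leverage_factor = 3,
                           ...) {
  type <- match.arg(type)
  if (type == "fit") {
    plot(x$fitted.values, x$y, xlab = "Fitted activity",
         ylab = "Observed activity", ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    d <- outlier_report(x, residual_threshold = residual_threshold,
                        leverage_factor = leverage_factor)
    plot(d$leverage, d$studentized_residual, xlab = "Leverage",
         ylab = "Studentized residual", ...)
    graphics::abline(h = c(-1, 1) * attr(d, "residual_threshold"), lty = 2)
    graphics::abline(v = attr(d, "leverage_cutoff"), lty = 2)
  }
  invisible(x)
}
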