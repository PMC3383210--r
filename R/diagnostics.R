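#' Compound leverages in latent-variable space
#'
#' Leverage of compound i is `h_i = 1/n + t_i' (T'T)^{-1} t_i`, with
#' `t_i` its score vector. Leverages sum to A + 1 (A latent variables
#' plus the intercept/centering term).
#'
#' @param model a fitted `"pls_model"`.
#' @return numeric vector of leverages, one per training compound.
#' @export
leverages <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  Tm <- model$scores
  G <- crossprod(Tm)
  if (rcond(G) < 1e-14) stop("singular score cross-product", call. = FALSE)
  1 / model$n + rowSums((Tm %*% solve(G)) * Tm)
}

#' Studentized residuals
#'
#' Residuals scaled by the calibration error and the leverage,
#' `r_i = (y_i - yhat_i) / (s * sqrt(1 - h_i))`, with `s` the standard
#' error of calibration. Values beyond about 2.5 flag response outliers.
#'
#' @param y observed activities.
#' @param fitted fitted activities.
#' @param h leverages (in (0, 1)).
#' @param p number of latent variables.
#' @return numeric vector of studentized residuals.
#' @export
studentized_residuals <- function(y, fitted, h, p) {
  if (any(h >= 1) || any(h <= 0))
    stop("leverages must lie strictly in (0, 1)", call. = FALSE)
  s <- fit_statistics(y, fitted, p)$sec
  if (s == 0) return(rep(0, length(y)))   # exact fit: all residuals zero
  (y - fitted) / (s * sqrt(1 - h))
}

#' Outlier diagnostics (Williams-plot data)
#'
#' Combines leverages and studentized residuals with the conventional
#' cutoffs: residual threshold `residual_threshold` (default 2.5 sigma)
#' and leverage cutoff `h* = leverage_factor * (A + 1) / n` (default
#' factor 3).
#'
#' @param model a fitted `"pls_model"`.
#' @param residual_threshold studentized-residual cutoff (default 2.5).
#' @param leverage_factor multiplier of `(A + 1)/n` for the leverage
#'   cutoff (default 3).
#' @param ids compound labels; defaults to names/indices of the training
#'   activities.
#' @return data frame of class `"outlier_report"` with columns `id`,
#'   `leverage`, `studentized_residual`, `high_leverage`,
#'   `high_residual`; cutoffs stored as attributes `leverage_cutoff`
#'   and `residual_threshold`.
#' @export
outlier_report <- function(model, residual_threshold = 2.5,
                           leverage_factor = 3, ids = NULL) {
  stopifnot(inherits(model, "pls_model"))
  h <- leverages(model)
  r <- studentized_residuals(model$y, model$fitted.values, h, model$ncomp)
  hstar <- leverage_factor * (model$ncomp + 1) / model$n
  out <- data.frame(
    id = as.character(ids %||% names(model$y) %||% seq_len(model$n)),
    leverage = h, studentized_residual = r,
    high_leverage = h > hstar,
    high_residual = abs(r) > residual_threshold,
    row.names = NULL)
  attr(out, "leverage_cutoff") <- hstar
  attr(out, "residual_threshold") <- residual_threshold
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "Outlier diagnostics: leverage cutoff %.3f, residual threshold %.1f\n",
    attr(x, "leverage_cutoff"), attr(x, "residual_threshold")))
  nlev <- sum(x$high_leverage); nres <- sum(x$high_residual)
  cat("  high leverage:", nlev,
      if (nlev) paste0("(", paste(x$id[x$high_leverage], collapse = ", "), ")")
      else "", "\n")
  cat("  high residual:", nres,
      if (nres) paste0("(", paste(x$id[x$high_residual], collapse = ", "), ")")
      else "", "\n")
  invisible(x)
}
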