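#' Remove missing, invariant and quasi-invariant descriptors
#'
#' Drops every descriptor column that contains a missing value, has zero
#' sample variance, or whose most frequent value occurs in more than
#' `quasi_invariant_fraction` of the compounds.
#'
#' @param X numeric descriptor matrix (compounds x descriptors).
#' @param quasi_invariant_fraction modal-frequency cutoff in (0, 1];
#'   default 0.95.
#' @return list with `X` (the cleaned matrix) and `report`, a
#'   `filter_report` recording removed/kept columns and the reason.
#' @export
remove_degenerate_columns <- function(X, quasi_invariant_fraction = 0.95) {
  stopifnot(is.matrix(X), quasi_invariant_fraction > 0,
            quasi_invariant_fraction <= 1)
  nm <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- nm
  reason <- character(0); removed <- character(0)
  drop <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    if (anyNA(xj)) { drop[j] <- TRUE; removed <- c(removed, nm[j]); reason <- c(reason, "missing"); next }
    if (stats::var(xj) == 0) { drop[j] <- TRUE; removed <- c(removed, nm[j]); reason <- c(reason, "invariant"); next }
    modal <- max(table(xj)) / length(xj)
    if (modal > quasi_invariant_fraction) {
      drop[j] <- TRUE; removed <- c(removed, nm[j]); reason <- c(reason, "quasi-invariant")
    }
  }
  if (all(drop)) stop("no descriptors remain after cleaning", call. = FALSE)
  rep <- structure(list(removed = removed, reason = reason,
                        kept = nm[!drop], threshold = quasi_invariant_fraction,
                        type = "degenerate"),
                   class = "filter_report")
  list(X = X[, !drop, drop = FALSE], report = rep)
}

#' Autoscale a descriptor matrix
#'
#' Column-wise mean centering and scaling to unit (sample, n-1) variance —
#' the standard chemometric preprocessing that puts all descriptors on a
#' comparable scale before PLS.
#'
#' @param X numeric matrix; every column must have positive variance.
#' @return list with `X` (scaled matrix) and `scaling` (list with `center`
#'   and `scale` vectors), usable with [unscale()].
#' @export
autoscale <- function(X) {
  stopifnot(is.matrix(X))
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stop("zero-variance column(s): ",
         paste((colnames(X) %||% as.character(seq_len(ncol(X))))[bad],
               collapse = ", "), call. = FALSE)
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, sds, "/")
  list(X = Xs, scaling = list(center = ctr, scale = sds))
}

#' Invert autoscaling
#'
#' @param Xs autoscaled matrix.
#' @param scaling the `scaling` element returned by [autoscale()].
#' @return matrix on the original scale.
#' @export
unscale <- function(Xs, scaling) {
  sweep(sweep(Xs, 2, scaling$scale, "*"), 2, scaling$center, "+")
}

#' Correlation pre-filter against the activity
#'
#' Keeps the descriptors whose absolute Pearson correlation with the
#' activity is at least `min_abs_r`; descriptors with |r| strictly below
#' the threshold are removed. This is the classical first reduction step
#' before OPS variable selection.
#'
#' @param X numeric descriptor matrix.
#' @param y activity vector aligned with the rows of `X`.
#' @param min_abs_r threshold in \[0, 1\]; default 0.3.
#' @return list with `X` (filtered matrix) and `report` (a
#'   `filter_report` carrying every |r| value).
#' @export
correlation_prefilter <- function(X, y, min_abs_r = 0.3) {
  stopifnot(is.matrix(X), min_abs_r >= 0, min_abs_r <= 1)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  if (stats::sd(y) == 0) stop("zero-variance activity vector", call. = FALSE)
  nm <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- nm
  r <- as.vector(abs(stats::cor(X, y)))
  names(r) <- nm
  keep <- r >= min_abs_r - 1e-12    # boundary |r| == threshold is retained
  rep <- structure(list(removed = nm[!keep], reason = rep("low |r|", sum(!keep)),
                        kept = nm[keep], abs_r = r, threshold = min_abs_r,
                        type = "correlation"),
                   class = "filter_report")
  list(X = X[, keep, drop = FALSE], report = rep)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Descriptor filter (", x$type, "): ", length(x$kept), " kept, ",
      length(x$removed), " removed (threshold ", x$threshold, ")\n", sep = "")
  if (length(x$removed)) {
    tab <- table(x$reason)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}
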