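#' Train/test split aided by hierarchical cluster analysis
#'
#' Selects a structurally and activity-representative external test set:
#' compounds are clustered by agglomerative hierarchical clustering
#' (Euclidean distance on the autoscaled descriptors), the activity range
#' is divided into `n_test` quantile strata, and one test compound is
#' drawn per stratum, from a distinct cluster where possible. The global
#' activity minimum and maximum are never selected, so the training set
#' always spans the full activity range.
#'
#' @param x descriptor matrix (original units; autoscaled internally).
#' @param y activity vector.
#' @param n_test number of test compounds (must be < n/2 and >= 1).
#' @param linkage agglomeration method for [stats::hclust()]; default
#'   `"complete"`.
#' @param seed integer seed used when several candidates remain after the
#'   cluster/stratum preferences (local RNG).
#' @param ids compound ids; default row names of `x`.
#' @return object of class `"split_spec"`: `train_ids`, `test_ids`,
#'   `method`.
#' @export
hca_split <- function(x, y, n_test, linkage = "complete", seed = 1,
                      ids = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  ids <- as.character(ids %||% rownames(x) %||% seq_len(n))
  if (n_test < 1 || n_test >= n / 2)
    stop("n_test must be >= 1 and < n/2", call. = FALSE)
  Xs <- autoscale(x)$X
  hc <- stats::hclust(stats::dist(Xs), method = linkage)
  cluster <- stats::cutree(hc, k = min(n - 1, max(n_test, 2)))
  stratum <- cut(rank(y, ties.method = "first"),
                 breaks = n_test, labels = FALSE)
  banned <- c(which.min(y), which.max(y))
  test_idx <- with_local_seed(seed, {
    used_clusters <- integer(0)
    sel <- integer(0)
    for (s in seq_len(n_test)) {
      cand <- setdiff(which(stratum == s), c(banned, sel))
      if (!length(cand)) cand <- setdiff(seq_len(n), c(banned, sel))
      fresh <- cand[!cluster[cand] %in% used_clusters]
      if (length(fresh)) cand <- fresh
      pick <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      sel <- c(sel, pick)
      used_clusters <- c(used_clusters, cluster[pick])
    }
    sel
  })
  structure(list(train_ids = ids[-test_idx], test_ids = ids[test_idx],
                 method = "hca-representative", linkage = linkage,
                 seed = seed),
            class = "split_spec")
}

#' Fixed-list train/test split
#'
#' @param ids all compound ids.
#' @param test_ids ids of the external test set (must be a non-empty
#'   proper subset of `ids`).
#' @return object of class `"split_spec"`.
#' @export
fixed_split <- function(ids, test_ids) {
  ids <- as.character(ids); test_ids <- as.character(test_ids)
  if (!length(test_ids)) stop("test set must be non-empty", call. = FALSE)
  if (!all(test_ids %in% ids))
    stop("unknown test ids: ",
         paste(setdiff(test_ids, ids), collapse = ", "), call. = FALSE)
  if (length(test_ids) >= length(ids))
    stop("test set must be a proper subset", call. = FALSE)
  structure(list(train_ids = setdiff(ids, test_ids), test_ids = test_ids,
                 method = "fixed-list"),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("Train/test split (", x$method, "): ", length(x$train_ids),
      " training, ", length(x$test_ids), " test compounds\n", sep = "")
  cat("  test:", paste(x$test_ids, collapse = ", "), "\n")
  invisible(x)
}

#' External validation metrics (R2pred, SEP, Golbraikh-Tropsha)
#'
#' Computes the standard external-predictivity battery from observed and
#' predicted test-set activities:
#' `R2pred = 1 - PRESS_test / sum((obs - y_train_mean)^2)` (note the
#' training-set mean in the denominator), `SEP = sqrt(PRESS_test/n)`,
#' the through-origin regression slopes `k = sum(obs*pred)/sum(pred^2)`
#' and `k' = sum(obs*pred)/sum(obs^2)`, and the through-origin
#' determination coefficients `R2_0` (observed on predicted) and `R'2_0`
#' (predicted on observed). A model is considered externally predictive
#' when `R2pred > 0.5`, both slopes lie in \[0.85, 1.15\] and
#' `|R2_0 - R'2_0| < 0.3`.
#'
#' @param obs observed test activities.
#' @param pred predicted test activities.
#' @param y_train_mean mean activity of the training set.
#' @param r2pred_limit,slope_range,diff_limit pass thresholds.
#' @return object of class `"external_validation"`: `r2pred`, `sep`,
#'   `press_test`, `k`, `kprime`, `r2_0`, `rprime2_0`, `abs_diff`, and
#'   logical pass flags.
#' @export
external_metrics <- function(obs, pred, y_train_mean,
                             r2pred_limit = 0.5,
                             slope_range = c(0.85, 1.15),
                             diff_limit = 0.3) {
  if (length(obs) != length(pred) || length(obs) < 2)
    stop("obs and pred must have equal length >= 2", call. = FALSE)
  n <- length(obs)
  press <- sum((obs - pred)^2)
  denom <- sum((obs - y_train_mean)^2)
  if (denom == 0) stop("degenerate denominator: obs equal to training mean",
                       call. = FALSE)
  if (sum(pred^2) == 0) stop("degenerate denominator: sum(pred^2) = 0",
                             call. = FALSE)
  if (sum(obs^2) == 0) stop("degenerate denominator: sum(obs^2) = 0",
                            call. = FALSE)
  if (stats::var(obs) == 0) stop("degenerate: zero variance in obs",
                                 call. = FALSE)
  if (stats::var(pred) == 0) stop("degenerate: zero variance in pred",
                                  call. = FALSE)
  k <- sum(obs * pred) / sum(pred^2)
  kprime <- sum(obs * pred) / sum(obs^2)
  r2_0 <- 1 - sum((obs - k * pred)^2) / sum((obs - mean(obs))^2)
  rprime2_0 <- 1 - sum((pred - kprime * obs)^2) / sum((pred - mean(pred))^2)
  abs_diff <- abs(r2_0 - rprime2_0)
  r2pred <- 1 - press / denom
  structure(list(
    r2pred = r2pred, sep = sqrt(press / n), press_test = press,
    k = k, kprime = kprime, r2_0 = r2_0, rprime2_0 = rprime2_0,
    abs_diff = abs_diff, n = n,
    pass_r2pred = r2pred > r2pred_limit,
    pass_k = k >= slope_range[1] && k <= slope_range[2],
    pass_kprime = kprime >= slope_range[1] && kprime <= slope_range[2],
    pass_diff = abs_diff < diff_limit
  ), class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  ok <- function(f) if (f) "pass" else "FAIL"
  cat("External validation (n =", x$n, ")\n")
  cat(sprintf("  R2pred = %.3f (> 0.5: %s)   SEP = %.3f\n",
              x$r2pred, ok(x$pass_r2pred), x$sep))
  cat(sprintf("  k = %.3f (%s)   k' = %.3f (%s)\n",
              x$k, ok(x$pass_k), x$kprime, ok(x$pass_kprime)))
  cat(sprintf("  |R2_0 - R'2_0| = %.3f (< 0.3: %s)\n",
              x$abs_diff, ok(x$pass_diff)))
  invisible(x)
}
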