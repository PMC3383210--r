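#' Informative vector for ordered predictors selection
#'
#' Scores every descriptor by its expected importance for the activity:
#' `"correlation"` uses the Pearson correlation with the activity,
#' `"regression"` the standardized regression vector of a pilot PLS fit,
#' and `"product"` their elementwise product.
#'
#' @param X autoscaled descriptor matrix.
#' @param y centered activity vector.
#' @param kind `"correlation"`, `"regression"` or `"product"`.
#' @param ncomp latent variables of the pilot fit for the regression
#'   vector; default `min(8, n - 2, m)`.
#' @return numeric vector of scores, one per descriptor (named).
#' @export
informative_vector <- function(X, y, kind = c("correlation", "regression",
                                              "product"),
                               ncomp = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  nm <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  ncomp <- ncomp %||% min(8, nrow(X) - 2, ncol(X))
  corv <- drop(stats::cor(X, y))
  regv <- function() pls1_engine(X, y - mean(y), ncomp)$b
  out <- switch(kind,
                correlation = corv,
                regression  = regv(),
                product     = corv * regv())
  stats::setNames(out, nm)
}

#' Ordered predictors selection (OPS) over PLS
#'
#' OPS ranks the descriptors by the absolute value of an informative
#' vector, reorders the matrix so the most informative come first, and
#' then scans nested subsets of increasing size, fitting a PLS model and
#' scoring it by leave-one-out cross validation (Q2 or SEV) at each
#' candidate number of latent variables. The best-scoring
#' subset/latent-variable combination is returned together with the full
#' trial table.
#'
#' @param x descriptor matrix (original units; autoscaling is applied
#'   internally both for ranking and within each cross-validation fold).
#' @param y activity vector.
#' @param kind informative vector kind, see [informative_vector()].
#' @param window smallest subset size scanned; default `max(lv_range)`.
#' @param increment subset-size step; default 1.
#' @param max_subset largest subset size; default `min(m, 30)`.
#' @param lv_range candidate latent-variable counts; default
#'   `1:min(8, n - 2)`.
#' @param criterion rank trials by maximal `"q2"` (default) or minimal
#'   `"sev"` (equivalent orderings at fixed n).
#' @param refit_scaling see [loo_cv()].
#' @return object of class `"ops_result"`: `ranking` (descriptor names,
#'   most informative first), `trials` (data frame of size, ncomp, q2,
#'   sev), and `best` (list with `descriptors`, `ncomp`, `q2`, `sev`).
#' @export
ops_search <- function(x, y, kind = "correlation", window = NULL,
                       increment = 1, max_subset = NULL, lv_range = NULL,
                       criterion = c("q2", "sev"), refit_scaling = TRUE) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); m <- ncol(x)
  lv_range <- lv_range %||% seq_len(min(8, n - 2))
  if (max(lv_range) > n - 2) stop("lv_range infeasible for n", call. = FALSE)
  window <- window %||% min(max(lv_range), m)
  max_subset <- max_subset %||% min(m, 30)
  if (window < 1 || window > max_subset || max_subset > m)
    stop("need 1 <= window <= max_subset <= m", call. = FALSE)
  sc <- autoscale(x)
  score <- informative_vector(sc$X, y - mean(y), kind,
                              ncomp = max(lv_range))
  ranking <- colnames(x)[order(-abs(score))]
  sizes <- seq(window, max_subset, by = increment)
  trials <- vector("list", length(sizes) * length(lv_range)); k <- 0L
  for (size in sizes) {
    xsub <- x[, ranking[seq_len(size)], drop = FALSE]
    for (A in lv_range[lv_range <= min(size, n - 2)]) {
      cv <- loo_cv(xsub, y, A, refit_scaling = refit_scaling)
      k <- k + 1L
      trials[[k]] <- data.frame(size = size, ncomp = A,
                                q2 = cv$q2, sev = cv$sev)
    }
  }
  trials <- do.call(rbind, trials[seq_len(k)])
  ## best trial: criterion first, then parsimony (smaller subset, fewer
  ## LVs), then lexicographic descriptor names for full determinism
  key <- if (criterion == "q2") -trials$q2 else trials$sev
  ord <- order(key, trials$size, trials$ncomp)
  best_row <- trials[ord[1], ]
  structure(list(
    ranking = ranking, trials = trials,
    best = list(descriptors = ranking[seq_len(best_row$size)],
                ncomp = best_row$ncomp, q2 = best_row$q2,
                sev = best_row$sev),
    kind = kind, criterion = criterion, scores = score
  ), class = "ops_result")
}

#' Run OPS with all three informative vectors
#'
#' Runs [ops_search()] with the correlation, regression and product
#' informative vectors and returns the best result by the chosen
#' criterion; the per-kind results are retained.
#'
#' @inheritParams ops_search
#' @param ... passed to [ops_search()].
#' @return the winning `"ops_result"`, with the per-kind results in
#'   attribute-free element `all_results` (a named list).
#' @export
ops_run_all <- function(x, y, criterion = c("q2", "sev"), ...) {
  criterion <- match.arg(criterion)
  kinds <- c("correlation", "regression", "product")
  res <- lapply(kinds, function(k)
    ops_search(x, y, kind = k, criterion = criterion, ...))
  names(res) <- kinds
  crit <- vapply(res, function(r)
    if (criterion == "q2") r$best$q2 else -r$best$sev, numeric(1))
  best <- res[[which.max(crit)]]
  best$all_results <- res
  best
}

#' @export
print.ops_result <- function(x, ...) {
  cat("OPS variable selection (", x$kind, " vector, criterion ",
      x$criterion, ")\n", sep = "")
  cat("  trials:", nrow(x$trials), "  best subset size:",
      length(x$best$descriptors), "  LVs:", x$best$ncomp, "\n")
  cat(sprintf("  best Q2 = %.3f  SEV = %.3f\n", x$best$q2, x$best$sev))
  cat("  descriptors:", paste(x$best$descriptors, collapse = ", "), "\n")
  invisible(x)
}
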