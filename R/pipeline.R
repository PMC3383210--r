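#' Configuration for the end-to-end QSAR pipeline
#'
#' Collects every tunable of [run_pipeline()] with the conventional
#' defaults: |r| >= 0.3 activity pre-filter, OPS over all three
#' informative vectors ranked by Q2_LOO, leave-N-out up to N = 7 in
#' hexaplicate, 10 y-scrambles, and a 5-compound HCA-aided test set.
#'
#' @param prefilter_r activity correlation threshold (default 0.3).
#' @param quasi_invariant_fraction see [remove_degenerate_columns()].
#' @param ops_kind `"all"` (three informative vectors) or one of
#'   `"correlation"`, `"regression"`, `"product"`.
#' @param window,increment,max_subset,lv_range,criterion see
#'   [ops_search()].
#' @param ncomp fixed number of latent variables; `NULL` takes the OPS
#'   winner's.
#' @param lno_n_max,lno_replicates see [lno_cv()].
#' @param n_scrambles see [y_randomization()].
#' @param n_test external test-set size.
#' @param linkage HCA linkage for the split.
#' @param test_ids optional fixed test-set ids (skips the HCA heuristic).
#' @param refit_scaling autoscale within cross-validation folds.
#' @param seed integer seed driving every stochastic stage.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(prefilter_r = 0.3,
                            quasi_invariant_fraction = 0.95,
                            ops_kind = "all", window = NULL, increment = 1,
                            max_subset = NULL, lv_range = NULL,
                            criterion = "q2", ncomp = NULL,
                            lno_n_max = 7, lno_replicates = 6,
                            n_scrambles = 10, n_test = 5,
                            linkage = "complete", test_ids = NULL,
                            refit_scaling = TRUE, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

## Internal: run one stage, rethrowing errors with the stage name.
pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the complete PLS-QSAR pipeline
#'
#' Executes, in order: descriptor cleaning, activity correlation
#' pre-filter, OPS variable selection, PLS fit with calibration
#' statistics, leave-one-out and leave-N-out cross validation,
#' y-randomization, train/test split, training-set refit, external
#' validation, and outlier diagnostics. Every statistic is returned
#' together with its pass/fail against the conventional QSAR thresholds
#' (R2 > 0.6, Q2_LOO > 0.5, PRESS < SSy, y-randomization intercepts,
#' R2pred > 0.5, Golbraikh-Tropsha ranges).
#'
#' @param x descriptor matrix (compounds x descriptors, original units).
#' @param y activity vector (e.g. pIC50).
#' @param ids compound ids; default row names of `x`.
#' @param config a [pipeline_config()].
#' @return list of class `"qsar_pipeline"` with elements `cleaning`,
#'   `prefilter`, `ops`, `model`, `fit`, `cv`, `lno`, `yrand`, `split`,
#'   `training_model`, `external`, `diagnostics`, `flags` and `config`.
#' @export
run_pipeline <- function(x, y, ids = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- as.matrix(x)
  ids <- as.character(ids %||% rownames(x) %||% seq_len(nrow(x)))
  rownames(x) <- ids
  cl <- pipeline_stage("clean", remove_degenerate_columns(
    x, config$quasi_invariant_fraction))
  pf <- pipeline_stage("prefilter", correlation_prefilter(
    cl$X, y, config$prefilter_r))
  ops <- pipeline_stage("ops", {
    m_avail <- ncol(pf$X)
    args <- list(x = pf$X, y = y,
                 window = if (!is.null(config$window))
                   min(config$window, m_avail),
                 increment = config$increment,
                 max_subset = min(config$max_subset %||% m_avail, m_avail),
                 lv_range = config$lv_range,
                 criterion = config$criterion,
                 refit_scaling = config$refit_scaling)
    if (identical(config$ops_kind, "all")) do.call(ops_run_all, args)
    else do.call(ops_search, c(args, list(kind = config$ops_kind)))
  })
  sel <- ops$best$descriptors
  A <- config$ncomp %||% ops$best$ncomp
  xsel <- pf$X[, sel, drop = FALSE]
  model <- pipeline_stage("fit", fit_pls(xsel, y, ncomp = A))
  fit <- pipeline_stage("fit", fit_statistics(y, model$fitted.values, p = A))
  cv <- pipeline_stage("loo", loo_cv(xsel, y, A,
                                     refit_scaling = config$refit_scaling))
  lno <- pipeline_stage("lno", lno_cv(
    xsel, y, A, n_max = config$lno_n_max,
    replicates = config$lno_replicates, seed = config$seed,
    refit_scaling = config$refit_scaling))
  yrand <- pipeline_stage("y-randomization", y_randomization(
    xsel, y, A, n_scrambles = config$n_scrambles, seed = config$seed))
  split <- pipeline_stage("split", {
    if (!is.null(config$test_ids)) fixed_split(ids, config$test_ids)
    else hca_split(xsel, y, n_test = config$n_test,
                   linkage = config$linkage, seed = config$seed, ids = ids)
  })
  tr <- ids %in% split$train_ids
  train_model <- pipeline_stage("refit", fit_pls(
    xsel[tr, , drop = FALSE], y[tr], ncomp = A))
  ext <- pipeline_stage("external", external_metrics(
    obs = y[!tr],
    pred = predict(train_model, xsel[!tr, , drop = FALSE]),
    y_train_mean = mean(y[tr])))
  diag <- pipeline_stage("diagnostics", outlier_report(model, ids = ids))
  flags <- list(
    r2_ok = fit$r2 > 0.6,
    q2_ok = cv$q2 > 0.5,
    press_lt_ssy = cv$press < cv$ssy,
    f_ok = fit$f_value > fit$f_crit,
    yrand_ok = yrand$pass_r2 && yrand$pass_q2,
    r2pred_ok = ext$pass_r2pred,
    gt_ok = ext$pass_k && ext$pass_kprime && ext$pass_diff)
  structure(list(cleaning = cl$report, prefilter = pf$report, ops = ops,
                 model = model, fit = fit, cv = cv, lno = lno,
                 yrand = yrand, split = split,
                 training_model = train_model, external = ext,
                 diagnostics = diag, flags = flags, config = config),
            class = "qsar_pipeline")
}

#' @export
print.qsar_pipeline <- function(x, ...) {
  cat("QSAR pipeline report\n====================\n")
  print(x$prefilter)
  print(x$ops)
  print(x$fit)
  print(x$cv)
  print(x$lno)
  print(x$yrand)
  print(x$external)
  print(x$diagnostics)
  ok <- vapply(x$flags, isTRUE, logical(1))
  cat("Threshold flags: ",
      paste0(names(x$flags), "=", ifelse(ok, "pass", "FAIL"),
             collapse = "  "), "\n")
  invisible(x)
}

#' Consistency of a printed statistics block
#'
#' Recomputes the derivable members of a packaged model-statistics block
#' (`"eq1_stats"` or `"eq2_stats"`) from its primary entries: SEC and F
#' from (R2, SSy, n, p), Q2 and SEV from (PRESS, SSy, n), and the F
#' critical value from (p, n, alpha = 0.05).
#'
#' @param name `"eq1_stats"` or `"eq2_stats"`.
#' @return data frame with columns `statistic`, `printed`, `derived`.
#' @export
stats_block_consistency <- function(name = c("eq1_stats", "eq2_stats")) {
  name <- match.arg(name)
  fx <- qsar_fixture(name)
  v <- stats::setNames(fx$value, fx$name)
  n <- v[["n"]]; p <- v[["p"]]
  rss <- (1 - v[["r2"]]) * v[["ssy"]]
  data.frame(
    statistic = c("sec", "f_value", "f_crit", "q2_loo", "sev"),
    printed = unname(v[c("sec", "f_value", "f_crit", "q2_loo", "sev")]),
    derived = c(sqrt(rss / (n - p - 1)),
                (v[["r2"]] / p) / ((1 - v[["r2"]]) / (n - p - 1)),
                stats::qf(0.95, p, n - p - 1),
                1 - v[["press"]] / v[["ssy"]],
                sqrt(v[["press"]] / n)))
}

#' Recompute the worked example's printed statistics from the packaged
#' tables
#'
#' Everything that is derivable from the packaged activity table, the
#' observed/predicted external-validation table and the printed
#' coefficient lists is recomputed by the package and compared with the
#' printed value: the pIC50 conversions, SSy of the full and training
#' activities, the external-validation battery (PRESS, SEP, R2pred, k,
#' k', |R2_0 - R'2_0|), the F critical values and the Wold significance
#' threshold.
#'
#' @param alternative_split use the alternative test-set listing
#'   \{B2, C4, C5, C9, A0\} that appears elsewhere in the source study's
#'   text instead of the observed/predicted table's ids; the two
#'   external-validation statistics then disagree with the printed
#'   values, exposing the internal inconsistency of the source listings.
#' @return data frame of class `"paper_reproduction"`: `target`,
#'   `computed`, `printed`, `tolerance`, `pass`.
#' @export
reproduce_paper <- function(alternative_split = FALSE) {
  act <- load_activity_table("table1")
  op <- load_observed_predicted("table2")
  eq1 <- stats::setNames(qsar_fixture("eq1_stats")$value,
                         qsar_fixture("eq1_stats")$name)
  test_ids <- if (alternative_split) c("B2", "C4", "C5", "C9", "A0")
              else op$id
  train <- act$pic50[!act$id %in% test_ids]
  ext <- external_metrics(op$observed, op$predicted, mean(train))
  std <- eq1[startsWith(names(eq1), "std_")]
  wold <- 0.5 * max(abs(std))
  conv_dev <- max(abs(act$pic50 - ic50_to_pic50(act$ic50_nM)))
  rows <- list(
    c("pic50_conversion_max_dev", conv_dev, 0, 5e-4),
    c("ssy_full", ssy(act$pic50), 9.491, 2e-3),
    c("ssy_training", ssy(train), 8.026, 2e-3),
    c("press_test", ext$press_test, 0.529, 2e-3),
    c("sep", ext$sep, 0.325, 2e-3),
    c("r2pred", ext$r2pred, 0.641, 2e-3),
    c("k", ext$k, 1.017, 2e-3),
    c("kprime", ext$kprime, 0.981, 2e-3),
    c("abs_diff_r2_0", ext$abs_diff, 0.004, 2e-3),
    c("f_crit_full", stats::qf(0.95, 3, 27), 2.960, 1e-3),
    c("f_crit_training", stats::qf(0.95, 3, 22), 3.049, 1e-3),
    c("wold_threshold", wold, 0.274, 1e-3))
  out <- data.frame(
    target = vapply(rows, `[[`, "", 1),
    computed = as.numeric(vapply(rows, `[[`, "", 2)),
    printed = as.numeric(vapply(rows, `[[`, "", 3)),
    tolerance = as.numeric(vapply(rows, `[[`, "", 4)))
  out$pass <- abs(out$computed - out$printed) <= out$tolerance
  class(out) <- c("paper_reproduction", "data.frame")
  attr(out, "alternative_split") <- alternative_split
  out
}

#' @export
print.paper_reproduction <- function(x, ...) {
  cat("Reproduction of the worked example's printed statistics",
      if (attr(x, "alternative_split")) "(alternative test-set listing)",
      "\n")
  df <- data.frame(target = x$target,
                   computed = signif(x$computed, 6),
                   printed = x$printed, tolerance = x$tolerance,
                   pass = ifelse(x$pass, "yes", "NO"))
  print.data.frame(df, row.names = FALSE)
  cat(sum(x$pass), "/", nrow(x), "targets within tolerance\n")
  invisible(x)
}
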