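#' Convert an IC50 to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar half-maximal
#' inhibitory concentration. For an IC50 given in nanomolar,
#' `pIC50 = 9 - log10(IC50[nM])`.
#'
#' @param ic50 positive numeric vector of IC50 values.
#' @param unit unit of `ic50`: `"nM"` (default), `"uM"` or `"M"`.
#' @return numeric vector of pIC50 values (unitless, -log10 molar).
#' @examples
#' ic50_to_pic50(11.2)   # 7.951
#' ic50_to_pic50(100)    # 7
#' @export
ic50_to_pic50 <- function(ic50, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  if (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 values must be finite and strictly positive", call. = FALSE)
  molar <- ic50 * switch(unit, nM = 1e-9, uM = 1e-6, M = 1)
  -log10(molar)
}

#' Molecular softness from frontier-orbital energies
#'
#' Softness is the reciprocal of the HOMO-LUMO gap, `1 / (E_LUMO - E_HOMO)`.
#' Softer molecules (small gap) are generally more reactive.
#'
#' @param e_lumo,e_homo orbital energies (same units; softness is in the
#'   reciprocal of those units).
#' @return numeric softness values.
#' @examples
#' softness_from_orbitals(0.15, -0.05)  # gap 0.2 -> 5
#' @export
softness_from_orbitals <- function(e_lumo, e_homo) {
  gap <- e_lumo - e_homo
  if (any(gap == 0)) stop("zero HOMO-LUMO gap", call. = FALSE)
  1 / gap
}

#' Packaged example data sets
#'
#' Returns one of the plain-CSV fixtures shipped with the package:
#' \describe{
#'   \item{`"table1"`}{activity table of the 31 cinnamoyl pyrrolidine
#'     MMP-2 inhibitors (id, substituents, IC50 in nM, pIC50).}
#'   \item{`"table2"`}{observed/predicted pIC50 of the 5 external test
#'     compounds of the worked example.}
#'   \item{`"eq1_stats"`}{printed statistics and coefficients of the
#'     full-data (n = 31) reference PLS model.}
#'   \item{`"eq2_stats"`}{the same for the training-set (n = 26) model.}
#' }
#'
#' @param name fixture name.
#' @return a data frame.
#' @export
qsar_fixture <- function(name = c("table1", "table2", "eq1_stats", "eq2_stats")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "opsqsar",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a compound activity table
#'
#' Expects a CSV with a header and columns `id` plus `ic50_nM` and/or
#' `pic50`; when `pic50` is absent it is filled from `ic50_nM`. When both
#' are present they are cross-checked (|pic50 - (9 - log10 ic50)| <= 5e-4).
#'
#' @param path a CSV file path, or a fixture name accepted by
#'   [qsar_fixture()] (e.g. `"table1"`).
#' @param unit IC50 unit, see [ic50_to_pic50()].
#' @return a data frame of class `"activity_table"` with at least columns
#'   `id` and `pic50`.
#' @export
load_activity_table <- function(path, unit = "nM") {
  tab <- if (is.character(path) && length(path) == 1 && !file.exists(path) &&
             path %in% c("table1")) qsar_fixture(path)
         else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(tab)) stop("activity table needs an 'id' column", call. = FALSE)
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id))
    stop("duplicate compound ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "), call. = FALSE)
  has_ic <- "ic50_nM" %in% names(tab)
  has_p  <- "pic50"   %in% names(tab)
  if (!has_ic && !has_p)
    stop("activity table needs an 'ic50_nM' and/or a 'pic50' column", call. = FALSE)
  if (has_ic) {
    tab$ic50_nM <- as.numeric(tab$ic50_nM)
    if (any(!is.finite(tab$ic50_nM)) || any(tab$ic50_nM <= 0))
      stop("IC50 values must be finite and positive", call. = FALSE)
  }
  if (!has_p) {
    tab$pic50 <- ic50_to_pic50(tab$ic50_nM, unit = unit)
  } else {
    tab$pic50 <- as.numeric(tab$pic50)
    if (any(!is.finite(tab$pic50))) stop("unparsable pic50 values", call. = FALSE)
    if (has_ic) {
      dev <- abs(tab$pic50 - ic50_to_pic50(tab$ic50_nM, unit = unit))
      if (any(dev > 5e-4 + 1e-12))
        stop("pic50 inconsistent with ic50_nM for: ",
             paste(tab$id[dev > 5e-4 + 1e-12], collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(tab) == 0) stop("empty activity table", call. = FALSE)
  class(tab) <- c("activity_table", "data.frame")
  tab
}

#' Read an observed/predicted activity table
#'
#' @param path a CSV file path with columns `id`, `observed`, `predicted`,
#'   or the fixture name `"table2"`.
#' @return a data frame with an added `residual = observed - predicted`
#'   column.
#' @export
load_observed_predicted <- function(path) {
  tab <- if (is.character(path) && length(path) == 1 && !file.exists(path) &&
             path %in% c("table2")) qsar_fixture(path)
         else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "observed", "predicted")
  if (!all(need %in% names(tab)))
    stop("need columns: ", paste(need, collapse = ", "), call. = FALSE)
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) stop("duplicate ids", call. = FALSE)
  tab$observed  <- as.numeric(tab$observed)
  tab$predicted <- as.numeric(tab$predicted)
  if (any(!is.finite(tab$observed)) || any(!is.finite(tab$predicted)))
    stop("unparsable observed/predicted values", call. = FALSE)
  tab$residual <- tab$observed - tab$predicted
  tab
}

#' Read a descriptor matrix from CSV
#'
#' First column must be the compound id; all remaining columns are numeric
#' descriptors.
#'
#' @param path CSV file path.
#' @return numeric matrix with compound ids as row names.
#' @export
load_descriptor_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate compound ids", call. = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyDuplicated(colnames(X))) stop("duplicate descriptor names", call. = FALSE)
  rownames(X) <- ids
  X
}

#' Write a descriptor matrix to CSV
#'
#' @param X numeric matrix with row names (compound ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(X, path) {
  df <- data.frame(id = rownames(X) %||% seq_len(nrow(X)), X,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
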