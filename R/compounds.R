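#' Convert an IC50 in micromolar to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar half-maximal
#' inhibitory concentration. For an IC50 given in uM this is
#' `6 - log10(ic50)`, the only unit convention consistent with the
#' packaged compound table (e.g. 0.0920 uM -> 7.0362).
#'
#' @param ic50 numeric vector of IC50 values in uM; must be positive.
#' @return numeric vector of pIC50 values (unitless).
#' @export
#' @examples
#' pic50_from_ic50(1)       # 6
#' pic50_from_ic50(0.0920)  # 7.036
pic50_from_ic50 <- function(ic50) {
  if (!is.numeric(ic50) || length(ic50) == 0) {
    stop("ic50 must be a non-empty numeric vector")
  }
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 values must be positive and finite (concentration in uM)")
  }
  -log10(ic50 * 1e-6)
}

#' Load the packaged dihydropyrimidine inhibitor table
#'
#' Returns the 46 2-substituted 6-oxo-1,6-dihydropyrimidine-5-carboxylic
#' acid (ODC) xanthine-oxidase inhibitors plus the febuxostat reference:
#' substituent labels, IC50 (uM), actual and model-predicted pIC50,
#' training/test split membership and the pharmacophore-modelling flag.
#'
#' @param path optional path to an alternative CSV with the same columns.
#' @return data.frame with one row per compound, ordered by `compound_id`,
#'   columns `compound_id`, `r1`, `r2`, `r3`, `ic50_um`, `pic50`,
#'   `pred_comfa`, `pred_comsia`, `split` (train/test/reference),
#'   `pharmacophore_set` (logical), `smiles`.
#' @export
load_compounds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "odc_compounds.csv", package = "xoiqsar")
  }
  if (!nzchar(path) || !file.exists(path)) stop("compound fixture not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(compound_id = "character"))
  required <- c("compound_id", "ic50_um", "pic50", "split", "pharmacophore_set")
  missing <- setdiff(required, names(d))
  if (length(missing)) stop("compound fixture missing columns: ",
                            paste(missing, collapse = ", "))
  bad <- which(!is.finite(d$ic50_um) | d$ic50_um <= 0)
  if (length(bad)) stop("non-positive IC50 in fixture row(s): ",
                        paste(d$compound_id[bad], collapse = ", "))
  if (anyDuplicated(d$compound_id)) stop("duplicate compound_id in fixture")
  if (!all(d$split %in% c("train", "test", "reference"))) {
    stop("invalid split label in fixture")
  }
  incons <- which(abs(pic50_from_ic50(d$ic50_um) - d$pic50) > 5e-4)
  if (length(incons)) stop("IC50/pIC50 inconsistency in fixture row(s): ",
                           paste(d$compound_id[incons], collapse = ", "))
  d[order(d$compound_id), , drop = FALSE]
}

#' Build an actual-vs-predicted activity table
#'
#' @param id character vector of compound identifiers.
#' @param actual numeric actual pIC50 values.
#' @param predicted numeric predicted pIC50 values.
#' @param role "train" or "test".
#' @return data.frame of class `activity_table` with columns
#'   `id`, `actual`, `predicted` and attribute `role`.
#' @export
activity_table <- function(id, actual, predicted, role = c("test", "train")) {
  role <- match.arg(role)
  if (length(id) != length(actual) || length(id) != length(predicted)) {
    stop("id, actual and predicted must have equal length")
  }
  if (anyDuplicated(id)) stop("duplicate compound id in activity table")
  if (length(id) < 3) stop("an activity table needs at least 3 rows")
  if (!is.numeric(actual) || !is.numeric(predicted) ||
      any(!is.finite(actual)) || any(!is.finite(predicted))) {
    stop("actual and predicted must be finite numerics")
  }
  out <- data.frame(id = as.character(id), actual = as.numeric(actual),
                    predicted = as.numeric(predicted), stringsAsFactors = FALSE)
  attr(out, "role") <- role
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Extract an activity table for one model and split from the compound table
#'
#' @param compounds data.frame from [load_compounds()].
#' @param model "comfa" or "comsia" (which predicted column to use).
#' @param split "train" or "test".
#' @return an [activity_table()].
#' @export
compound_activity <- function(compounds, model = c("comfa", "comsia"),
                              split = c("test", "train")) {
  model <- match.arg(model)
  split <- match.arg(split)
  col <- paste0("pred_", model)
  rows <- compounds[compounds$split == split & is.finite(compounds[[col]]), ]
  activity_table(rows$compound_id, rows$pic50, rows[[col]], role = split)
}

#' Read / write activity tables as CSV
#'
#' The on-disk format is a UTF-8 CSV with header columns `id`, `actual`,
#' `predicted`. A write followed by a read is the identity on values to
#' well below 1e-9.
#'
#' @param path file path.
#' @param role "train" or "test" (read only).
#' @return [read_activity_table()] returns an [activity_table()];
#'   `write_activity_table` returns `path` invisibly.
#' @export
read_activity_table <- function(path, role = c("test", "train")) {
  role <- match.arg(role)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  missing <- setdiff(c("id", "actual", "predicted"), names(d))
  if (length(missing)) stop("activity CSV missing columns: ",
                            paste(missing, collapse = ", "))
  if (!is.numeric(d$actual) || !is.numeric(d$predicted)) {
    stop("activity CSV has non-numeric actual/predicted cells")
  }
  activity_table(d$id, d$actual, d$predicted, role = role)
}

#' @rdname read_activity_table
#' @param table an [activity_table()].
#' @export
write_activity_table <- function(table, path) {
  stopifnot(inherits(table, "activity_table"))
  utils::write.csv(table[, c("id", "actual", "predicted")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
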