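#' Root-mean-squared error of a test-set activity table
#'
#' @param test an [activity_table()] (or data.frame with `actual`,
#'   `predicted`).
#' @return sqrt of the mean squared (actual - predicted).
#' @export
rmse <- function(test) {
  sqrt(mean((test$actual - test$predicted)^2))
}

#' Predictive correlation coefficient r_pred^2
#'
#' `1 - sum((pred - actual)^2) / sum((actual - training_mean)^2)` over the
#' test rows: the fraction of test-set variance about the training-set
#' mean explained by the predictions.
#'
#' @param test an [activity_table()].
#' @param training_mean mean actual activity of the training compounds.
#' @return r_pred^2 (can be negative).
#' @export
r_pred_sq <- function(test, training_mean) {
  stopifnot(is.finite(training_mean))
  1 - sum((test$predicted - test$actual)^2) /
    sum((test$actual - training_mean)^2)
}

#' Through-origin regression statistics of predicted vs actual activities
#'
#' Computes both orientations of the zero-intercept regression between
#' actual (y) and predicted (yhat) activities:
#' \describe{
#'   \item{k}{slope of the through-origin fit of actual on predicted,
#'     `sum(y*yhat)/sum(yhat^2)`; its determination coefficient is
#'     `r0_sq = 1 - sum((y - k*yhat)^2) / sum((y - mean(y))^2)`.}
#'   \item{k_prime}{slope of the through-origin fit of predicted on
#'     actual, `sum(y*yhat)/sum(y^2)`, with
#'     `r0p_sq = 1 - sum((yhat - k'*y)^2) / sum((yhat - mean(yhat))^2)`.}
#' }
#' This orientation pairing is the one that reproduces the printed
#' external-validation table of the study the packaged compound set comes
#' from; the opposite labeling convention also circulates, so the concrete
#' formulas above are the contract.
#'
#' @param test an [activity_table()].
#' @return list with `r0_sq`, `r0p_sq`, `k`, `k_prime`.
#' @export
through_origin_stats <- function(test) {
  y <- test$actual; yh <- test$predicted
  k <- sum(y * yh) / sum(yh^2)
  k_prime <- sum(y * yh) / sum(y^2)
  r0_sq <- 1 - sum((y - k * yh)^2) / sum((y - mean(y))^2)
  r0p_sq <- 1 - sum((yh - k_prime * y)^2) / sum((yh - mean(yh))^2)
  list(r0_sq = r0_sq, r0p_sq = r0p_sq, k = k, k_prime = k_prime)
}

#' The rm2 metric family
#'
#' `rm2 = r2 * (1 - sqrt(r2 - r0_sq))` for each through-origin orientation,
#' plus their absolute difference and mean. A negative radicand (r0
#' exceeding r2, a degenerate configuration the formula is undefined for)
#' is clamped to 0 with a warning.
#'
#' @param r2 squared Pearson correlation of predicted vs actual.
#' @param r0_sq,r0p_sq through-origin determination coefficients, the two
#'   orientations (see [through_origin_stats()]).
#' @return list with `rm_sq`, `rmp_sq`, `delta_rm_sq`, `mean_rm_sq`.
#' @export
rm_sq_pair <- function(r2, r0_sq, r0p_sq) {
  one <- function(r0) {
    rad <- r2 - r0
    if (rad < 0) {
      warning("r0^2 exceeds r2; radicand clamped to 0")
      rad <- 0
    }
    r2 * (1 - sqrt(rad))
  }
  rm_sq <- one(r0_sq); rmp_sq <- one(r0p_sq)
  list(rm_sq = rm_sq, rmp_sq = rmp_sq,
       delta_rm_sq = abs(rm_sq - rmp_sq),
       mean_rm_sq = (rm_sq + rmp_sq) / 2)
}

#' Full external-validation report for a test-set activity table
#'
#' Bundles RMSE, the squared Pearson correlation r2, both through-origin
#' regressions, the rm2 family, r_pred^2 and the pass/fail threshold
#' battery into one report.
#'
#' @param test an [activity_table()].
#' @param training_mean mean actual activity of the training set (needed
#'   for r_pred^2; NA omits it).
#' @param q2 optional internal cross-validated q2 of the underlying model,
#'   included in the threshold battery when given.
#' @param r2_fit optional non-cross-validated model R^2 for the battery.
#' @return object of class `validation_report` (a list of the statistics
#'   plus `checks`, see [threshold_battery()]).
#' @export
validation_report <- function(test, training_mean = NA_real_,
                              q2 = NA_real_, r2_fit = NA_real_) {
  r2 <- stats::cor(test$actual, test$predicted)^2
  to <- through_origin_stats(test)
  rm2 <- rm_sq_pair(r2, to$r0_sq, to$r0p_sq)
  rep <- c(list(n = nrow(test), rmse = rmse(test), r2 = r2), to, rm2,
           list(r_pred_sq = if (is.finite(training_mean))
                  r_pred_sq(test, training_mean) else NA_real_,
                q2 = q2, r2_fit = r2_fit))
  rep$checks <- threshold_battery(rep)
  class(rep) <- "validation_report"
  rep
}

#' Acceptability threshold battery for a QSAR model
#'
#' Evaluates the standard external-validation criteria:
#' q2 > 0.5; model R^2 > 0.8; (r2 - r0^2)/r2 < 0.1 for at least one
#' through-origin orientation; 0.85 <= k (or k') <= 1.15;
#' delta rm2 < 0.2; mean rm2 > 0.5; r_pred^2 > 0.6.
#' Criteria whose inputs are absent come back NA.
#'
#' @param report a [validation_report()] or compatible named list.
#' @return named logical vector.
#' @export
threshold_battery <- function(report) {
  r <- report
  rel <- function(r0) (r$r2 - r0) / r$r2
  c(q2_gt_0.5 = if (is.finite(r$q2 %||% NA_real_)) r$q2 > 0.5 else NA,
    r2_fit_gt_0.8 = if (is.finite(r$r2_fit %||% NA_real_)) r$r2_fit > 0.8 else NA,
    r0_ratio_lt_0.1 = min(rel(r$r0_sq), rel(r$r0p_sq)) < 0.1,
    k_in_0.85_1.15 = (r$k >= 0.85 && r$k <= 1.15) ||
      (r$k_prime >= 0.85 && r$k_prime <= 1.15),
    delta_rm_sq_lt_0.2 = r$delta_rm_sq < 0.2,
    mean_rm_sq_gt_0.5 = r$mean_rm_sq > 0.5,
    r_pred_sq_gt_0.6 = if (is.finite(r$r_pred_sq %||% NA_real_))
      r$r_pred_sq > 0.6 else NA)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report (n = %d): RMSE = %.3f, r2 = %.3f, ",
                     "r0^2 = %.3f, r0'^2 = %.3f, k = %.3f, k' = %.3f,\n",
                     "  rm2 = %.3f, rm2' = %.3f, delta = %.3f, mean = %.3f, ",
                     "r_pred^2 = %.3f>\n"),
              x$n, x$rmse, x$r2, x$r0_sq, x$r0p_sq, x$k, x$k_prime,
              x$rm_sq, x$rmp_sq, x$delta_rm_sq, x$mean_rm_sq, x$r_pred_sq))
  passes <- x$checks[!is.na(x$checks)]
  cat("  checks:", paste(names(passes), ifelse(passes, "pass", "FAIL"),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report a `validation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  out <- unclass(report)
  out$checks <- as.list(out$checks)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
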