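#' Fit a partial least-squares (PLS1) regression by NIPALS
#'
#' Classical chemometrics NIPALS with deflation on mean-centered data
#' (no column autoscaling, the molecular-field convention). The weight
#' direction starts from the X'y covariance, which makes the single-y fit
#' deterministic; deflation stops early when the residual covariance
#' collapses (rank-deficient input) and the number of components actually
#' extracted is reported in the model.
#'
#' @param X numeric descriptor matrix (n x p), rows = compounds.
#' @param y numeric response vector (activity, pIC50).
#' @param ncomp number of latent components requested.
#' @param tol deflation stop: components are no longer extracted once
#'   `||X'y||` falls below `tol` relative to its initial value.
#' @return object of class `pls_model`: latent arrays (`weights`,
#'   `loadings`, `scores`, `y_loadings`), `coefficients` on the original
#'   columns, `x_mean`, `x_sd`, `y_mean`, training `fitted`, `r2`,
#'   `see` (standard error of estimate, denominator n - c - 1),
#'   `f_stat`, `ncomp` (requested) and `ncomp_used`.
#' @export
fit_pls <- function(X, y, ncomp, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n < 4) stop("PLS fit needs at least 4 rows")
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop("ncomp must be in 1..min(rows-1, columns)")
  }
  x_mean <- colMeans(X); y_mean <- mean(y)
  x_sd <- apply(X, 2, stats::sd)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  norm0 <- sqrt(sum(crossprod(Xc, yc)^2))
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw <= tol * max(norm0, 1)) break
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt <= tol) break
    pvec <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pvec)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
    used <- a
  }
  if (used == 0L) stop("degenerate input: no PLS component could be extracted")
  W <- W[, seq_len(used), drop = FALSE]; P <- P[, seq_len(used), drop = FALSE]
  Tm <- Tm[, seq_len(used), drop = FALSE]; q <- q[seq_len(used)]
  # regression coefficients on original (centered) X
  B <- W %*% solve(crossprod(P, W), q)
  fitted <- as.vector(sweep(X, 2, x_mean) %*% B) + y_mean
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - y_mean)^2)
  r2 <- 1 - ss_res / ss_tot
  c_used <- used
  see <- sqrt(ss_res / max(n - c_used - 1, 1))
  f_stat <- (r2 / c_used) / ((1 - r2) / max(n - c_used - 1, 1))
  structure(list(ncomp = ncomp, ncomp_used = used, x_mean = x_mean,
                 x_sd = x_sd, y_mean = y_mean, weights = W, loadings = P,
                 scores = Tm, y_loadings = q, coefficients = as.vector(B),
                 fitted = fitted, r2 = r2, see = see, f_stat = f_stat,
                 n = n),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d/%d components, r2 = %.4f, SEE = %.4f, F = %.2f>\n",
              x$ncomp_used, x$ncomp, x$r2, x$see, x$f_stat))
  invisible(x)
}

#' Predict activities from a fitted PLS model
#' @param object a `pls_model`.
#' @param newdata matrix with the same columns as the training X.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.vector(sweep(newdata, 2, object$x_mean) %*% object$coefficients) +
    object$y_mean
}

#' Leave-one-out cross-validated q2
#'
#' `q2 = 1 - PRESS / SS_total` where PRESS accumulates the squared error
#' of n refits each predicting its single left-out row, and SS_total is
#' taken about the full training-set mean. Rows are left out in order, so
#' the result is deterministic.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param ncomp latent components per refit.
#' @return q2 (can be negative for models worse than the mean).
#' @export
loo_q2 <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 5) stop("leave-one-out q2 needs at least 5 rows")
  press <- 0
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i],
                   min(ncomp, min(n - 2, ncol(X))))
    press <- press + (predict(fit, X[i, , drop = FALSE]) - y[i])^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Choose the optimal number of latent components (parsimony rule)
#'
#' Scans 1..max_components, computing the leave-one-out q2 for each count,
#' and returns the smallest count whose q2 is within 5 percent (relative)
#' of the maximum; exact ties already favor the smaller count.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param max_components scan bound.
#' @param window relative parsimony window (default 0.05).
#' @return integer component count with attribute `q2_scan`.
#' @export
select_onc <- function(X, y, max_components, window = 0.05) {
  max_components <- min(max_components, nrow(X) - 2, ncol(X))
  stopifnot(max_components >= 1)
  q2s <- vapply(seq_len(max_components), function(c) loo_q2(X, y, c),
                numeric(1))
  best <- max(q2s)
  onc <- which(q2s >= best - window * abs(best))[1]
  structure(as.integer(onc), q2_scan = q2s)
}

#' Per-field-type contribution fractions of a fitted model
#'
#' The contribution of field f is the sum over its columns of
#' `|coefficient * column stdev|`, normalized over all columns, i.e. the
#' share of explained descriptor-weighted variance mass (the quantity the
#' contour convention StDev*Coeff is built from).
#'
#' @param model a `pls_model`.
#' @param column_meta data.frame with a `field` column, one row per
#'   descriptor column (e.g. from a `field_matrix`).
#' @return named numeric vector of fractions summing to 1.
#' @export
field_contributions <- function(model, column_meta) {
  stopifnot(nrow(column_meta) == length(model$coefficients))
  mass <- abs(model$coefficients * model$x_sd)
  tot <- sum(mass)
  if (tot == 0) stop("all coefficients are zero; contributions undefined")
  fr <- vapply(split(mass, column_meta$field), sum, numeric(1)) / tot
  fr[unique(column_meta$field)]
}

#' StDev*Coeff contour point summary
#'
#' For each field type, grid points whose StDev*Coeff value is at or above
#' the favored percentile, or at or below the disfavored percentile, of
#' that field's value distribution.
#'
#' @param model a `pls_model`.
#' @param column_meta per-column `grid_index` and `field`.
#' @param favored_pct,disfavored_pct percentile thresholds (default 80/20).
#' @return data.frame with `field`, `grid_index`, `value`,
#'   `contour` ("favored"/"disfavored").
#' @export
stdev_coeff_contours <- function(model, column_meta, favored_pct = 80,
                                 disfavored_pct = 20) {
  stopifnot(nrow(column_meta) == length(model$coefficients))
  v <- model$coefficients * model$x_sd
  out <- lapply(split(seq_along(v), column_meta$field), function(idx) {
    vi <- v[idx]
    hi <- stats::quantile(vi, favored_pct / 100, names = FALSE)
    lo <- stats::quantile(vi, disfavored_pct / 100, names = FALSE)
    sel_hi <- idx[vi >= hi]; sel_lo <- idx[vi <= lo]
    data.frame(field = column_meta$field[c(sel_hi, sel_lo)],
               grid_index = column_meta$grid_index[c(sel_hi, sel_lo)],
               value = v[c(sel_hi, sel_lo)],
               contour = rep(c("favored", "disfavored"),
                             c(length(sel_hi), length(sel_lo))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
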