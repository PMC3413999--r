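# Regression estimators for the 1-D random-walk models, and the nested
# F-test between them.
#
# Model conventions (x = distance from wound, um; t = minutes):
#   drift (mean distance):      m(t) = intercept + v * t
#   pure diffusion (MSD):       s(t) = intercept + 2 D * t
#   drift-diffusion (MSD):      s(t) = b0 + b1 * t + b2 * t^2,
#                               D = b1 / 2,  |v| = sqrt(max(b2, 0))
# All fits are unweighted OLS on the per-timepoint population moments; the
# sign of v is taken from the trend of the mean distance because the
# quadratic coefficient b2 = v^2 is sign-blind.  D is deliberately NOT
# constrained to be non-negative: an unconstrained fit can and does return
# negative diffusion estimates on real data, which is itself diagnostic.

as_summary_rows <- function(ps, need, min_rows) {
  ww_assert(is.data.frame(ps) && all(need %in% names(ps)),
            sprintf("expected a population_summary with columns %s",
                    paste(need, collapse = ", ")),
            "woundwalk_format_error")
  ps <- as.data.frame(ps)[order(ps$time_min), , drop = FALSE]
  if (nrow(ps) < min_rows) {
    ww_abort(sprintf("need at least %d timepoints, got %d",
                     min_rows, nrow(ps)))
  }
  if (var(ps$time_min) == 0) ww_abort("all observation times are identical")
  ps
}

# Classical OLS standard errors from the fit's QR decomposition.  Avoids
# summary.lm(), which warns on the noiseless (zero-residual) fixtures the
# suite uses for exact-recovery checks.
ols_se <- function(fit) {
  p <- fit$rank
  Rm <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  XtXinv <- chol2inv(Rm)
  piv <- fit$qr$pivot[seq_len(p)]
  sigma2 <- deviance(fit) / stats::df.residual(fit)
  se <- rep(NA_real_, length(coef(fit)))
  se[piv] <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- names(coef(fit))
  se
}

#' Estimate the drift coefficient from the mean-distance curve
#'
#' Ordinary least squares of mean distance on time,
#' `m(t) = intercept + v t`.  Motion toward the wound gives `v < 0`,
#' motion away `v > 0`.
#'
#' @param ps a [population_summary()] with at least 3 rows.
#' @return A `drift_fit`: list with `v` (um/min), `v_se`, `intercept` (um),
#'   `rss`, `n`.
#' @export
fit_drift_linear <- function(ps) {
  ps <- as_summary_rows(ps, c("time_min", "mean_dist"), 3L)
  fit <- stats::lm(mean_dist ~ time_min, data = ps)
  se <- ols_se(fit)
  structure(list(v = unname(coef(fit)[["time_min"]]),
                 v_se = unname(se[["time_min"]]),
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 rss = deviance(fit),
                 n = nrow(ps)),
            class = "drift_fit")
}

#' Fit the pure-diffusion (zero-drift) model to the MSD curve
#'
#' OLS of mean squared distance on time, `s(t) = intercept + slope * t`;
#' for a 1-D coordinate the MSD slope is `2 D`, so `D = slope / 2` and
#' `D_se = se(slope) / 2`.  The slope is unconstrained, so `D` may come out
#' negative on noisy data.
#'
#' @param ps a [population_summary()] with at least 3 rows.
#' @return A `pure_diffusion_fit`: list with `D` (um^2/min), `D_se`,
#'   `intercept` (um^2), `rss`, `n`.
#' @export
fit_pure_diffusion <- function(ps) {
  ps <- as_summary_rows(ps, c("time_min", "mean_sq_dist"), 3L)
  fit <- stats::lm(mean_sq_dist ~ time_min, data = ps)
  se <- ols_se(fit)
  structure(list(D = unname(coef(fit)[["time_min"]]) / 2,
                 D_se = unname(se[["time_min"]]) / 2,
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 rss = deviance(fit),
                 n = nrow(ps)),
            class = "pure_diffusion_fit")
}

#' Fit the drift-diffusion model to the MSD curve
#'
#' OLS of mean squared distance on `{1, t, t^2}`.  The quadratic
#' coefficient carries the squared drift (`b2 = v^2`), so
#' `|v| = sqrt(max(b2, 0))` and the sign of `v` is taken from the slope of
#' the mean-distance curve; `D = b1 / 2` as in [fit_pure_diffusion()].
#' `v_se` is the delta-method standard error `se(b2) / (2 sqrt(b2))`
#' (NA when `b2 <= 0`).
#'
#' Note the structural caveat documented in the package vignette: for a
#' population with initial mean distance `m0`, the true linear MSD
#' coefficient is `2 D + 2 v m0`, so `D = b1 / 2` is confounded with
#' `v * m0` whenever the cohort does not start at the wound.
#'
#' @param ps a [population_summary()] with at least 4 rows (columns
#'   `time_min`, `mean_dist`, `mean_sq_dist`).
#' @return A `drift_diffusion_fit`: list with `v`, `v_se`, `D`, `D_se`,
#'   `intercept`, `rss`, `n`.
#' @export
fit_drift_diffusion <- function(ps) {
  ps <- as_summary_rows(ps, c("time_min", "mean_dist", "mean_sq_dist"), 4L)
  fit <- stats::lm(mean_sq_dist ~ time_min + I(time_min^2), data = ps)
  if (fit$rank < 3L) ww_abort("collinear design: cannot fit quadratic model")
  b <- coef(fit)
  se <- ols_se(fit)
  b2 <- unname(b[["I(time_min^2)"]])
  trend <- sign(unname(coef(stats::lm(mean_dist ~ time_min,
                                      data = ps))[["time_min"]]))
  v <- trend * sqrt(max(b2, 0))
  v_se <- if (b2 > 0) unname(se[["I(time_min^2)"]]) / (2 * sqrt(b2)) else NA_real_
  structure(list(v = v, v_se = v_se,
                 D = unname(b[["time_min"]]) / 2,
                 D_se = unname(se[["time_min"]]) / 2,
                 intercept = unname(b[["(Intercept)"]]),
                 rss = deviance(fit),
                 n = nrow(ps)),
            class = "drift_diffusion_fit")
}

#' Nested F-test: does the drift term earn its keep?
#'
#' Compares the pure-diffusion (linear, 2 parameters) and drift-diffusion
#' (quadratic, 3 parameters) MSD fits on the same summary:
#' `F = (rss_pure - rss_dd) / (rss_dd / (n - 3))`, with 1 and `n - 3`
#' degrees of freedom.  The conventional decision rule prefers the
#' drift-diffusion model when `F` exceeds the threshold (default 5).
#'
#' The reference F distribution assumes independent homoscedastic errors
#' across timepoints; population moments of persistent tracks violate this
#' (see the vignette), so treat `prefer_drift` as a screening rule, not a
#' calibrated test.
#'
#' @param pure a [fit_pure_diffusion()] result.
#' @param dd a [fit_drift_diffusion()] result computed on the same summary.
#' @param threshold decision threshold on F (default 5).
#' @return An `f_test_result`: list with `F`, `df1 = 1`, `df2 = n - 3`,
#'   `p_value` (nominal), `prefer_drift`.
#' @export
f_test <- function(pure, dd, threshold = 5) {
  ww_assert(inherits(pure, "pure_diffusion_fit"),
            "pure must come from fit_pure_diffusion()")
  ww_assert(inherits(dd, "drift_diffusion_fit"),
            "dd must come from fit_drift_diffusion()")
  ww_assert(threshold > 0, "threshold must be > 0")
  if (pure$n != dd$n) {
    ww_abort(sprintf("fits disagree on n (%d vs %d): not the same summary",
                     pure$n, dd$n))
  }
  n <- dd$n
  if (n <= 3L) ww_abort("F-test needs n > 3 timepoints")
  num <- pure$rss - dd$rss
  Fstat <- if (dd$rss > 0) num / (dd$rss / (n - 3)) else if (num > 0) Inf else 0
  structure(list(F = Fstat, df1 = 1L, df2 = n - 3L,
                 p_value = stats::pf(Fstat, 1, n - 3, lower.tail = FALSE),
                 prefer_drift = Fstat > threshold,
                 threshold = threshold),
            class = "f_test_result")
}

#' Pool distance series from several subjects
#'
#' Concatenates the per-cell distance series of several subjects into one,
#' namespacing cell ids by subject so that per-timepoint moments are taken
#' over the pooled cell population (the "all data" rows of a fit report).
#' Observation times of every series must land within `tolerance` minutes
#' of the first series' time grid; matching times are snapped to that grid.
#'
#' @param series a list of `distance_series` (names, if any, become the
#'   subject prefixes; otherwise `s1`, `s2`, ...).
#' @param tolerance maximum time mismatch when aligning grids, minutes.
#' @return A pooled `distance_series`.
#' @export
pool_subjects <- function(series, tolerance = 0.5) {
  ww_assert(is.list(series) && length(series) >= 1,
            "series must be a non-empty list of distance_series")
  series <- lapply(series, as_distance_series)
  prefixes <- names(series)
  if (is.null(prefixes) || any(!nzchar(prefixes))) {
    prefixes <- sprintf("s%d", seq_along(series))
  }
  ref <- sort(unique(series[[1L]]$time_min))
  pooled <- lapply(seq_along(series), function(i) {
    ds <- as.data.frame(series[[i]])
    idx <- findInterval(ds$time_min, ref, all.inside = FALSE)
    # nearest reference time (findInterval gives the left neighbour)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(ref))
    nearest <- ifelse(abs(ds$time_min - ref[lo]) <= abs(ds$time_min - ref[hi]),
                      lo, hi)
    off <- abs(ds$time_min - ref[nearest])
    if (any(off > tolerance)) {
      ww_abort(sprintf(
        "subject %s: time %g min is %.3g min from the reference grid (tolerance %g)",
        prefixes[[i]], ds$time_min[which.max(off)], max(off), tolerance))
    }
    ds$time_min <- ref[nearest]
    ds$cell_id <- paste(prefixes[[i]], ds$cell_id, sep = ".")
    ds
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  as_distance_series(out)
}

# Printing -------------------------------------------------------------------

fmt_est <- function(x, se) {
  if (is.na(se)) sprintf("%.4g (se NA)", x) else sprintf("%.4g (%.3g)", x, se)
}

#' @export
print.drift_fit <- function(x, ...) {
  cat("Drift model  m(t) = intercept + v t\n")
  cat(sprintf("  v  = %s um/min\n", fmt_est(x$v, x$v_se)))
  cat(sprintf("  intercept = %.4g um, rss = %.4g, n = %d\n",
              x$intercept, x$rss, x$n))
  invisible(x)
}

#' @export
print.pure_diffusion_fit <- function(x, ...) {
  cat("Pure-diffusion model  s(t) = intercept + 2 D t\n")
  cat(sprintf("  D  = %s um^2/min\n", fmt_est(x$D, x$D_se)))
  cat(sprintf("  intercept = %.4g um^2, rss = %.4g, n = %d\n",
              x$intercept, x$rss, x$n))
  invisible(x)
}

#' @export
print.drift_diffusion_fit <- function(x, ...) {
  cat("Drift-diffusion model  s(t) = b0 + (2D) t + v^2 t^2\n")
  cat(sprintf("  v  = %s um/min\n", fmt_est(x$v, x$v_se)))
  cat(sprintf("  D  = %s um^2/min\n", fmt_est(x$D, x$D_se)))
  cat(sprintf("  intercept = %.4g um^2, rss = %.4g, n = %d\n",
              x$intercept, x$rss, x$n))
  invisible(x)
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("Nested F-test: F(%d, %d) = %.4g (nominal p = %.3g)\n",
              x$df1, x$df2, x$F, x$p_value))
  cat(sprintf("  prefer drift-diffusion (F > %g): %s\n",
              x$threshold, x$prefer_drift))
  invisible(x)
}
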