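#' Single-cosinor fit with fixed period
#'
#' Fits the linearized single-component cosinor model
#' \deqn{y = M + \beta \cos(\omega t) + \gamma \sin(\omega t), \quad
#'       \omega = 2\pi/\mathrm{period}}
#' by ordinary least squares and reports the rhythm parameters in their
#' conventional form: mesor \eqn{M} (rhythm-adjusted mean), amplitude
#' \eqn{A = \sqrt{\beta^2+\gamma^2}} (half the peak-trough difference)
#' and acrophase \eqn{\phi} (time of the fitted maximum in hours after
#' lights-on, so the fitted curve is \eqn{M + A\cos(\omega(t-\phi))}).
#'
#' Rhythmicity is assessed by the zero-amplitude test: the F statistic
#' comparing the full model against the intercept-only model,
#' \deqn{F = \frac{(RSS_0 - RSS_1)/2}{RSS_1/(n-3)}}
#' with p from the upper tail of \eqn{F(2, n-3)}. 95% confidence limits
#' for the mesor come from the OLS coefficient covariance; limits for
#' amplitude and acrophase use the delta method.
#'
#' Unequal numbers of replicates per time point are handled naturally by
#' OLS; observations are never averaged within a time point first.
#'
#' @param times numeric vector of sampling times in hours (Zeitgeber
#'   time). Values beyond one period are allowed; the fit depends on
#'   them only modulo the period.
#' @param values numeric vector of expression values (relative units),
#'   same length as `times`.
#' @param period fixed rhythm period in hours. Default 24; every
#'   pipeline caller uses 24.
#' @return an object of class `cosinor_fit`: a list with elements
#'   `mesor`, `amplitude`, `rel_amplitude`, `acrophase` (hours in
#'   `[0, period)`), `beta`, `gamma`, `n`, `rss_full`, `rss_reduced`,
#'   `f_statistic`, `p_value`, `ci_mesor`, `ci_amplitude`,
#'   `ci_acrophase` (95% limits), `se_acrophase`, `degenerate` (logical:
#'   residual variance at machine tolerance, p forced to 0 or 1) and
#'   `period`.
#' @examples
#' t <- rep(c(10, 14, 18, 22, 26, 30), c(4, 4, 4, 4, 4, 5))
#' y <- 2 + 1 * cos(2 * pi * (t - 16) / 24)
#' fit_cosinor(t, y)
#' @seealso [acrophase_display()] for the sampling-window reporting
#'   convention, [screen_rhythms()] for matrix-wide application.
#' @export
fit_cosinor <- function(times, values, period = 24) {
  if (length(times) != length(values))
    format_error("times (%d) and values (%d) differ in length",
                 length(times), length(values))
  n <- length(values)
  if (n < 4) format_error("cosinor fit needs at least 4 observations, got %d", n)
  if (!all(is.finite(times)) || !all(is.finite(values)))
    format_error("cosinor fit requires finite times and values")
  phases <- sort(unique(round(times %% period, 9)))
  if (length(phases) < 3)
    format_error("design is rank-deficient: only %d distinct phase(s) modulo %g h (need >= 3)",
                 length(phases), period)

  w <- 2 * pi / period
  X <- cbind(mesor = 1, beta = cos(w * times), gamma = sin(w * times))
  fit <- stats::lm.fit(X, values)
  if (fit$rank < 3L)
    format_error("design matrix is rank-deficient at the sampled phases")
  cf <- fit$coefficients
  M <- unname(cf["mesor"]); beta <- unname(cf["beta"]); gamma <- unname(cf["gamma"])

  rss_full <- sum(fit$residuals^2)
  rss_reduced <- sum((values - mean(values))^2)
  df <- n - 3L
  A <- sqrt(beta^2 + gamma^2)
  phi <- (atan2(gamma, beta) / w) %% period

  tol <- max(1e-10 * max(rss_reduced, 1), .Machine$double.eps * n)
  degenerate <- rss_full < tol
  if (degenerate) {
    f_stat <- if (rss_reduced < tol) 0 else Inf
    p <- if (rss_reduced < tol) 1 else 0
  } else {
    f_stat <- ((rss_reduced - rss_full) / 2) / (rss_full / df)
    p <- stats::pf(f_stat, 2, df, lower.tail = FALSE)
  }

  # coefficient covariance and delta-method limits
  sigma2 <- rss_full / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  vc <- sigma2 * XtX_inv
  tq <- stats::qt(0.975, df)
  se_M <- sqrt(vc[1, 1])
  if (A > 0) {
    gA <- c(0, beta / A, gamma / A)
    se_A <- sqrt(drop(t(gA) %*% vc %*% gA))
    gphi <- c(0, -gamma, beta) / (A^2 * w)   # hours
    se_phi <- sqrt(drop(t(gphi) %*% vc %*% gphi))
  } else {
    se_A <- se_phi <- NA_real_
  }

  structure(list(
    mesor = M, amplitude = A,
    rel_amplitude = if (M != 0) A / M else NA_real_,
    acrophase = phi, beta = beta, gamma = gamma,
    n = n, period = period,
    rss_full = rss_full, rss_reduced = rss_reduced,
    f_statistic = f_stat, p_value = p, degenerate = degenerate,
    ci_mesor = M + c(-1, 1) * tq * se_M,
    ci_amplitude = if (is.na(se_A)) c(NA_real_, NA_real_)
                   else A + c(-1, 1) * tq * se_A,
    ci_acrophase = if (is.na(se_phi)) c(NA_real_, NA_real_)
                   else phi + c(-1, 1) * tq * se_phi,
    se_acrophase = se_phi
  ), class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Cosinor fit (period %g h, n = %d)\n  mesor %s  amplitude %s (rel %s)  acrophase ZT%s\n  zero-amplitude F = %s, p = %s%s\n",
    x$period, x$n,
    signif(x$mesor, digits), signif(x$amplitude, digits),
    signif(x$rel_amplitude, digits), signif(x$acrophase, digits),
    signif(x$f_statistic, digits), format.pval(x$p_value, digits = digits),
    if (x$degenerate) "  [degenerate fit]" else ""))
  invisible(x)
}

#' Display an acrophase inside the sampling window
#'
#' Acrophases are estimated in `[0, 24)` hours after lights-on, but a
#' study sampling ZT10-ZT30 reports peak times inside that window, e.g.
#' a ZT0.7 peak is displayed as ZT24.7. Phases earlier than
#' `window_start` are shifted forward by one period.
#'
#' @param phi acrophase(s) in hours, each in `[0, 24)`.
#' @param window_start first hour of the sampling window (default 10).
#' @return value(s) in `[window_start, window_start + 24)`.
#' @examples
#' acrophase_display(15.6)  # 15.6
#' acrophase_display(0.7)   # 24.7
#' @export
acrophase_display <- function(phi, window_start = 10) {
  if (any(phi < 0 | phi >= 24, na.rm = TRUE))
    format_error("acrophase must lie in [0, 24)")
  ifelse(phi >= window_start, phi, phi + 24)
}
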