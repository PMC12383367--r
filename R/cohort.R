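# Cohort statistics: two-group comparison, median stratification,
# linear regression, Kaplan-Meier survival and the log-rank test.

#' Unpaired two-group comparison
#'
#' Classical two-sided unpaired t-test with the pooled-variance
#' (equal-variance) formula by default; `welch = TRUE` switches to the
#' Welch correction. Two constant groups with equal means return
#' t = 0, p = 1 rather than an error.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param welch use the Welch unequal-variance test.
#' @return a list with `t`, `p_value`, `means`, `sems`, `df`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    format_error("each group needs >= 2 observations")
  means <- c(mean(a), mean(b))
  sems <- c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b)))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (means[1] == means[2])
      return(list(t = 0, p_value = 1, means = means, sems = sems,
                  df = length(a) + length(b) - 2))
    return(list(t = sign(means[1] - means[2]) * Inf, p_value = 0,
                means = means, sems = sems,
                df = length(a) + length(b) - 2))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       means = means, sems = sems, df = unname(tt$parameter))
}

#' Split values at the median
#'
#' Partitions observations into `low` (value <= median) and `high`
#' (value > median); the median is the standard midpoint of the sorted
#' values, so with an odd n the median member goes to the low group.
#' When all values are identical the high group is empty and the
#' result is flagged.
#'
#' @param values numeric vector, length >= 2.
#' @return a list with `low`, `high` (values), `low_idx`, `high_idx`
#'   (indices), `median` and `degenerate`.
#' @export
stratify_by_median <- function(values) {
  if (length(values) < 2) format_error("need >= 2 values to stratify")
  med <- stats::median(values)
  low_idx <- which(values <= med)
  high_idx <- which(values > med)
  list(low = values[low_idx], high = values[high_idx],
       low_idx = low_idx, high_idx = high_idx,
       median = med, degenerate = length(high_idx) == 0)
}

#' Ordinary least-squares line with Pearson correlation
#'
#' @param x,y numeric vectors, length >= 3; `x` must have variance.
#' @return a list with `slope`, `intercept`, `r` (signed Pearson),
#'   `p_value` (two-sided slope test) and `n`.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) format_error("x and y differ in length")
  if (length(x) < 3) format_error("need >= 3 points")
  if (stats::var(x) == 0) format_error("x has zero variance")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # an exact line is a legitimate input (p -> 0); keep summary quiet
  p <- if (stats::var(y) == 0) NA_real_
       else suppressWarnings(summary(fit))$coefficients[2, 4]
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r = if (stats::var(y) == 0) 0 else stats::cor(x, y),
       p_value = p, n = length(x))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group (time origin at surgery,
#' i.e. 0) and the standard two-group log-rank chi-square with 1 df.
#' Tied event times are handled by the usual simultaneous-risk-set
#' convention. With no events in either group the test is degenerate:
#' chi-square 0, p = 1.
#'
#' @param time_a,event_a follow-up times (months) and event indicators
#'   (1 = death, 0 = censored) for group A.
#' @param time_b,event_b same for group B.
#' @return a list with `curves` (data.frame: `group`, `time`,
#'   `n_risk`, `n_event`, `survival`, `lower`, `upper`), `chisq`,
#'   `p_value`.
#' @export
km_logrank <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b))
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  group <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, survival = sf$surv,
                       lower = sf$lower, upper = sf$upper,
                       stringsAsFactors = FALSE)
  if (sum(event) == 0) {
    chisq <- 0; p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  list(curves = curves, chisq = chisq, p_value = p)
}

#' Kaplan-Meier curve for one group
#'
#' @param time follow-up times.
#' @param event event indicators (1 = death, 0 = censored).
#' @return a data.frame with `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_curve <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             survival = sf$surv, stringsAsFactors = FALSE)
}
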