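# Matrix-wide rhythm screen: cosinor per feature, expression-quartile
# stratification, acrophase clusters, dark/light ratios.

#' Assign an acrophase cluster
#'
#' Bins a peak time into the four half-phase clusters of a 12:12 LD
#' cycle: D1 = first half of the dark phase (ZT12-18), D2 = second half
#' (ZT18-24), L1 = first half of the light phase (ZT0-6), L2 = second
#' half (ZT6-12). Intervals are half-open on the right.
#'
#' @param phi acrophase(s) in hours, each in `[0, 24)`.
#' @return character vector of cluster labels.
#' @examples
#' assign_cluster(c(15.6, 0.7, 12, 6))  # D1 L1 D1 L2
#' @export
assign_cluster <- function(phi) {
  if (any(!is.finite(phi) | phi < 0 | phi >= 24))
    format_error("acrophase must lie in [0, 24)")
  ifelse(phi >= 12 & phi < 18, "D1",
  ifelse(phi >= 18,            "D2",
  ifelse(phi < 6,              "L1", "L2")))
}

#' Dark/light expression ratio
#'
#' Mean expression over samples collected in the dark phase
#' (collection time mod 24 in `[12, 24)`) divided by the mean over
#' light-phase samples.
#'
#' @param values numeric expression vector.
#' @param zt_hours collection times (hours after lights-on).
#' @return a list with `ratio` (NA when the light-phase mean is zero)
#'   and `defined`.
#' @export
dl_ratio <- function(values, zt_hours) {
  stopifnot(length(values) == length(zt_hours))
  dark <- (zt_hours %% 24) >= 12
  if (!any(dark) || !any(!dark))
    format_error("need at least one sample in each phase")
  mL <- mean(values[!dark])
  if (mL == 0) return(list(ratio = NA_real_, defined = FALSE))
  list(ratio = mean(values[dark]) / mL, defined = TRUE)
}

# quartile band of each value given all values; boundary ties go to the
# lower band ("above the upper quartile" is strictly > Q3)
.quartile_band <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  ifelse(x > q[3], "75-100",
  ifelse(x > q[2], "50-75",
  ifelse(x > q[1], "25-50", "0-25")))
}

#' Screen a matrix for rhythmic features
#'
#' Fits the 24 h single cosinor to every feature, flags rhythmicity at
#' the zero-amplitude test (`p < alpha`, raw p by default as is
#' conventional in rhythm screens; Benjamini-Hochberg adjustment is
#' available via `p_adjust`), stratifies features into quartile bands
#' of mean expression, assigns acrophase clusters to rhythmic features
#' and computes dark/light ratios. Sampling times beyond one period are
#' reduced modulo 24, which is exact for a period-24 fit.
#'
#' All-zero features cannot be fitted and are flagged `unfittable`.
#'
#' @param mat features x samples expression matrix.
#' @param meta sample metadata with `sample_id` and `zt_hours`.
#' @param alpha rhythm significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return a data.frame (one row per feature, sorted by quartile band
#'   then mean expression, both descending) with columns `feature_id`,
#'   `mean_expr`, `quartile_band`, `mesor`, `amplitude`,
#'   `rel_amplitude`, `acrophase`, `f_statistic`, `p_value`,
#'   `rhythmic`, `cluster` (`"none"` for non-rhythmic rows),
#'   `dl_ratio`, `dl_defined`, `degenerate`, `unfittable`.
#' @export
screen_rhythms <- function(mat, meta, alpha = 0.05,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  meta <- validate_sample_meta(as.data.frame(meta))
  mat <- validate_expression(mat, meta)
  times <- meta$zt_hours[match(colnames(mat), meta$sample_id)] %% 24
  if (length(unique(times)) < 3)
    format_error("screen needs >= 3 distinct ZT phases")

  rows <- lapply(seq_len(nrow(mat)), function(i) {
    y <- mat[i, ]
    dl <- dl_ratio(y, times)
    if (all(y == 0)) {
      return(data.frame(feature_id = rownames(mat)[i], mean_expr = 0,
                        mesor = NA_real_, amplitude = NA_real_,
                        rel_amplitude = NA_real_, acrophase = NA_real_,
                        f_statistic = NA_real_, p_value = NA_real_,
                        degenerate = FALSE, unfittable = TRUE,
                        dl_ratio = dl$ratio, dl_defined = dl$defined,
                        stringsAsFactors = FALSE))
    }
    f <- fit_cosinor(times, y)
    data.frame(feature_id = rownames(mat)[i], mean_expr = mean(y),
               mesor = f$mesor, amplitude = f$amplitude,
               rel_amplitude = f$rel_amplitude, acrophase = f$acrophase,
               f_statistic = f$f_statistic, p_value = f$p_value,
               degenerate = f$degenerate, unfittable = FALSE,
               dl_ratio = dl$ratio, dl_defined = dl$defined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_eff <- if (p_adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$p_adjusted <- p_eff
  out$rhythmic <- !is.na(p_eff) & p_eff < alpha
  out$cluster <- rep("none", nrow(out))
  idx <- which(out$rhythmic)
  out$cluster[idx] <- assign_cluster(out$acrophase[idx] %% 24)
  out$quartile_band <- .quartile_band(out$mean_expr)
  band_rank <- match(out$quartile_band, c("75-100", "50-75", "25-50", "0-25"))
  out <- out[order(band_rank, -out$mean_expr), ]
  rownames(out) <- NULL
  out
}

#' Quartile-by-rhythmicity summary of a screen
#'
#' Counts rhythmic features per expression-quartile band, with the
#' percentage of each count relative to all screened features — the
#' conventional per-quartile census of a rhythm screen.
#'
#' @param screen a data.frame from [screen_rhythms()].
#' @return a data.frame with columns `quartile_band`, `n_features`,
#'   `n_rhythmic`, `pct_of_all` plus an attribute `total_rhythmic`.
#' @export
screen_summary <- function(screen) {
  bands <- c("75-100", "50-75", "25-50", "0-25")
  out <- data.frame(
    quartile_band = bands,
    n_features = vapply(bands, function(b) sum(screen$quartile_band == b), 0L),
    n_rhythmic = vapply(bands, function(b)
      sum(screen$rhythmic & screen$quartile_band == b), 0L),
    stringsAsFactors = FALSE)
  out$pct_of_all <- 100 * out$n_rhythmic / nrow(screen)
  attr(out, "total_rhythmic") <- sum(screen$rhythmic)
  attr(out, "pct_rhythmic") <- 100 * sum(screen$rhythmic) / nrow(screen)
  rownames(out) <- NULL
  out
}

#' Regression of dark/light ratio on abundance
#'
#' OLS of `log(dl_ratio)` on `log(mean_expr)` across screened features,
#' to ask whether abundant features tend toward tonic (flat)
#' expression. Both axes are log-transformed because expression is
#' strongly right-skewed.
#'
#' @param screen a data.frame from [screen_rhythms()]; rows with
#'   undefined or nonpositive ratios or zero mean expression are
#'   dropped.
#' @return a list with `slope`, `intercept`, `r` (Pearson), `p_value`
#'   (two-sided slope test), `n` and `degenerate` (zero-variance
#'   response).
#' @export
abundance_ratio_regression <- function(screen) {
  ok <- screen$dl_defined & is.finite(screen$dl_ratio) &
    screen$dl_ratio > 0 & screen$mean_expr > 0
  x <- log(screen$mean_expr[ok]); y <- log(screen$dl_ratio[ok])
  if (length(x) < 3)
    format_error("need >= 3 features with defined D/L ratio, got %d", length(x))
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r = 0, p_value = NA_real_,
                n = length(x), degenerate = TRUE))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y),
       p_value = sm$coefficients[2, 4],
       n = length(x), degenerate = FALSE)
}

#' Per-feature min-max normalization for heat-map display
#'
#' Rescales each row to `[0, 1]` for display only (constant rows map
#' to 0); never used in any statistic.
#'
#' @param mat expression matrix.
#' @return matrix of the same shape.
#' @export
minmax_rows <- function(mat) {
  t(apply(mat, 1, function(y) {
    r <- range(y)
    if (r[1] == r[2]) rep(0, length(y)) else (y - r[1]) / (r[2] - r[1])
  }))
}
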