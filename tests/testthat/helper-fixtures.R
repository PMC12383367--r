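# Fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except the quartile lists shipped
# under inst/extdata.

# the unbalanced time-course design used throughout
rat_meta <- function() design_meta()

# a tiny balanced metadata table
toy_meta <- function(n_samples = 6, zt = c(10, 14, 18, 22, 26, 30)) {
  validate_sample_meta(data.frame(
    sample_id = paste0("s", seq_len(n_samples)),
    zt_hours = rep(zt, length.out = n_samples),
    replicate = 1L, stringsAsFactors = FALSE))
}

toy_matrix <- function(values, feature_ids, sample_ids) {
  m <- matrix(values, nrow = length(feature_ids), byrow = TRUE,
              dimnames = list(feature_ids, sample_ids))
  m
}

# structural census fixture with exact class counts:
# dual/single-arm x single/multi-locus
make_census_fixture <- function(n_dual_single = 199, n_single_single = 126,
                                n_dual_multi = 35, n_single_multi = 11) {
  samples <- paste0("s", 1:4)
  ann <- list(); ids <- character(); k <- 0
  add_fam <- function(i, dual, multi) {
    fam <- sprintf("mir-f%03d", i)
    arms <- if (dual) c("5p", "3p") else "5p"
    pres <- if (multi) paste0(fam, c("-1", "-2")) else fam
    do.call(rbind, lapply(arms, function(a)
      data.frame(mature_id = sprintf("miR-f%03d-%s", i, a), arm = a,
                 precursor_id = pres, locus_id = paste0(pres, "-locus"),
                 stringsAsFactors = FALSE)))
  }
  spec <- rbind(
    data.frame(dual = TRUE, multi = FALSE)[rep(1, n_dual_single), ],
    data.frame(dual = FALSE, multi = FALSE)[rep(1, n_single_single), ],
    data.frame(dual = TRUE, multi = TRUE)[rep(1, n_dual_multi), ],
    data.frame(dual = FALSE, multi = TRUE)[rep(1, n_single_multi), ])
  ann <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i)
    add_fam(i, spec$dual[i], spec$multi[i])))
  ids <- unique(ann$mature_id)
  mature <- matrix(1, length(ids), length(samples),
                   dimnames = list(ids, samples))
  list(annotation = validate_annotation(ann), mature = mature)
}

# deterministic screen fixture: n_total features with means 10*(1:n),
# rhythmic_per_band noiseless low-amplitude cosines planted at the top
# of each quartile band, everything else exactly flat
make_headline_matrix <- function(n_total, rhythmic_per_band,
                                 meta = rat_meta(), prefix = "feat") {
  t <- meta$zt_hours
  w <- 2 * pi / 24
  means <- 10 * seq_len(n_total)           # rank i has mean 10*i
  band_of_rank <- function(r) {
    q <- stats::quantile(means, c(0.25, 0.5, 0.75), names = FALSE)
    m <- means[r]
    if (m > q[3]) "75-100" else if (m > q[2]) "50-75"
    else if (m > q[1]) "25-50" else "0-25"
  }
  bands <- vapply(seq_len(n_total), band_of_rank, "")
  rhythmic <- logical(n_total)
  for (b in names(rhythmic_per_band)) {
    rk <- which(bands == b)
    rhythmic[utils::tail(rk, rhythmic_per_band[[b]])] <- TRUE
  }
  m <- t(vapply(seq_len(n_total), function(i) {
    if (rhythmic[i]) means[i] * (1 + 0.01 * cos(w * (t - 16)))
    else rep(means[i], length(t))
  }, numeric(length(t))))
  dimnames(m) <- list(sprintf("%s_%04d", prefix, seq_len(n_total)),
                      meta$sample_id)
  list(matrix = m, rhythmic = rhythmic, bands = bands)
}

# brute-force product-limit estimator: risk-set enumeration
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut)); s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# brute-force cosinor: direct normal-equations solve (independent of
# the package's lm.fit path)
cosinor_normal_equations <- function(times, values, period = 24) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  cf <- solve(t(X) %*% X, t(X) %*% values)
  list(mesor = cf[1], beta = cf[2], gamma = cf[3],
       amplitude = sqrt(cf[2]^2 + cf[3]^2),
       acrophase = (atan2(cf[3], cf[2]) / w) %% period)
}

# 1e-3 acrophase grid search with per-phase closed-form (M, A):
# regression of y on cos(w(t - phi)) for each candidate phase
cosinor_grid_search <- function(times, values, period = 24, step = 1e-3) {
  w <- 2 * pi / period
  phis <- seq(0, period - step, by = step)
  best <- list(rss = Inf)
  for (phi in phis) {
    z <- cos(w * (times - phi))
    fit <- stats::lm.fit(cbind(1, z), values)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss)
      best <- list(rss = rss, mesor = fit$coefficients[1],
                   amplitude = fit$coefficients[2], acrophase = phi)
  }
  # a negative fitted amplitude means the antiphase is the true peak
  if (best$amplitude < 0) {
    best$amplitude <- -best$amplitude
    best$acrophase <- (best$acrophase + period / 2) %% period
  }
  best
}
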