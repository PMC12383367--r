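test_that("acrophase clusters partition the day with half-open bins", {
  expect_equal(assign_cluster(15.6), "D1")
  expect_equal(assign_cluster(0.7), "L1")
  expect_equal(assign_cluster(12.0), "D1")
  expect_equal(assign_cluster(6.0), "L2")
  expect_equal(assign_cluster(18.0), "D2")
  expect_equal(assign_cluster(0), "L1")
  # exhaustive partition at a 0.01 h grid: exactly one label everywhere
  grid <- seq(0, 23.99, by = 0.01)
  lab <- assign_cluster(grid)
  expect_true(all(lab %in% c("D1", "D2", "L1", "L2")))
  expect_equal(sum(lab == "D1"), sum(grid >= 12 & grid < 18))
  expect_equal(sum(lab == "L2"), sum(grid >= 6 & grid < 12))
})

test_that("dark/light ratio follows the hand-computed arithmetic", {
  zt <- c(10, 14, 18, 22, 26, 30)
  expect_equal(dl_ratio(rep(4, 6), zt)$ratio, 1)
  expect_equal(dl_ratio(c(1, 2, 3, 2, 1, 1), zt)$ratio, mean(c(2, 3, 2)) / 1)
  # phase-sign property: a dark-peaking cosine has ratio > 1
  peak18 <- 1 + 0.5 * cos(2 * pi * (zt - 18) / 24)
  peak6 <- 1 + 0.5 * cos(2 * pi * (zt - 6) / 24)
  expect_gt(dl_ratio(peak18, zt)$ratio, 1)
  expect_lt(dl_ratio(peak6, zt)$ratio, 1)
  # zero light-phase mean is undefined, flagged
  expect_false(dl_ratio(c(0, 1, 1, 1, 0, 0), zt)$defined)
  expect_error(dl_ratio(1:3, c(13, 14, 15)), "each phase")
})

test_that("quartile bands partition features with ties to the lower band", {
  meta <- toy_meta()
  m <- matrix(rep(1:100, each = 6), 100, 6, byrow = TRUE,
              dimnames = list(sprintf("f%03d", 1:100), meta$sample_id))
  sc <- screen_rhythms(m, meta)
  expect_equal(unname(table(sc$quartile_band)[c("0-25", "25-50", "50-75", "75-100")]),
               rep(25L, 4), ignore_attr = TRUE)
  # per-band counts sum to the total rhythmic count
  sm <- screen_summary(sc)
  expect_equal(sum(sm$n_rhythmic), attr(sm, "total_rhythmic"))
})

test_that("screen recovers planted rhythmic features and controls false positives", {
  set.seed(7)
  meta <- rat_meta()
  t <- meta$zt_hours
  n <- 100; n_rhythmic <- 10
  s_log <- sqrt(log(1 + 0.1^2))
  noise <- matrix(exp(rnorm(n * length(t), -s_log^2 / 2, s_log)), n)
  base <- t(vapply(seq_len(n), function(i) {
    if (i <= n_rhythmic) 50 * (1 + 0.5 * cos(2 * pi * (t - 15) / 24))
    else rep(50, length(t))
  }, numeric(length(t))))
  m <- base * noise
  dimnames(m) <- list(sprintf("f%03d", 1:n), meta$sample_id)
  sc <- screen_rhythms(m, meta)
  planted <- sprintf("f%03d", 1:n_rhythmic)
  expect_true(all(sc$rhythmic[sc$feature_id %in% planted]))
  fp <- sum(sc$rhythmic[!sc$feature_id %in% planted])
  expect_lte(fp, qbinom(0.975, n - n_rhythmic, 0.05))
  # all planted features peak near ZT15: cluster D1
  expect_true(all(sc$cluster[sc$feature_id %in% planted] == "D1"))
})

test_that("null screens flag features at roughly the alpha rate", {
  # 20 arrhythmic features per seed, 200 seeds: total flags ~ Binomial
  meta <- rat_meta(); t <- meta$zt_hours
  s_log <- sqrt(log(1 + 0.2^2))
  total <- 0L
  set.seed(1234)
  for (rep in 1:200) {
    m <- matrix(10 * exp(rnorm(20 * length(t), -s_log^2 / 2, s_log)),
                20, length(t), dimnames = list(sprintf("f%02d", 1:20),
                                               meta$sample_id))
    total <- total + sum(screen_rhythms(m, meta)$rhythmic)
  }
  expect_gt(total, qbinom(0.005, 200 * 20, 0.05))
  expect_lt(total, qbinom(0.995, 200 * 20, 0.05))
})

test_that("screen is permutation-invariant in feature order and flags all-zero rows", {
  set.seed(11)
  meta <- rat_meta()
  m <- matrix(stats::rlnorm(15 * nrow(meta), 2, 1), 15,
              dimnames = list(sprintf("f%02d", 1:15), meta$sample_id))
  m[3, ] <- 0
  sc1 <- screen_rhythms(m, meta)
  sc2 <- screen_rhythms(m[sample(15), ], meta)
  expect_equal(sc1[order(sc1$feature_id), ], sc2[order(sc2$feature_id), ],
               ignore_attr = TRUE)
  expect_true(sc1$unfittable[sc1$feature_id == "f03"])
  expect_equal(sc1$cluster[sc1$feature_id == "f03"], "none")
})

test_that("abundance-ratio regression matches the closed-form OLS oracle", {
  meta <- toy_meta()
  # three features with exact log-linear D/L dependence on abundance
  make_feature <- function(mean_expr, ratio) {
    # light samples (10, 26, 30) get l, dark (14, 18, 22) get d with
    # d/l = ratio and (d + l)/2 = mean_expr
    l <- 2 * mean_expr / (1 + ratio); d <- ratio * l
    stats::setNames(c(l, d, d, d, l, l), meta$sample_id)
  }
  mexp <- c(10, 100, 1000)
  ratio <- exp(0.5 - 0.25 * log(mexp))   # exact log-linear, slope -0.25
  m <- do.call(rbind, lapply(1:3, function(i) make_feature(mexp[i], ratio[i])))
  dimnames(m) <- list(c("a", "b", "c"), meta$sample_id)
  sc <- screen_rhythms(m, meta)
  reg <- abundance_ratio_regression(sc)
  # hand-computed slope of log(ratio) on log(realized mean)
  x <- log(sc$mean_expr); y <- log(sc$dl_ratio)
  xb <- x - mean(x); slope_hand <- sum(xb * y) / sum(xb^2)
  expect_equal(reg$slope, slope_hand, tolerance = 1e-9)
  expect_equal(abs(reg$r), 1, tolerance = 1e-6)

  # degenerate: identically-1 ratios
  m1 <- matrix(5, 3, 6, dimnames = list(c("a", "b", "c"), meta$sample_id))
  m1 <- m1 * c(1, 2, 3)
  reg0 <- abundance_ratio_regression(screen_rhythms(m1, meta))
  expect_true(reg0$degenerate)
  expect_equal(reg0$slope, 0)
  expect_equal(reg0$r, 0)
})

test_that("tonic-abundant construction yields a negative abundance-ratio slope", {
  # high-abundance features generated flat, low-abundance rhythmic
  set.seed(55)
  meta <- rat_meta(); t <- meta$zt_hours
  n <- 200
  s_log <- sqrt(log(1 + 0.1^2))
  mexp <- exp(seq(log(5), log(5000), length.out = n))
  relamp <- seq(0.8, 0, length.out = n)   # amplitude falls with abundance
  m <- t(vapply(seq_len(n), function(i) {
    mexp[i] * (1 + relamp[i] * cos(2 * pi * (t - 16) / 24)) *
      exp(rnorm(length(t), -s_log^2 / 2, s_log))
  }, numeric(length(t))))
  dimnames(m) <- list(sprintf("f%03d", 1:n), meta$sample_id)
  reg <- abundance_ratio_regression(screen_rhythms(m, meta))
  expect_lt(reg$slope, 0)
  expect_lt(reg$p_value, 0.05)
})

test_that("min-max row normalization is display-only and bounded", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  mm <- minmax_rows(m)
  expect_equal(unname(mm["a", ]), c(0, 0.5, 1))
  expect_equal(unname(mm["b", ]), c(0, 0, 0))
})
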