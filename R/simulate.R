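# Seeded synthetic-data generators. The defaults reproduce the study
# conditions of a rat colon profiling experiment: colon sampled every
# 4 h across one light/dark cycle (ZT10, 14, 18, 22, 26 with n = 4 and
# ZT30 with n = 5), ~10% of mature miRNAs rhythmic with acrophases
# concentrated in the first half of the dark phase, the mature
# strand/precursor family census, and a 47-patient tumor cohort.

#' Sampling design metadata for the default time-course
#'
#' Builds the sample-metadata table for a Zeitgeber-time design with the
#' given time points and per-time-point replicate counts. The defaults
#' are the unbalanced rat colon design (ZT10-ZT26 n = 4, ZT30 n = 5).
#'
#' @param timepoints ZT hours of collection.
#' @param replicates integer replicate count per time point (recycled).
#' @return a `sample_meta` data.frame.
#' @export
design_meta <- function(timepoints = c(10, 14, 18, 22, 26, 30),
                        replicates = c(4, 4, 4, 4, 4, 5)) {
  replicates <- rep(replicates, length.out = length(timepoints))
  zt <- rep(timepoints, replicates)
  rep_idx <- unlist(lapply(replicates, seq_len))
  validate_sample_meta(data.frame(
    sample_id = sprintf("ZT%g_r%d", zt, rep_idx),
    zt_hours = zt, replicate = rep_idx, group = "timecourse",
    stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Collects the parameters of [simulate_expression()] with defaults set
#' to the study conditions. Fractions of the four strand/precursor
#' family classes must sum to 1.
#'
#' @param n_families number of mature-miRNA families.
#' @param frac_rhythmic fraction of families with a true rhythm.
#' @param cluster_weights probabilities over acrophase clusters
#'   D1/D2/L1/L2 for true peak placement. The default leaves L2 empty,
#'   matching the observed absence of late-light-phase peaks.
#' @param mesor_log_mu,mesor_log_sigma log-scale mean and sd of the
#'   lognormal family abundance (mesor) distribution.
#' @param rel_amplitude_range range of true relative amplitudes for
#'   rhythmic families.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise (mean-1 factors).
#' @param timepoints,replicates the sampling design (see
#'   [design_meta()]).
#' @param frac_dual_strand,frac_single_strand,frac_dual_multigene,frac_single_multigene
#'   fractions of families that are dual-arm single-locus, single-arm
#'   single-locus, dual-arm multi-locus and single-arm multi-locus;
#'   defaults follow the observed census (54/34/9/3 %).
#' @param guide_passenger_ratio mean expression ratio of the guide arm
#'   over the passenger arm (> 1).
#' @param p_pre_couples_guide probability that a family's precursor
#'   shares the guide arm's temporal profile.
#' @param frac_orphan_pre fraction of additional precursor-only
#'   families whose mature arms are absent (expression exactly 0).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_families = 200,
                       frac_rhythmic = 0.10,
                       cluster_weights = c(D1 = 0.45, D2 = 0.35, L1 = 0.20, L2 = 0),
                       mesor_log_mu = 4, mesor_log_sigma = 1.5,
                       rel_amplitude_range = c(0.2, 0.8),
                       noise_cv = 0.2,
                       timepoints = c(10, 14, 18, 22, 26, 30),
                       replicates = c(4, 4, 4, 4, 4, 5),
                       frac_dual_strand = 0.54,
                       frac_single_strand = 0.34,
                       frac_dual_multigene = 0.09,
                       frac_single_multigene = 0.03,
                       guide_passenger_ratio = 10,
                       p_pre_couples_guide = 0.89,
                       frac_orphan_pre = 0.03,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$frac_rhythmic, cfg$cluster_weights, cfg$p_pre_couples_guide,
             cfg$frac_orphan_pre)
  if (any(probs < 0 | probs > 1))
    format_error("all probabilities must lie in [0, 1]")
  fr <- c(cfg$frac_dual_strand, cfg$frac_single_strand,
          cfg$frac_dual_multigene, cfg$frac_single_multigene)
  if (abs(sum(fr) - 1) > 1e-9)
    format_error("strand-class fractions must sum to 1 (got %.12f)", sum(fr))
  if (abs(sum(cfg$cluster_weights) - 1) > 1e-9)
    format_error("cluster_weights must sum to 1")
  if (cfg$noise_cv <= 0) format_error("noise_cv must be > 0")
  if (cfg$guide_passenger_ratio <= 1)
    format_error("guide_passenger_ratio must exceed 1")
  if (any(cfg$rel_amplitude_range <= 0 | cfg$rel_amplitude_range > 1))
    format_error("rel_amplitude_range must lie in (0, 1]")
  if (!is_count(cfg$n_families)) format_error("n_families must be a positive integer")
  if (length(unique(cfg$timepoints %% 24)) < 4 && cfg$frac_rhythmic > 0)
    format_error("cosinor recovery needs >= 4 distinct time points when rhythmic features are simulated")
  class(cfg) <- c("sim_config", "list")
  cfg
}

# acrophase cluster bins in hours: D1 [12,18), D2 [18,24), L1 [0,6), L2 [6,12)
.cluster_bins <- list(D1 = c(12, 18), D2 = c(18, 24), L1 = c(0, 6), L2 = c(6, 12))

# mean-1 multiplicative lognormal noise factors with the given CV
.noise_factors <- function(n, cv) {
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

.cosine_profile <- function(t, mesor, rel_amp, phi, period = 24) {
  mesor * (1 + rel_amp * cos(2 * pi * (t - phi) / period))
}

#' Simulate a mature + precursor miRNA expression dataset
#'
#' Generates a mature-arm expression matrix, a precursor matrix, the
#' linking annotation, the sampling metadata and a ground-truth table.
#' Each rhythmic feature's noiseless profile is
#' `mesor * (1 + rel_amplitude * cos(2*pi*(t - acrophase)/24))`;
#' every observation is multiplied by an independent mean-1 lognormal
#' factor with the configured coefficient of variation. A coupled
#' precursor shares the guide arm's temporal profile (up to its own
#' independent noise); an uncoupled precursor is flat. Orphan
#' precursor-only families carry mature rows that are exactly zero.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `mature`, `pre` (matrices),
#'   `annotation`, `meta`, `truth` (data.frames) and `config`.
#' @export
simulate_expression <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  meta <- design_meta(cfg$timepoints, cfg$replicates)
  t <- meta$zt_hours
  ns <- nrow(meta)

  n_fam <- cfg$n_families
  n_orphan <- round(cfg$frac_orphan_pre * n_fam)
  classes <- sample(c("dual_single_locus", "single_single_locus",
                      "dual_multi_locus", "single_multi_locus"),
                    n_fam, replace = TRUE,
                    prob = c(cfg$frac_dual_strand, cfg$frac_single_strand,
                             cfg$frac_dual_multigene, cfg$frac_single_multigene))
  guide <- sample(c("5p", "3p"), n_fam + n_orphan, replace = TRUE)
  rhythmic <- stats::runif(n_fam + n_orphan) < cfg$frac_rhythmic
  cluster <- sample(names(cfg$cluster_weights), n_fam + n_orphan,
                    replace = TRUE, prob = cfg$cluster_weights)
  phi <- vapply(cluster, function(cl) {
    b <- .cluster_bins[[cl]]; stats::runif(1, b[1], b[2])
  }, numeric(1))
  rel_amp <- ifelse(rhythmic,
                    stats::runif(n_fam + n_orphan, cfg$rel_amplitude_range[1],
                                 cfg$rel_amplitude_range[2]), 0)
  mesor <- stats::rlnorm(n_fam + n_orphan, cfg$mesor_log_mu, cfg$mesor_log_sigma)
  coupled <- stats::runif(n_fam + n_orphan) < cfg$p_pre_couples_guide

  mature_rows <- list(); pre_rows <- list()
  ann <- list(); truth <- list()
  for (i in seq_len(n_fam + n_orphan)) {
    orphan <- i > n_fam
    fam <- sprintf("miR-%04d", i)          # family id as derived from arms
    fam_pre <- sprintf("mir-%04d", i)      # precursor naming convention
    cls <- if (orphan) "orphan" else classes[i]
    arms <- if (orphan) guide[i]
            else if (cls %in% c("dual_single_locus", "dual_multi_locus")) c("5p", "3p")
            else guide[i]
    n_loci <- if (!orphan && cls %in% c("dual_multi_locus", "single_multi_locus"))
      sample(2:3, 1) else 1L
    precursors <- if (n_loci == 1) fam_pre
                  else sprintf("%s-%d", fam_pre, seq_len(n_loci))
    ph <- if (rhythmic[i]) phi[i] else 0
    for (a in arms) {
      id <- sprintf("%s-%s", fam, a)
      is_guide <- a == guide[i]
      m_arm <- if (is_guide) mesor[i] else mesor[i] / cfg$guide_passenger_ratio
      # arm-asymmetric processing: the guide arm inherits the family
      # rhythm, the passenger arm is tonic
      ra_arm <- if (is_guide) rel_amp[i] else 0
      y <- if (orphan) rep(0, ns)
           else .cosine_profile(t, m_arm, ra_arm, ph) * .noise_factors(ns, cfg$noise_cv)
      mature_rows[[id]] <- y
      truth[[id]] <- data.frame(
        feature_id = id, level = "mature", family = fam,
        true_mesor = if (orphan) 0 else m_arm,
        true_rel_amplitude = if (orphan) 0 else ra_arm,
        true_acrophase = if (rhythmic[i] && !orphan && is_guide) ph else NA_real_,
        rhythmic = rhythmic[i] && !orphan && is_guide,
        strand_class = cls, guide_arm = guide[i],
        coupled = coupled[i], stringsAsFactors = FALSE)
      for (p in precursors)
        ann[[paste(id, p)]] <- data.frame(
          mature_id = id, arm = a, precursor_id = p,
          locus_id = paste0(p, "-locus"), stringsAsFactors = FALSE)
    }
    # precursor series: the first locus may couple to the guide profile,
    # additional loci are always flat
    m_pre <- mesor[i] / 5
    for (k in seq_along(precursors)) {
      cp <- coupled[i] && k == 1L
      ra <- if (cp) rel_amp[i] else 0
      y <- .cosine_profile(t, m_pre, ra, ph) * .noise_factors(ns, cfg$noise_cv)
      pre_rows[[precursors[k]]] <- y
      truth[[precursors[k]]] <- data.frame(
        feature_id = precursors[k], level = "pre", family = fam,
        true_mesor = m_pre, true_rel_amplitude = ra,
        true_acrophase = if (ra > 0) ph else NA_real_,
        rhythmic = ra > 0 && rhythmic[i],
        strand_class = cls, guide_arm = guide[i],
        coupled = cp, stringsAsFactors = FALSE)
    }
  }

  mature <- do.call(rbind, mature_rows)
  colnames(mature) <- meta$sample_id
  pre <- do.call(rbind, pre_rows)
  colnames(pre) <- meta$sample_id
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(mature = mature, pre = pre, annotation = validate_annotation(annotation),
       meta = meta, truth = truth, config = cfg)
}

#' Simulate replicate rhythmic time series at a fixed design
#'
#' Generates `n_series` independent series sharing one true cosine
#' profile, for parameter-recovery studies (e.g. how precisely the
#' acrophase of an abundant miRNA is recovered at the unbalanced
#' 4-h-interval design).
#'
#' @param n_series number of replicate series.
#' @param acrophase true peak time in hours.
#' @param rel_amplitude true relative amplitude.
#' @param mesor true mesor (relative units).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param timepoints,replicates the sampling design.
#' @param seed integer RNG seed.
#' @return a list with `times` (shared sampling times) and `values`
#'   (matrix, one row per series).
#' @export
simulate_rhythmic_series <- function(n_series, acrophase,
                                     rel_amplitude = 0.5, mesor = 100,
                                     noise_cv = 0.2,
                                     timepoints = c(10, 14, 18, 22, 26, 30),
                                     replicates = c(4, 4, 4, 4, 4, 5),
                                     seed = 1L) {
  set.seed(seed)
  meta <- design_meta(timepoints, replicates)
  t <- meta$zt_hours
  base <- .cosine_profile(t, mesor, rel_amplitude, acrophase)
  values <- matrix(rep(base, each = n_series), nrow = n_series) *
    matrix(.noise_factors(n_series * length(t), noise_cv), nrow = n_series)
  rownames(values) <- sprintf("series_%03d", seq_len(n_series))
  colnames(values) <- meta$sample_id
  list(times = t, values = values, meta = meta)
}

#' Construct a strand-correlation fixture with known class counts
#'
#' Builds a set of single-precursor dual-arm families whose
#' mature-vs-precursor correlation classes are fixed by construction:
#' a correlating arm is an exact positive linear function of its
#' precursor series (regression p ~ 0), while a non-correlating arm is
#' seeded noise made exactly orthogonal to the precursor (sample
#' correlation 0, so the regression slope test gives p = 1). The class
#' counts are therefore reproduced deterministically for any seed.
#'
#' @param counts named integer vector with elements `both`, `p5_only`,
#'   `p3_only`, `neither` — the number of families per correlation
#'   class. The default reproduces the published census of 199
#'   single-precursor dual-arm families.
#' @param n_samples number of samples per series (>= 4).
#' @param seed integer RNG seed.
#' @return a list with `mature`, `pre` matrices and `annotation`.
#' @export
sim_correlation_families <- function(counts = c(both = 26, p5_only = 77,
                                                p3_only = 74, neither = 22),
                                     n_samples = 25, seed = 1L) {
  stopifnot(all(c("both", "p5_only", "p3_only", "neither") %in% names(counts)))
  set.seed(seed)
  n_fam <- sum(counts)
  cls <- rep(names(counts), counts)
  mature <- matrix(0, 2 * n_fam, n_samples)
  pre <- matrix(0, n_fam, n_samples)
  m_ids <- character(2 * n_fam); p_ids <- character(n_fam)
  ann <- vector("list", n_fam)
  for (i in seq_len(n_fam)) {
    fam <- sprintf("mir-c%03d", i)
    x <- stats::rlnorm(n_samples, meanlog = 3, sdlog = 0.5)
    pre[i, ] <- x
    p_ids[i] <- fam
    corr5 <- cls[i] %in% c("both", "p5_only")
    corr3 <- cls[i] %in% c("both", "p3_only")
    arm_series <- function(correlates) {
      if (correlates) {
        stats::runif(1, 0.5, 5) * x + stats::runif(1, 0, 10)
      } else {
        z <- stats::rlnorm(n_samples, meanlog = 3, sdlog = 0.5)
        b <- stats::cov(z, x) / stats::var(x)
        zp <- z - b * (x - mean(x))          # exactly orthogonal to x
        zp - min(zp) + 1                     # shift positive; cor unchanged
      }
    }
    mature[2 * i - 1, ] <- arm_series(corr5)
    mature[2 * i, ] <- arm_series(corr3)
    m_ids[2 * i - 1] <- sprintf("miR-c%03d-5p", i)
    m_ids[2 * i] <- sprintf("miR-c%03d-3p", i)
    ann[[i]] <- data.frame(mature_id = m_ids[c(2 * i - 1, 2 * i)],
                           arm = c("5p", "3p"), precursor_id = fam,
                           locus_id = paste0(fam, "-locus"),
                           stringsAsFactors = FALSE)
  }
  sample_ids <- sprintf("s%02d", seq_len(n_samples))
  dimnames(mature) <- list(m_ids, sample_ids)
  dimnames(pre) <- list(p_ids, sample_ids)
  list(mature = mature, pre = pre,
       annotation = validate_annotation(do.call(rbind, ann)),
       true_class = stats::setNames(cls, p_ids))
}

#' Simulate a tumor cohort with a known age-response relationship
#'
#' Draws patient ages uniformly over `age_range` and generates the
#' regression response from `slope * age + intercept` plus Gaussian
#' noise whose SD is set analytically so the population correlation
#' magnitude equals `target_R`:
#' `sd = |slope| * sd(age) * sqrt(1/target_R^2 - 1)` with
#' `sd(age) = (range width)/sqrt(12)`. Patients are split at the median
#' response into low/high groups; survival times are exponential with
#' the group's hazard, administratively censored at 60 months (5-year
#' follow-up from surgery).
#'
#' The response column holds the linear-model response itself (it can
#' go negative under additive noise, so it is not forced into a
#' nonnegative expression column); `response_type` records whether it
#' is read as a proximal/tumor expression ratio or as tumor expression.
#' Positive `expr_tumor`/`expr_adjacent` columns for group comparisons
#' are generated alongside, with tumor expression downregulated in
#' proportion to age.
#'
#' @param n_patients number of patients (>= 4).
#' @param age_range numeric length-2, uniform age range in years.
#' @param slope,intercept the true linear model of response on age.
#' @param target_R target population correlation magnitude, in (0, 1).
#' @param survival_hazard_by_group named vector `c(low = , high = )` of
#'   exponential hazards per month for the median-split groups.
#' @param seed integer RNG seed.
#' @param response_type `"ratio"` (adjacent/tumor expression ratio, the
#'   default) or `"tumor"` — how the response column is interpreted.
#' @return a data.frame with columns `patient_id`, `age`, `response`,
#'   `expr_tumor`, `expr_adjacent`, `cry1_tumor`, `expr_group`,
#'   `survival_months`, `event` (1 death, 0 censored).
#' @export
simulate_cohort <- function(n_patients = 47, age_range = c(37, 86),
                            slope = -1.163, intercept = 72.265,
                            target_R = 0.301,
                            survival_hazard_by_group = c(low = 0.02, high = 0.008),
                            seed = 1L, response_type = c("ratio", "tumor")) {
  response_type <- match.arg(response_type)
  if (!is_count(n_patients) || n_patients < 4)
    format_error("n_patients must be an integer >= 4")
  if (diff(range(age_range)) <= 0)
    format_error("age_range must have positive width (zero age variance is infeasible)")
  if (!(target_R > 0 && target_R < 1))
    format_error("target_R must lie strictly in (0, 1); R = 1 would need zero noise")
  set.seed(seed)
  age <- stats::runif(n_patients, age_range[1], age_range[2])
  sd_age <- diff(range(age_range)) / sqrt(12)
  # with a null slope the population correlation is 0 for any noise
  # level, so the analytic formula (which returns 0 there) is replaced
  # by a unit SD to keep the response non-degenerate
  noise_sd <- if (slope == 0) 1
              else abs(slope) * sd_age * sqrt(1 / target_R^2 - 1)
  response <- slope * age + intercept + stats::rnorm(n_patients, 0, noise_sd)

  expr_adjacent <- stats::rlnorm(n_patients, meanlog = 4, sdlog = 0.4)
  # tumor downregulation grows with age (older tumors lose more expression)
  age01 <- (age - age_range[1]) / diff(range(age_range))
  expr_tumor <- expr_adjacent *
    exp(-0.3 - 0.8 * age01 + stats::rnorm(n_patients, 0, 0.3))
  cry1_tumor <- pmax(-0.528 * response + 2703.9 +
                       stats::rnorm(n_patients, 0, 300), 0)

  split <- stratify_by_median(response)
  grp <- ifelse(seq_len(n_patients) %in% split$low_idx, "low", "high")
  hz <- survival_hazard_by_group[grp]
  death_time <- stats::rexp(n_patients, rate = hz)
  survival_months <- pmin(death_time, 60)
  event <- as.integer(death_time <= 60)

  data.frame(patient_id = sprintf("P%03d", seq_len(n_patients)),
             age = age, response = response, response_type = response_type,
             expr_tumor = expr_tumor, expr_adjacent = expr_adjacent,
             cry1_tumor = cry1_tumor, expr_group = grp,
             survival_months = survival_months, event = event,
             stringsAsFactors = FALSE)
}
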