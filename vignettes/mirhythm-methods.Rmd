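---
title: "Methods: rhythm detection and strand-level analysis in mirhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm detection and strand-level analysis in mirhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhythm)
```

## The problem

Peripheral tissues such as the colon run cell-autonomous circadian
oscillators, and a sizeable fraction of their transcriptome — including
small non-coding RNAs — cycles with the light/dark (LD) cycle. miRNAs
add a structural layer that mRNAs lack: each precursor hairpin
(pre-miRNA) is processed into a 5p and a 3p mature arm, of which
usually one (the *guide* strand) is loaded into the silencing complex,
and one mature miRNA can be encoded by several genomic loci. Asking
"which miRNAs are rhythmic, when do they peak, and does the rhythm
propagate from precursor to mature form?" therefore requires a
pipeline that couples rhythm detection with arm- and precursor-level
bookkeeping. `mirhythm` implements that pipeline: cosinor
rhythmometry across a mature and a precursor expression matrix,
expression-quartile stratification, acrophase clustering, a
strand-correlation census, acrophase-clustered target/pathway set
selection, and the patient-cohort statistics used to connect a
rhythmic miRNA to colorectal cancer outcomes.

## The cosinor model

For a series $y_i$ sampled at Zeitgeber times $t_i$ (hours after
lights-on), the single-component cosinor with fixed period $T = 24$ h
is fit by ordinary least squares through its linearization

$$y = M + \beta\cos(\omega t) + \gamma\sin(\omega t) + \varepsilon,
  \qquad \omega = 2\pi/T,$$

giving mesor $M$ (rhythm-adjusted mean), amplitude
$A = \sqrt{\beta^2 + \gamma^2}$ (half the peak–trough difference,
also reported relative to the mesor), and acrophase
$\phi = (\arctan_2(\gamma, \beta)/\omega) \bmod T$, chosen so the
fitted curve is $M + A\cos(\omega(t - \phi))$ and peaks at $t \equiv
\phi$. The sign convention is deliberate: $\phi$ is the *time of the
fitted maximum in hours after lights-on*, not the negative-radian
angle some rhythmometry texts use, because that is how peak times are
reported in the experimental literature this pipeline serves.

Rhythmicity is decided by the zero-amplitude test, the F comparison of
the cosinor against the intercept-only model:

$$F = \frac{(\mathrm{RSS}_0 - \mathrm{RSS}_1)/2}{\mathrm{RSS}_1/(n-3)}
  \sim F(2,\, n-3) \text{ under } A = 0 .$$

Confidence limits for $M$ come from the OLS coefficient covariance;
limits for $A$ and $\phi$ use the delta method (gradients
$(\beta/A, \gamma/A)$ and $(-\gamma, \beta)/(A^2\omega)$). The exact
elliptical joint region is deliberately not the default: the studies
this package targets report no acrophase intervals, and the delta
method is adequate away from $A \approx 0$, where the acrophase is
ill-defined anyway.

Two numerical edge cases are handled explicitly. A residual sum of
squares at machine tolerance marks the fit *degenerate*: for an exact
cosine the p-value is reported as 0 with the flag set, and for an
exactly constant series $F = 0$, $p = 1$. Sampling designs whose
times collapse to fewer than three distinct phases modulo the period
are rejected as rank-deficient rather than silently fitted.

Unequal replication (the default design has $n = 5$ at the last time
point and $n = 4$ elsewhere) is handled naturally by OLS; values are
never averaged within a time point first, because averaging discards
degrees of freedom from the zero-amplitude test.

### Acrophase display

Acrophases live on $[0, 24)$, but a study that samples ZT10–ZT30
reports peaks inside its sampling window: a fitted peak at ZT0.7 is
displayed as ZT24.7. `acrophase_display()` implements exactly that
convention (`phi + 24` when `phi < window_start`, default window start
ZT10). The statistic is unchanged; only the reported number moves.

## The rhythm screen

`screen_rhythms()` applies the cosinor to every feature, with these
conventions:

* **Significance.** Raw $p < \alpha$ (default 0.05) declares a feature
  rhythmic — no multiple-testing correction by default, matching the
  convention of tissue rhythm screens where the per-feature cosinor p
  is reported as-is. A Benjamini–Hochberg option (`p_adjust = "BH"`)
  exists for users who want FDR control; it is off by default because
  the downstream census semantics (cluster counts per quartile) are
  defined on the raw threshold.
* **Quartile bands.** Features are stratified by empirical quartiles
  of per-feature *mean* expression over all samples (the alternative,
  total counts, is proportional for a fixed design and would not
  change the bands). Boundary ties go to the lower band, so "above
  the upper quartile" means strictly greater than Q3.
* **Clusters.** Rhythmic features are binned by acrophase into
  D1 = ZT[12, 18), D2 = ZT[18, 24), L1 = ZT[0, 6), L2 = ZT[6, 12) —
  half-open bins that provably partition the day. Non-rhythmic
  features carry the cluster label `none`.
* **Times beyond 24 h** in the metadata (ZT26, ZT30) are reduced
  modulo 24 before fitting and phase assignment; for a period-24 fit
  this is exact, not an approximation.
* **Dark/light ratio.** Mean expression over samples *collected*
  during ZT[12, 24) divided by the light-phase mean (assignment by
  collection phase, because that is what the ratio is plotted against
  in the source analyses). The abundance–ratio regression runs on
  log–log scales, since expression spans orders of magnitude.
* **All-zero features** are unfittable and flagged, never dropped
  silently; the min–max row normalization (`minmax_rows()`) exists for
  heat-map display only and is never used in a statistic.

## The strand atlas

`strand_atlas()` reproduces the strand/precursor census. Families are
keyed by the arm-stripped mature id (`miR-150-5p` and `miR-150-3p`
form family `miR-150`); an arm counts as expressed when it is present
in the matrix with any nonzero value. Four structural classes cross
dual/single expressed arms with single/multiple precursors; a
precursor whose family has no expressed arm at all is an *orphan*.
Percentages are always recomputed from counts (the package reports
both), with the expressed-family count as denominator.

"Correlation" between a mature arm and its precursor is
operationalized as the OLS regression slope test at $p < 0.05$ on
untransformed relative units, with a log-scale option — the source
convention is regression analysis, and the slope test is the natural
reading. Only single-precursor dual-arm families enter the
correlation analysis (a multi-locus mature form has no unique
precursor series to regress on), giving classes `both` / `5p_only` /
`3p_only` / `neither`. The guide strand is assigned by relative
abundance (greater mean across samples), with an explicit
annotation override for users who trust curated guide calls more, and
an exact tie mapping to `undetermined`.

## Candidate selection and set algebra

`select_candidates()` implements the two inclusion criteria for
"abundant rhythmic miRNA with rhythmic biogenesis": (1) the mature
form is rhythmic with mean expression strictly above the upper
quartile; (2) at least one annotated precursor is rhythmic with mean
expression above the median of all screened precursors. Where a
mature form has several precursors, *any* rhythmic above-median
precursor suffices — the source analyses do not specify any-vs-all,
and "any" is the permissive reading consistent with treating each
precursor as an independent biogenesis route; the choice is recorded
here as an assumption. Candidates inherit the acrophase cluster of
the mature fit, and matures with no precursor link are excluded with
an explicit log rather than silently.

Target genes are the per-cluster union over a curated
interaction table filtered to strong experimental support (default
label set `{"Functional MTI"}`, configurable since support-type
vocabularies drift between releases). Rat-to-human id translation is
a user-supplied two-column map plus species-prefix stripping; there is
no remote lookup. `venn()` computes exact disjoint region counts for
two or three labeled sets, and `pathway_sets()` retains a pathway for
a cluster only when at least `min_genes = 3` of the cluster's genes
map to it — enrichment *statistics* (binomial/Fisher machinery) are
intentionally out of scope; only the set/threshold logic is
implemented.

## Cohort statistics

The cohort stage uses the field-standard estimators: unpaired
two-sided t-test with the pooled-variance formula (a Welch flag
exists; note the tumor-vs-adjacent comparison is applied unpaired to
match the source convention even though samples are paired per
patient — a paired analysis would typically be more powerful),
median stratification with the median member assigned to the low
group, OLS regression with Pearson R and the slope t-test, and
Kaplan–Meier product-limit curves with the two-group log-rank test
(survival time origin at surgery, standard simultaneous-risk-set tie
handling). KM and log-rank are computed via the `survival` package
and cross-checked in the test suite against an independent risk-set
enumeration.

## The synthetic-data generator

Because the profiling and patient datasets behind the published
numbers are not deposited with public accessions, every stage is
exercised on generated data with known ground truth.

`simulate_expression()` emulates:

* the unbalanced sampling design — ZT10, 14, 18, 22, 26 ($n = 4$) and
  ZT30 ($n = 5$) — by default, so unbalanced-design handling is always
  exercised;
* the family census: 54% dual-arm single-precursor, 34% single-arm
  single-precursor, 9% dual-arm multi-precursor, 3% single-arm
  multi-precursor, plus 3% precursor-only (orphan) families whose
  mature rows are exactly zero;
* rhythm structure: 10% of families rhythmic by default, acrophases
  drawn within cluster bins with weights 0.45/0.35/0.20/0 (the empty
  L2 weight mirrors the observed absence of late-light peaks; all
  weights are configurable), relative amplitudes uniform on
  [0.2, 0.8], lognormal mesors;
* arm asymmetry: the guide arm (Bernoulli(0.5) per family — no 5p
  bias is hard-coded because the source reports only a trend) carries
  the family rhythm and a `guide_passenger_ratio` (default 10)
  abundance advantage; the passenger arm is tonic;
* precursor coupling: with probability `p_pre_couples_guide`
  (default 0.89) the precursor shares the guide arm's noiseless
  temporal profile up to independent noise; otherwise it is flat.

Noise is multiplicative lognormal with mean-1 factors at a configured
coefficient of variation (default 0.2 — a stated assumption, since
per-feature dispersions are not published). The lognormal is chosen
over a count model (negative binomial) because the pipeline consumes
normalized relative units, not raw counts; simulating reads is a
non-goal. Identical seeds give bit-identical outputs.

What the generator does **not** emulate: sequencing depth and count
discreteness, shared per-animal (sample-level) biological variation
across features, inter-feature correlation beyond the arm/precursor
coupling, and any sequence-level structure. Consequently, passing
recovery tests demonstrate correctness of the estimators under the
declared noise model, not robustness to count noise or batch
structure. One consequence worth spelling out: because coupling acts
through the shared *temporal profile*, an arrhythmic family's arm and
precursor series are independent by construction, so
coupling-detection properties are evaluated on fully rhythmic
configurations.

`sim_correlation_families()` is different in kind: it is a
deterministic fixture constructor. Correlating arms are exact
positive linear functions of their precursor (slope p → 0);
non-correlating arms are seeded noise *residualized against the
precursor*, making the sample correlation exactly zero (slope t = 0,
p = 1). Plain independent noise would leak ~5% chance correlations
and corrupt constructed class counts for some seeds; residualization
guarantees the census for every seed while remaining random data.

`simulate_cohort()` draws ages uniformly, builds the regression
response from a configurable line with Gaussian noise whose SD is set
analytically so the population correlation magnitude hits `target_R`
($\sigma = |b|\,\mathrm{sd}(x)\sqrt{1/R^2 - 1}$, with the uniform
population SD $(\max-\min)/\sqrt{12}$), and generates exponential
survival with administrative censoring at 60 months. The response is
kept in its own column rather than forced into an expression column:
over the default age span the published line takes negative values,
so it cannot literally be a nonnegative expression — the published
description is ambiguous between tumor expression and an
adjacent/tumor ratio, and the `response_type` field documents which
reading the caller intends. `target_R = 1` is rejected (it would
require zero noise), and a zero slope falls back to unit noise SD
since the population correlation is 0 there for any noise level.

## Problem sizes and runtime choices

The test suite validates the cosinor against two independent oracles
(a direct normal-equations solve and a $10^{-3}$-resolution acrophase
grid search with per-phase closed-form mesor/amplitude), checks the
zero-amplitude test's size on 5 000 null series at the default design,
acrophase recovery on 200 replicate series, log-rank power on 500
simulated trials, the strand-class census convergence at 5 000
families, and the cohort correlation calibration at $n = 10\,000$.
These sizes give Monte-Carlo standard errors comfortably below the
asserted tolerances while keeping the full suite around a minute on
one CPU.

## Known limitations

* Free-period fitting, multi-component cosinor, population-mean
  cosinor and rank-based rhythm detectors are out of scope; a feature
  whose period deviates from 24 h will lose power accordingly.
* The delta-method acrophase interval degrades near zero amplitude.
* The raw-p default means the screen's rhythmic count at $\alpha =
  0.05$ carries the expected 5% false-positive load; consumers who
  need FDR control must opt in to `p_adjust = "BH"`.
* Guide-strand assignment by abundance can disagree with curated
  annotation for near-balanced duplexes; the override exists for that
  reason.
* The unpaired tumor-vs-adjacent default mirrors the source
  convention, not best practice for paired samples.
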