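# mirhythm

Cosinor rhythmometry and strand-level analysis of daily miRNA
expression.

`mirhythm` is for transcriptomics researchers asking whether miRNAs in
a peripheral tissue cycle with the light/dark (LD) cycle, and what
that rhythm implies downstream. Given a mature-arm expression matrix,
a precursor (pre-miRNA) matrix, Zeitgeber-time sample metadata and an
arm/precursor annotation, it runs the full pipeline:

* **Cosinor rhythm detection** — single-component cosinor with fixed
  24 h period, fit by OLS through the linearization
  `y = M + β·cos(ωt) + γ·sin(ωt)`, reporting mesor *M*, amplitude
  `A = √(β² + γ²)`, acrophase `φ = (atan2(γ, β)/ω) mod 24` (the time
  of the fitted maximum, hours after lights-on) and the zero-amplitude
  test `F = ((RSS₀ − RSS₁)/2)/(RSS₁/(n − 3)) ~ F(2, n − 3)`.
* **Rhythm screen** — per-feature fits, expression-quartile bands,
  acrophase clusters (D1 = ZT12–18, D2 = ZT18–24, L1 = ZT0–6,
  L2 = ZT6–12), dark/light expression ratios and the log–log
  abundance–ratio regression.
* **Strand atlas** — the structural census of families (dual/single
  arm × single/multi precursor, orphan precursors), regression-based
  mature↔precursor correlation classes, and abundance-based
  guide-strand assignment.
* **Candidate selection and set algebra** — the two-criterion rule
  (rhythmic mature above the upper quartile + rhythmic above-median
  precursor), per-cluster target-gene unions from a miRTarBase-style
  table, exact Venn regions, and ≥3-gene pathway retention on a
  Panther-style table.
* **Cohort statistics** — unpaired t-test, median stratification,
  OLS regression with Pearson R, Kaplan–Meier curves and the log-rank
  test.
* **Synthetic data** — seeded generators reproducing the unbalanced
  rat-colon sampling design (ZT10–ZT30 every 4 h, n = 4, ZT30 n = 5),
  the family census, precursor coupling and a patient cohort, so every
  stage is testable with known ground truth.

## Worked example

Simulate a study-shaped dataset, screen both expression levels and
select candidates:

```r
library(mirhythm)

sim  <- simulate_expression(sim_config(n_families = 200, seed = 1))
sc_m <- screen_rhythms(sim$mature, sim$meta)
sc_p <- screen_rhythms(sim$pre, sim$meta)
screen_summary(sc_m)
#>   quartile_band n_features n_rhythmic pct_of_all
#> 1        75-100         82         15   4.573171
#> 2         50-75         82          9   2.743902
#> 3         25-50         82          9   2.743902
#> 4          0-25         82          6   1.829268
```

39 of 328 mature arms (11.9%) screen rhythmic at α = 0.05 on this
seed — consistent with the configured 10% of families rhythmic plus
the 5% false-positive load of the raw-p threshold — and rhythmic
features concentrate in the top expression quartile. The most
abundant rhythmic arms, with their fitted phases:

```r
head(sc_m[sc_m$rhythmic,
          c("feature_id", "mean_expr", "rel_amplitude",
            "acrophase", "p_value", "cluster")], 5)
#>     feature_id mean_expr rel_amplitude acrophase  p_value cluster
#> 9  miR-0151-5p       750        0.6605      5.28 8.89e-08      L1
#> 17 miR-0094-3p       425        0.6724     15.89 2.27e-08      D1
#> 24 miR-0057-3p       314        0.4467     14.42 5.09e-07      D1
#> 31 miR-0132-3p       264        0.0852     16.95 4.02e-02      D1
#> 36 miR-0117-5p       223        0.1655     23.62 1.12e-02      D2
```

`acrophase` is the fitted peak time in hours after lights-on;
`cluster` bins it into the LD half-phases. Candidate miRNAs passing
both inclusion criteria (rhythmic, top expression quartile, with a
rhythmic above-median precursor):

```r
select_candidates(sc_m, sc_p, sim$annotation)$candidates[
  , c("mature_id", "cluster", "mature_p", "precursor_id")]
#>     mature_id cluster mature_p precursor_id
#> 1 miR-0151-5p      L1 8.89e-08     mir-0151
#> 2 miR-0094-3p      D1 2.27e-08     mir-0094
#> 3 miR-0057-3p      D1 5.09e-07     mir-0057
#> 4 miR-0032-5p      D1 4.16e-04     mir-0032
#> 5 miR-0147-5p      L1 4.62e-10     mir-0147
#> 6 miR-0152-3p      D1 3.44e-06     mir-0152
```

A single series fits in one call:

```r
s <- simulate_rhythmic_series(1, acrophase = 15.6, seed = 4)
fit_cosinor(s$times, s$values[1, ])
#> Cosinor fit (period 24 h, n = 25)
#>   mesor 109.8  amplitude 56.61 (rel 0.5156)  acrophase ZT15.7
#>   zero-amplitude F = 44.29, p = 1.933e-08
```

The true peak was ZT15.6; the fit recovers ZT15.7 from 25 noisy
observations. Phases that fall before the sampling window are
reported in-window with `acrophase_display()` (a ZT0.7 peak displays
as ZT24.7).

A thin command-line wrapper over the same functions ships in
`inst/scripts/mirhythm-cli.R` (subcommands `validate`, `simulate`,
`cosinor`, `screen`, `atlas`).

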