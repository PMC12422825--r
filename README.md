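# mrscreen

Two-sample Mendelian randomization (MR) screening from GWAS summary
statistics, with a synthetic-data backbone that makes every stage of the
pipeline testable against known ground truth.

`mrscreen` is for analysts running **many-exposure × many-outcome causal
screens** — the motivating design is a panel of gut-microbiome taxa and
functional pathways screened against age-related outcomes and circulating
plasma proteins — where each pair needs the full discipline of modern MR:
independent, strong instruments; several estimators that fail in different
ways; pleiotropy, heterogeneity and outlier diagnostics; within-outcome
false-discovery control; reverse-direction and replication checks; and
post-hoc power.

## The statistics in brief

With harmonized per-variant effects β<sub>Xj</sub> (exposure) and
β<sub>Yj</sub> (outcome), Wald ratios r<sub>j</sub> = β<sub>Yj</sub>/β<sub>Xj</sub>
and weights w<sub>j</sub> = β<sub>Xj</sub>²/σ<sub>Yj</sub>²:

- **IVW** (primary): β̂<sub>c</sub> = Σw<sub>j</sub>r<sub>j</sub>/Σw<sub>j</sub>,
  multiplicative random-effects se inflated by max(1, √(Q/(m−1))) with
  Cochran's Q = Σw<sub>j</sub>(r<sub>j</sub> − β̂<sub>c</sub>)².
- **Weighted median**: interpolated 50% point of the ratio distribution
  under IVW weights; bootstrap se; consistent with ≥ 50% valid weight.
- **MR-Egger**: weighted regression with intercept after exposure-positive
  orientation; the intercept tests directional pleiotropy (only the
  intercept gates — Egger slopes are reported, not gated).
- **PRESSO-style outlier test**: leave-one-out weighted residual sum of
  squares against a parametric resampling null; per-variant outlier calls
  (Bonferroni), outlier-corrected estimate, distortion test.
- Instrument strength: per-variant R² = β²/(β² + n·se²) summed over the
  clumped set, F = R²(n−k−1)/(k(1−R²)), screened at F > 10.
- Power: Φ(√(N·R²)·|β<sub>c</sub>|·c − z<sub>1−α/2</sub>), c = 1
  (continuous) or √ratio/(1+ratio) (binary, ratio = cases/controls).

A pair is **significant** only if it passes the full conjunctive gate:
BH-FDR (within its outcome) < 0.05, weighted-median p < 0.05, PRESSO p
< 0.05, Egger-intercept p > 0.05, heterogeneity p > 0.05, reverse-MR
p ≥ 0.05, and no leave-one-out sign change. Every gate column is exported,
so tables can be re-gated with `regate()`.

## Worked example

Simulate one exposure/outcome pair with a true causal effect of 0.25, then
run the estimator battery:

```r
library(mrscreen)

scenario <- sim_scenario(m_snps = 15, beta_causal = 0.25,
                         exposure_r2_total = 0.05,
                         n_exposure = 7738, n_outcome = 200000, seed = 42)
sim  <- simulate_pair(scenario)
inst <- harmonize(sim$exposure, sim$outcome)
fit  <- mr_fit(inst, seed = 42)
tidy(fit)
#> # A tibble: 4 × 6
#>   method          estimate std.error statistic  p.value n_snps
#>   <chr>              <dbl>     <dbl>     <dbl>    <dbl>  <int>
#> 1 ivw              0.228     0.0190     12.0   4.84e-33     15
#> 2 weighted_median  0.239     0.0189     12.6   1.17e-36     15
#> 3 egger_slope      0.218     0.0382      5.70  7.26e- 5     15
#> 4 egger_intercept  0.00110   0.00370     0.298 7.71e- 1     15
```

All three causal estimators sit near the true 0.25 within ~1–2 standard
errors, and the Egger intercept (average directional pleiotropy) is
indistinguishable from zero, as simulated. The heterogeneity in `glance()`
(`q = 56.4` on 14 df) reflects exposure-side sampling noise from the small
exposure GWAS (n = 7738) — exactly why the multiplicative random-effects
model is the default. Instrument selection and strength:

```r
ivs <- clump(sim$exposure, sim$ld)          # p < 5e-6, 10 Mb, r2 < 0.001
instrument_diagnostics(sim$exposure, ivs)
#> # A tibble: 1 × 4
#>   r2_total f_stat     k     n
#>      <dbl>  <dbl> <int> <dbl>
#> 1   0.0497   57.7     7  7738
```

Seven of the fifteen simulated variants reach the instrument threshold in
an n = 7738 exposure GWAS; together they recover the simulated explained
variance (5%) and clear the F > 10 strength screen. At the outcome's
sample size that instrument gives essentially unit power for an effect of
0.25 (`power_continuous(0.25, 200000, 0.0497)` → 1.00).

Full screens run from named lists of `summary_stats` objects:

```r
g   <- simulate_grid(5, 8, causal_pairs = tibble::tibble(
         exposure = "exposure_001", outcome = "outcome_0001", beta = 0.35),
       seed = 1)
res <- run_screen(g$exposures, g$outcomes, g$ld, mr_config(seed = 1))
export_results(res, "screen_out")   # results.tsv, significant.tsv, forest.tsv
```

`plot_mr_scatter()`, `plot_leave_one_out()`, `plot_forest()` and
`plot_power_curve()` draw the standard MR figures from these objects, and
`read_summary_stats()` ingests real tab-delimited GWAS exports (header
remapping via `column_map` / YAML).

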