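---
title: "Methods: two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

# The problem

Two-sample Mendelian randomization (MR) asks whether an exposure causally
affects an outcome using only GWAS summary statistics from two (possibly
disjoint) cohorts. Genetic variants robustly associated with the exposure
serve as instrumental variables: because alleles are randomized at meiosis,
a variant that changes the exposure and — only through the exposure — the
outcome supports a causal interpretation, free of classical confounding and
reverse causation. `mrscreen` implements the complete screening workflow for
many exposures against many outcomes (the motivating setting is a
gut-microbiome panel of taxa and functional pathways screened against
age-related disease and circulating-protein outcomes): instrument selection,
an estimator suite with sensitivity gates, within-outcome false-discovery
control, bidirectional MR, replication, and post-hoc power — plus a
synthetic GWAS generator with known ground truth so that every stage is
verifiable without downloading any real GWAS.

# Instrument selection

For each exposure the pipeline:

1. **Checks eligibility**: at least one genome-wide-significant association
   (`p < 5e-8`). Traits with no strong genetic signal make unreliable
   exposures; this also limits confounding through weakly heritable traits.
2. **Removes artifact effect sizes**: variants with `|beta|` above 4
   standardized-trait units are dropped. This cut is deliberately absolute
   rather than a band around the mean effect: across a summary-statistics
   panel the variant-wise SD of effects is on the scale of the median
   standard error, so a mean ± 4 SD band would remove precisely the
   genome-wide-significant variants the screen needs, while a per-allele
   effect of four trait SDs is not biologically plausible and indicates a
   unit or coding problem.
3. **Clumps** at `p < 5e-6` in a 10 Mb window with an r² cutoff of 0.001:
   greedily take the smallest-p variant as an index and discard every
   variant on the same chromosome within the window whose squared
   correlation with it reaches the cutoff. Ties in p are broken by
   lexicographic rsid so the selection is invariant to row order. The
   window is one-sided from the index (the PLINK convention), giving a
   20 Mb total span.
4. **Screens instrument strength**: the explained variance of variant *j*
   is `R²_j = 2β²f(1−f) / (2β²f(1−f) + 2n·se²·f(1−f))`, which cancels to
   `β²/(β² + n·se²)` — the implementation uses the cancelled form, so a
   missing allele frequency never blocks the diagnostic. With
   `R² = Σ_j R²_j` over the `k` instruments, the strength statistic is
   `F = R²(n−k−1) / (k(1−R²))`, and instrument sets with `F ≤ 10` are set
   aside as untestable (weak instruments).

# Harmonization

Outcome effects are re-expressed for the exposure's effect allele: matching
alleles are copied, swapped alleles flip the sign (and reflect the effect
allele frequency), and opposite-strand records are complemented first.
Palindromic variants (A/T, C/G) cannot be resolved from allele labels; they
are kept only when both studies report allele frequencies outside
0.5 ± 0.08 on the same side of 0.5, and dropped as ambiguous otherwise.
Harmonization is idempotent, and all estimators are invariant to flipping
any instrument's allele frame (both signs at once).

# Estimators

Let `β_Xj`, `β_Yj` be the harmonized effects with standard errors
`σ_Xj, σ_Yj`, `r_j = β_Yj/β_Xj` the per-variant Wald ratio, and
`w_j = β_Xj²/σ_Yj²` the inverse-variance weight.

* **IVW** (primary test): `β_c = Σ w_j r_j / Σ w_j`, equivalently the
  zero-intercept weighted regression of `β_Y` on `β_X`. The fixed-effect
  standard error is `1/√(Σ w_j)`; by default the multiplicative
  random-effects model inflates it by `max(1, √(Q/(m−1)))`, with Cochran's
  `Q = Σ w_j (r_j − β_c)²` (chi-square on `m−1` df) the heterogeneity
  statistic. P-values are two-sided normal. A single instrument reduces to
  the Wald ratio with the delta-method standard error `σ_Y/|β_X|`.
* **Weighted median**: the estimate interpolates the sorted ratios over the
  cumulative weight midpoints `p_j = (S_j − w_j/2)/S_m` at 0.5, and is
  consistent whenever at least half the total weight comes from valid
  instruments. Its standard error has no closed form; a seeded parametric
  bootstrap (default 1000 draws from the effects' sampling distributions,
  weights recomputed per draw) supplies it, with a normal test for p.
* **MR-Egger**: after orienting every instrument so `β_X ≥ 0` (results
  differ if this step is skipped), a weighted regression *with* intercept,
  weights `1/σ_Y²`. The slope is a pleiotropy-robust causal estimate under
  the InSIDE assumption; the intercept estimates average directional
  pleiotropy. Standard errors carry the overdispersion factor
  `max(1, √(RSS_w/(m−2)))` and p-values use Student's t on `m−2` df. Egger
  causal estimates are reported but never gate significance (their type-I
  error is inflated); only the intercept test gates.
* **Leave-one-out**: IVW repeated dropping each instrument in turn. The
  classical check is visual; the automated proxy gating the screen is a
  sign change of any subset estimate relative to the full estimate.
* **PRESSO-style outlier test**: the observed statistic is the
  leave-one-out weighted residual sum of squares
  `RSS = Σ_j (β_Yj − β_c^{(−j)} β_Xj)²/σ_Yj²`. Its null distribution comes
  from parametric replicates (default 1000) drawing
  `β_X* ~ N(β_X, σ_X²)`, `β_Y* ~ N(β_c^{(−j)}β_X, σ_Y²)`; the global p is
  `(1 + #{RSS* ≥ RSS})/(1 + n_sim)`, never zero. Per-variant simulated
  residual distributions give outlier p-values, Bonferroni-corrected at
  0.05. When outliers are found, an outlier-corrected IVW fit is reported
  together with a distortion p-value: the observed shift of the IVW
  estimate after removing the outliers is compared against the null shift
  from removing equally many randomly chosen instruments (two-sided
  empirical p with the same +1 correction). Instruments are sorted by rsid
  before any resampling, so results are invariant to row order at a fixed
  seed.

# The significance gate

The IVW p-values are adjusted by Benjamini–Hochberg **within each outcome**
(across that outcome's exposures): outcomes are heterogeneous families, and
correcting within each mirrors testing one outcome against the exposure
panel. A pair is called **significant** only if all of the following hold;
each component is exported so any table can be re-gated:

| gate | requirement |
|---|---|
| discovery | BH-adjusted IVW p < 0.05 |
| weighted median | p < 0.05 (direction-concordant support) |
| PRESSO | outlier-corrected (or raw, if no outliers) IVW p < 0.05 |
| pleiotropy | Egger intercept p > 0.05 |
| heterogeneity | Cochran's Q p > 0.05 |
| reverse causality | reverse IVW p ≥ 0.05 |
| leave-one-out | no sign change |

Bidirectional (reverse) MR — instrument selection and IVW with the roles
swapped — runs only for FDR-passing pairs, matching the reported workflow
and saving a factor of two in compute. Sensitivity tests that cannot run
(fewer than 3 instruments for weighted median/Egger/leave-one-out, fewer
than 4 for PRESSO, no reverse instruments) pass by NA and are listed in a
`gates_na` column rather than failing the pair; with 0.05 on every gate and
several gates drawing near-uniform p-values under their own nulls, roughly
one true causal pair in seven is expected to fail some sensitivity gate by
chance — the price of a conjunctive rule, and the reason every gate column
is exported for re-gating.

Replication reruns IVW with the same instruments against an independent
outcome dataset; a result replicates when `p < 0.05` with the same effect
direction as the main analysis.

# Post-hoc power

`Power = Φ( √(N·R²)·|β_c|·c − z_{1−α/2} )` with `c = 1` for continuous
outcomes and `c = √(ratio)/(1+ratio)` for binary outcomes on the log-odds
scale (`ratio` = cases/controls; the factor `ratio/(1+ratio)²` is the
product of case and control fractions, symmetric in `ratio ↔ 1/ratio` and
maximal for a balanced design). An alternative reading of this expression
with the quantile subtracted *outside* Φ is not bounded in [0, 1] and is
rejected. Two properties worth noting: at `β_c = 0` the formula returns the
one-tail mass α/2 = 0.025, while a two-sided test rejects at α — the
approximation tracks the upper rejection region only, so simulated
rejection frequencies are compared to it away from zero, where the lower
tail is negligible; and `R²` here is the exposure's explained variance, so
the same `snp_r2` arithmetic feeds both the F-statistic and power.

# The synthetic-data generator

`sim_scenario()`/`simulate_pair()` implement the standard two-sample MR
generative process, chosen so every formula above is exact under it:

* MAFs uniform on a configurable range (default 0.05–0.45, echoing a
  reference panel filtered at 1% MAF);
* per-allele exposure effects rescaled so `Σ 2f(1−f)b²` equals the target
  explained variance exactly (standardized trait) — the algebraic inverse
  of the `R²` formula, so diagnostics recover the simulated `R²` up to
  sampling noise;
* per-variant pleiotropy `N(mean, sd²)` applied in the
  exposure-increasing-allele frame (so a nonzero mean is directional in
  exactly the sense the Egger intercept estimates; with random allele
  orientation a "directional" mean would cancel), plus an additive shift
  for planted outliers;
* sampling noise `N(0, se²)` with `se = 1/√(2n·f(1−f))`, times
  `√(ratio)/(1+ratio)` scaling on the log-odds scale for binary outcomes
  (a floor of 1e-8 keeps the noise-free limit `n → ∞` numerically exact);
* a block-diagonal LD matrix (within-block r² = `ld_rho²`), each block on
  its own chromosome so blocks always fall within one clumping window and
  never clump across blocks.

Defaults mirror the motivating screen: a small exposure GWAS (n = 7738, the
scale of a shotgun-sequenced microbiome cohort), modest explained variance
(2%), and a large outcome GWAS. Seeds are mandatory; no global RNG state is
consumed, and per-pair sub-seeds are derived from the pipeline seed plus the
pair's identifiers, making whole screens bit-reproducible and invariant to
enumeration order.

`simulate_grid()` builds a multi-trait panel over a shared variant set: each
trait owns a block of directly associated variants (Gaussian per-allele
effects rescaled to the trait's target explained variance), and causal
edges copy the source's direct effects
into the receiver scaled by the edge's `beta` — so planted forward effects
produce exactly the mediated summary-statistic signal a real causal pair
would show, and `direction = "reverse"` edges plant reverse causation for
testing the bidirectional gate.

**What the generator does not emulate.** Sampling noise is independent
across variants: LD affects clumping but not the correlation of effect
estimates, so clumped instruments behave as exactly independent.
There is no population stratification, no sample overlap
between the two GWAS (which biases real two-sample MR toward the
confounded estimate), no MAF-dependent architecture, no binary *exposures*,
and mediation is single-step. Passing tests therefore certify the
statistical machinery under the stated model, not robustness to these
real-data complications.

# Numerical and design choices

* **Estimator arithmetic** is closed-form from the 2×2 normal equations;
  generic least-squares routines serve only as independent cross-checks in
  the test suite.
* **Problem sizes in the validation suite** (chosen once as study
  conditions): null calibration uses 2000 replicates at m = 10, n = 50 000
  (type-I error within 0.05 ± 0.015, slightly conservative because the
  random-effects inflation is active only when Q exceeds its df);
  parameter recovery uses 200 seeds at m = 30, n = 10⁶ with β_c = 0.2;
  outlier recovery plants a 10-se shift in one of 20 instruments over 100
  seeds; the end-to-end screen is a 5 × 8 grid with three planted effects
  of |β| = 0.35–0.4 — strong enough that the mediated per-variant signal
  stays below the instrument threshold in the outcome GWAS, which is what
  keeps forward hits from contaminating their own reverse test.
* **Degenerate inputs**: a single instrument reduces IVW to the Wald ratio
  and leaves heterogeneity undefined; constant exposure effects after
  orientation make the Egger design singular (reported as untestable);
  empty clumping output marks the pair untestable rather than erroring;
  p-values from resampling are bounded below by `1/(n_sim+1)`.
* **FDR scope**: literal within-outcome correction. Adding or removing an
  unrelated *outcome* never changes another outcome's adjusted p-values;
  adding an *exposure* can — the test suite asserts both.
* **Exports**: the canonical per-pair table plus a lossless variant with
  all gate bookkeeping (`regate()` reproduces the significant set exactly
  from the re-imported file), a significant-only table in the shape of the
  headline results table, and a forest-plot table with `β ± 1.96·se`
  intervals.

# Known limitations

* The reverse-MR gate, like the underlying design, cannot distinguish
  reverse causation from strong mediated forward signal when the exposure
  GWAS is large enough to detect the mediated effects at the instrument
  threshold (no Steiger filtering is implemented; it is out of scope).
* The weighted-median p-value relies on a bootstrap-normal approximation.
* The PRESSO distortion test uses random same-size subsets as its null;
  with very few instruments its resolution is limited.
* The conjunctive gate trades sensitivity for specificity by construction;
  see the gate table above for the expected attrition of true positives.
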