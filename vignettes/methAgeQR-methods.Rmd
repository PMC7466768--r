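---
title: "Methods: quantile-regression age models across methylation platforms"
author: "methAgeQR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantile-regression age models across methylation platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`methAgeQR` estimates chronological age from a small panel of CpG
β-values by linear quantile regression. For quantile level τ the fit
minimises the pinball loss

$$ \sum_i \rho_\tau\!\big(y_i - b_0 - x_i^\top b\big), \qquad
   \rho_\tau(u) = u\,(\tau - \mathbb{1}[u < 0]), $$

whose minimiser is the τ-th conditional quantile of age given the
β-values. Three quantiles are fitted by default: q10 and q90 bound a
prediction interval with nominal 80% coverage, and q50 — median
regression — supplies the point estimate. The reference methodology
behind these models is interval-centric and does not prescribe a point
rule; we take the median as the natural point summary and record it as a
package assumption.

The working assumptions are: (i) each marker's mean methylation is
approximately linear in age over the modelling window (18–75 years);
(ii) conditional age quantiles are approximately linear in the β-panel,
which holds when trajectories are linear with roughly Gaussian
inter-individual noise; and (iii) platform effects act per CpG, either
affinely (offset/scale) or through a monotone dye-gain curve. None of
these assumptions is needed for the solver itself — it returns the exact
loss minimiser for whatever data it is given.

## Exact optimisation

The pinball-loss problem is a linear program. We solve its dual,

$$ \max_a\; y^\top a \quad \text{s.t.}\quad X^\top a = (1-\tau)X^\top \mathbb{1},
   \quad 0 \le a \le 1, $$

with a two-phase bounded-variable simplex written for this package. The
basis has $p+1$ elements (one per coefficient), so one iteration costs
$O(np)$ and cohorts of thousands of samples with a 3-CpG panel solve in
fractions of a second. At optimality the simplex multipliers are the
regression coefficients: the optimal hyperplane interpolates $p+1$
sample points, which is also what makes an independent test oracle
possible — on small instances one can enumerate *all* hyperplanes
through $p+1$ points and verify the returned loss is the global minimum.
The test suite does exactly that on 200 random instances
($n \le 12$, $p \le 2$) and requires agreement within $10^{-8}$;
observed gaps are at the $10^{-13}$ level.

Numerical choices: pivot tolerance $10^{-9}$; Dantzig pricing with a
Bland's-rule fallback after 50 consecutive degenerate pivots (guarantees
termination); rank-deficient designs and $n \le p+1$ are rejected up
front. With multiple optimal bases any optimum may be returned, so tests
compare losses, never coefficients, in ambiguous cases. Quantile
crossing (a q10 prediction above q90, possible in finite samples under
extrapolation) is resolved by swapping the bounds and flagging the
sample; crossings are detected with a $10^{-9}$-year tolerance so that
machine-precision ties on degenerate noiseless data are not reported as
crossings. Refitting under non-crossing constraints was considered and
rejected as beyond the reference methodology.

# Agreement between platforms

Two platforms measuring the same samples are compared by Bland–Altman
analysis: differences $d_i = x_i - y_i$ (first-listed platform minus
second) against means $(x_i + y_i)/2$. The limits of agreement are
$\bar d \pm 1.96\,s_d$ with the $n-1$ sample SD — the standard
Bland–Altman convention. The acceptance band is fixed *a priori* at
$\pm 1.96 \times 0.05 = \pm 0.098$, i.e. the inter-technology deviation
tolerated if platforms disagreed no more than accepted intra-technical
replicate variance (SD ≤ 0.05). A pair is acceptable only when **both**
limits lie inside the band; a small mean difference with wide limits is
not sufficient. Two diagnostics accompany each comparison: Shapiro–Wilk
normality of the differences (recommended, not essential), and a
uniformity regression of differences on means — a significant slope
means the bias changes across the measurement range, which rules out
interchangeable use regardless of the limits. Degenerate zero-residual
regressions get conventional p-values (exact zero slope → p = 1,
exact trend → p = 0) with a logged flag, since the t statistic is
undefined there. Raw p-values at α = 0.01 are reported throughout; no
multiple-testing correction is applied across CpGs or pairs.

# Z-score harmonisation

Per-CpG standardisation $z = (\beta - \mu)/\sigma$ removes affine
platform bias exactly: if platform B reports $a + c\beta$ with $c > 0$,
B's z-scores equal the underlying ones. The dye-gain distortion is not
affine, but over the 0.2–0.6 stretch a single marker traverses it is
close to linear, so standardisation removes most of that bias too.

Two design choices deserve explanation:

**Granularity.** Statistics are computed per *platform block*, not per
pooled dataset. Scaling a pooled multi-platform training set with a
single mean/SD would leave the between-platform offsets in place, which
is precisely what the transform exists to remove.

**Reference statistics.** By default a dataset is standardised with its
own statistics (self-standardisation), which needs no calibration data.
This is only valid when the dataset's age distribution resembles the
training design: the per-CpG mean and SD are driven by the cohort's age
composition, so a test panel spanning 18–99 years standardised against
itself is shifted and compressed relative to an 18–75 training cohort,
and predictions degrade badly (we observed median errors near 10 years
in exactly this configuration). Whenever calibration data measured on
the test platform under the training age design exist — in the study
layout, each platform's own training cohort — their statistics should be
used instead, via `predictAge(..., zscore_stats = )`. The study
orchestrator and the cross-validation loop do this automatically (CV
standardises held-out folds with the training remainder's statistics;
folds are too small for stable self-standardisation).

# Training-set harmonisation

Training cohorts are harmonised before fitting: ages floored to integer
years, the window 18–75 applied inclusively, and within each year of age
at most two samples retained (uniformly at random under a recorded
seed). This flattens the age distribution and equalises cohort sizes so
that per-platform models are comparable. The operation is idempotent and
its output order is deterministic. Test samples outside the window are
still predicted — extrapolation to ages up to 99 is an intended use,
flagged only through the resulting wider errors.

# Evaluation

MAE here is the **median** absolute prediction error (the field's
convention for these models — robust, and not to be confused with the
mean absolute error); RMSE is the usual quadratic mean. %CP±5 and %CP±PI
are the percentages of samples predicted within ±5 years and within
their q10–q90 interval. Both membership tests are inclusive, with a
$10^{-8}$-year boundary tolerance so that degenerate zero-width
intervals produced by noiseless data are handled correctly in floating
point. Cross-validation uses a seeded random partition into k = 10
near-equal folds and pools all held-out predictions before computing
metrics (rather than averaging per-fold metrics). Differences in
absolute prediction error between platforms are tested by one-way ANOVA
at α = 0.01.

# The synthetic-cohort generator

No public cohort accompanies the reference training data, so the
package's study design runs on synthetic cohorts that emulate their
statistical structure:

- **Trajectories.** Each CpG follows
  $\beta = \text{intercept} + \text{slope}\cdot\text{age} + N(0, \sigma_{bio})$,
  clipped to $[0,1]$. The default panel has an ELOVL2-like steep
  hypermethylating marker (intercept 0.08, slope 0.0075/y, σ 0.035), an
  FHL2-like shallower one (0.10, 0.0045/y, σ 0.030) and a MIR29B2-like
  hypomethylating one (0.90, −0.0045/y, σ 0.035). These give
  single-marker age SDs of ~5–8 years and 3-marker median errors in the
  2–4-year range typical of published blood panels.
- **Platforms.** Observed values are
  $\text{clip}_{[0,1]}(\text{offset} + \text{scale}\cdot g(\beta) + N(0, \sigma_{tech}))$
  per replicate, with $g(\beta) = g\beta/(g\beta + 1 - \beta)$ the
  dye-gain curve of SBE peak-ratio calling: it fixes 0 and 1, is
  strictly increasing, and deviates most mid-range — the divergence
  pattern semi-quantitative platforms show against quantitative ones.
  The default quantitative platforms carry only small offsets
  (−0.02…+0.01) and σ_tech = 0.015; the default SBE platform carries a
  +0.12 offset on the ELOVL2-like marker, gain 1.6 on the MIR29B2-like
  marker, duplicate measurements, and σ_tech = 0.05 — the accepted
  intra-technical replicate SD, which is also the value behind the
  0.098 agreement threshold. Published per-platform bias magnitudes are
  only observable as mean differences (≈0.12 for the ELOVL2/SBE
  contrast), so the defaults are configurable emulation choices, not
  asserted ground truth.
- **Cohort designs.** `uniform` draws integer ages uniformly;
  `one_per_year` cycles through the integer years one sample per pass,
  so one- and two-per-year panels (58 and 116 samples over 18–75) are
  exact. All generators are seeded and record their seed in the output
  metadata; with biological and technical SDs at zero the whole pipeline
  is deterministic regardless of seed.

What the generator does **not** emulate: cell-composition effects on
blood methylation, bisulfite-conversion efficiency differences, amplicon
length or DNA-input effects, nonlinear (e.g. logistic) age trajectories,
and age-dependent biological variance. Consequently, passing tests show
that the statistical machinery behaves as specified under a
well-specified linear model — they do not certify accuracy on real
cohorts, where trajectory curvature and heteroscedasticity shift
coverage away from nominal.

# Problem sizes and reproducibility

The test suite and the acceptance script size their simulations for
desk-scale runs: interval-coverage checks use 20 seeds of n = 500
train/test cohorts (nominal 80%, accepted band 75–85%); the dye-bias
transfer experiment uses 20 seeds of a 116-sample training design and an
84-sample one-per-year panel; solver exactness uses 200 random small
instances against the enumeration oracle; calibration checks use 200
replicate datasets of n = 84 and 5000 simulated differences. Every
stochastic step takes an explicit seed, and study runs write a manifest
(config digest, package and R versions, timestamps) sufficient to
reproduce deterministic stages bit for bit.

# Known limitations

- Linear quantile regression cannot capture the flattening of
  methylation trajectories at high ages; real panels above ~80 years
  will show systematic underestimation that no platform harmonisation
  fixes.
- Self-standardisation transfers platform bias into age bias when the
  test cohort's age composition differs from the training design (see
  above); the package mitigates but cannot remove the need for
  calibration data in that case.
- The dye-gain rescue by z-scoring is approximate: strong gains
  (g ≳ 3) over wide β-ranges leave a nonlinear residual that
  standardisation cannot absorb.
- Quantile fits at q10/q90 need moderate cohort sizes; below ~50
  training samples the interval endpoints are noisy and coverage
  deviates from nominal.
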