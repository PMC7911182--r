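---
title: "Methods: compositional analysis of dietary fatty acids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional analysis of dietary fatty acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facoda)
```

This vignette documents the statistical model, the synthetic-cohort
generator, the numerical conventions, and the judgement calls behind
`facoda`. It is the reference for *why* the defaults are what they are; the
README shows *how* to run the pipeline.

## 1. The compositional model

The exposure is the four-part fatty-acid composition
$\mathbf{x} = (x_\text{SFA}, x_\text{MUFA}, x_{\omega 6}, x_{\omega 3})$,
each part the share of total fatty-acid intake, closed to
$\sum_j x_j = \kappa = 100$. Only ratios of parts are informative: adding
the raw grams to a regression confounds amount with pattern, and the
closure constraint makes the covariance matrix of raw shares singular and
its correlations spurious. The package therefore works in Aitchison
geometry throughout.

**Log-ratio transforms.** With $g(\mathbf{x})$ the geometric mean of the
parts,

$$\operatorname{clr}(\mathbf{x})_j = \ln\frac{x_j}{g(\mathbf{x})},
\qquad \sum_j \operatorname{clr}(\mathbf{x})_j = 0 .$$

Isometric log-ratio (ilr) coordinates are
$\mathbf{z} = V^\top \operatorname{clr}(\mathbf{x})$ for an orthonormal
$D\times(D-1)$ contrast matrix $V$. `pivot_basis()` builds the *pivot*
basis, whose first coordinate isolates the first-listed part against the
geometric mean of the rest:

$$z_1 = \sqrt{\tfrac{D-1}{D}}\,
\ln\frac{x_1}{g(x_2,\dots,x_D)} .$$

**Dispersion.** The variation matrix
$T_{ij} = \operatorname{var}\,\ln(x_i/x_j)$ (sample variance, $N-1$
divisor) is the scale-invariant dispersion summary; `variation_matrix()`
computes it from the clr covariance as
$T_{ij} = S_{ii} + S_{jj} - 2S_{ij}$, which the tests verify against a
brute-force double loop. The compositional center is the vector of
per-part geometric means of the closed shares (`comp_geometric_mean()`).
Note the reported center is *not* re-closed after taking geometric means —
the published reference values sum to 99.2, not 100 — and
`reference_estimates()` preserves that convention.

## 2. Outcome regression with rotating pivots

For outcome $y$ (log-transformed for LDL-C, HDL-C, AST, ALT, GGT), the
model is ordinary least squares on the ilr coordinates plus confounders
$\mathbf{c}$:

$$y = \beta_0 + \boldsymbol\beta^\top \mathbf{z} +
\boldsymbol\gamma^\top \mathbf{c} + \varepsilon .$$

Because every pivot basis spans the same $(D-1)$-dimensional space, the
fitted values, $R^2$, residual SD and the composition-block $F$-test are
identical whichever part is pivoted first. `fit_compositional()` refits the
model $D$ times, once with each part in first position, and reports the
first coordinate of each rotation: the interpretable "this fatty acid
relative to the geometric mean of the others" effect, with its own $t$-test.
The rotation-invariance of fitted values is checked to $10^{-9}$ on every
fit and exposed in `$diagnostics`.

The full clr coefficient vector is recovered from the first-pivot
estimates as

$$a_j = \sqrt{\tfrac{D-1}{D}}\;\beta_j^{(\text{first}=j)},
\qquad \sum_j a_j = 0 .$$

For $D = 4$ the factor is $\sqrt{3}/2 \approx 0.866$.
`clr_from_first_pivot()` inverts published coefficient tables this way and
also reports the residual $r = \sum_j a_j$: for an exact fit it is zero,
so a nonzero $r$ measures how much rounding the printed table carries
(about $-0.0087$ for the reference LDL-C row, i.e. two-decimal rounding).
Downstream reconstructions use the vector as given rather than forcing the
zero-sum, so the reconstruction error stays attributable to the source
table.

**Reallocation change matrices.** For mean composition $\bar{\mathbf{x}}$
and a transfer of $\delta$ points from part *from* to part *to*
(`reallocate()`), the predicted outcome change is

$$\Delta = \mathbf{a}^\top\bigl(\operatorname{clr}(\bar{\mathbf{x}}') -
\operatorname{clr}(\bar{\mathbf{x}})\bigr),$$

reported as $e^\Delta$ (a ratio) for log-scale outcomes. `change_matrix()`
tabulates all ordered pairs with the *receiving* part on rows and the
*donor* on columns; `change_matrix_from_fit()` does the same from a fitted
model via `predict_change()`, an independent ilr-coordinate path that the
tests compare to the clr path to $10^{-10}$. Defaults: $\delta = 4$
percentage points, $\bar{\mathbf{x}}$ = the reference geometric mean
$(36.1, 38.9, 20.0, 4.2)$. Transfers with $\delta \ge \bar{x}_\text{from}$
are undefined (`NA`); donors left with under 25% of their share are
flagged as extrapolation — with $\delta = 4$ this always flags the
4.2-point omega-3 share, a caution the output prints.

**Isocaloric substitution models** (`fit_substitution()`) are the
traditional comparator: OLS of the outcome on total energy (kcal),
protein %E, carbohydrate %E, three of the four fatty acids in %E, and
fat-without-fatty-acids %E (`fat_e - fa_total_e`), plus confounders. With
total energy and all other energy sources held, the coefficient of an
included fatty acid is the effect of substituting 1 %E of it for the
omitted one (omega-6 in the SFA model, SFA otherwise). The
reparameterization identity — the SFA-for-omega-6 coefficient equals minus
the omega-6-for-SFA coefficient — holds exactly when the two models span
the same column space and is verified in the tests.

**Confounder sets.** Set A: age, sex, energy, carbohydrate %E, sodium,
physical activity, sleep, screen time, single-parent household, siblings.
Set B adds BMI z-score and is used for the blood-based and blood-pressure
outcomes (LDL-C, HDL-C, SBP, DBP, AST, ALT, GGT), where adiposity is a
plausible mediator-confounder; zBMI itself uses set A.

## 3. The synthetic cohort generator

No subject-level data ship with the package. `generate_cohort()` draws a
cohort whose *published summary statistics* match the reference study: a
school-based sample of 5485 Japanese eighth-graders (12–14 y). The
defaults in `cohort_config()` *are* the study conditions; they are not
tuning knobs.

**Composition.** The fatty-acid composition is logistic-normal:
$\operatorname{clr}(\mathbf{x}) \sim \mathcal{N}(\boldsymbol\mu, \Sigma)$
with closure applied after exponentiation.

- $\Sigma$ comes from the target variation matrix by double-centering,
  $\Sigma = -\tfrac{1}{2} G\,T\,G$ with $G = I - \tfrac{1}{D}\mathbf{1}\mathbf{1}^\top$
  (`clr_cov_from_variation()`). A variation matrix is *realizable* only if
  this $\Sigma$ is positive semi-definite; the function rejects matrices
  with an eigenvalue below $-10^{-8}$. Published, rounded variation
  matrices are typically near the realizability boundary, which matters
  for calibration (below).
- $\boldsymbol\mu$ is calibrated by `calibrate_center()` so that the
  *closed* draws reproduce the target geometric means: closure makes the
  map from $\boldsymbol\mu$ to realized geometric means nonlinear, so a
  fixed-point iteration $\mu_j \mathrel{+}= \ln(\text{target}_j /
  \text{achieved}_j)$ runs on a pilot sample with common random numbers
  (the same standard-normal draws reused every iteration, so the
  iteration solves a deterministic equation rather than chasing noise).
  Ratios converge in one step; any residual common-scale misfit reflects
  the rounded targets (geometric means summing to 99.2 with a variation
  matrix fixed independently), not the iteration. Defaults: pilot size
  $10^5$, tolerance 0.05 on the closure ($\kappa$) scale, 50 iterations
  maximum, failure is an error rather than a warning.

**Diet and covariates.** Fatty-acid %E total
$\sim \mathcal{N}(26.2, 5.1^2)$ truncated to $\pm 4$ SD; fat %E is the
deterministic `fa_total_e / 0.87` (fatty acids are 87% of fat energy in
the reference marginals, 26.2/30.1); per-acid %E columns are the closed
shares times `fa_total_e/100`. Energy $\sim \mathcal{N}(2238, 640^2)$ kcal,
protein $\mathcal{N}(14.2, 2.4^2)$ %E, carbohydrate
$\mathcal{N}(54.2, 6.7^2)$ %E, sodium $\mathcal{N}(1848, 429^2)$ mg, age
$\mathcal{N}(13.56, 0.29^2)$ y, sex Bernoulli(0.521 male). Truncated
normals use the inverse-CDF construction (`qnorm(runif(...))` between the
bound quantiles), which is exact and vectorized.

Confounder marginals not available in the published tables — physical
activity (0.5 active), sleep hours ($7.3 \pm 0.9$), screen-time category,
single-parent household (0.12), sibling count — were set once to plausible
values for Japanese eighth-graders and are independent of the composition
by default. They exist so that adjusted models have realistic design
matrices; they carry no configured confounding.

**Outcomes.** Each outcome is linear in $\operatorname{clr}(\mathbf{x})$
with coefficient vector $\mathbf{a} = \tfrac{\sqrt{3}}{2}\,
\boldsymbol\beta_\text{ref}$ taken from the reference first-pivot rows,
plus Gaussian noise. Log-scale outcomes are generated as
$\exp(\mathcal{N})$ with $\sigma_{\log} = \sqrt{\ln(1 + \mathrm{CV}^2)}$
from the published mean/SD (LDL-C $\approx 0.216$), and the intercept
absorbs the realized mean of the linear predictor and the
$-\sigma^2_{\log}/2$ lognormal correction so the arithmetic mean matches
its target. Confounder effects $\boldsymbol\gamma$ default to zero;
`cohort_config()` accepts overrides for every block.

**What the generator does and does not emulate.** It reproduces: the
compositional center and variation matrix, the dietary and demographic
marginals, the outcome means/SDs, and the composition–outcome clr effects.
It does not reproduce: between-covariate correlations (diet–activity,
sex-specific intakes), measurement error structure, school-level
clustering, or non-linear dose response. Conclusions about *estimator
behavior* transfer; conclusions about *biology* do not.

**Exclusions.** `apply_exclusions()` mirrors the study's eligibility
screen, applied in order with each record tallied at its first failing
rule: (1) missing required fields, (2) implausible energy intake outside
[0.5 × EER_low(sex), 1.5 × EER_high(sex)], bounds inclusive, (3) prevalent
disease, (4) LDL-C ≥ 140 mg/dL (dyslipidemia referral threshold,
inclusive). The EER bounds default to the Japanese Dietary Reference
Intakes for ages 12–14 (male 2300–2900, female 2150–2700 kcal/day, lowest
to highest physical-activity level); they are package defaults, not values
printed in the reference tables, and `filter_config()` makes them
overridable.

## 4. Numerical conventions

- **Closure constant** $\kappa = 100$ everywhere; all log-ratio machinery
  is closure-invariant, and tests assert ratio-scale change-matrix entries
  move by less than $5\times 10^{-4}$ under re-closure of the inputs.
- **Quantiles and ties.** Quintile cut points use the type-7 sample
  quantile (R's default); ties at a cut point go to the *lower* category.
- **Variance divisor** $N-1$ throughout, matching `stats::var`.
- **Truncation** at 4 SD for all truncated normals: wide enough to leave
  moments essentially unchanged, tight enough to exclude physically
  impossible intakes.
- **PSD tolerance** $-10^{-8}$ on eigenvalues when validating
  realizability; calibration tolerance 0.05 closure units, chosen to sit
  above the irreducible misfit of rounded published targets (~0.03) and
  below anything that would bias the acceptance-scale quantities.
- **Degenerate designs fail loudly.** `fit_compositional()` and
  `fit_substitution()` error on aliased coefficients and name them, rather
  than silently dropping columns; one genuine case is documented below.

## 5. Decisions on under-specified points

- *Change-matrix orientation*: rows are the receiving part, columns the
  donor, matching the published LDL-C block (the SFA-column entry of the
  omega-6 row is 0.981, the SFA→omega-6 transfer).
- *Reference center not re-closed*: the published geometric means sum to
  99.2; re-closing them would shift every reconstructed ratio, so they are
  used as printed.
- *`fat_other_e` collinearity*: because the generator sets
  `fat_e = fa_total_e / 0.87` deterministically, the
  fat-without-fatty-acids term is an exact linear function of protein and
  carbohydrate whenever %E closes exactly. Substitution models keep the
  term by default (it is estimable on default generator output, where %E
  does not close exactly), and `include_fat_other = FALSE` is provided for
  span-matched comparisons.
- *Omega-3 extrapolation*: $\delta = 4$ against a 4.2-point share is
  reported, but flagged; the flag threshold (donor retains <25% of its
  share) is deliberately conservative.
- *Exclusion order and inclusive bounds* are fixed as listed above so the
  tally is reproducible; reordering rules changes the tally but not the
  retained set.

## 6. Problem sizes and limitations

Routine analyses run at the study size ($n = 5485$) in well under a
second. Recovery checks in the test suite use $n = 2\times 10^5$ (sampling
SE of a geometric mean ≈ 0.015 closure units, comfortably inside the 0.05
check tolerance) and a 1000-replicate null simulation at $n = 500$ for the
type-I error of the first-coordinate $t$-test. Calibration's pilot sample
of $10^5$ dominates generator start-up (~1 s).

Limitations: the four-part composition ignores within-class heterogeneity
(e.g. trans fats, individual omega-3 species); effects are linear in clr
coordinates, so the change matrix extrapolates linearly in log-ratio space;
the generator's independence assumptions mean adjusted and unadjusted fits
coincide in expectation on synthetic data, which is a feature for testing
and a caveat for interpretation; and cross-sectional data cannot support
the causal reading that the substitution vocabulary invites.
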