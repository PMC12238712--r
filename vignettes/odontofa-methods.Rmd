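---
title: "Methods: composite dental FA, mixed-data factor analysis, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite dental FA, mixed-data factor analysis, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odontofa)
```

## The scientific problem

Fluctuating asymmetry (FA) is the random, non-directional component of
left–right differences in bilateral traits. Under the standard developmental
view, a well-buffered organism produces both sides of a trait from the same
genome under the same conditions, so signed differences $d = R - L$ should
be centred on zero with small variance; physiological stress during
development widens that variance. Dental traits — here, molar intercuspal
distances in millimetres — are attractive FA substrates because enamel does
not remodel: an adult tooth preserves a record of conditions during crown
formation in infancy and gestation.

`odontofa` implements a complete analysis chain for this setting:

1. a **pre-FA screening battery** that removes traits whose apparent
   asymmetry is dominated by observer or measurement error, and tests for
   the patterned biases (directional asymmetry, antisymmetry, size
   dependence) that invalidate FA as an instability measure;
2. a **composite FA index** aggregating per-trait unsigned asymmetries into
   one z-standardised score per individual, dichotomised into high versus
   low/average FA;
3. **factor analysis of mixed data (FAMD)** over a table of quantitative
   and categorical early-life covariates, with **regularised iterative FAMD
   imputation** of missing cells;
4. **sex-stratified logistic regression** of the high-FA indicator on the
   retained latent dimensions;
5. a **synthetic cohort generator** with known ground truth so that every
   stage can be validated end-to-end without access to restricted
   growth-study records.

## The QC battery

Each trait passes through, in order:

* **Replicate bias** — a paired two-sided $t$-test of second-session minus
  first-session measurements on the twice-measured cast subset. A
  Holm-significant shift means systematic observer drift; the trait is
  dropped. If the paired differences have zero variance but nonzero mean
  the $t$ statistic is undefined and the trait is flagged as exact bias.
* **Error versus asymmetry** — the trait is dropped when mean
  $|m_2 - m_1|$ (replicate error) strictly exceeds mean $|R - L|$: its
  asymmetry signal cannot be distinguished from error. Equality does not
  exclude.
* **Grubbs scan** — iterative two-sided Grubbs tests on $d$ confirm
  irregular raw values; the critical value comes from the
  $t$-quantile formula
  $G_{crit} = \frac{n-1}{\sqrt{n}}\sqrt{t^2_{\alpha/(2n),\,n-2}/(n-2+t^2)}$.
  Removal is **cell-level**: only the individual's value for that trait is
  discarded, not the individual.
* **Directional asymmetry** — a one-sample $t$-test of mean $d$ against 0.
* **Antisymmetry** — an Anscombe–Glynn kurtosis test on $d$; antisymmetry
  (one side consistently larger, but randomly which) produces a bimodal,
  platykurtic distribution, so the flag requires the kurtosis deviate to be
  significant *and negative*. A Shapiro–Wilk omnibus p-value is reported
  alongside but is informational. For $d$ so extremely platykurtic that the
  Anscombe–Glynn transformation leaves its domain, the deviate saturates at
  $-\infty$ (p of zero), which is the correct decision in that regime.
* **Size dependence** — Spearman correlation (tie-averaged ranks) between
  $|d|$ and $(R+L)/2$, pooled and within sex; groups below 5 observations
  are skipped with a reason code.

P-values are Holm-corrected (sequential Bonferroni) across traits, with
**one family per test kind**. By default only the error screens and a
low-presence rule (below 25% of the sample carrying the trait) force
exclusion; the pattern tests are reported, and `qc_config(exclude_on_bias =
TRUE)` makes them exclusionary for sensitivity analyses. These choices —
the specific normality-deviation tests, $\alpha = 0.05$, the family
definition, and the presence cutoff — are stated in the output rather than
hidden, because the analysis tradition names the conditions to screen for
but not one canonical test battery.

## The composite FA index

For each retained trait, unsigned asymmetries are z-standardised over every
individual carrying the trait (sexes pooled, sample standard deviation with
$n-1$). An individual's raw composite is the mean of their observed
per-trait z-scores; individuals with fewer than $\lceil T/2 \rceil$
observed traits (10 of 20; 8 of 15 for deciduous-style variants) are
excluded, because a composite over very few traits can sit several standard
deviations from the mean by sampling noise alone. The composite is then
z-standardised **over the included individuals**, and "high FA" is the
strict indicator $z > 1$ (a value exactly at the cutoff is low/average).
Deciduous-trait variants are the same code path with a different trait set
and threshold — nothing else differs.

## FAMD from its weighted SVD

A quantitative column enters as $(x - \bar x)/s_n$ with the
$n$-denominator standard deviation; the indicator column of category $k$
with proportion $p_k$ enters as $(y_k - p_k)/\sqrt{p_k}$. With row weight
$1/n$, the squared singular values of $X/\sqrt n$ are the eigenvalues; a
quantitative variable contributes 1 and a categorical variable with $K$
observed levels contributes $K-1$ to total inertia, so the decomposition
reduces exactly to correlation-matrix PCA when all variables are
quantitative, and to the proportion-weighted indicator decomposition when
all are categorical. Individual coordinates are $\sqrt n\,U D$ (variance
$\lambda_l$ per dimension, $n$ denominator); the contribution of column $c$
to dimension $l$ is $100\,v_{cl}^2$, summed over a variable's categories
for variable-level contributions; for a quantitative column the column
coordinate equals its correlation with the dimension. The
$n$-denominator convention keeps this inertia bookkeeping exact.

SVD signs are arbitrary, so each dimension is flipped to make its
largest-magnitude column coordinate positive — deterministic output across
platforms. Dimension retention is a user decision made from
`screeplot_data()`; the package never picks the dimensionality silently.

## Regularised iterative imputation

FAMD cannot tolerate missing cells. `impute_famd()` initialises missing
quantitative cells at column means and missing categorical cells at the
observed category proportions (fuzzy memberships), then iterates: encode,
decompose, reconstruct with `ncp` components using shrunken singular values
$d_l(d_l^2 - \hat\sigma^2)/d_l^2$ (where $\hat\sigma^2$ is the mean
discarded eigenvalue — the regularisation that keeps the loop from
overfitting noise), back-transform to the original scales, overwrite
**only** the missing cells, and recompute all means, scales and proportions.
Convergence is declared when the summed squared change in the imputed
cells, relative to the previous iteration, drops below `tol` (default
1e-6, capped at 1000 iterations with a warning). `ncp = 0` degenerates to
plain mean/proportion imputation in one pass.

Fuzzy categorical memberships are clamped to be nonnegative and renormalised
to sum to one; downstream FAMD consumes the fuzzy memberships directly,
while hard assignments (highest membership) are exported for inspection.
`ncp` defaults to 5; an automatic cross-validated choice of `ncp` is
deliberately out of scope — the default can be varied by hand and the
missingness here (under 5% per variable) makes the fit insensitive to it.
The algorithm contains no randomness, so results are reproducible by
construction; the `seed` argument exists only to shield downstream draws.

## Regression stage

High FA is regressed on the retained dimension scores by maximum-likelihood
logistic regression (IRLS, tight convergence control), separately per sex,
with Wald tests per term and the residual-deviance lack-of-fit p-value
$P(\chi^2_{n-p} > D_{res})$. Dimension scores enter unscaled, exactly as
FAMD produces them, so coefficients are per dimension-unit. Possible
complete separation is flagged rather than silently reported. The
descriptive helpers mirror the conventions that reproduce hand
computation: the 2×2 high-FA-by-sex chi-square uses **no continuity
correction**, and two-group comparisons use Welch's $t$ with fractional
Welch–Satterthwaite degrees of freedom.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the emulated study conditions: 303
individuals (149 F, 154 M); 20 bilateral traits with mean sizes evenly
spaced over the 2–7 mm intercuspal range and per-trait FA standard
deviations 0.06–0.14 mm; a 30-cast subset measured twice with 0.03 mm
re-measurement error; 21 mixed covariates (6 quantitative, 15 categorical,
frequencies emulating a 1950s Ontario growth cohort, e.g. ~42% breastfed)
driven by four latent factors (parental age; breastfeeding; socioeconomic
status; parental condition), several variables being pure noise; under-5%
MCAR covariate missingness.

Developmental instability enters as a log-linear scale on the asymmetry
standard deviation, $s_i = \exp(\sum_d \beta_{d,\,sex(i)} z_{id})$ with
$d_{it} \sim N(DA_t, (\sigma_t s_i)^2)$ — the minimal FA-as-variance model
consistent with FA theory. Defaults inject female-only effects
$\beta_2 = -0.25$, $\beta_4 = -0.30$ (all male $\beta = 0$). Sides are
built as $L = T_{it} - d_{it}/2$, $R = T_{it} + d_{it}/2$ around an
individual trait size $T_{it}$.

Two calibration choices deserve comment:

* **Measurement-cell missingness** is a two-component mixture: most
  individuals have per-cell observation probability 0.905, while 3% are
  "sparsely cast" with probability uniform on (0.15, 0.65). A single
  Bernoulli rate cannot simultaneously give a realistic mean observed-trait
  count (~17.8 of 20) and a non-negligible fraction (~2%) of individuals
  falling below the 10-trait threshold; the mixture reproduces both, giving
  an analysed sample averaging ~297 of 303.
* **High-FA prevalence.** Under a Gaussian composite the expected high-FA
  fraction is $P(Z > 1) \approx 15.9\%$, and the generator's null
  configuration ($\beta = 0$) reproduces it. At the default female effects
  the pooled composite is a mixture of a constant-scale male population and
  a lognormal-scale female population — leptokurtic, so the measured
  fraction drops to ~11% (about 20% in females, 2% in males). This is a
  real property of the variance model at these effect sizes, reported as
  such rather than retuned away.

The generator does **not** emulate: realistic covariance between
odontometric traits (traits are conditionally independent given $s_i$),
longitudinal multi-age casting, familial structure, or MAR/MNAR
missingness. Passing recovery tests therefore demonstrate that the
pipeline's logic is correct under its own assumptions, not that real dental
data satisfy those assumptions.

`inject_pathology()` amends a config so chosen traits violate exactly one
screened assumption — inflated replicate error (in multiples of the
trait's $\sigma_t$), a DA mean shift (mm), a two-mode antisymmetry mixture
(mode separation in mm), or size-dependent asymmetry (a power exponent) —
which is how the QC battery's selectivity is tested: a 28-trait
configuration with 6 error-inflated and 2 rarely-expressed traits passes
exactly 20 traits through the screen.

## Numerical and design choices

* Per-trait standardisation uses the $n-1$ standard deviation (it
  standardises data, not an encoding); FAMD encoding uses $n$ (it keeps
  inertia bookkeeping exact). Both are stated on the functions.
* Zero-variance traits are dropped from the index with a warning;
  zero-variance encodings are errors (impute or drop first).
* Ties at the high-FA cutoff go to 0 (strict inequality); contribution
  ranking ties break by variable name for determinism.
* Degenerate inputs (constant vectors, single-class outcomes, rank
  deficiency, all-missing rows) error or flag early with the offending
  variable named, never silently.
* All randomness in a cohort flows from the single `generate_cohort()`
  seed through a fixed draw order, so any intermediate table is
  reproducible from (config, seed) alone.

## Validation strategy and problem sizes

The test suite checks every closed-form statistic against independently
coded textbook formulas, FAMD against PCA/MCA limits and an `eigen()`-based
dense oracle, the logistic fit against direct likelihood maximisation, and
the pipeline against the generator's ground truth. Monte-Carlo calibration
uses 400 null cohorts for the screens' family-wise error (binomial-CI
bound), 200 for the Wald type-I rate, 100 for the sign-recovery regression
(frozen from a pilot at a ≥90% female-sign recovery rate), and 50 paired
cohorts for the imputation-versus-mean comparison; these sizes put the
Monte-Carlo error comfortably below the margins being asserted while the
full suite completes in about two minutes. In those runs the female
dimension-2/4 slopes average about −0.64 and −0.88 with lack-of-fit
p-values near 1, male slopes centre on zero, and the Wald type-I rate sits
at 4.5–5%.

## Known limitations

* Single-rater replicate design only; no inter-observer or Procrustes
  ANOVA error partitioning.
* One analysis value per trait-side (the "optimal cast" convention);
  multi-cast longitudinal measurement selection is out of scope.
* Single imputation: no between-imputation uncertainty propagated into the
  regressions.
* Wald-based inference only; no Firth correction for the rare-event male
  stratum, where separation is flagged but not repaired.
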