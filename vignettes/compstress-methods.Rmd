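---
title: "Methods: compositional activity and salivary biomarker trajectory models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional activity and salivary biomarker trajectory models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compstress)
```

## The problem

During a school morning (08:30-12:30), a child's time splits exhaustively into
sedentary behavior (SB), light physical activity (LPA) and moderate-to-vigorous
physical activity (MVPA). These three fractions are a *composition*: they sum
to 1, so they cannot be treated as independent regressors. `compstress` models
how this composition relates to the within-morning trajectory of two salivary
biomarkers — cortisol (the classic HPA-axis stress marker, which normally
declines through the morning) and circulating cell-free DNA (cfDNA, a candidate
acute exercise/stress marker) — in two groups of students: an intervention
group taught outdoors in a forest (IG) and an indoor-taught control group (CG).

Saliva is sampled at 08:30, 10:30 and 12:30. Each day's trajectory is reduced
to two summary indices computed on the natural-log concentration scale:

* **AUCi** — area under the trajectory with respect to increase: the
  trapezoidal ground area minus baseline × elapsed time,
  $\mathrm{AUCi} = \sum_i \tfrac{m_{i+1}+m_i}{2}(t_{i+1}-t_i) - m_1 (t_n-t_1)$.
  Negative for a declining morning.
* **PR** — peak reactivity, implemented as change from baseline at each
  post-baseline timepoint: $m_2 - m_1$ (midmorning) and $m_3 - m_1$ (noon).

Logging comes *first*, indices second: both indices can be negative, so the
reverse order would be undefined. PR's exact published definition lives in
supplementary material we do not reproduce; the per-timepoint reading is the
one under which a midmorning/noon covariate in the PR models is well defined,
and a `max_minus_baseline` switch provides the obvious alternative.

## The hierarchical model

For each of four model families (BHLM 1: cortisol PR, 2: cortisol AUCi, 3:
cfDNA PR, 4: cfDNA AUCi) the response $Y_i$ of student $id_i$ is

$$Y_i \sim N\!\big(\alpha_{id_i} + \beta_{cmp}^\top (grp_i \times x_{[1:3]i})
 + \beta_{ssn} x_{4i} + \beta_{gdr} x_{5i} + \beta_t x_{6i},\; \sigma_y^2\big)$$

where $x_{[1:3]i}$ is the closed SB/LPA/MVPA row. Compositions enter **raw**
(no ilr/clr transform). The composition block is expanded to six columns —
each behavior interacted with the group indicator — so each behavior gets a
group-specific slope, labeled `SB (CG)` … `MVPA (IG)`.

Collinearity of the raw composition (its three columns sum to the constant
vector) is controlled by a ridge prior with *alternative hierarchical
centering*: all six slopes share $\beta_{cmp,j} \sim N(\mu_\alpha, 1)$, and the
single hyper-mean $\mu_\alpha$ doubles as the center of the random-intercept
distribution. Because each composition row sums to 1, a common shift of the
six slopes acts exactly as a grand intercept, so $\mu_\alpha$ absorbs the
overall level while $\alpha_{id} \sim N(0, \sigma_\alpha^2)$ carries subject
deviations. The weakly identified within-composition contrasts are shrunk
toward $\mu_\alpha$ by the unit-precision ridge; the strongly identified level
is driven by the data.

### Priors and their two readings

The cortisol models use $\mu_\alpha, \beta_{ssn}, \beta_{gdr}, \beta_t \sim
N(0, 5)$ and half-Cauchy$(0, 5)$ scales; the cfDNA "reference" models use
super-vague $N(0, 10^{-6})$ and half-Cauchy$(0, 25)$. Two notational
ambiguities are resolved as explicit switches on `prior_set()`:

* `normal_second_arg`: the second Normal argument is read as a **precision**
  (JAGS convention; default). This is the only reading under which
  $N(0, 10^{-6})$ is "super-vague" — as a variance it would be an extremely
  informative sd of 0.001. The `"variance"` reading remains available.
* `half_cauchy_on`: the half-Cauchy is placed on the **standard deviations**
  (the usual recommendation for variance components; default) although the
  source notates $\sigma^2$; `"variance"` applies it to the variance with the
  Jacobian correction.

Season (3 levels), gender and timepoint enter as indicator contrasts with
reference levels fall / female / midmorning, each indicator receiving the
table prior. The source writes single coefficients $\beta_{ssn}$ etc.; with
three seasons that notation forces either integer coding or contrasts, and we
choose contrasts (reference levels documented here and in `build_design()`).
Responses and covariates are not standardized; coefficients are on the raw
log-index scale.

### Sampling

The posterior is sampled by a self-contained Gibbs sampler (`run_mcmc()`): the
slope vector, the random intercepts and $\mu_\alpha$ are conjugate Normal
blocks; $\sigma_y$ and $\sigma_\alpha$ get stepping-out slice updates on the
log scale under their half-Cauchy priors. Chains initialize overdispersed from
the priors (scale draws truncated to a numerically safe band) and are
reproducible from the seed (chain $c$ uses `seed + c - 1`). The default
schedule is the published one — 50,000 iterations, 25,000 burn-in, thinning
10 — and the chain count is **3**, inferred from the maximum reported
effective sample size 7,500 = 3 × 2,500 retained draws; it is configurable
because the source does not state it.

Diagnostics follow the modern defaults: split-chain Rhat;
autocorrelation-based ESS with Geyer initial-positive-sequence truncation
(capped at the retained draw count); DIC with the classic $p_D = \bar D -
D(\bar\theta)$ variant matching the JAGS toolchain the analysis names;
posterior predictive tail probabilities for mean/sd/min/max. Coefficients are
displayed with the interval shading rule: black = 0 outside the 95% credible
interval, gray closed = 0 outside the 50% but inside the 95%, gray open =
0 inside the 50% (`classify_credibility()`).

## Accelerometry

Epoch-level vector-magnitude counts are classified by cut-points: SB if
counts ≤ `sb_max`, MVPA if ≥ `mvpa_min`, LPA between (ties are assigned
outward by definition, since the source is silent). The `"romanzini_vm"`
preset ships 180 / 757 counts per 15-s epoch, the commonly used
child/adolescent vector-magnitude thresholds; the numbers are deliberately
*configuration*, to be confirmed against the calibration study, never
constants. Epoch length defaults to 15 s (common for child cut-points; not
stated in the source) and scales the preset. A day is closed into a
composition by label frequencies; days under `min_wear_minutes` (default 120
of the 240-minute window) are flagged invalid and excluded from modeling. No
non-wear-detection algorithm is applied — the only non-wear mechanism modeled
is sensor loss, which right-truncates the series because children were
instructed not to re-attach a fallen sensor.

The descriptive compositional mean is the component-wise geometric mean,
re-closed. Zero parts are first replaced multiplicatively (each zero set to a
configurable floor, the rest of the row shrunk proportionally) — the standard
compositional treatment; with replacement disabled, a zero part is an error
naming the row.

## The synthetic cohort: a stated world

`simulate_study()` generates cohorts with the structure the analysis assumes,
so every stage runs and is testable without the study's (supplementary-only)
data. Stated values: 48 students (37 IG / 11 CG), three seasons with one
measurement day each, samples at 8.5/10.5/12.5 h. Where the source states no
number, values were chosen once on field-realism grounds and are not tuned:

* log-cortisol baseline $\log 9$ (≈ 9 nmol/L at 08:30, a typical child
  morning value) with diurnal slopes −0.20/h (IG) vs −0.10/h (CG),
  implementing the stronger IG decline; season shifts 0/−0.10/−0.15.
* log-cfDNA baseline $\log 100$ with small timepoint bumps and **no** seasonal
  pattern; the source itself reports no clear cfDNA tendency, and realistic
  child salivary cfDNA ranges are unknown — these defaults are configurable,
  not claimed realistic.
* $\sigma_\alpha = 0.30$, $\sigma_y = 0.25$ (log scale), and a
  between-subject diurnal-slope sd of 0.05/h. The slope heterogeneity is an
  addition to the stated parameter list: a purely additive subject intercept
  cancels exactly in PR/AUCi, so without it the index-scale model would have
  no subject effect to estimate.
* group mixtures IG (0.50, 0.32, 0.18) vs CG (0.62, 0.30, 0.08) — CG more
  sedentary, less MVPA — constant across seasons (no seasonal composition
  differences were observed), jittered per student-day by a
  Dirichlet(60 × mixture) draw.
* missingness: 10% saliva-day dropout; sensor-loss 3% (fall, spring) and 12%
  (summer — sensors fell off in warm weather).

Counts are drawn from a 3-state mixture whose state probabilities are the
student-day composition and whose state distributions straddle the configured
cut-points, so classification recovers the mixture in expectation. The
injected composition effect enters the log-concentration with a linear ramp
from baseline to the last sample, so the noon change-from-baseline recovers
exactly $\beta_{grp}^\top x$. Generation is on the natural-log scale
(matching the analysis's transform) and exponentiated for output realism.

What the generator does **not** emulate: raw 100 Hz acceleration (counts are
generated at epoch level), assay noise structure beyond log-Normal, cortisol's
increasing within-day variance, pulsatile secretion, or informative
missingness. A green recovery test therefore establishes sampler and pipeline
correctness under the stated world, not validity of the scientific
conclusions for real cohorts.

## Numerical choices

* Closure checks at 1e-12 for emitted compositions; 1e-8 when validating
  modeling input (CSV round-trips).
* The slope block is sampled via a Cholesky solve of the 10×10 (PR) or 9×9
  (AUCi) conditional precision; no matrix inversion.
* Slice sampling uses unit step width with stepping-out capped at 50 steps —
  tuning-free and exact, at ≈3–8 density evaluations per update.
* Constant chains: Rhat is defined as 1 (with a warning) and ESS as the total
  draw count (with a warning); negative $p_D$ is reported with a warning
  rather than suppressed.
* Zero sds are admitted in `true_params()` so noise-free closed-form tests
  are expressible; realistic configurations keep them positive.

## Limitations

The cfDNA models are intentionally a "reference" analysis under super-vague
priors; their deviance is expected to be high and their posteriors diffuse.
Complete-case joining (per model) is the only missing-data treatment, as the
source implies. The exact published cut-point numbers, epoch length and PR
formula are not printed in the source; all three are explicit configuration
with documented defaults. The three-timepoint schedule itself biases trajectory
indices relative to denser sampling designs; no correction is attempted.
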