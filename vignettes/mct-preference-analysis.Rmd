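---
title: "Modelling GP and public preferences for multi-cancer tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling GP and public preferences for multi-cancer tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mctchoice` implements a complete stated-preference workflow for multi-cancer
early-detection tests (MCTs): a discrete choice experiment (DCE) in which
general practitioners (GPs) and members of the public repeatedly choose
between two hypothetical tests described by seven attributes, and the models
that turn those choices into preference estimates, trade-offs and rankings.
This vignette is the package's account of the science: the models and their
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices behind the
implementation.

## The descriptive system

`mct_schema()` defines the seven attributes: positive predictive value (PPV:
20/40/60/80%), negative predictive value (NPV: 96/99/99.5/99.9%, shown to
GPs as risk of cancer after a negative test), waiting time (1 week vs 1–2
weeks), number of cancers tested for (1/5/10/25), whether the test
identifies the cancer site, the form of the test (blood/faecal/urine/breath)
and early-stage detection. Level counts (4,4,2,4,2,4,2) give
$4\cdot4\cdot2\cdot4\cdot2\cdot4\cdot2 = 2048$ distinct profiles,
enumerated by `enumerate_profiles()` in lexicographic order.

Because presenting PPV and NPV simultaneously confused pilot respondents,
the public sample is split: the PPV arm never sees the NPV attribute and
vice versa, so each public respondent faces 6 attributes while GPs face all
7. The package represents arm views by setting the hidden attribute to `NA`;
encoding maps `NA` to zero in both alternatives so the attribute drops out
of that respondent's likelihood (arm-specific utility functions — nothing is
imputed).

## Experimental design

`generate_design()` builds 24 binary tasks in 2 blocks of 12. The criterion
is the Bayesian D-error
$E_\beta\,[\det I(\beta)]^{-1/K}$, where $I$ is the binary-logit information
matrix of the encoded design, normalised per task so that duplicating tasks
leaves the criterion unchanged, and the expectation runs over quasi-random
draws from a normal prior (default 100 draws). For split designs the
criterion is the 50/50 average of the per-arm D-errors, each arm evaluated
with its own utility function — the hidden attribute's columns dropped.

The search is a balanced-start coordinate exchange: the start assigns each
level of each attribute exactly $48/L$ of the 48 alternative slots at
random, and improvement proposals are pairwise level swaps between slots,
which preserve exact balance by construction. A proposal is rejected if it
makes the two profiles of a task identical or lets one weakly dominate the
other on the monotone attributes (PPV ↑, NPV ↑, cancers ↑, site yes ≻ no,
early yes ≻ no, 1 week ≻ 1–2 weeks; form is treated as non-monotone).
Dominance screening is conventional for D-efficient generators; it
sacrifices a little statistical information for tasks that actually involve
a trade-off. `n_sweeps` controls search effort (default 200 sweeps of one
proposal per attribute per task); the analysis scripts use 60 sweeps and the
test suite 10, which already beat the median random balanced design by a
wide margin (ratio ≈ 0.55 in step 01). The seed fixes the start, the
proposals and the prior draws, so designs are exactly reproducible.

The shipped priors (`design_priors.yaml`) are pilot-scale stand-ins: mild
monotone accuracy preferences with variance 0.04. They shape the design
search only, never the estimators.

## The synthetic-data generator

No public dataset exists for this design, so `generate_respondents()` and
`simulate_choices()` produce one from known ("true") parameters; every
downstream stage is tested against that truth. The generator inverts exactly
the assumptions the estimators make:

* 251 GPs on the full design and 1005 public respondents randomised 50/50
  to the PPV or NPV arm and 50/50 to one of two blocks of 12 tasks;
* binary demographics at prevalences matched to the emulated samples
  (age ≥ 65: 0.25, female: 0.51, ethnic minority: 0.20, degree: 0.43);
  rural/suburban/urban come from a single three-way draw (0.23/0.46/0.31)
  because the indicators are mutually exclusive — the one place the
  "independent covariates" idealisation must bend;
* a latent cancer-knowledge/experience score $LV_n = \gamma'z_n + \eta_n$,
  $\eta_n \sim N(0,1)$, generating three binary indicators through logit
  measurement equations and a 0–16 symptom-recognition count through an
  ordered logit with 16 cut-points;
* individual utility coefficients
  $\beta_n = \beta + \mathbb{1}[\text{public}]\,\delta + \kappa' c_n +
  \tau\,LV_n + \sigma \circ \xi_n$, with one standard-normal draw $\xi_n$
  per respondent (panel structure), and utilities
  $\lambda_n\, x'\beta_n$ plus independent standard Gumbel noise per
  alternative (inverse-CDF of uniforms); the argmax is the stated choice.

The fixture truth (`true_parameters()`) transcribes published GP and public
odds ratios onto the log-odds scale so synthetic runs are qualitatively
faithful; it is illustrative, not the original study's estimate. Levels the
source does not report are filled in deliberately: GP PPV coefficients are
extended log-linearly below the reported 60%-level value; the GP NPV-96%
coefficient is back-derived from the reported GP marginal rate of
substitution (32.4 PPV points for NPV 99.9→96) and the linearised PPV
slope; the public NPV-96% coefficient uses the printed odds ratio 0.64
directly, which makes the package's public MRS come out near 14 rather than
the printed 12.5 — the two printed numbers are not mutually consistent
without the original full-model coefficients, and the direct transcription
wins. The GP-vs-public scale truth, 0.407, is the ratio of the one PPV
log-odds ratio printed for both groups; the NPV-arm multiplier 1.15 is
illustrative.

What the generator does **not** emulate: quota screening, dropouts,
speeders, duplicate or nonsense responses, attribute non-attendance,
ordering or framing effects, and any mixing distribution other than the
normal. Passing recovery tests therefore certify that the estimators invert
this generating process at these sample sizes — not that real survey data
are this clean.

## The pooled mixed logit

`estimate()` with `canonical_pooled_spec()` fits the pooled GP + public
model by simulated maximum likelihood:

$$\log L = \sum_n w_n \log \frac1R \sum_{r=1}^R \prod_t
  P_{nt}\big(\lambda_n\, x'(\beta + \mathbb{1}_{pub}\delta + \sigma\circ\xi_{nr})\big)$$

* **Dummy coding.** Categorical attributes enter as level-vs-reference
  indicators (references: PPV 80%, NPV 99.9%, 1 week, blood, site no,
  early no); the number of cancers enters linearly per 10 cancers.
* **Random coefficients.** The six PPV/NPV level coefficients are normal
  with panel structure; which terms are random is configurable (`random =`),
  since the original specification is unpublished. Spreads are estimated
  unconstrained with an $|\sigma|$ interpretation.
* **Scales.** GPs are the reference ($\lambda = 1$); public utilities carry
  $\lambda_{pub}$; the public NPV arm additionally carries $\lambda_{arm}$.
  Both are estimated on the log scale, so positivity is structural.
* **Sample interactions.** Public shifts $\delta$ sit on the NPV, cancers,
  site, early-stage and form terms but *not* on PPV or waiting time. This
  is an identification requirement, not a stylistic choice: with shifts on
  every term, $\lambda_{pub}(\beta+\delta)$ collapses into one free
  quantity per term and the GP-vs-public scale is unidentified. The shared
  PPV terms anchor $\lambda_{pub}$.
* **Weights.** $w_n = 0.5\,N_{total}/N_{group}$, so the four-times-larger
  public sample does not dominate. Because weighting invalidates the plain
  inverse Hessian, the reported covariance is the respondent-clustered
  sandwich (numerical Hessian bread from the analytic gradient,
  score-outer-product meat).

Simulation draws are scrambled Halton sequences (prime bases, first 50
points dropped, seeded Cranley–Patterson rotation), R = 500 per respondent
by default, sliced per respondent from one stream. Optimisation is BFGS
with fully analytic gradients (verified against central finite differences
to 1e-6 relative); mixed models start from the fixed-coefficient logit
solution with spreads at 0.1, which keeps iteration counts modest.
Likelihood evaluations are numerically guarded (one-`exp` stable
log-logistic; probabilities floored at 1e-300 in the ordered block).

`refine_interactions()` implements backward refinement: fit the full model,
repeatedly drop the single interaction with the smallest $|t|$ below 1.96
and refit, never touching main effects. Threshold 0 returns the full model
unchanged.

## The ICLV model

`estimate_iclv()` estimates the Integrated Choice and Latent Variable system
jointly: the structural equation (latent variable on six demographics, unit
disturbance variance), the measurement equations (logit for the three
binary indicators, ordered logit for the symptom count — links chosen for
consistency with the logit choice kernel; the source names neither), and
the choice model whose PPV-60, site and early-stage terms shift with the
latent variable ($\tau$). The simulated likelihood integrates the latent
disturbance with the same Halton machinery (a dedicated dimension of the
same stream); at $\tau = \zeta = 0$ it separates exactly into choice and
measurement likelihoods, which the tests assert to 1e-8.

Identification: disturbance variance fixed at 1; no structural intercept
(the location is absorbed by the measurement intercepts — the tests verify
the exact invariance); the screened-indicator loading constrained positive,
implemented by sign-flipping a converged fit into the canonical mode (the
two modes are exactly likelihood-equivalent). Cut-points are parameterised
as a free first cut plus log-increments, so they are strictly increasing by
construction. "Ever tested for cancer" is included as a third binary
indicator (the survey asks it), configurable off via `measurement_spec()`.

`factor_loadings()` provides the motivating one-factor principal-axis
solution (squared-multiple-correlation communalities). It is deliberately
*not* iterated by default: on near-independent indicators, communality
iteration feeds noise back into itself and inflates loadings; iterated to
its fixed point on genuinely one-factor data it agrees with
`stats::factanal` to ~0.01. `latent_scores()` returns posterior-mean latent
scores by reweighting the simulation draws with each respondent's joint
likelihood contributions; at the fixture effect sizes and n = 1005 they
correlate ≈ 0.85 with the hidden generating scores.

## Post-estimation

`group_coefficients()` maps a pooled fit to per-group effective
coefficients: GPs are the base terms; the public gets
$\lambda_{pub}(\beta+\delta)$, the PPV-arm scale — the NPV-arm multiplier
is excluded from reporting as a survey-format artifact. `odds_ratios()`
exponentiates these with 95% Krinsky–Robb intervals (10000 seeded draws
from the asymptotic normal; a non-PSD covariance is repaired by eigenvalue
clipping with a warning).

`ppv_slope()` converts the dummy-coded PPV levels into utility per
percentage point by least squares through (20, β₂₀), (40, β₄₀), (60, β₆₀),
(80, 0) — a linear contrast, so its variance is exact. The source reports
that the required PPV gain does not depend on the PPV starting point, which
is what justifies a single slope; the residual from the line is returned
for inspection. `mrs_npv_ppv()` forms the marginal rate of substitution
$-\Delta\beta_{NPV}/s$ with a delta-method CI from the analytic gradient;
the scale parameters cancel in the ratio (verified as an invariance test),
and a slope with $|t| < 1$ flags the result unstable rather than erroring.

## Ranking against a benchmark

`rank_against_benchmark()` evaluates all 2048 profiles at the group's
coefficient means with the group scale applied and computes each profile's
binary-logit probability of being chosen over the benchmark. Prediction at
the coefficient means (no mixing integration) ranks at representative
preferences; the benchmark profile — PPV 76%, NPV 98%, 1–2 weeks,
identifies the site, blood, early-stage, with its >50 cancer types clamped
to the design maximum 25 — has off-grid accuracies evaluated by
piecewise-linear interpolation between adjacent level coefficients (the
reference level contributing zero). "Preferred in X% of cases" is the share
of profiles whose probability against the benchmark is strictly below 0.5;
exact ties (e.g. the benchmark against itself) count as not preferred by
the benchmark and are logged. The FIT/PSA/CA125 comparator profiles shipped
in `benchmarks.yaml` are labelled illustrative: the originally used values
are not republished here, so theirs are clinically plausible placeholders
(single-cancer tests, PPV clamped at the 20% design floor).

## Problem sizes and what the tests show

The recovery experiments fit 500 GPs + 2000 public (pooled mixed logit, 30
parameters, R = 500) and 2000 public (ICLV, 46 parameters, R = 500),
asserting every generating parameter within 3 reported standard errors;
the refinement size/power study runs 50 replicates of 250 respondents per
scenario; the analysis scripts use the emulated study sizes (251 + 1005).
These sizes make the whole suite run in minutes on one CPU while leaving
the asymptotic approximations comfortably valid. Known limitations: BFGS
with simulated likelihoods can in principle stop at local optima (the
two-stage starts mitigate this); simulation chatter of order
$1/\sqrt{R}$ remains in the spread estimates, and at study-scale samples a
single spread can collapse to zero for some data realisations, where its
standard error is boundary-unreliable (the reproduction script reports
spread recovery separately from mean-coefficient recovery for this reason); the delta-method MRS interval
is first-order and the Krinsky–Robb cross-check in the tests bounds the
discrepancy at 10% of the interval width; and all recovery statements are
conditional on the generator's idealisations listed above.
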