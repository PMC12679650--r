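---
title: "Matching-adjusted indirect comparison: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching-adjusted indirect comparison: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maickit)
```

## The problem

Two phase III trials in immunoglobulin A nephropathy (IgAN) compared an
active treatment against a renin–angiotensin-system-inhibitor (RASi)
control: an *index* trial for which individual patient data (IPD) are
available, and a *comparator* trial reported only as published aggregates.
The trials enrolled measurably different populations (age, sex, race,
baseline eGFR and proteinuria), all of which are prognostic for IgAN
progression, so a naive cross-trial comparison of the two active agents is
confounded. `maickit` implements the standard population-adjustment remedy,
the matching-adjusted indirect comparison (MAIC): reweight the index-trial
IPD so its baseline moments equal the comparator's published aggregates,
re-estimate the index trial's treatment effects under those weights, and
combine them with the comparator's published effects.

## Weight model

Let $x_i$ be the vector of matched baseline summaries for subject $i$
(raw values for mean targets, strict 0/1 threshold indicators for
proportion targets) and $\theta$ the target moments. With centered
covariates $c_i = x_i - \theta$, MAIC weights take the exponential-tilt
form $w_i = \exp(c_i^\top \beta)$, and the method-of-moments $\beta$ is the
minimizer of the convex objective

$$Q(\beta) = \sum_i \exp(c_i^\top \beta),$$

whose gradient $\sum_i w_i c_i$ vanishes exactly when every weighted moment
equals its target. `solve_weights()` minimizes $Q$ by damped Newton
iteration with step halving from $\beta = 0$, on internally sd-scaled
columns for conditioning, stopping when the gradient norm falls below
$10^{-10} n$ (cap 200 iterations). A step is accepted if it does not
increase $Q$ beyond rounding resolution ($10^{-9}$ relative), which keeps
full Newton steps viable once the objective is flat at machine precision.
Feasibility is checked first: each target must lie strictly inside the
observed range of its column (both levels present for binary columns);
already-balanced columns are flagged and dropped; centered columns with
pairwise correlation above $1 - 10^{-10}$ (coincident threshold indicators)
are dropped with a warning rather than failing. Reported weights are
rescaled to sum to $n$ for presentation; models consume the raw relative
weights, and every downstream quantity is invariant to that rescaling. The
effective sample size is $(\sum w)^2 / \sum w^2$.

Anchored matching pools both index arms into one fit against the overall
comparator population. Unanchored matching fits each arm separately against
the corresponding comparator arm; arm-specific conventions (such as a lower
UACR threshold for the active-vs-active match) are expressed through the
arm-specific target sets, not through code paths.

## Outcome models

eGFR is analyzed as absolute change from baseline and UPCR/UACR as log
post-baseline/baseline ratios, each with a mixed-effects model for repeated
measures (MMRM): fixed effects for treatment, visit, baseline (log baseline
for ratio endpoints), baseline-by-visit and treatment-by-visit, and an
unstructured within-subject residual covariance. Because the fixed-effect
structure is saturated by visit, the model reduces to a per-visit weighted
ANCOVA under complete data; with one visit that equivalence is exact and is
asserted to $10^{-8}$ in the tests. Estimation is iterative generalized
least squares: a weighted GLS step for the coefficients given the
covariance, then a pairwise weighted residual cross-product update with a
residual degrees-of-freedom correction (denominator $n - p/V$ per pair),
iterated until the weighted restricted log-likelihood changes by less than
$10^{-8}$ relative (cap 100). Missing visit values simply drop out of their
subject's likelihood block — no imputation. If the unstructured update
loses positive definiteness, the fit falls back to compound symmetry with a
warning; residual variances are floored at $10^{-10}$ so degenerate
(noise-free) fixtures remain well defined. MAIC weights are treated as
fixed, and all contrast standard errors come from a robust sandwich
estimator $A^{-1} B A^{-1}$ — uncertainty in the estimated weights is not
propagated (a bootstrap would be the natural extension). Least-squares
means are evaluated at the weighted mean baseline of the analysis set.

The composite endpoint is the first of: confirmed 40% eGFR reduction (a
visit at or below 60% of baseline, confirmed at the next scheduled visit,
dated at the first qualifying visit — "confirmed" has no published rule, so
the next-visit convention is this package's choice), end-stage kidney
disease, or death; otherwise censoring at the last visit. The weighted Cox
model for the active-vs-control hazard ratio is fitted by
`survival::coxph` with Efron tie handling and a robust standard error; an
event-free arm returns an infinite-interval flag rather than an error.

## Cross-trial synthesis

Published comparator effects arrive as point estimates with 95% intervals;
ratio scales are log-transformed before the standard error is extracted as
$(u - \ell) / (2 \times 1.959964)$. That z-multiplier is used for every
interval in the package; intervals are normal-theory throughout because the
source reports give no degrees-of-freedom detail. The anchored synthesis is
a two-trial fixed-effects network with a shared anchor: normal likelihoods
for both relative effects, independent $N(0, \sigma_0^2)$ priors on the two
basic parameters, and the active–active contrast as the difference of the
conjugate posteriors. The closed form is always computed; an optional
direct posterior sampler (default $4 \times 10{,}000$ draws when enabled)
serves as an internal check and must agree within three Monte-Carlo
standard errors. With the default vague prior $\sigma_0 = 100$ the
posterior reproduces the Bucher estimate and standard error to well within
$10^{-3}$ of their scale; the prior and chain settings of the original
analysis were not published, so these defaults are recorded in the run
manifest rather than asserted as the originals. The unanchored pipeline
reweights each index arm to its comparator counterpart and contrasts the
two reweighted arms through the weighted outcome models, which is how the
source describes its sensitivity analysis; a generic
`unanchored_contrast()` for published arm-level effects is provided as
well. Log-scale results back-transform monotonically to geometric mean
ratios, hazard ratios, or percent changes.

Sign convention: contrasts are always active minus control, and cross-trial
results are always index-active versus comparator-active, so a positive
eGFR mean difference denotes benefit of the index treatment.

## The synthetic study conditions

Real IPD for either trial is proprietary, so the package ships a generator
that emulates the published study conditions and makes every stage testable
offline. The defaults are fixed once, as follows.

* **Sample sizes and marginals.** The bundled scenarios use $n = 364$
  (index) and $n = 404$ (comparator) with the published baseline columns as
  marginal targets: age 42.70 vs 46.00 years, male 65.93 vs 69.80%, White
  75.55 vs 67.33%, eGFR 57.87 vs 56.95 ml/min/1.73 m², mean UPCR 1.48 vs
  1.44 g/g, UACR > 1.1 g/g 40.66 vs 50.00%, urinary protein > 1.8 g/day
  65.66 vs 50.00%.
* **Marginal families.** Age and eGFR are truncated normals (SD 12 years on
  [18, 85]; SD 13 on [15, 105] ml/min/1.73 m² — spreads typical of adult
  IgAN trial populations); sex and race are Bernoulli; UPCR, UACR and 24-h
  protein are log-normal with log-SDs 0.55, 0.70 and 0.60, the right order
  for proteinuria distributions whose means sit near 1.5 g/g. Locations are
  solved so the *analytic* moments equal the targets exactly (truncated-normal
  location by root finding; log-normal $\mu = \log m - \sigma^2/2$ for a
  mean target, $\mu = \log t - \sigma \Phi^{-1}(1-p)$ for a threshold
  target). Where a covariate carries both a mean and a threshold target,
  the threshold wins, with a message.
* **Joint structure.** A Gaussian copula with a fixed correlation matrix:
  the three proteinuria measures strongly positive (0.75–0.85), eGFR mildly
  negative against proteinuria (−0.20 to −0.25) and age (−0.30). The real
  joint distribution is unpublished; this matrix is an explicit assumption.
* **Trajectories.** eGFR visits are baseline + arm-by-visit mean change +
  subject intercept (SD 4) + exchangeable-correlation residuals (SDs 5/6/8
  at months 9/12/24, correlation 0.5); proteinuria ratios follow the same
  structure on the log scale. Index-trial defaults show the
  treat-then-withdraw pattern of a 9-month course (+1.0/−0.5/−3.0 vs
  −4.0/−5.5/−9.0 control, i.e. roughly a 4.5 ml/min/1.73 m²/year untreated
  decline); comparator defaults show a sustained on-treatment separation.
  An optional modifier term lets the active effect shift by `coef` per unit
  of a covariate (or threshold indicator), which is how the
  effect-modification stress tests are built.
* **Events.** Terminal events (ESKD/death, split 60/40) come from a Weibull
  proportional-hazards model (shape 1.2, rate 0.0035, log HR −0.3 for
  active, log-hazard loadings −0.02 per eGFR unit and +0.40 per log-UPCR
  unit), administratively censored at month 24 — a low two-year event rate,
  as expected in a slowly progressing nephropathy. Confirmed 40% eGFR
  reductions arise from the trajectories themselves.
* **Exact finite-sample calibration.** `calibrate_trial_moments()`
  deterministically pins a drawn sample onto a printed column: shifts for
  age/eGFR, rescaling for positive measures, count flips for binary
  covariates, and a rescale placing exactly `round(n p)` subjects strictly
  beyond a threshold. Visit series are shifted/rescaled with their
  baselines so change scores and ratios are untouched. Count-valued moments
  are exact to the integer resolution of $n$ (e.g. 240/364 = 65.93%).
* **Seeds.** All randomness flows from one integer seed; paired scenarios
  derive child seeds through a fixed affine-mod scheme, so runs are
  reproducible and trials are independent.

What the generator does *not* emulate: dropout and intercurrent events,
titration schedules, measurement rounding, non-Gaussian dependence, or the
real trials' unpublished joint distributions. Passing tests therefore
demonstrate correctness of the estimation machinery under a faithful but
idealized data-generating process, not replication of the real trials'
effect estimates — the published effective sample size (208 of 364) and
headline contrasts depend on the proprietary IPD and are out of reach by
construction; on calibrated synthetic data the ESS lands in the same
general range (about 230–250, seed-dependent) but is not expected to match.

## Problem sizes and verification

The test suite checks the solver against grid-search and bisection oracles
on 100+ random small instances ($n \le 20$, up to 3 covariates), the Cox
fit against a brute-force partial-likelihood maximizer, the Bayesian
synthesis against its closed form and a 10⁶-draw Monte-Carlo difference of
normals, and the full anchored pipeline against a known +3 ml/min/1.73 m²
active–active difference over 200 replicate paired scenarios at 200
subjects per arm (estimator mean within Monte-Carlo error of the truth,
95% interval coverage required to land in 93–97%). Coverage smoke tests at
50 replicates use a binomial three-standard-error band around the nominal
level, since the tighter band only has meaning at the full replication
size. An effect-modification stress (effect 4 ml/min/1.73 m² stronger
above 1.8 g/day urinary protein, populations differing in that proportion)
verifies over 100 replicates that the unadjusted Bucher comparison is
biased while the MAIC-adjusted one is not.

## Known limitations

Weight uncertainty is not propagated (fixed-weight sandwich only). The
MMRM's covariance update is an EM-flavored iterative GLS, exact for
complete data and an approximation to restricted likelihood under
missingness. No trimming or truncation of extreme weights is offered, and
no outcome-regression (simulated treatment comparison) alternative. The
network is exactly two trials with one shared anchor — no multi-trial
networks, random-effects synthesis, or inconsistency checks. Like every
MAIC, validity rests on having matched all effect modifiers and on
cross-trial exchangeability, neither of which the data can verify.
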