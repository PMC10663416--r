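---
title: "Count-based regression modelling of PET arterial input functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-based regression modelling of PET arterial input functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(aifcount)
```

## The problem

Quantitative PET with arterial sampling needs the arterial input function
(AIF): the concentration of unmetabolized radiotracer in arterial plasma
over the examination. The AIF is never observed directly. It is composed
from several measurement streams — a continuous whole-blood detector (the
automatic blood sampling system, ABSS) running at about 1 Hz for the first
ten minutes, manual whole-blood and plasma samples counted in a gamma
counter at scheduled times out to 90 minutes, and a handful of
parent-fraction determinations — each with its own equipment, volumes,
durations and error sources.

The conventional workflow converts each raw count into a concentration,
applies a chain of corrections (decay, dispersion, blood-to-plasma ratio,
parent fraction), and then fits a curve by nonlinear least squares with an
ad hoc weighting scheme. But the raw observations are *counts*: they are
non-negative, integer, and have a variance tied to their mean. This
package instead models the counts directly:

$$y_i \sim \mathrm{Poisson}(\lambda_i), \qquad
  \log \lambda_i = f(t_i, \theta) + \log \tau_i,$$

where $f$ is the decay-corrected parent-plasma rate (counts/s/mL at
injection-time calibration) and $\tau_i$ is a known per-sample *exposure*
collecting every conventional correction as a multiplicative offset:

$$\tau_i = \underbrace{d_i}_{\text{duration}}
  \cdot \underbrace{v_i}_{\text{volume}}
  \cdot \underbrace{e^{\rho v_i}}_{\text{counter calibration}}
  \cdot \underbrace{2^{-t_i/T_{1/2}}}_{\text{decay}}
  \cdot \underbrace{\delta_i}_{\text{ABSS dispersion}}
  \cdot \underbrace{r(t_i)}_{\text{blood/plasma ratio}}
  \cdot \underbrace{PF(t_i)^{-1}}_{\text{parent fraction}}.$$

With the log link the offset enters as an additive $\log\tau_i$ with
coefficient fixed at one, and the count distribution supplies the correct
mean-variance weighting automatically. Where counts are more variable
than Poisson — which is what the diagnostics show on realistic data — the
negative binomial with variance $\mu + \psi\mu^2$ ($\psi = 0$ recovers
the Poisson) absorbs the overdispersion.

## Offset conventions

The algebraic direction of each offset component follows one rule: the
model predicts the *true* parent-plasma rate, and $\tau_i$ maps it to the
*measured* expected counts. Hence:

* the parent fraction enters as a divisor (whole plasma holds
  $1/PF$ times the parent counts);
* the whole-blood-to-plasma ratio $r(t)$ multiplies whole-blood samples
  and is exactly 1 for plasma samples;
* the ABSS dispersion component is `uncorrected / corrected` — the factor
  that re-applies the tubing smearing to the modelled true curve — and is
  exactly 1 for manual samples drawn after the 10-minute cutoff, which
  bypass the tubing.

Two offset components are themselves estimated. The blood-to-plasma
ratio is a penalized thin-plate spline (basis dimension 10, REML
smoothing, Gaussian working family) fitted to the ratio of decay-matched
count rates of paired whole-blood/plasma draws; predictions are held
constant beyond the sampled range and floored at a small positive value
because a spline fitted to very noisy ratios can overshoot below zero.
The parent fraction uses a three-parameter Hill-type sigmoid
$pf(t) = a + (1-a)/(1+(t/t_{50})^k)$, which satisfies $pf(0) = 1$, is
non-increasing, and has floor $a$; it is fitted by bounded least squares
from multiple starts over a log-grid of midpoints. The sigmoid form is a
package choice (the fitting seam accepts any parameter object that
evaluates through `pf_sigmoid()`).

External dispersion of the ABSS stream is handled in the classical
deconvolution form: the cumulative true signal equals
$\kappa C_{meas}(t) + \int_0^t C_{meas}$, integrated by the trapezoidal
rule on the uniform 1-s grid and differenced centrally over $2\Delta t$
(one-sided at the ends). The per-sample dispersion factor is computed
from a moving-average-smoothed counts-per-second series (default 9-s
window) rather than the raw 1-s counts: the differencing step amplifies
raw count noise into 10–20% multiplicative noise on the offset, which
would be attributed to the samples rather than the correction.

## Model classes

Four model classes share the engine:

1. **Tri-exponential nonlinear Poisson regression.**
   $f(t) = \sum_{k=1}^3 A_k e^{-\gamma_k t}$, fitted on the
   log-parameterized scale by quasi-Newton search with analytic
   gradients, initialized by curve stripping (exponential peeling with
   segment boundaries equally spaced in log time, matching where
   multi-exponential components separate).
2. **Shape-constrained Poisson GAM.** Cubic B-splines with the
   working-parameter transform
   $\beta_j = \beta_1 - \sum_{l \le j} e^{\delta_l}$, which guarantees a
   non-increasing fitted curve for *every* parameter value; a first-order
   difference penalty acts on the $\delta$ scale.
3. **Thin-plate negative-binomial GAM**, on linear or log time. Log time
   spreads the basis functions to match where the curve actually bends
   (fast early, slow late) and is the preferred configuration.
4. **Hierarchical GAM** across examinations: per-examination intercepts
   and ABSS-bias effects, one global smooth of log time (basis
   dimension 20), and per-examination deviation smooths (dimension 5)
   sharing one smoothing parameter under a full-rank penalty, so
   deviations shrink to exactly zero as the penalty grows.

All single-examination models include an ABSS indicator fixed effect: the
continuous detector reads systematically higher than the gamma counter,
and a single multiplicative factor (uniform on the log scale) absorbs the
cross-calibration difference. Manual samples are the reference;
predictions exclude the bias term unless ABSS reference is requested.

## The engine

The fitting engine is penalized iteratively reweighted least squares with
step-halving, supporting the shape-constraint transform through its
Jacobian inside each iteration (Gauss–Newton linearization plus a
constant correction term). Smoothing parameters — and, for the negative
binomial, $\log\psi$ jointly — maximize the Laplace-approximate REML
criterion

$$\mathcal{V} = \ell(\hat\beta) - \tfrac12 \hat\beta^T S_\lambda \hat\beta
 + \tfrac12\log|S_\lambda|_+ - \tfrac12\log|H + S_\lambda|
 + \tfrac{M_p}{2}\log 2\pi,$$

with $H$ the expected information at the penalized optimum, $|\cdot|_+$
the product of positive eigenvalues, and $M_p$ the penalty null-space
dimension. Effective degrees of freedom are the trace of the influence
matrix; AIC is $-2\ell + 2\,\mathrm{edf}$ (plus one for an estimated
$\psi$). A separate profile-likelihood estimator of $\psi$ (Brent search
on $[10^{-8}, 10]$, refitting coefficients at each candidate) is exposed
for dispersion diagnostics; a boundary solution is reported as
"effectively Poisson".

Numerical choices: inner relative penalized-deviance tolerance $10^{-9}$
(at most 200 iterations), outer criterion tolerance $10^{-7}$, linear
predictor clamped at $\pm 37$, Cholesky solves with escalating jitter
only on indefiniteness. The pipeline is deterministic given the data, so
refits reproduce coefficients exactly.

### Basis constructions

* **B-splines**: knots at covariate quantiles with replicated boundary
  knots; second-order difference penalty.
* **Thin-plate (1-D)**: radial basis $|x - x_j|^3$ on the unique
  covariate values with the $\{1, x\}$ polynomial constraint absorbed and
  the penalized subspace eigen-truncated to $k - 2$ columns; when
  combined with an explicit intercept the smooth drops its constant
  column and is centered.
* **Factor smooths**: one common thin-plate basis built on the pooled
  covariate, replicated per group in block-diagonal columns. The basis is
  put in natural parameterization (penalized columns scaled by
  $1/\sqrt{\lambda_j}$) and all columns standardized to unit RMS under a
  single identity penalty. This keeps every deviation direction —
  including the former null space — in one commensurate metric. An
  earlier construction with per-group bases and a mean-eigenvalue ridge
  on the null space let a data-poor examination purchase an almost free
  linear deviation, dragging the global smooth into a spurious hump; the
  commensurate metric removes that failure mode, and a group with
  arbitrarily few observations needs no special-casing because the basis
  is shared. The contract is unchanged: full-rank penalty, one shared
  smoothing parameter, deviations shrink to zero exactly.

Log-transformation of time, where requested, is applied *before* knot or
basis placement, so the basis functions are spaced evenly where the data
and curvature live.

## The synthetic-data generator

`sim_config()` / `simulate_examination()` emulate the acquisition
protocol that motivated the package: ABSS whole-blood sampling each
second for 10 min (with pre-injection background samples), manual draws
at 1, 3, 5, 7, 9, 10.5, 20, 30, 40, 50, 60, 70, 80 and 90 min (volumes
1–3 mL whole blood, 0.8–1.5 mL plasma, 10 s counting), and parent
fraction at 1, 3, 5, 10.5, 20, 40, 60 and 90 min. The post-peak truth is
a decreasing tri-exponential (defaults $A = (5\times10^4, 10^4,
2\times10^3)$ counts/s/mL, $\gamma = (3, 0.3, 0.03)$ min$^{-1}$, peak at
0.7 min with a linear ascent); whole blood is composed through the true
ratio curve $0.8 + 0.2e^{-t/20}$ and sigmoid parent fraction
$(a, t_{50}, k) = (0.05, 10, 2)$; the ABSS stream is forward-dispersed
by convolution with a unit-mass exponential kernel ($\kappa = 2.5$ s),
biased by a factor 1.10, and contaminated with Poisson background
(2 counts/s). The carbon-11 half-life constant (20.36 min) and the
nominal ABSS draw volume (0.01 mL/s, absorbed with detector efficiency
into the bias term) are package-supplied constants, configurable.

Parent-fraction measurements are drawn as binomial proportions with an
effective HPLC count budget of 2000 per measurement, so their error
scales as $\sqrt{pf(1-pf)/n}$ like a real count-derived fraction; a
constant absolute error would imply large negative-probability artifacts
at late times where $pf \approx 0.06$.

`simulate_suite()` generates several examinations from a shared curve
family (log-normal jitter, SD 0.15 on amplitudes and 0.10 on rates, the
scale of between-subject variation one would call similar-but-distinct),
and `make_missing()` reduces an examination to two manual draws
(first/last, first two, or last two), dropping its ABSS stream by
default so the missing-data experiment genuinely extrapolates over the
removed samples. A flag retains the stream for the other reading of that
experiment.

What the generator does *not* emulate: metabolite chromatography
details, tracer-specific non-monotone descents, internal (vasculature)
dispersion, extraction-efficiency variation, or scanner time-activity
curves. Tests passing on these simulations show the estimators are
correct under the stated data-generating process; they do not certify
performance on any particular real tracer.

## Diagnostics

Randomized quantile residuals — $\Phi^{-1}(u_i)$ with $u_i$ uniform on
the fitted CDF step at $y_i$ — are exactly standard normal under a
correctly specified discrete model, which turns the visual Q–Q
inspection into an assertable check (slope/intercept of the Q–Q
regression, Kolmogorov–Smirnov statistic, moments). They are
deterministic given a seed. The Pearson statistic
$\sum (y_i-\hat\mu_i)^2/V(\hat\mu_i)/(n-\mathrm{edf})$ sits near 1 under
a correct variance function and near $1 + \psi\mu$ when a Poisson fit is
applied to negative-binomial counts. Because the smooth absorbs part of
the sampling variation, the KS check is mildly conservative; only
anti-conservatism would indicate a defect.

## Experiments and study-scale choices

`run_model_evolution()` fits the four model classes per examination and
tabulates AIC, with differences reported against the log-time
negative-binomial reference ($\Delta = AIC_{ref} - AIC_{model}$;
negative favours the reference). `run_pseudo_loo()` implements the
missing-data study: each examination in turn is reduced to two manual
samples while the others keep complete data, the hierarchical model is
refitted, and held-out manual times are scored by absolute percentage
error against both the full-data fit and (for synthetic data) the truth.

Problem sizes used in the shipped tests and acceptance script — 10 to
20 replicate examinations per property, 50–100 replicates for rate-style
checks, 10-examination suites for the hierarchical experiments — were
chosen as the smallest sizes at which the binomial pass/fail bounds are
meaningful. The missing-data resilience check runs on the generator's
default (Poisson) suite: with heavy overdispersion the two retained
samples alone carry ~30% noise and the experiment measures sampling
noise rather than the borrow-strength property. The overdispersion and
model-ordering experiments use $\psi = 0.3$ negative-binomial suites.

## A worked example

```{r example}
sim <- simulate_examination(sim_config(), seed = 1)
prep <- prepare_examination(sim$exam)
fit <- fit_aif(prep, model = "gam", family = "negbin")
fit
predict_aif(fit, c(1, 5, 20, 60, 90))
```

## Known limitations

* Offsets treat the fitted parent fraction and ratio curves as known;
  their estimation error is not propagated (late-time accuracy is
  limited by the parent-fraction floor estimate, the dominant error
  source in the recovery experiments).
* The a-priori dispersion factor is an approximation; modelling the
  forward dispersion inside the likelihood would be the cleaner (and
  heavier) formulation.
* Only the descent of the curve is modelled; the ascent and peak are out
  of scope.
* The tri-exponential's fast component lies on a likelihood ridge when
  data begin at the peak: the fitted curve is accurate while
  $(A_1, \gamma_1)$ individually can wander 10–25%. This is a property
  of descent-only acquisition, not of the optimizer.
* Intervals are empirical-Bayes bands from the penalized-fit covariance,
  interpreted pointwise.
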