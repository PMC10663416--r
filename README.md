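# aifcount

Count-based regression modelling of PET arterial input functions.

## The problem

Quantitative PET with arterial sampling requires the arterial input
function (AIF): the metabolite-corrected radiotracer concentration in
arterial plasma over the examination. The AIF is assembled from raw
gamma **counts** recorded by a continuous automatic blood sampling
system (ABSS) and by a gamma counter on manual whole-blood and plasma
samples, combined with parent-fraction measurements. The conventional
workflow converts counts to concentrations, applies a chain of
corrections, and fits curves by weighted nonlinear least squares —
discarding the one thing the raw data tell us for free, their
mean-variance structure.

`aifcount` models the counts directly with Poisson and
negative-binomial regression:

    y_i ~ Poisson(lambda_i)            (or NegBin(mu_i, psi),
                                        variance mu + psi * mu^2)
    log(lambda_i) = f(t_i) + log(tau_i)

where `f` is the decay-corrected parent-plasma rate and the exposure
`tau_i` collects every conventional correction — counting duration,
sample volume, counter volume calibration `exp(rho * vol)`, radioactive
decay, ABSS external dispersion, blood-to-plasma ratio, and the inverse
parent fraction — as multiplicative offsets. The curve `f` can be a
tri-exponential (nonlinear Poisson regression initialized by curve
stripping), a shape-constrained (monotone-decreasing) B-spline GAM, a
thin-plate spline GAM on log time with REML-selected penalties and a
profiled dispersion, or a hierarchical GAM across examinations with a
global smooth plus penalized per-examination deviation smooths. A
synthetic examination generator with full ground truth emulates the
acquisition protocol (1 Hz ABSS for 10 min, 14 manual draw times to
90 min, 8 parent-fraction times) so every stage is testable offline.

## A worked example

```r
library(aifcount)

sim  <- simulate_examination(sim_config(), seed = 1)  # known ground truth
prep <- prepare_examination(sim$exam)   # background, descent, offsets
fit  <- fit_aif(prep, model = "gam", family = "negbin")
fit
#> AIF model fit: negbin GAM (thin-plate spline, log time, k = 15)
#>   n = 585 samples, edf = 13.59, logLik = -2062.70, AIC = 4154.58
#>   dispersion psi = 0.0000
#>   ABSS bias factor exp(beta_abss): 1.097

predict_aif(fit, c(1, 5, 20, 60, 90))
#>   time_min   estimate      lower      upper
#> 1        1 11824.2274 11787.5790 11860.9898
#> 2        5  3944.4788  3924.0499  3965.0141
#> 3       20  1119.5530  1112.4297  1126.7220
#> 4       60   340.4267   337.2088   343.6753
#> 5       90   149.5292   145.9058   153.2425
```

The generator's true curve at those times is `11838.4, 3952.7, 1122.4,
330.6, 134.4` counts/s/mL: the fitted curve tracks it to about 1% over
most of the range (late times are limited by parent-fraction
estimation), and the true 10% ABSS calibration bias is recovered as
1.097. With the examination simulated as overdispersed counts the same
call selects a positive dispersion `psi` and the negative binomial wins
the AIC comparison; `residuals(fit)` returns randomized quantile
residuals for Q-Q checks, and `plot(fit)` draws data and fitted band.

`fit_hgam_aif()` fits all examinations jointly and remains identified
even when one examination is reduced to two manual samples
(`make_missing()`); `run_model_evolution()` and `run_pseudo_loo()`
orchestrate the model-comparison and missing-data experiments. A thin
command-line interface is installed at `inst/cli/aifcount.R`
(`simulate`, `fit`, `diagnose`, `evolve`, `loo`).

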