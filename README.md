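# mpefr — multiple predator effects from functional responses

`mpefr` quantifies **multiple predator effects** (MPEs) in non-replacement
predator feeding trials: experiments in which P predators are confined
with N0 prey for a fixed time T and the survivors are counted. It is aimed
at community and experimental ecologists who run factorial feeding trials
across predator densities, prey densities, and arena conditions (here:
water volume, i.e. search space) and want to know whether predators
combine additively, antagonistically (prey risk reduction, e.g.
interference), or synergistically (risk enhancement).

## The model at the core

Single-predator trials are fitted with **Rogers' random predator
equation**, the type II functional response integrated over prey
depletion:

    Ne = N0 (1 − exp(a (Ne h − T)))

with attack rate `a` and handling time `h`, solved in closed form via the
Lambert W function and fitted by maximum binomial likelihood
(`fit_rogers()`). Response type is classified from the sign of the linear
coefficient of a binomial regression of proportion eaten on prey density
(`classify_fr_type()`); attack rates and handling times are compared
between treatments with the Juliano differences parameterization
(`compare_params_delta()`).

Multi-predator feeding is then *predicted* under predator independence by
integrating the population-dynamic model

    dN/dt = − a N P / (1 + a h N)

(`integrate_depletion()`, `predict_trophic_IS()`). The observed
interaction strength `IS = (N_start − N_end)/N_start` (proportion of prey
killed) is decomposed per trial into the trophic prediction `IS_T` and the
emergent, nontrophic remainder

    IS_NT = IS − IS_T

(`nontrophic_IS()`); negative `IS_NT` means risk reduction. Uncertainty in
(a, h) is propagated through the prediction by Latin hypercube sampling
over the 95% confidence intervals (`lhs_sensitivity()`). The statistical
layer provides quasi-binomial analysis of deviance with backward
elimination and Tukey post hoc tests for proportions eaten
(`glm_quasibinomial_anodev()`, `tukey_posthoc()`), and AICc-based
selection between linear and quadratic prey-density models of `IS_NT`
(`fit_isnt_models()`, `aicc()`).

A seeded synthetic-trial generator (`simulate_experiment()`) emulates the
full factorial design — 6 prey densities × 2 volumes × 4 predator
densities × 5 replicates (240 units) plus predator-free controls — with a
type II feeding process and an optional predator-interference coefficient,
so the entire pipeline is testable without any external data. Real trial
tables in CSV form are loaded with `read_trials()` (arbitrary headers via
a column mapping).

## Worked example

Simulate the full design with predator interference (`c = 1`), fit, and
decompose:

```r
library(mpefr)
design <- experiment_design()
trials <- simulate_experiment(design, default_generator_params(interference = 1),
                              seed = 42)
summarize_controls(trials)
#> Control survival: mean 96.7% (SD 8.4%), n = 60

s40 <- trials[trials$predator_count == 1 & trials$volume_ml == 40, ]
classify_fr_type(s40)
#> FR type: type II (linear coefficient -0.03839, SE 0.00645, p = 2.62e-09, alpha = 0.05)

fit40 <- fit_rogers(s40, T = 0.75)   # T in days; 18 h trial
fit40
#> Rogers random predator fit (n = 30 trials, T = 0.75):
#>   attack rate a  = 1.469 (SE 0.688)
#>   handling time h = 0.2434 (SE 0.043)
#>   logLik = -47.2510, converged: TRUE

fit80 <- fit_rogers(trials[trials$predator_count == 1 &
                           trials$volume_ml == 80, ], T = 0.75)
rec <- nontrophic_IS(trials, list(`40` = fit40, `80` = fit80))
round(tapply(rec$is_nontrophic, rec$predator_count, mean), 3)
#>      1      2      3      4
#> -0.002 -0.070 -0.103 -0.191

fit_isnt_models(rec)
#> IS_NT model selection: quadratic prey-density coding chosen (delta AICc = 6.15)
#>   AICc: linear -121.09, quadratic -127.23 (n = 240)
#>   predator_density               F(3, 226) = 11.64, p = 4.03e-07
#>   volume                         F(1, 226) = 6.75, p = 0.00997
#>   ...
```

Reading the output: control mortality is negligible, so no correction is
applied; single-predator feeding is type II (proportion eaten falls with
prey density); the fitted attack rate and handling time carry wide
intervals, as is typical of 30-trial designs. Mean `IS_NT` grows more
negative with predator density — prey risk reduction emerging from the
generated interference — and the quadratic prey-density model wins the
AICc comparison, i.e. the antagonism peaks at intermediate prey densities
where it is masked neither by total depletion (low N0) nor by predator
satiation (high N0).

The same analysis runs end to end from one configuration object
(`run_pipeline(run_config(...))`), writing CSV tables, JSON reports and a
seed-bearing manifest; identical configuration and seed reproduce every
output byte for byte. A thin command-line wrapper lives in
`inst/scripts/run_pipeline.R`.

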