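# eiderIPM

An integrated population model (IPM) for the demography of spectacled
eiders (*Somateria fischeri*) breeding on the Yukon–Kuskokwim Delta,
Alaska — a threatened Arctic sea duck whose adult survival and nest
success respond nonlinearly to winter sea-ice conditions in the Bering
Sea.  The package is aimed at quantitative population ecologists who
want to fit, test, or extend joint demographic models of this kind: it
implements the full model, a matching synthetic-data generator, and the
derived statistics used to interpret the fit.

## The model

Three data likelihoods share parameters through a female-only,
prebreeding-census projection model with four stages — 1-year-olds
(n₁), non-breeding 2-year-olds (n₂), breeding 2-year-olds (n₃), and
3+-year-olds (n₄):

```
            ⎡   0        0     (f/2)·φⱼ  (f/2)·φⱼ ⎤
  n_{t+1} = ⎢ φₐ(1−α)    0        0         0     ⎥ n_t
            ⎢  φₐ·α      0        0         0     ⎥
            ⎣   0        φₐ       φₐ        φₐ    ⎦
```

* **Counts** (aerial breeding-abundance estimates with per-year SDs):
  a Normal state-space likelihood `Y_t ~ N(Nbpop_t, σ_y,t)` with
  `Nbpop_t = 2(n₃+n₄)` and a stochastic (Poisson/binomial) latent state
  process — by default moment-matched by a Gaussian and integrated out
  analytically (Kalman recursion); exact integer latent states are
  available behind a flag.
* **Capture–recapture** (females marked as ducklings or as breeding
  adults): a multistate Cormack–Jolly–Seber likelihood in m-array
  multinomial form.  One-year-olds and non-breeding 2-year-olds are
  unobservable; a duckling-marked bird can be recaptured no earlier
  than two years after release, when it breeds with propensity α (and
  certainly at age 3).
* **Productivity** (nest records): binomial nest success with annual
  logit random effects, Poisson clutch size at hatch, and a constant
  duckling survival ds = 0.67, giving fecundity `f_t = ns_t · cs · ds`.

Annual rates follow logit-scale linear predictors: a quadratic effect
of standardized extreme-ice days (days with ≥ 95 % ice cover in the
core wintering area, Nov 1 – Apr 30) on adult survival and nest
success, the winter Arctic Oscillation on first-year survival, and fox
sign plus summer precipitation on nest success.  Posterior sampling is
by MCMC in JAGS; derived output includes annual and geometric-mean
growth rates, rate–growth correlations with p(r > 0), Freeman–Tukey
and chi-square posterior-predictive checks, and the proportion of
temporal variance explained by covariates, V = (σ²_total − σ²)/σ²_total.

## Worked example

```r
library(eiderIPM)

# a 23-year synthetic data set at the default generative parameters
bundle <- simulate_ipm_data(ipm_truth(), seed = 42)
data   <- as_ipm_data(bundle)

fit <- ipm_fit(data, chains = 2, n_adapt = 500, n_burnin = 1000,
               n_iter = 1500, seed = 7)
round(coef(fit), 3)
#>   mean_phia   mean_phij       alpha      mean_p     mean_ns          cs
#>       0.865       0.240       0.409       0.524       0.773       4.339
#>  sigma_phia  sigma_phij     sigma_p    sigma_ns  b_phia_lin b_phia_quad
#>       0.807       0.963       0.257       0.997      -0.486      -0.239
#>   b_phij_ao    b_ns_lin   b_ns_quad    b_ns_fox b_ns_precip
#>       0.445      -0.050      -0.499      -0.012      -0.103
```

The posterior means sit close to the generative truth (adult survival
0.878, first-year survival 0.290, breeding propensity 0.359, recapture
0.5, nest success 0.778, clutch size 4.297, quadratic ice coefficients
−0.251 and −0.455); the weakly informed quantities (α, first-year
survival, the betas) carry wide credible intervals at this sample
size.  `summary(fit)` prints the full Table-style report with modes,
95 % CrIs, R-hat, and geometric mean growth; `gof_freeman_tukey(fit)`
and `gof_chisq_counts(fit)` give posterior-predictive p-values;
`demographic_correlations(fit)` ranks the rates by their correlation
with realized population growth.

A command-line pipeline wraps the same functions:

```sh
Rscript inst/cli/eider-ipm.R simulate --out bundle --seed 1
Rscript inst/cli/eider-ipm.R fit --bundle bundle --out run --seed 2
Rscript inst/cli/eider-ipm.R gof --fit run
Rscript inst/cli/eider-ipm.R summarize --fit run
```

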