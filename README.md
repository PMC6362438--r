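# hsipm — habitat- and age-structured integrated population models

`hsipm` implements a Bayesian integrated population model (IPM) for a
territorial songbird population breeding in two contrasting farmland
habitat types — "Short" (permanently short ground vegetation, e.g.
grazed pastures) and "Tall" (growing vegetation, e.g. crop fields) —
with two male age classes (Young = one year old, Old = older). The
motivating system is a declining northern wheatear (*Oenanthe
oenanthe*) population in which habitat quality, individual movement
between habitats, and a large residual inflow of apparent immigrants
jointly drive the population trajectory.

The model joins four data streams with shared parameters:

1. **breeding-success trials** — successes `B` out of `R` monitored
   sites: `B[a,h,t] ~ Binomial(R[a,h,t], b[a,h,t])`;
2. **fledgling counts** at successful sites with known brood size:
   `F − S ~ Poisson(S (2 fled − 1))`, where `fled` is the mean number
   of modelled-sex fledglings per successful brood (even sex ratio);
3. **adult multi-event mark–resight histories** with state
   uncertainty: hidden states are age × habitat × breeding success
   (plus dead); apparent survival `phi` and habitat transitions `psi`
   are conditional on breeding success; detection `p` and state
   certainty `c` link states to seven event codes;
4. **territory counts** per class, tied to a latent binomial/Poisson
   population process with year-specific apparent immigrant numbers
   `Im[a,h,t]` estimated as the count-process residual
   (`NB_{t+1} = A_t NB_t + Im_{t+1}` in expectation, with `A_t` the
   4×4 projection matrix over classes Y_S, Y_T, O_S, O_T).

Juvenile recruitment (`phi_fl`, natal-habitat transition `psi_fl`) is
informed by single-occasion resightings of ringed fledglings. Breeding
success, fledgling numbers, survival and recruitment carry independent
normal year effects on the logit/log scale; transitions, `p` and `c`
are constant.

On top of the fit the package provides:

* **transient LTRE** — a covariance-weighted decomposition of the
  temporal variance of the realized growth rate into contributions of
  vital rates, age-habitat structure, and apparent immigration;
* **real-time transient elasticities** — the accumulated response of
  the geometric mean growth rate to a small yearly perturbation
  (default 0.001) of each parameter, re-propagating the trajectory
  from the year-1 state;
* **occupancy scenarios** — e.g. adding Short sites occupied by Old
  males every year and comparing geometric mean growth;
* **habitat productivity** — (first-year recruits + surviving adults)
  per breeder of a habitat.

An individual-based simulator (`sim_config()`, `simulate_ipm_dataset()`)
generates all four data streams under the model's assumptions at the
scale of the motivating study (24 years, ~90 occupied territories,
immigration near 45% of the population), so the whole pipeline is
testable without any field data.

Inference runs on a purpose-built Metropolis-within-Gibbs sampler
(Rcpp) that marginalises nothing away from the stated model: hidden
adult states are resampled by forward-filtering backward-sampling, and
the integer latent count process by local moves. Its posteriors are
cross-validated in the test suite against an independent latent-state
implementation of the identical model in JAGS.

## Worked example

```r
library(hsipm)

cfg <- sim_config(seed = 20190205)        # study-scale defaults
dat <- simulate_ipm_dataset(cfg)
fit <- fit_ipm(dat$observed, chains = 3, iter = 3000, burnin = 1000, seed = 11)

summ <- summarize_posterior(fit)
subset(summ, parameter %in% c("b_O_S", "phi_fl_S", "omega_total",
                              "lambda_geomean", "prod_S", "prod_T"))
```

```
        parameter   mean    l95   u95
            b_O_S 0.8061 0.7854 0.825
         phi_fl_S 0.1201 0.1016 0.140
      omega_total 0.4118 0.3756 0.444
   lambda_geomean 0.9991 0.9885 1.010
           prod_S 0.6195 0.5868 0.654
           prod_T 0.4573 0.4198 0.496
```

`b_O_S` is the breeding success of Old males on Short sites (posterior
mean with 95% credible interval), `phi_fl_S` the apparent recruitment
of fledglings born on Short sites, `omega_total` the share of each
year's breeders that are apparent immigrants, `lambda_geomean` the
geometric mean annual growth rate over the 24 years, and `prod_S` /
`prod_T` the geometric mean productivities of the two habitats — Short
sites produce distinctly more recruits-plus-survivors per breeder than
Tall sites under the default generating values.

The numbered drivers under `analysis/` run the full workflow
(`01_simulate.R` → `02_fit.R` → `03_ltre.R` → `04_elasticity.R`),
writing tables and a run manifest under `results/`. Event-code
dialects of the history tables: adults `0` not seen, `1/2/3` seen on
Short with success/failure/unknown status, `4/5/6` the same on Tall;
juveniles `0` not seen, `1` seen breeding on Short, `2` on Tall.

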