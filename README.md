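# sdart — stratified distributional analysis of response times

`sdart` implements stratified distributional analysis (SDA), a
hierarchical Bayesian measurement-model framework for response-time (RT)
distributions from lexical-decision megastudies (and any other speeded
task). Instead of regressing mean RTs on predictors, SDA stratifies the
trials of every participant into (word-frequency band × word length)
cells and fits the full RT distribution of every cell, revealing how word
properties shape the *shape* of the distribution — without assuming any
functional form for that dependence.

Each RT is decomposed as

    Y_ijkl = theta_j + X_ijkl

where `theta_j` is a participant-specific deterministic shift
(nondecision time: encoding and motor execution) and `X_ijkl > 0` is the
stochastic component of participant `j`, frequency band `k`, word length
`l`. `X` is modelled by a shifted lognormal (parameters mu, sigma²),
shifted Wald / inverse Gaussian (mean mu, shape lambda) or shifted gamma
(shape alpha, rate beta) — three positively skewed families with distinct
mechanistic readings. Cell parameters get length-specific gamma priors,
shifts a gamma prior, and the 30 resulting hyperparameters gamma
hyperpriors fixed before the analysis. Models are checked with posterior
predictive p-values (cell means; values near 0.5 indicate fit) and
compared by expected log pointwise predictive density (elpd; PSIS-LOO by
default) as `Δelpd ± se` against the best model.

The package is self-contained for validation: a synthetic-data module
generates Zipf-distributed lexicons (three correlated occurrence
measures: word-form frequency and two contextual-diversity measures) and
trial archives with known ground truth, so every stage — file reading,
participant filters, quantile banding, MCMC, assessment, selection — is
testable end to end without downloading the megastudy archives.

## Worked example

```r
library(sdart)

## a known-truth synthetic study: 20 participants x 4 bands x 3 lengths,
## 50 trials per cell, lognormal stochastic component
des  <- sda_design(family = "lognormal")
sim  <- gen_trials(des, seed = 1)
trials <- filter_participants(sim$trials)$trials   # 60% / 150-2000ms / 20% rules
strat  <- stratify(trials)                          # (j, k, l) cells

fit <- sda_fit(strat, "lognormal", draws = 600, warmup = 1000,
               chains = 2, seed = 1)
print(fit)
#> SDA fit: shifted lognormal family
#>   12000 trials, 20 participants, 240 cells
#>   1200 draws (2 chain(s), warmup 1000)
#>   max split R-hat: 1.092

head(posterior_medians(fit, "theta"), 4)     # nondecision times (ms)
#>      p01      p02      p03      p04
#> 214.7562 217.8709 210.1278 258.9587
head(sim$truth$theta, 4)                     # the generating truth
#>      p01      p02      p03      p04
#> 216.9538 214.8190 209.3327 251.9388

pp <- ppp_values(fit, R = 200, seed = 2)     # posterior predictive checks
mean(pp$ppp)                                 # ~0.5 under a well-specified model
#> [1] 0.5019583

## family comparison on the same trials
fits <- lapply(sda_families(), function(f)
  sda_fit(strat, f, draws = 300, warmup = 600, chains = 1, seed = 1))
cmp <- compare_elpd(lapply(fits, elpd, method = "loo-is"))
print(cmp)
#> model comparison (reference: lognormal)
#>      model delta_elpd    se
#>  lognormal       0.00  0.00
#>      gamma    -119.05 18.97
#>       wald    -235.04 39.76
```

The generating lognormal family is ranked first; the posterior medians of
`theta_j` recover the true shifts to within a few ms. `summary()`,
`coef()`, `predict()`, `plot()`, `simulate()` and `residuals()` methods
are available on the fit; `run_pipeline(sda_config(...))` drives the whole
simulate/load → filter → band → fit → assess → compare → report sequence
from one declarative config (YAML supported) and writes tidy csv/JSON
outputs with a manifest.

The numbers above were produced by the code shown (seeds included);
`vignette("sda-methods")` documents the model, the sampler, and every
numerical choice.

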