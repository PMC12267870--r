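---
title: "Stratified distributional analysis of response times: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified distributional analysis of response times: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdart)
```

## The model

Stratified distributional analysis (SDA) treats each lexical-decision
response time as the sum of a deterministic and a stochastic part,

$$Y_{ijkl} = \theta_j + X_{ijkl},$$

where $j$ indexes the participant, $k$ the word-frequency band, $l$ the word
length, and $i$ the trial. The shift $\theta_j$ is the participant's
nondecision time — encoding and motor execution, the irreducible minimum of
an RT — and is independent of item properties. The stochastic component
$X_{ijkl} > 0$ carries all item effects and is modelled by one of three
positively skewed families evaluated at $y - \theta_j$ (hence "shifted"
distributions): the lognormal with parameters
$\rho[1] = \mu$ (log-ms) and $\rho[2] = \sigma^2$; the Wald
(inverse Gaussian) with mean $\mu$ (ms) and shape $\lambda$ (ms); and the
gamma with shape $\alpha$ and rate $\beta$ (1/ms). Each family has a
mechanistic reading — multiplicative cascades for the lognormal, noisy
evidence accumulation to a threshold for the Wald, serial exponential
stages for the gamma — so selecting among them by predictive fit is also a
statement about plausible generating processes.

Cell parameters are tied together hierarchically. Both components of
$\rho_{jkl}$ receive gamma priors whose shape and rate depend on word
length only,

$$\rho_{jkl}[1] \sim \mathrm{Gamma}(\alpha_l[1], \beta_l[1]), \qquad
  \rho_{jkl}[2] \sim \mathrm{Gamma}(\alpha_l[2], \beta_l[2]),$$

the shifts receive $\theta_j \sim \mathrm{Gamma}(\alpha_\theta,
\beta_\theta)$, and every element $\phi_i$ of the hyperparameter set
$\psi = (\alpha_l[1], \beta_l[1], \alpha_l[2], \beta_l[2], \alpha_\theta,
\beta_\theta)$ carries a $\mathrm{Gamma}(a_i, b_i)$ hyperprior fixed before
the analysis — 30 $(a_i, b_i)$ pairs when all seven lengths 4–10 are
modelled. Crucially, nothing constrains how $\rho$ varies across frequency
bands: the band dimension is left free, so the fitted posteriors *reveal*
the frequency scaling instead of assuming one.

### Units

Everything is in milliseconds. This matters for the lognormal: its
location $\mu = E[\ln(y - \theta)]$ must be positive to be compatible with
a gamma prior, which holds on the ms scale (typical values 5–6) but would
fail in seconds (negative values).

### Default hyperprior

`sda_prior()` defaults to $a_i = b_i = 0.01$ for every element of $\psi$:
each hyperprior has mean 1 and variance 100. This is weakly informative on
every scale the hyperparameters live on, and deliberately diffuse for the
shift hyperpair, so the data dominate $\theta_j$. The defaults are
configurable per element and are recorded in the metadata sidecar of every
serialised fit. `psi_fixed` fixes $\psi$ entirely, which turns the model
into independent per-cell fits — useful for validation against quadrature
(below) and for prior-predictive work.

## Preprocessing

The trial filters mirror megastudy practice and are applied in a fixed
order: first, participants with overall accuracy below 60% are removed
(inclusive bound: exactly 60% is retained), accuracy being computed over
all trials, words and nonwords, because the archives are filtered before
any lexical restriction; second, participants whose fraction of RTs
outside [150, 2000] ms is *strictly greater* than 20% are removed. Only
participants are excluded — out-of-window trials of retained participants
stay, since the procedure specifies no trial-level trimming. Nonword
trials and words outside lengths 4–10, absent from the lexicon under the
chosen occurrence measure, or carrying an excluded part-of-speech label
are then dropped.

Word-frequency bands are quantile-based on the *trial-level* occurrence
values (a frequent word contributes many observations): boundaries at the
$m/k$ quantiles (linear-interpolation definition), values equal to a
boundary assigned to the lower band, so band membership is a function of
the occurrence value and no value can sit in two bands. The band count $k$
is the largest for which every band keeps at least `min_count`
observations after tie handling; ties can only lower $k$, and the
degenerate all-tied case collapses to one band. A 40,000-observation
floor — the scale used for megastudy analyses — implies about 19 bands on
778k observations, while band counts of 20 (ELP) and 18 (BLP) are used in
practice; since no exact divisor rule reproduces those counts, the floor
is a configurable parameter and the maximise-$k$ rule is this package's
documented choice.

## Posterior computation

The sampler is an adaptive Metropolis-within-Gibbs scheme written for this
hierarchy. Per sweep it updates, in order: all cell parameters (log-scale
random walks, one pass per component plus one joint co-scaling pass along
the $\rho[1]$–$\rho[2]$ ridge — cells are conditionally independent given
$\theta, \psi$, so all cells accept or reject in parallel); all shifts
(random walk on $\mathrm{logit}(\theta_j / \min_i y_{ij\cdot\cdot})$,
which enforces the support $0 < \theta_j < \min_i y_{ij\cdot\cdot}$ where
the likelihood would otherwise be $-\infty$); a *shift-transport* move
that proposes $\theta_j + \delta$ while deterministically adjusting each
of the participant's cell location parameters to keep every cell's
expected RT fixed (a diffeomorphism whose Jacobian enters the acceptance
ratio) — without it, $\theta$ and $\rho$ random-walk along a narrow ridge
and mixing is impractically slow; and the hyperparameters, with conjugate
Gibbs draws for the rates ($\mathrm{Gamma}$ likelihood ×
$\mathrm{Gamma}$ prior), log-scale Metropolis for the shapes, and a joint
(shape, rate) co-scaling move for their ridge. Proposal scales adapt
toward 0.44 acceptance during warmup only, so the post-warmup chain is a
fixed Markov kernel. Chains are seeded independently and initialised by
overdispersed method-of-moments estimates; split-chain R-hat is computed
for every scalar quantity and a warning is raised above 1.01.

Correctness is checked two independent ways in the test suite: with no
data the sampler must reproduce the hierarchical prior (compared against
ancestral simulation), and on a one-participant, two-cell instance with
fixed $\psi$ the posterior means must match dense-grid quadrature built
from the families' sufficient statistics, within Monte-Carlo error, for
every family.

## Assessment and selection

Posterior predictive replicates redraw every cell's RTs at a randomly
selected joint posterior draw, preserving cell sizes. The posterior
predictive $p$-value of a cell is the fraction of replicates whose cell
mean is *greater than or equal to* the observed cell mean — ties count
toward the numerator, which is deterministic and conservative toward 0.5
under discreteness. Values near 0.5 indicate fit; the package computes
them at cell granularity by default (the finest level consistent with the
stratification) with participant-level aggregation available.

Predictive accuracy is summarised by the expected log pointwise predictive
density (elpd). Because the true generating density is unknown, the
integral is approximated; the default is Pareto-smoothed
importance-sampling leave-one-out (PSIS-LOO): per trial, the leave-one-out
importance ratios $1/f(y_i \mid \vartheta^{(s)})$ have their largest 20%
replaced by expected order statistics of a generalised Pareto fitted to
the tail (Zhang–Stephens profile estimator), with the tail-shape $\hat k$
reported per trial and $\hat k > 0.7$ flagged as unreliable. WAIC and
in-sample lpd are available as cross-checks. Models are ranked by elpd;
the best model is the reference with $\Delta\mathrm{elpd} = 0$, and every
other model reports $\Delta\mathrm{elpd} = \mathrm{elpd}_m -
\mathrm{elpd}_{ref} \le 0$ with the paired standard error
$\sqrt{n}\,\mathrm{sd}$(pointwise differences).

A practical note on the shifted Wald: its log density falls like
$-\lambda/(2x)$ as $x \to 0^+$, so the predictive density of trials just
above the shift is volatile across posterior draws. When the data are
generated by a lognormal, WAIC and PSIS-LOO penalise this volatility
heavily (and flag the affected trials), which is why the Wald can trail by
far more than its in-sample misfit alone would suggest. This is a genuine
property of predictive scoring for shifted families at moderate data
sizes, not an artefact.

## The synthetic-data generator

`sda_design()` / `gen_trials()` emulate the structure of a
lexical-decision megastudy with known ground truth: a Zipf-distributed
lexicon (rank-frequency slope $-s$, three occurrence measures with
configurable rank correlation via a Gaussian copula, so that word-form
frequency and the two contextual-diversity measures are highly but not
perfectly aligned, as in real corpora), shifts drawn from
$\mathrm{Gamma}(\alpha_\theta^*, \beta_\theta^*)$, cell parameters from
the length-specific priors at true hyperparameters $\psi^*$, and RTs from
the chosen family. Words are assigned to bands by occurrence rank within
length with equal trial weighting, so banding tests exercise the same
code path as real data.

The default design — 20 participants × 4 bands × 3 lengths (4, 7, 10) ×
50 trials per cell, 12,000 trials — is the package's canonical
desk-scale study condition: large enough that hierarchical recovery,
calibration, and family selection are all informative, small enough that
a full fit takes seconds. The default truths produce realistic
lexical-decision RTs: shifts around 250 ms (sd ≈ 35), stochastic
components around 200–250 ms. For the lognormal the variance parameter
defaults to $\sigma^2 \approx 0.25$ (coefficient of variation ≈ 0.5 for
the decision component): empirical single-trial RT distributions are
strongly right-skewed, and at much smaller variance the three families
become essentially indistinguishable, which would misrepresent the
discrimination problem the method faces on real data.

What the generator does *not* emulate: linguistic structure of items
(words are random letter strings), sequential effects and practice/fatigue
drifts, trial-level accuracy dynamics, and the very unequal band sizes of
real quantile banding on Zipf-distributed corpora. Passing tests therefore
demonstrate correctness of the machinery under the model's own
assumptions, not robustness to real-data violations of them.

## Study-condition choices in the test suite

Problem sizes in the tests are the package's own validation design.
Parameter recovery and ppp calibration run at the canonical design above;
with 240 cells, binomial fluctuation around nominal 95% coverage makes a
90% acceptance floor appropriate. Family selection repeats the canonical
design ten times under lognormal truth: with a free shift a Wald can
imitate a lognormal closely (the asymptotic per-trial log-score gap is of
order $10^{-3}$), so reliable ranking needs $n$ in the $10^4$ range —
the canonical 12,000 trials — while the gamma is separated an order of
magnitude more strongly. The sampler-versus-quadrature check uses one
participant, two cells and 20 trials so the oracle can integrate the
exact joint on a dense grid.

Two findings from that validation are worth recording. First, the
posterior of $\theta_j$ is essentially invariant to which occurrence
measure defines the bands, but *not* numerically identical across
families: each family has its own pseudo-true shift (the Wald's sharp
left edge pulls $\theta$ down, the gamma's polynomial edge pushes it up),
so across families the per-participant medians track each other with a
bounded, family-specific offset — the same shape shifted horizontally —
rather than coinciding. The test suite asserts exactly that. Second, at
desk scale the Wald's elpd estimate is noticeably noisier than the other
families' (see above), which the $\hat k$ flags make visible.

## Numerical choices and edge cases

Density at $y \le \theta$ is 0 (log-density $-\infty$), including at
exactly $y = \theta$ (right limit), so log-likelihoods are finite or
$-\infty$, never NaN. Cells with fewer than five trials are fitted —
the hierarchy shrinks them — but flagged in summaries. Posterior medians
use the usual midpoint convention for even draw counts. The band rule
falls back to a single band with a warning when the floor exceeds the
observation count. Draws are reproducible given a seed; chains use
distinct derived seeds. A band-dependent shift $\theta_{jk}$ is a
conceivable extension of the decomposition; the package deliberately fits
the band-free $\theta_j$ and exposes no such option beyond the config
surface, since the measurement model treats nondecision time as
item-independent.

## Known limitations

The sampler is tuned for datasets up to the low millions of trials;
beyond that a compiled likelihood would be warranted. PSIS-LOO flags but
does not repair unreliable pointwise estimates (refitting without the
offending trials is the principled fix). The elpd standard error is the
usual paired large-$n$ approximation and can understate uncertainty when
pointwise differences are heavy-tailed. Banding assumes the occurrence
measure is fixed and error-free; uncertainty in corpus counts is not
propagated.
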