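---
title: "Belief, confidence, and wagering in a POMDP decision maker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief, confidence, and wagering in a POMDP decision maker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomdpconf)
```

## The model

`pomdpconf` implements a Bayesian model of perceptual decision making with
*incomplete knowledge* of the stimulus statistics, framed as a partially
observable Markov decision process. The hidden state of a trial is the signed
motion coherence $c$ (a fraction; $c = 0.128$ means 12.8% coherent motion,
positive = rightward). Every 10 ms the stimulus delivers a momentary
observation

$$z_t \sim \mathcal{N}(c,\, w_z),$$

where $w_z$ is the *true* observation noise. The decision maker does not know
$w_z$, nor the discrete set of coherences used in the experiment. It carries a
learned observation noise $\sigma_z$ and a Gaussian prior
$b_0 = \mathcal{N}(0, \sigma_0)$ over $c$, and updates its belief by conjugate
Bayes:

$$\mu_t = \frac{\sigma_z^{-2}\sum_{j\le t} z_j}{t\sigma_z^{-2} + \sigma_0^{-2}},
\qquad
\sigma_t^2 = \frac{1}{t\sigma_z^{-2} + \sigma_0^{-2}}.$$

The direction choice is the sign of $\mu_t$ (an exact zero is broken by a fair
coin), and confidence — the posterior probability that the chosen direction is
correct — is $\Phi(|\mu_t|/\sigma_t)$, which lives in $[0.5, 1)$. When a
sure-bet (opt-out) target is available, the model compares confidence with the
utility ratio $r_\text{sure}/r_\text{direction}$ and opts out whenever
confidence does not exceed it; the tie goes to the sure bet.

```{r}
p <- monkey_params("M1")   # w_z 0.90, sigma_z 1.60, sigma_0 0.46, ratio 0.63
b <- belief_from_sum(3.833, t = 40, p)
c(confidence = confidence(b), V = ddm_from_belief(b, p))
```

The mismatch between $(\sigma_z, \sigma_0)$ and the true generative process
$(w_z,\ \text{discrete } c)$ is the point, not a nuisance: it is what produces
the classic dissociations between confidence and accuracy that the
`run_*` experiments reproduce.

## Parameters, units, defaults

* `w_z` — true observation sd per 10 ms step, in coherence units. Defaults in
  `monkey_params()`: 0.90 (M1) and 1.69 (M2), the values estimated from the
  two animals' choice data.
* `sigma_z`, `sigma_0` — the decision maker's learned observation noise and
  prior sd: 1.60/0.46 (M1), 3.59/0.87 (M2). The prior mean is clamped to 0
  (symmetric task); estimation may report a nonzero sample mean for
  diagnostics only.
* `cost` — utility paid per observation taken (including the first). 0 means
  free observations and no early stopping.
* `utility_ratio` — sure-bet utility relative to a correct direction choice:
  0.63 (M1), 0.59 (M2). Values at or below 0.5 make the sure bet worthless
  because confidence never falls below 0.5.
* `dt_ms = 10`, `horizon` — the time base; durations are integer step counts.

## The termination policy and its DDM equivalent

With an observation cost, the model stops sampling when the expected gain in
confidence from one more look,

$$E_{z}\!\left[\Phi(|\mu_{t+1}|/\sigma_{t+1})\right] - \Phi(|\mu_t|/\sigma_t),$$

drops to the cost (in units of the direction reward). Because this gain falls
monotonically with $|\mu_t|$ and with $t$, the rule is a collapsing symmetric
bound $\Theta'(t)$ on the inferred mean (`compute_termination_bound()`), and it
maps *exactly* onto a time-varying bound on the accumulated evidence
$V_t = \sum z_j$ of a drift-diffusion model:

$$\Theta(t) = \left(t + \sigma_z^2/\sigma_0^2\right)\Theta'(t).$$

A DDM run against $\Theta(t)$ stops at the same step with the same choice as
the POMDP on any observation stream; the test suite checks this stream by
stream.

**Which predictive distribution?** The expected gain depends on what the
decision maker assumes about its next observation. The package's default is
the belief-conditional marginal — the posterior predictive
$\mathcal{N}(\mu_t, \sqrt{\sigma_t^2 + \sigma_z^2})$ — which is the coherent
Bayesian choice: it integrates the remaining uncertainty about $c$ instead of
plugging the point estimate $\mu_t$ in as if it were the truth. The plug-in
alternative $\mathcal{N}(\mu_t, \sigma_z)$ is available via
`model_params(predictive = "plugin")`. The default also reproduces the
package's reference simulation results for the cost experiment (see the
metacognition section); under the plug-in form the bounds sit further out,
early stopping is rarer, and the same experiment yields a visibly weaker
dissociation (ratio ≈ 0.85 instead of ≈ 0.74).

**A known limitation.** The one-step look-ahead rule is *myopic*: it beats any
fixed-sample-size strategy (tested), but a full finite-horizon dynamic program
is allowed to continue past the one-step bound because continuing preserves
the option of stopping later in a better state. On a toy instance
($\sigma_z = \sigma_0 = 1$, cost 0.02, $H = 8$) the DP stop boundary sits
10–40% beyond the one-step bound and earns about 0.008 more expected utility
per trial. At the small costs used throughout the analyses ($10^{-4}$ to
$2\times10^{-3}$) the rule is the model definition, not an optimality claim.

## The synthetic task generator

No public behavioural dataset exists for this task, so `generate_trials()`
emulates the experimental design: signed coherences drawn uniformly from the
seven magnitudes {0, 1.6, 3.2, 6.4, 12.8, 25.6, 51.2}% with both signs,
stimulus durations of 100–900 ms in 10 ms steps, and a sure-bet target on a
random half of trials. The duration distribution is not printed in the source
description; the default is uniform over the range, with a truncated
exponential (favouring short trials, as is typical for this task family)
selectable via `duration_distribution = "truncexp"`. At $c = 0$ no direction
is correct and reward is a fair coin; those trials are excluded from
accuracy-based fits.

What the generator does *not* emulate: motion-energy structure within a
trial, fixation breaks, lapses, session-level drift, or any sequential
dependence between trials. Tests that pass on this generator therefore
certify the model implementation and its internal consistency, not the
model's adequacy for any particular animal's data.

## The estimation pipeline

`fit_pipeline()` chains the published recipe:

1. `fit_wz()` — with free observations the rightward-choice probability is
   $\Phi(\sqrt{t}\,c/w_z)$; $w_z$ is a 1-D Bernoulli MLE on the no-sure-bet
   trials ($c = 0$ excluded as uninformative).
2. `estimate_prior()` — one draw per trial from
   $\mathcal{N}(c, \text{noise}/\sqrt{t})$, pooled into a Gaussian MLE.
3. `fit_sigma_z()` — simulate each trial's observation sum from the true
   generative model, and fit the *believed* rightward probability
   $\Phi(\sigma_z^{-2}\sum z_i/\sqrt{t\sigma_z^{-2}+\sigma_0^{-2}})$ to the
   recorded choices by 1-D MLE.
4. `iterate_prior_noise()` — alternate 2 and 3 (later prior passes use the
   current $\sigma_z$) until $\sigma_0$ stabilises.
5. `fit_utility_ratio()` — the opt-out rule maps to symmetric thresholds
   $\pm\Phi^{-1}(\text{ratio})\sqrt{t\sigma_z^2+\sigma_z^4/\sigma_0^2}$ on the
   observation sum, giving a closed-form opt-out probability per (c, t) and a
   1-D MLE on the sure-shown trials.

Two numerical points deserve emphasis. First, because step 2 re-draws one
stochastic sample per trial on every pass, successive $\sigma_0$ estimates
carry Monte-Carlo noise of scale $\sigma_0/\sqrt{n}$; the convergence
tolerance defaults to three times that scale (the precision of the estimator
itself), and a fixed tolerance below it would spin until the iteration guard.
A deterministic moment-matching variant of step 2 exists behind
`deterministic = TRUE`.

Second, **$\sigma_z$ and $\sigma_0$ are not identifiable from zero-cost
choices**. The agent's direction choice is the sign of its evidence sum
whatever it believes, so the fit converges to the *calibration fixed point*
implied by $w_z$ and the task mix — approximately
$\sigma_0^2 = \mathrm{Var}(c) + E[\sigma_z^2/t]$, with $\sigma_z$ the noise
that best calibrates the believed probability against realised accuracy —
not to the values the simulated agent carried. `analysis/03_fit_recovery.R`
demonstrates this: $w_z$ and the utility ratio recover well, while
$\sigma_0$ lands at the fixed point of the simulated duration mix (about
0.37 under uniform durations). Matching a particular animal's printed
$(\sigma_z, \sigma_0)$ would require that animal's empirical trial mix.

For non-zero cost there is no closed-form choice probability;
`particle_filter_loglik()` estimates per-cell choice probabilities by forward
simulation (20,000 particles by default) and `grid_search_cost_model()`
maximises over a (cost, $w_z$) grid — published resolutions $10^{-5}$ and
0.01 — re-estimating the prior/noise pair at each grid point. Model
comparison uses Vuong's closeness test (`vuong_test()`), with the standard
sample-sd denominator and an unpenalised-LR option.

## Metacognitive sensitivity

`type1_dprime()` and `meta_dprime()` implement equal-variance signal
detection for binary confidence ratings. Meta-d$'$ is the sensitivity an
SDT-ideal rater would need to produce the observed
$p(\text{high}\mid\text{stimulus},\text{response})$, holding the type-1
criterion at its scaled position $c_1\,\text{meta-}d'/d'$; the two type-2
criteria are profiled out by 1-D likelihood maximisation inside a bounded
scalar MLE over meta-d$'$. Empty cells get the log-linear $+1/2$ correction.

The reference experiment (`run_metad_cost()`, M1 parameters, ±12.8%, 400 ms,
threshold 0.63) reproduces in closed form and by simulation: accuracy 81.6%,
$P(\text{high}) = 64.7\%$ split 72%/31% by correctness, and
$d' = \text{meta-}d' = 1.80$ at zero cost; adding a $10^{-4}$ cost drops
accuracy only to 79.5% but inflates $P(\text{high})$ to 83.6% (errors: 31% →
70%), giving $d' = 1.65$, meta-d$' = 1.23$, ratio ≈ 0.74. A note on the
prior: a wider $\sigma_0 = 0.75$ (used elsewhere for illustration) changes
these numbers by less than the simulation noise at $2\times10^5$ trials.

## The five discrepancy experiments

Each `run_*` function snapshots its full configuration (parameters and
seeds), returns a tidy results table, and encodes its qualitative
expectations as sign/ordering checks with Monte-Carlo margins; rerunning from
the snapshot reproduces the table bit for bit.

* `run_hard_easy()` — marginalisation over unknown stimulus strength makes
  confidence exceed accuracy at low coherence and lag it at high coherence;
  the Gaussian prior also sits slightly below the exact discrete-prior
  confidence at high coherence.
* `run_variability()` — raising $w_z$ 0.9 → 1.5 with $\sigma_z$ fixed lowers
  accuracy but raises confidence and sure-bet rejections, including the
  closed-form two-threshold analysis on the observation sum.
* `run_metad_cost()` — above.
* `run_rt_confidence()` — reaction-time variant ($w_z = 0.4$,
  $\sigma_z = 0.75$, $\sigma_0 = 5$, cost $2\times10^{-3}$): with
  simultaneous report, error confidence rises with coherence; with sequential
  report, 250 ms of post-decision evidence reverses the slope and can push
  reported confidence in the (unchanged) choice below 0.5.
* `run_congruent_classifier()` — when the experimenter's record of the
  observations differs from what the agent used (a subset, or noisy copies
  with sd 1.12), a logistic classifier of the agent's confidence must
  up-weight choice-congruent evidence; the choice classifier stays balanced
  up to a small (~10%) residual asymmetry that is a property of the
  single-positive-coherence design itself (negative observations are rarer
  and individually more informative), not of any confirmation bias. The
  confidence threshold is placed at the median of the confidence statistic,
  pinning $P(\text{high})$ at 0.5. Under experimenter noise with the full
  stream in use the weight imbalance is of order $10^{-3}$, so that variant
  is run at two million trials to resolve its sign at three standard errors.

## Numerical choices

* Expected-gain quadrature: `stats::integrate` over ±8 predictive sd,
  absolute tolerance $10^{-8}$ on the gain; bound root-finding by bisection
  to $|\Delta\mu| < 10^{-6}$.
* Recursive and closed-form belief updates are both computed and
  cross-checked at relative $10^{-9}$ on every update.
* Simulations are vectorised over trials (column-wise cumulative sums and a
  first-crossing scan), so $10^6$ trials of 40 steps run in seconds; the
  classifier experiment streams its observation matrices in 250k-trial
  chunks to bound memory.
* Scalar MLEs use `stats::optimize` on bounded intervals
  ($w_z \in [0.05, 10]$, $\sigma_z \in [0.05, 20]$, ratio ∈ (0.5, 1));
  boundary-pinned optima are flagged as unidentifiable.
* Test problem sizes: the reference metacognition runs use $2\times10^5$
  trials (acceptance script: $10^6$, the published scale), recovery runs
  $5\times10^4$ trials, and the RT experiment 2,500–5,000 trials per signed
  coherence; these keep the full suite in the few-minute range while leaving
  Monte-Carlo error well inside the asserted margins.

## Known limitations

* One-step look-ahead is myopic relative to full dynamic programming
  (quantified above); all downstream results use the one-step rule as the
  model definition.
* $(\sigma_z, \sigma_0)$ recovery targets a calibration fixed point, not the
  generating values (identifiability, above).
* Binary confidence ratings only; multi-level ratings, response-specific
  meta-d$'$, and hierarchical variants are out of scope.
* The generator omits the real task's non-stationarities, so passing checks
  validate the implementation, not the model's fit to any particular dataset.
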