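---
title: "Belief-updating models of slot-machine gambling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief-updating models of slot-machine gambling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and its synthetic stand-in

The package models behaviour on a naturalistic slot-machine task: a fixed,
pre-programmed sequence of 200 trials in which every player experiences the
same outcomes, so that differences in play reflect only the player's own
choices. Each trial ends in one of four outcome classes: a *true win* (payout
above the bet), a *fake win* (a win banner, but a payout below the bet), a
*near-miss* (a loss in which only the last reel breaks the match), or a
*true loss*. Half of the wins are followed by an offer to double the win in a
fair 50–50 gamble (the double-up, DU). Four binary behavioural readouts are
recorded per trial: bet increase (BI), double-up acceptance (DU), casino
switch (CS) and machine switch (MS).

Because no subject-level data ship with the package, `generate_trace()` and
`generate_cohort()` produce the full study input synthetically:

* **Trace.** 200 trials; 40% wins, half of them fake; DU offered after 50% of
  wins; 18% of trials near-misses; five 40-trial streak blocks with win
  probabilities (0.40, 0.55, 0.25, 0.55, 0.25) — an even opening phase and a
  more volatile remainder, with exact global counts (80/40/40/36). The block
  schedule itself is a design choice: the task defines streaks but not their
  timetable.
* **Pay table.** Nine symbol combinations, payouts log-spaced from 0.05 to
  20 EUR at the 20-cent bet and 0.15 to 60 EUR (the jackpot) at the 60-cent
  bet, rounded to cents. Only the endpoints and the nine-combination count
  are fixed by the task description; log-spacing is the package's choice and
  mirrors how real machines skew payouts toward small wins. Combinations
  paying below the bet at both levels serve as the fake-win outcomes.
* **Return-to-player.** True-win payouts are drawn with weights proportional
  to 1/payout and then nudged entry-by-entry until the RTP under both
  constant-bet policies sits within ±0.02 of the 0.90 design mode (safely
  inside one 5% rounding bin) and above the 0.70 regulatory floor. The
  double-up gamble is expectation-neutral and ignored by RTP.
* **Agents.** Each synthetic subject is one core model (below) with
  parameters drawn uniformly from ranges centred on the scale typical for
  this task (ω ∈ [−6, −2], ϑ ∈ [0.01, 0.1], β ∈ [0.5, 8], α ∈ [0.1, 0.6]).
  Channels are independent Bernoulli draws from the model's response
  probability, scaled by base-rate multipliers (BI 1.0, DU 1.0, CS 0.15,
  MS 0.3) that reproduce the empirical rarity of switching; DU is forced to
  0 where no offer occurred.
* **Trait scores.** A BIS-11-like total is a linear function of the
  generative parameters plus Gaussian noise,
  `trait = intercept + b_ω ω + b_ϑ ϑ + ε`. The default slopes (2.42 on ω,
  243.64 on ϑ) are anchored at the construct-validity regression
  coefficients of the winning model; the default noise SD (11) makes the
  population R² moderate (≈ 0.28).

What the generator deliberately does **not** emulate: monetary magnitudes of
bets (only the binary bet-increase event is modelled), reaction times, the
sequential dependence of real play (channels are conditionally independent
given the model probability), and any within-subject non-stationarity.
Passing tests therefore show that the *pipeline* recovers what it simulates,
not that real gamblers satisfy the channel-independence assumption.

# Perceptual and response codings

Trial outcomes are reduced to a binary input series `u` under three schemes —
WLN (only true wins count as wins), WLG (true and fake wins), OL (wins, fake
wins and near-misses) — and the four channels are reduced to a binary
response series `y` by a trial-wise OR over one of four nested sets {BI},
{BI, DU}, {BI, DU, CS}, {BI, DU, CS, MS}. The 3 × 4 product yields twelve
datasets per cohort; the win definitions are nested, so the coded inputs
satisfy OL ≥ WLG ≥ WLN trial by trial.

# The five core models

The perceptual backbone is a three-level binary Hierarchical Gaussian
Filter: level 1 is the outcome, level 2 a Gaussian random walk on the
log-odds of winning, level 3 a Gaussian random walk on the log-volatility of
level 2. The level-2 step-size variance is `exp(κ μ3 + ω)` with κ fixed at 1
for identifiability; ϑ > 0 is the level-3 step-size variance. Each trial the
filter forms the prediction `x̂1 = logistic(μ2)`, computes the outcome
prediction error `δ1 = u − x̂1`, and updates each level by a
precision-ratio-weighted prediction error; the level-3 precision update uses
the volatility prediction error `δ2` with weight
`w2 = exp(κ μ3 + ω) π̂2`. A non-positive updated precision marks the
parameter set invalid; the fitting objective treats that region as −∞ rather
than clipping. The concrete update equations are the standard variational
scheme for the binary three-level filter; any algebraically equivalent
parameterisation would pass the same invariant suite (precision-ratio form,
monotone convergence under constant input, ω-graded learning rates,
volatility-responsive third level).

Responses follow a sigmoid `p(y=1) = 1 / (1 + exp(−2 β x))` whose argument
and temperature define the model space:

| model | temperature β(k) | argument | free parameters |
|-------|------------------|----------|-----------------|
| M1 | constant (estimated) | x̂1 | ω, ϑ, β |
| M2 | 1 / σ2 (pre-trial) | x̂1 | ω, ϑ |
| M3 | 1 / exp(μ3) (pre-trial) | x̂1 | ω, ϑ |
| M4 | constant (estimated) | 4 σ1 | ω, ϑ, β |
| RW | constant (estimated) | V (pre-trial) | α, β |

σ1 = x̂1(1 − x̂1) is the Bernoulli variance of the prediction, maximal (0.25)
at x̂1 = 0.5; the factor 4 maps it onto the unit interval. The
Rescorla–Wagner comparator tracks the outcome probability by
`V(k) = V(k−1) + α (u(k) − V(k−1))` with V0 = 0.5.

Two timing/form conventions are genuinely open and were fixed as follows:

* **Response timing.** The trial-k response uses beliefs available *before*
  outcome k: x̂1(k) (a function of μ2(k−1)), σ2(k−1), μ3(k−1), V(k−1). A
  player bets and switches before the reels stop.
* **Sigmoid form.** The mapping is implemented literally, so p ≥ 0.5
  whenever the argument is non-negative — the response probability never
  drops below one half for any belief in [0, 1]. A centred variant
  (argument x − 0.5) is available behind `literal = FALSE` because the
  uncentred form cannot express below-chance responding, but the literal
  form is the default and is what all shipped analyses use.

# Fitting: MAP with Laplace evidence

Each subject × model × dataset fit maximises the log joint (Bernoulli
response likelihood plus Gaussian priors in transformed space: ω identity,
log ϑ, log β, logit α) by deterministic multistart BFGS. Default priors are
weak and centred on the task-typical scale: ω ~ N(−4, 2),
log ϑ ~ N(log 0.05, 1), log β ~ N(0, 2), logit α ~ N(0, 1.5); they are
configuration, not constants. Starting points come from the prior-quantile
lattice {0.1, 0.5, 0.9} per dimension, deterministically subsampled to 8
restarts (500 iterations, relative tolerance 1e−10). The log model evidence
is the Laplace approximation at the mode, with a central finite-difference
Hessian (step 1e−4); if the negative Hessian is not positive definite the
fit falls back to a BIC-style evidence `loglik − (d/2) log n` and flags it.
Response probabilities are clipped to [1e−12, 1 − 1e−12] inside the
likelihood; x̂1 is clipped to [1e−8, 1 − 1e−8] before σ1 and δ1.

This MAP + Laplace scheme is the package's inference surrogate for the
fixed-form variational optimisation used with this model family: both
approximate the posterior by a Gaussian, and the downstream random-effects
comparison consumes any consistent evidence approximation.

# Model selection

**Stage 1.** Within each dataset, the subjects × models log-evidence matrix
enters random-effects Bayesian model selection: a variational
Dirichlet-multinomial scheme (uniform Dirichlet prior α0 = 1, tolerance
1e−6, at most 500 iterations) yielding posterior expected model
probabilities r_k and Monte-Carlo exceedance probabilities (1e5 seeded
Dirichlet draws). On a decisive two-subject toy problem the variational
posterior agrees with brute-force numerical integration to well under a
percentage point.

**Stage 2.** Each dataset's stage-1 winner contributes a regression of the
trait score on its subject-wise native-space estimates. The twelve
candidates are ranked by the Gaussian-form BIC
`n ln(RSS/n) + (k+1) ln(n)` (ties to fewer regressors), and significance is
Bonferroni-corrected at 0.05/12. The BIC convention is stated explicitly
because published regression tables do not always declare theirs; BIC
*differences* within the ranking are what matters, and those are invariant
to outcome shifts. Variance inflation factors are reported per regressor.

# Simulation-study sizes

The shipped validation studies use sizes chosen to keep a full run on one
core in minutes while preserving the study's structure: parameter recovery
uses 40 M2 agents at the full 200 trials; model recovery uses 3 replicates
per generating model at 16 subjects with a reduced optimiser budget (3
restarts × 200 iterations — estimates match the full budget to three
decimals in pilots); the end-to-end construct-validity study uses 5
replicates of 47 subjects, sharing the fitted models between the
linked-trait and noise-trait arms since the responses do not depend on the
trait model.

# Known limitations

* **ϑ is very weakly identified.** With a single 200-trial binary series and
  the default initial states, the likelihood is nearly flat in ϑ: the
  per-subject information corresponds to a standard error two orders of
  magnitude above the generative spread, so MAP estimates collapse to the
  prior mean. This mirrors the identifiability concerns that motivate fixing
  κ in the first place; cohort-level correlations between true and estimated
  ϑ are accordingly near zero, and analyses should treat ϑ̂ as
  prior-dominated.
* **Posterior σ2 confounds volatility with first-level certainty.** The
  second-level posterior variance falls when outcomes alternate, because
  x̂1 ≈ 0.5 maximises the Bernoulli observation precision — an effect that
  outweighs the volatility response. The volatility signal lives in μ3 (and
  the step-size variance `exp(κ μ3 + ω)`), which is what the package's
  property tests assert.
* **Stage-2 selection can dilute single-coefficient tests.** When a
  three-parameter model wins stage 1 on a mis-coded dataset, its β̂ estimate
  is collinear with ω̂ (both proxy the same generative quantity), splitting
  credit across coefficients; the overall F remains informative.
* The literal sigmoid cannot produce below-chance responding; channels are
  simulated conditionally independent; and all regressions are in-sample —
  no cross-validated prediction is attempted.
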