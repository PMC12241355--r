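---
title: "Modelling working-memory and reinforcement-learning contributions to stimulus-response learning"
author: "rlwm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling working-memory and reinforcement-learning contributions to stimulus-response learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

People can learn which response a stimulus demands in two ways: slowly and
incrementally, by reinforcement learning (RL), or instantly, by holding the
association in working memory (WM). WM is fast but capacity-limited, decays,
and costs effort. The task this package models dissociates the two systems
behaviourally: stimuli are learned in blocks whose *set size* varies from 2
to 5 items, each stimulus is presented nine times in pseudo-random order,
one of three buttons is correct per stimulus, and correct responses earn +2
points with probability 0.8 (+1 otherwise). Because WM holds only a few
items, its contribution shrinks as set size and inter-presentation delay
grow, while RL is insensitive to both — so accuracy as a function of set
size, delay, and previous correct iterations separates the systems. A
surprise test phase (pick the more rewarded of two stimuli drawn from across
blocks, no feedback) probes what the slow, stimulus-value system retained.

## The mixture model

Six free parameters: the RL learning rate $\alpha_{RL}$, the punishment
neglect $\gamma$, the WM decay $\phi$, the baseline WM reliance $\rho$, the
integer WM capacity $K \in \{2,\dots,5\}$, and the test-phase guessing rate
$\nu$. The softmax inverse temperature is fixed at $\beta = 50$ because it
trades off against $\alpha_{RL}$ and $\rho$; at that value choices are
effectively driven by the larger action value.

Per block, both systems start uniform, $Q(s,a) = WM(s,a) = 1/n_a$. After
each trial with binary outcome $r \in \{0,1\}$:

* RL: $Q \leftarrow Q + \alpha_{RL}(r - Q)$ on correct trials, and
  $Q \leftarrow Q + \alpha_{RL}\gamma(0 - Q)$ on errors — incorrect feedback
  is partially neglected.
* WM: $WM \leftarrow 1$ on correct trials (one-shot encoding);
  $WM \leftarrow (1 - \gamma)\,WM$ on errors.
* All WM entries other than the observed pair decay toward the prior:
  $WM \leftarrow WM + \phi(1/n_a - WM)$.
* A stimulus-level critic learns $V(s)$ with the same rates, and supplies
  the test-phase values.

Choice mixes the two softmax policies,
$p = (1-\omega)\,p_{RL} + \omega\,p_{WM}$, with a per-stimulus weight

$$\omega = \rho \cdot \min\!\left(1, \frac{K}{n_{delay}}\right),$$

where $n_{delay}$ is the delay since that stimulus's last correct response.
Test-phase choices follow a two-option softmax of the critic values mixed
with a uniform guess at rate $\nu$.

### How the delay is counted — a deliberate design choice

The delay clock is the one genuinely open design point, and it matters. The
package ships three variants (`delay_mode`):

* `"trials"` (default): $n_{delay}$ counts every trial since the stimulus's
  last correct response — the same clock as the behavioural delay regressor
  (correct at trial 4, shown at trial 7, delay 3).
* `"gap"`: unique intervening stimuli within each gap between successive
  presentations, accumulated across gaps since the last correct response.
* `"window"`: unique intervening stimuli over the whole window since the
  last correct response.

Under `"window"`, $n_{delay}$ can never exceed set size − 1 = 4, with two
hard consequences we verified empirically: capacities 4 and 5 produce
*identical* likelihoods for every possible dataset (the capacity-grid
profile ties exactly), and the delay modulation saturates so quickly that
set sizes 2–4 are indistinguishable at capacity 3 and parameter recovery
collapses. A capacity grid over 2..5 is only meaningful when the delay can
exceed 5, which is why the trial clock is the default; the item-counting
variants are retained because they are the reading under which "capacity at
least as large as the set size" guarantees one-shot-perfect WM (a limiting
case the test suite checks under `delay_mode = "gap"`).

Update order within a trial is fixed and identical in simulation and
likelihood: choice, then delay counters, then the RL/WM/critic updates for
the observed pair, then WM decay. Decay exempts only the observed
(stimulus, action) pair by default (`decay_scope = "pair"`); exempting the
stimulus's whole row is available. The critic learns from the binary
correct/incorrect signal by default; a point-coded mode (0/1/2) exists
because the test phase asks about points.

## Fitting

Per subject-session MAP estimation: for each integer capacity in 2..5, the
five continuous parameters are maximised by multi-start L-BFGS-B (default 20
starts: one mid-range deterministic start plus uniform draws; box bounds
shrunk inward by $10^{-5}$ so the priors stay finite), and the capacity with
the best log-posterior wins, smallest capacity on exact ties. Priors are
beta(1.05, 1.05) on $\phi$, $\gamma$, $\nu$ — just enough to pull estimates
off the bounds — and uniform on $\alpha_{RL}$, $\rho$, and the capacity
grid. The training-phase and test-phase likelihoods are maximised jointly by
default (`include_test = FALSE` gives a training-only ablation). After
fitting a cohort, `exclude_param_outliers()` applies the per-session ±2 SD
screen (single pass, zero-SD groups exclude nobody, groups under 3 are
passed through with a warning).

The session likelihood is implemented twice: a compiled core used
everywhere, and a plain-R step-by-step trace assembled from the exported
scalar update functions. The two are compared to $10^{-10}$ across random
tasks, parameters and model variants in the test suite; the softmax is
computed with max-subtraction so $\beta = 50$ never overflows.

## The synthetic cohort

`generate_population()` emulates the study's structure: a standard-normal
dopamine-synthesis proxy per subject, three drug sessions (placebo,
methylphenidate, sulpiride) in counterbalanced order, fresh stimuli and a
fresh design per session. Covariates shift parameters on the logit scale
through an effect map whose defaults reproduce the *direction* of the
reported group effects (synthesis capacity → more WM reliance; sulpiride →
less reliance, faster decay; methylphenidate × synthesis → higher learning
rate) with invented magnitudes — the source analyses report standardised
regression coefficients, not generative effect sizes, so these defaults are
placeholders for recovery exercises, not estimates. An optional effort cost
$\kappa$ devalues test-phase values by $\kappa \times$ set size of the
block a stimulus was learned in, the minimal mechanism for "rewards earned
under high WM load feel smaller"; it touches only simulated test choices.
Response times are lognormal with median 1.07 s purely so the 250 ms filter
is exercisable — they model nothing cognitive.

What the generator does *not* emulate: real PET-derived synthesis values,
session-order or fatigue effects, mood and physiological covariates,
reaction-time dynamics, and any within-session parameter drift. Passing
tests on synthetic cohorts therefore demonstrates internal consistency of
simulator, likelihood and fitting machinery — not that the model is true of
human data.

## Validation harnesses and what they show

* `run_recovery()` (90 subjects by default, parameters sampled uniformly
  from the published range of fitted values) simulates, refits, and reports
  per-parameter correlation, bias, RMSE and a capacity confusion matrix.
* `run_ppc()` simulates replicate sessions at MAP parameters on each
  subject's own realised design — conditioning on the realised stimulus
  sequences isolates model misfit from design variance — and compares
  accuracy in every set size × iteration cell.

Recovery at single-session scale is honest but sobering, and the package
reports it rather than hiding it. Two structural features limit it. First,
with $\beta = 50$ the policies saturate, so $\rho$, $\phi$ and (through the
error pathway) $\gamma$ all modulate "how effective WM looks" and trade off
along a ridge; even with every other parameter known, one session bounds
the precision of $\phi$ well below what a 0.7 truth-estimate correlation
would need over the fitted range. Second, the mixture has a genuine
reflection: an agent with $\alpha_{RL}$ near 1 (one-shot RL) and a small
$\rho$ on a decayed, uniform WM store behaves almost exactly like a
high-$\rho$ WM learner with a lapse, and for a minority of simulated
subjects that reflection is the true global MAP — more optimisation
restarts find it *more* reliably, not less. Capacity and $\gamma$ recover
best; $\rho$, $\phi$ and $\alpha_{RL}$ correlations are reported by
`run_recovery()` and the acceptance script for the exact numbers. Posterior
predictive checks are unaffected by the ridge (any point on it reproduces
the curves), which is precisely why both harnesses exist.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-variance recovery samplers
return flagged NaN correlations; empty sessions are flagged incomplete and
skipped; ties in test-pair earnings are flagged and excluded from accuracy
scoring; the logistic stand-in falls back to a lightly ridge-penalised IRLS
under complete separation. The pseudo-random sequence generator shuffles
per iteration sweep and rejects immediate repeats, which preserves exactly
nine appearances per stimulus; a single-stimulus block is a configuration
error. Validation runs use 90 subjects for recovery, a 200-subject
single-session cohort with 20 replicate draws for the posterior predictive
check, and 100 replicate 20-subject cohorts for the effort-cost sign check
— sizes at which the reported summaries are stable on one core.

## Known limitations

* The hierarchical Bayesian trial-level regressions of the original
  analyses are replaced by a fixed-effects logistic stand-in, used only for
  sign and qualitative checks; its coefficients are not comparable to
  published hierarchical estimates.
* Single-session MAP estimates of $\rho$, $\phi$ and $\alpha_{RL}$ are
  strongly interdependent (see above); group-level conclusions should rest
  on many subjects, and capacity estimates above 4 are design-limited.
* The generator's covariate effect magnitudes are conventions, not
  estimates; only effect *directions* are meaningful.
* No reaction-time model, no neural predictions, and no dynamic
  reliability-weighted WM mixture (rejected for recoverability in the model
  class this package implements).
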