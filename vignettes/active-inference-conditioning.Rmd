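---
title: "Active inference, Dirichlet learning, and simulated dopamine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active inference, Dirichlet learning, and simulated dopamine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`actinf` simulates an agent that solves a finite-horizon, discrete Markov
decision process by variational Bayes. The generative model has hidden states
$s_t$, observations $o_t$, and control states $u_t$; allowable control
sequences from the current time to the horizon $T$ are the policies $\pi$.
Three objects specify the model: an observation matrix $A$ with
$P(o_t = i \mid s_t = j) = A_{ij}$, control-dependent transition matrices
$B(u)$ with $P(s_{t+1} = i \mid s_t = j, u) = B(u)_{ij}$, and a
log-preference vector $C(s_T) = \ln P(s_T)$ over terminal states, whose
entries play the role of utilities.

Policies are valued by KL control: the quality of policy $\pi$ from state
$s$ is

$$Q(s, \pi) = -D_{KL}\!\left[ P(s_T \mid s_t = s, \pi) \,\|\, e^{C} \right],$$

the negative divergence between the predictive distribution over terminal
states and the preferred one, so $Q \le 0$ with equality only when a policy
is expected to land exactly on the preferences.

Within each epoch the agent iterates three closed-form updates (16 rounds by
default) to a fixed point:

* **states** $\hat{s}_t = \sigma(\hat{A}\cdot o_t + \hat{B}(a_{t-1})\hat{s}_{t-1} + \hat{\gamma}\, Q \hat{\pi})$,
* **policies** $\hat{\pi} = \sigma(\hat{\gamma}\, Q^\top \hat{s}_t)$,
* **precision** $\hat{\gamma} = \alpha \,/\, (\beta - \hat{\pi} \cdot Q^\top \hat{s}_t)$,

where $\sigma$ is a softmax, $\hat{A}$ and $\hat{B}$ are *expected-log*
matrices (digamma differences of Dirichlet concentrations), and
$(\alpha, \beta)$ are the shape and rate of a Gamma prior on precision
(named `prec_shape`/`prec_rate` throughout to keep them distinct from the
Dirichlet concentrations). The $\hat{\gamma} Q \hat{\pi}$ term in the state
update is an optimism bias: perception is pulled toward valuable states in
proportion to the confidence the agent has in its policy beliefs. That
coupling is what makes externally clamped precision scientifically
interesting — it is the lever by which the package simulates dopaminergic
interventions.

Actions are sampled from the posterior marginal over the control prescribed
at the current transition. Precision therefore acts as a context-sensitive
inverse temperature: it rises when observations raise the expected value of
the policies and collapses choice onto the best option, and it falls after
disappointments.

Learning is conjugate Dirichlet accumulation, applied once per trial:
observation counts $\hat{\alpha}_{ij} \mathrel{+}= o_{ti}\hat{s}_{tj}$ and,
for the action actually taken, transition counts
$\hat{\beta}(a)_{ij} \mathrel{+}= \hat{s}_{ti}\hat{s}_{(t-1)j}$. Exactly one
unit of mass is added per epoch and per transition, so concentration totals
count the evidence the agent has seen, and the implicit learning rate decays
as $1/(\text{prior mass} + n)$. Expected precision appears nowhere in these
updates — learning and precision are separated by a Markov blanket — which
is the formal content of the claim that the dopamine analogue modulates
performance rather than serving as a teaching signal.

## The conditioning task

`conditioning_task()` builds a trace-conditioning environment with 14 hidden
states — two pre-cue states, two cue states, four two-step delay chains (one
per cue-response combination, so the state itself remembers what was seen
and done), and win/no-win outcome states — five observations (null, two
cues, two outcomes) and three controls (wait, two responses). A trial has
six epochs: pre-cue, pre-cue, cue, delay, delay, outcome, with the response
taken at the third transition. Each cue-response pair pays out with a fixed
probability; the default contingencies are 0.8/0.2 for cue 1 and the mirror
image for cue 2. A single-cue variant (`single_cue_contingencies()`, cue
probabilities `c(1, 0)`) reproduces the stimulation-learning design in which
response 1 is never rewarded and response 2 pays half the time.

The agent's priors follow the task description: transitions it plausibly
knows from experience (the trial scaffold) get concentration 512 on the true
entries — split proportionally when the true column is stochastic, as for
the even cue draw — and a floor of $10^{-6}$ elsewhere; 512 dominates
anything a session can add, so these stay effectively fixed. The unknown
delay-to-outcome transitions get weak concentrations (no-win 1, win 0.4),
i.e. a prior win expectation of $0.4/1.4 \approx 0.286$ that learning must
overwrite. The preference puts probability 0.95 on the win state
(`pref_win`); the task description gives no number, and 0.95 (about 3 nats
of utility difference) is strong enough for KL control to discriminate
policies without drowning the evidence terms.

### Calibrated constants

Two constants are genuinely unidentified by the task description and were
fixed by calibration, once, against the phenomena the model is supposed to
exhibit jointly:

* **Precision prior, `prec_shape = 4`, `prec_rate = 1`.** The prior mean
  $\alpha/\beta$ is the ceiling of unclamped precision and hence the softmax
  gain on action selection. A grid over shapes 2–8 (rate 1) shows the
  competing pressures: at mean 8 the agent locks onto the first rewarded
  option after a trial or two and never samples the alternatives, so the
  unchosen contingencies are not learned; at mean 2 the policy posterior
  stays soft at the cue, and a visible fraction of the learned value signal
  resolves only when the delay state confirms the action, producing a
  spurious delay-epoch dopamine response. Means 3–6 reproduce everything;
  4 sits in the middle of that region. It also keeps the spike-rate readout
  physiological (peaks of 10–15 spikes/bin) and leaves the stimulation
  clamp of 16 four times above anything inference can produce, which is
  precisely what forces the false-inference effect.
* **Observation-prior floor, `a_floor = 0.1`.** "Strong and accurate"
  observation beliefs are implemented as concentration 512 on the true
  outcome and 0.1 elsewhere: the expected observation matrix is accurate to
  about $10^{-3}$, but the log-evidence penalty for a state inconsistent
  with the observation is finite ($\psi(0.1) - \psi(512) \approx -16.7$
  nats). With a $10^{-6}$ floor the penalty would be $\sim 10^{6}$ nats and
  no physiologically meaningful precision clamp could ever override the
  sensory evidence; with 0.1 the unclamped agent (log-odds about $-13$)
  still infers no-win essentially with certainty, while a clamp of 16
  supplies $16 \times 2.95 \approx 47$ nats of optimism and flips the
  posterior, as required.

## Interventions and the dopamine readout

Clamp schedules (`depletion_schedule()`, `stimulation_schedule()`) fix
$\hat{\gamma}$ at chosen epochs/trials, skipping the precision update
entirely so the trace shows a plateau; an action-contingent variant applies
only on trials where a given response was taken. Clamps touch nothing but
the precision pathway.

The dopamine analogue treats the per-iteration precision trace as the
convolution of a phasic innovation signal with an exponentially decaying
kernel of time constant 16 iterations (one epoch); `deconvolve_precision()`
inverts this by forward substitution. Because the first bin has no history
the first epoch carries a boundary artifact and is dropped from readouts.
The per-epoch "response" is the innovation in excess of the tonic level
needed to sustain current precision, summed over the epoch's bins, which
telescopes to the net within-epoch change in $\hat{\gamma}$ — so positive
responses are precision jumps and dips are drops. `simulate_spikes()` maps
innovations to Poisson rates (4 spikes/bin per unit innovation over a
4 spikes/bin background); negative innovations are rectified by default
(`dip_mode = "rectify"`), since firing cannot be negative, while the
`"subtract"` mode permits below-baseline dips for population-level
displays.

In the four replay conditions the same response (response 1) is forced after
both cues so the conditions differ only in cue and outcome; with the
symmetric default contingencies this makes cue 1 the high-reward and cue 2
the low-reward context for the replayed action. One consequence of the
symmetric task is worth knowing: after learning, *both* cues raise the
agent's prospects under its own preferred policy, so the "low cue dip"
appears at the first delay epoch (when the forced, dispreferred response
reveals itself) rather than at the cue.

## Per-trial free energy

The reported free energy is the minimized form, complexity minus accuracy,
summed over epochs: the expected log-likelihood of each observation under
the state posterior, minus KL terms for states (against the one-step
prediction), policies (against a uniform prior), and precision (Gamma
posterior $\Gamma(\alpha, \alpha/\hat{\gamma})$ against its prior). Because
concentrations update only at trial end, the parameter complexity of a trial
is the Dirichlet KL of end-of-trial against start-of-trial concentrations —
the increment that trial's data contributes. Measured this way the curve
falls across learning, driven by shrinking outcome surprise and shrinking
parameter increments; measuring parameter complexity against the time-zero
prior instead would make the curve grow mechanically with accumulated
evidence, which is why the per-trial increment is the quantity reported.

## What the simulations show (and what they do not)

The five experiment drivers reproduce, from the synthetic task alone:
contingency recovery with falling free energy (`learning_experiment()`);
the conditioning signature of the phasic signal and its direct outcome-to-cue
transfer without intermediate-epoch mediation
(`dopamine_dynamics_experiment()`); chance-level performance under a 0.1
precision clamp with intact learning revealed on restoration
(`depletion_experiment()`); clamp-induced false inference of a win outcome,
monotone in clamp strength (`stimulation_inference_experiment()`); and
action-contingent stimulation reversing preference toward a never-rewarded
response (`stimulation_learning_experiment()`).

Default sizes follow the full-scale designs (256 sessions; 128, 32+16, or
48 trials; 81-point clamp sweep; 64-trial spike averages). The packaged
tests and the acceptance script run the stochastic experiments at 64
sessions, a size at which every effect above is stable across seeds while a
full run stays in the minutes range on one core; the session count is an
argument everywhere, so full-scale runs are one call away.

These are simulations of an idealized agent in a small, fully specified
environment. The generator emulates the trial structure, contingencies and
observation model of a trace-conditioning experiment; it does not emulate
measurement noise, inter-animal variability, drifting contingencies,
vigor/latency phenomena, or any biophysics of dopamine neurons, so passing
tests validate the computational story, not quantitative predictions for
real recordings.

## Numerical choices and degenerate inputs

* Softmax inputs are shifted by their maximum; log-evidence from
  near-impossible transitions ($\sim -10^{6}$ nats) is handled without
  overflow.
* KL divergences floor the second argument at $10^{-16}$ (deterministic
  predictions carry exact zeros); $0 \log 0 = 0$ on the first argument.
* The initial state is known; its log-prior is floored at $10^{-14}$.
* Dirichlet concentrations must be strictly positive; the constructors
  refuse nonpositive entries, and `dirichlet_expected_log()` is exercised
  down to concentrations of 0.1 (where $\psi$ is large and negative but
  finite).
* Ties in the objectively-correct-action metric break toward the lower
  response index; with the default contingencies ties never occur.
* All randomness flows through R's RNG: a session, an experiment, and the
  acceptance script are bit-reproducible given a seed.

## Known limitations

Policies are fixed control sequences (two of them by default); the policy
set does not branch on future observations, and the wait-throughout policy
is excluded by default because the task defines delay chains only for
cue-response pairs (a flag adds it back). Learning is online and per-trial;
there is no forgetting, no smoothing sweep over past states, and no learning
of the precision hyperparameters. Where a "do nothing" response at the
choice point would lead is undefined by the task; the agent's model treats
it as remaining in the cue state, and the default policy set never takes it.
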