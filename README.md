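# actinf

Active-inference agents with conjugate Dirichlet learning for discrete
Markov decision processes, built around a simulated instrumental-conditioning
task and a precision-based account of phasic dopamine.

## The problem

Phasic dopamine firing looks like a reward prediction error, yet dopamine
depletion mainly degrades task performance while leaving learning intact,
and direct stimulation of dopamine neurons is sufficient to create a
behavioral preference. `actinf` implements the computational account that
reconciles these observations: dopamine encodes the *expected precision*
γ̂ of beliefs about action — a context-sensitive inverse temperature — not a
teaching signal. The package is for computational neuroscientists and
decision-theory researchers who want a small, fully inspectable agent in
which that hypothesis, and its perturbations, can be simulated end to end.

## The model

The agent holds a generative model of a finite-horizon MDP: an observation
matrix `A` (`P(o|s)`), control-dependent transitions `B(u)` (`P(s'|s,u)`),
and log-preferences `C(s_T) = ln P(s_T)` over terminal states. Policies π
(control sequences to the horizon) are valued by KL control,

    Q(s, π) = −KL[ P(s_T | s_t = s, π) ‖ exp(C) ] ≤ 0,

and each epoch iterates the variational fixed point

    ŝ_t  = σ( Â·o_t + B̂(a_{t−1}) ŝ_{t−1} + γ̂ · Q π̂ )
    π̂    = σ( γ̂ · Qᵀ ŝ_t )
    γ̂    = α / ( β − π̂ · Qᵀ ŝ_t )

where `Â`, `B̂` are expected-log (digamma) matrices of Dirichlet beliefs
and `(α, β)` parameterize the Gamma prior on precision. Learning is
Hebbian-looking count accumulation on the Dirichlet concentrations, applied
at trial end; γ̂ never enters it. The γ̂·Qπ̂ term biases perception toward
valuable states, which is how clamping precision high ("stimulation")
produces false inference of reward, and clamping it low ("depletion")
produces outcome-insensitive choice with learning intact. The per-iteration
γ̂ trace, deconvolved with an exponential kernel, is the simulated dopamine
signal; a Poisson stage turns it into spike-count histograms.

## Worked example

```r
library(actinf)

task <- conditioning_task()     # two cues, two responses, p(win) 0.8 / 0.2
task
#> <task_spec> trace conditioning task
#>   14 states, 5 observations, 3 controls, 6 epochs
#>   cue probabilities: 0.5, 0.5
#>   reward probabilities (cue x response):
#>       response
#> cue    resp1 resp2
#>   cue1   0.8   0.2
#>   cue2   0.2   0.8

set.seed(7)
ses <- run_session(task, n_trials = 32)      # one conditioning session
round(estimated_win_probs(task, ses$beliefs), 3)
#>       response
#> cue    resp1 resp2
#>   cue1 0.805 0.167
#>   cue2 0.286 0.837
mean(ses$trials$correct[25:32])
#> [1] 1
```

After 32 trials the agent's posterior win probabilities sit near the true
contingencies for the options it has sampled (the cue2/resp1 cell is still
at its 0.4/1.4 ≈ 0.286 prior — that option stopped being chosen) and choice
is at ceiling. Clamping precision at outcome time reverses what the agent
believes it saw:

```r
si <- stimulation_inference_experiment()
round(si$unclamped[["nowin"]], 3)   # no-win observed, precision inferred
#> [1] 1
round(si$clamped[["win"]], 3)       # same observation, gamma_6 clamped at 16
#> [1] 1
```

The same no-win observation yields a near-certain *no-win* posterior when
precision is inferred, and a near-certain *win* posterior under the clamp —
the false-inference mechanism by which stimulation drives learning.
`si$sweep` holds the 81-point dose-response curve. The other drivers are
`learning_experiment()`, `depletion_experiment()`,
`stimulation_learning_experiment()` and `dopamine_dynamics_experiment()`;
see the vignette (`vignettes/active-inference-conditioning.Rmd`) for the
model details and design choices.

## Command-line use

```sh
Rscript inst/scripts/simulate.R learn --sessions 64 --trials 128 --seed 1 --out simout
Rscript inst/scripts/simulate.R stimulate-learn --sessions 64 --out simout
```

Subcommands `learn | deplete | stimulate-infer | stimulate-learn | dopamine`
write tidy CSV curves plus a JSON summary. A YAML config (`--config`) can
override the task (`high`/`low` or `single_cue` with `p1`/`p2`,
`cue_probs`) and any `agent_config()` field; see
`read_experiment_config()`.
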