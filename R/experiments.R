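#' Policy-value matrices for every epoch of a trial
#'
#' Backward recursion over the policies' control sequences, giving the same
#' matrices as calling [compute_policy_values()] at each epoch but with one
#' pass per policy. Beliefs are fixed within a trial, so this is computed
#' once per trial.
#'
#' @param model A [generative_model()].
#' @param beliefs A [dirichlet_beliefs()] object.
#' @return List of `T` matrices, each `n_states` x `n_policies`.
#' @export
policy_values_all <- function(model, beliefs) {
  n_pol <- nrow(model$policies)
  pref_log <- log(pmax(exp(model$C), 1e-16))
  Qs <- vector("list", model$T)
  for (t in seq_len(model$T)) {
    Qs[[t]] <- matrix(0, model$n_states, n_pol)
  }
  for (k in seq_len(n_pol)) {
    P <- diag(model$n_states)
    Qs[[model$T]][, k] <- neg_kl_columns(P, pref_log)
    for (t in (model$T - 1L):1L) {
      P <- P %*% beliefs$EB[[model$policies[k, t]]]
      Qs[[t]][, k] <- neg_kl_columns(P, pref_log)
    }
  }
  Qs
}

# columnwise -KL(P[, s] || exp(pref_log)); zero entries contribute zero
neg_kl_columns <- function(P, pref_log) {
  PlogP <- P * log(P)
  PlogP[P == 0] <- 0
  -(colSums(PlogP) - colSums(P * pref_log))
}

#' Simulate one trial of agent-environment interaction
#'
#' Alternates environment steps and epoch inference across the trial: the
#' true process starts in pre-cue 1, the agent infers states/policies/
#' precision each epoch, samples its action for each transition from the
#' policy posterior, and (optionally) applies the end-of-trial Dirichlet
#' update. Precision clamps from `schedule` are applied per epoch.
#'
#' @param model A [generative_model()].
#' @param beliefs A [dirichlet_beliefs()] object.
#' @param task A [conditioning_task()].
#' @param schedule Optional [clamp_schedule()] (or list of schedules).
#' @param trial Trial index (used by trial-ranged schedules).
#' @param learn Apply [end_of_trial_update()] (default `TRUE`).
#' @param learn_A,learn_B Flags passed to the update.
#' @return List with `record` (class `trial_record`: observations, actions,
#'   `s_hat_final`, `gamma_trace`, per-epoch `free_energy`, `action_S`,
#'   `param_complexity`, `cue`, `choice`, `outcome_win`, `correct`) and
#'   `beliefs` (updated when `learn`).
#' @export
run_trial <- function(model, beliefs, task, schedule = NULL, trial = 1L,
                      learn = TRUE, learn_A = TRUE, learn_B = TRUE) {
  T <- model$T
  Qs <- policy_values_all(model, beliefs)
  log_init <- log(pmax(c(1, rep(0, model$n_states - 1L)), 1e-14))
  bstate <- belief_state(model)

  s_true <- 1L
  s_true_seq <- integer(T)
  s_true_seq[1L] <- s_true
  observations <- integer(T)
  actions <- integer(T - 1L)
  free_energy <- numeric(T)
  choice_action <- NA_integer_

  observations[1L] <- sample.int(task$n_obs, 1L, prob = task$true_A[, 1L])
  clamp <- clamp_value(schedule, trial, 1L, choice_action)
  bstate <- infer_epoch(model, beliefs, bstate, observations[1L], 1L,
                        a_prev = NULL, Q = Qs[[1L]], clamp = clamp,
                        log_init = log_init)
  free_energy[1L] <- compute_free_energy(
    model, beliefs, bstate$s_hat[, 1L], bstate$pi_hat, bstate$gamma_hat,
    observations[1L], log_init = log_init)

  for (t in 2:T) {
    a <- sample_action(model, bstate$pi_hat, t - 1L)
    actions[t - 1L] <- a
    if (t - 1L == task$choice_epoch) choice_action <- a
    step <- environment_step(task, s_true, a)
    s_true <- step$state
    s_true_seq[t] <- s_true
    observations[t] <- step$obs
    clamp <- clamp_value(schedule, trial, t, choice_action)
    bstate <- infer_epoch(model, beliefs, bstate, observations[t], t,
                          a_prev = a, Q = Qs[[t]], clamp = clamp)
    free_energy[t] <- compute_free_energy(
      model, beliefs, bstate$s_hat[, t], bstate$pi_hat, bstate$gamma_hat,
      observations[t], s_prev = bstate$s_hat[, t - 1L], a_prev = a)
  }

  param_complexity <- 0
  if (learn) {
    rec0 <- list(observations = observations, actions = actions,
                 s_hat_final = bstate$s_hat)
    beliefs <- end_of_trial_update(beliefs, rec0, learn_A = learn_A,
                                   learn_B = learn_B)
    param_complexity <- attr(beliefs, "param_complexity")
  }

  cue <- s_true_seq[task$choice_epoch] - 2L    # cue states are 3 and 4
  choice <- if (is.na(choice_action) || choice_action == 1L) NA_integer_
            else choice_action - 1L
  correct <- !is.na(choice) && choice == best_response(task, cue)

  record <- structure(
    list(observations = observations, actions = actions,
         s_true = s_true_seq, s_hat_final = bstate$s_hat,
         pi_hat = bstate$pi_hat, gamma_trace = bstate$gamma_trace,
         clamped = bstate$clamped, free_energy = free_energy,
         action_S = sum(free_energy), param_complexity = param_complexity,
         cue = cue, choice = choice,
         outcome_win = s_true == task$win_state, correct = correct,
         trial = as.integer(trial)),
    class = "trial_record"
  )
  list(record = record, beliefs = beliefs)
}

#' Replay a fixed observation/action sequence through an agent
#'
#' Runs the within-trial inference loop on externally supplied observations
#' and actions, without touching the environment or the Dirichlet beliefs.
#' Used for the dopamine replay conditions and the stimulation-inference
#' probe, where identical sensory streams must be compared across agents or
#' clamp values.
#'
#' @param model A [generative_model()].
#' @param beliefs A [dirichlet_beliefs()] object.
#' @param observations Integer vector of `T` outcome indices.
#' @param actions Integer vector of `T - 1` control indices.
#' @param schedule Optional [clamp_schedule()] (or list).
#' @param trial Trial index for trial-ranged schedules.
#' @param choice_epoch Transition whose action is used for action-contingent
#'   clamps (default 3).
#' @return A `trial_record` (without environment fields `cue`/`correct`).
#' @export
replay_trial <- function(model, beliefs, observations, actions,
                         schedule = NULL, trial = 1L, choice_epoch = 3L) {
  T <- model$T
  stopifnot(length(observations) == T, length(actions) == T - 1L)
  Qs <- policy_values_all(model, beliefs)
  log_init <- log(pmax(c(1, rep(0, model$n_states - 1L)), 1e-14))
  bstate <- belief_state(model)
  free_energy <- numeric(T)
  choice_action <- NA_integer_

  clamp <- clamp_value(schedule, trial, 1L, choice_action)
  bstate <- infer_epoch(model, beliefs, bstate, observations[1L], 1L,
                        a_prev = NULL, Q = Qs[[1L]], clamp = clamp,
                        log_init = log_init)
  free_energy[1L] <- compute_free_energy(
    model, beliefs, bstate$s_hat[, 1L], bstate$pi_hat, bstate$gamma_hat,
    observations[1L], log_init = log_init)
  for (t in 2:T) {
    a <- actions[t - 1L]
    if (t - 1L == choice_epoch) choice_action <- a
    clamp <- clamp_value(schedule, trial, t, choice_action)
    bstate <- infer_epoch(model, beliefs, bstate, observations[t], t,
                          a_prev = a, Q = Qs[[t]], clamp = clamp)
    free_energy[t] <- compute_free_energy(
      model, beliefs, bstate$s_hat[, t], bstate$pi_hat, bstate$gamma_hat,
      observations[t], s_prev = bstate$s_hat[, t - 1L], a_prev = a)
  }
  structure(
    list(observations = as.integer(observations),
         actions = as.integer(actions), s_true = rep(NA_integer_, T),
         s_hat_final = bstate$s_hat, pi_hat = bstate$pi_hat,
         gamma_trace = bstate$gamma_trace, clamped = bstate$clamped,
         free_energy = free_energy, action_S = sum(free_energy),
         param_complexity = 0, cue = NA_integer_, choice = NA_integer_,
         outcome_win = NA, correct = NA, trial = as.integer(trial)),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> trial %d: obs [%s], actions [%s], gamma end %.3f\n",
    x$trial, paste(x$observations, collapse = " "),
    paste(x$actions, collapse = " "),
    x$gamma_trace[length(x$gamma_trace)]))
  invisible(x)
}

#' Simulate one session of consecutive trials
#'
#' Builds the agent from the task (unless `agent` is supplied), then runs
#' `n_trials` trials with across-trial Dirichlet learning, returning a tidy
#' per-trial log and the final beliefs. Optionally snapshots the posterior
#' concentrations at the start of selected trials (used to reconstruct
#' learning curves and per-block replays).
#'
#' @param task A [conditioning_task()].
#' @param cfg An [agent_config()].
#' @param n_trials Number of trials.
#' @param schedule Optional [clamp_schedule()] (or list).
#' @param learn_A,learn_B Learning flags.
#' @param snapshot_trials Integer vector of trials whose start-of-trial
#'   posterior concentrations to keep (default none).
#' @param agent Optional list `(model, beliefs)` overriding
#'   [build_agent_model()].
#' @param keep_records Keep the full per-trial records (default `FALSE`;
#'   they include the precision trace of every trial).
#' @return List with `trials` (data.frame: trial, cue, choice, correct,
#'   outcome_win, gamma_end, free_energy, and the four win-probability
#'   estimates at end of trial), `beliefs`, `model`, `records` (list of
#'   trial records) and `snapshots` (named by trial; each holds `a_post`,
#'   `b_post`).
#' @export
run_session <- function(task, cfg = agent_config(), n_trials = 128L,
                        schedule = NULL, learn_A = TRUE, learn_B = TRUE,
                        snapshot_trials = integer(0), agent = NULL,
                        keep_records = FALSE) {
  if (is.null(agent)) agent <- build_agent_model(task, cfg)
  model <- agent$model
  beliefs <- agent$beliefs
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 1L)

  est_names <- c("est_c1r1", "est_c1r2", "est_c2r1", "est_c2r2")
  out <- data.frame(
    trial = seq_len(n_trials), cue = NA_integer_, choice = NA_integer_,
    correct = NA, outcome_win = NA, gamma_end = NA_real_,
    free_energy = NA_real_
  )
  out[est_names] <- NA_real_
  snapshots <- list()
  records <- if (keep_records) vector("list", n_trials) else NULL

  for (tr in seq_len(n_trials)) {
    if (tr %in% snapshot_trials) {
      snapshots[[as.character(tr)]] <-
        list(a_post = beliefs$a_post, b_post = beliefs$b_post)
    }
    res <- run_trial(model, beliefs, task, schedule = schedule, trial = tr,
                     learn_A = learn_A, learn_B = learn_B)
    beliefs <- res$beliefs
    rec <- res$record
    if (keep_records) records[[tr]] <- rec
    est <- estimated_win_probs(task, beliefs)
    out$cue[tr] <- rec$cue
    out$choice[tr] <- rec$choice
    out$correct[tr] <- rec$correct
    out$outcome_win[tr] <- rec$outcome_win
    out$gamma_end[tr] <- rec$gamma_trace[length(rec$gamma_trace)]
    out$free_energy[tr] <- rec$action_S + rec$param_complexity
    out[tr, est_names] <- c(est[1, 1], est[1, 2], est[2, 1], est[2, 2])
  }
  list(trials = out, beliefs = beliefs, model = model,
       records = records, snapshots = snapshots)
}

#' Parameter-recovery (learning) experiment
#'
#' Repeated sessions of the two-cue task; averages, per trial, the agent's
#' posterior-expected win probability for each of the four cue-response
#' contingencies and the trial's variational free energy.
#'
#' @param task A [conditioning_task()].
#' @param cfg An [agent_config()].
#' @param n_sessions,n_trials Simulation size (defaults 256 and
#'   128).
#' @param seed Optional RNG seed.
#' @return List with `curves` (data.frame: trial, the four mean estimates,
#'   mean free energy), `final_est` (2 x 2 mean estimate at the last trial),
#'   `true_probs`, and `n_sessions`.
#' @export
learning_experiment <- function(task = conditioning_task(),
                                cfg = agent_config(), n_sessions = 256L,
                                n_trials = 128L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  est_names <- c("est_c1r1", "est_c1r2", "est_c2r1", "est_c2r2")
  est_sum <- matrix(0, n_trials, 4L, dimnames = list(NULL, est_names))
  fe_sum <- numeric(n_trials)
  for (s in seq_len(n_sessions)) {
    ses <- run_session(task, cfg, n_trials = n_trials)
    est_sum <- est_sum + as.matrix(ses$trials[est_names])
    fe_sum <- fe_sum + ses$trials$free_energy
  }
  curves <- data.frame(trial = seq_len(n_trials), est_sum / n_sessions,
                       free_energy = fe_sum / n_sessions)
  final_est <- matrix(as.numeric(curves[n_trials, est_names]), 2, 2,
                      byrow = TRUE, dimnames = dimnames(task$reward_probs))
  list(curves = curves, final_est = final_est,
       true_probs = task$reward_probs, n_sessions = as.integer(n_sessions))
}

#' Dopamine-depletion experiment
#'
#' Runs a lesioned arm (precision clamped low for the first
#' `n_trials_lesion` trials, then restored for `n_trials_restore` more) and
#' an unlesioned control arm, and tracks the per-trial proportion of
#' objectively correct choices and the mean contingency estimates of both.
#'
#' @param task A [conditioning_task()].
#' @param cfg An [agent_config()].
#' @param n_sessions Sessions per arm (default 256).
#' @param n_trials_lesion,n_trials_restore Trials in the clamped and
#'   restored phases.
#' @param clamp Depletion clamp value (default 0.1).
#' @param seed Optional RNG seed.
#' @return List with `curves` (data.frame: trial, phase, correct_lesion,
#'   correct_control, the four mean estimates per arm) and sizes.
#' @export
depletion_experiment <- function(task = conditioning_task(),
                                 cfg = agent_config(), n_sessions = 256L,
                                 n_trials_lesion = 32L,
                                 n_trials_restore = 16L, clamp = 0.1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_trials <- n_trials_lesion + n_trials_restore
  sched <- depletion_schedule(value = clamp, trials = c(1L, n_trials_lesion))
  est_names <- c("est_c1r1", "est_c1r2", "est_c2r1", "est_c2r2")

  arm <- function(schedule) {
    correct_sum <- numeric(n_trials)
    est_sum <- matrix(0, n_trials, 4L)
    for (s in seq_len(n_sessions)) {
      ses <- run_session(task, cfg, n_trials = n_trials, schedule = schedule)
      correct_sum <- correct_sum + as.numeric(ses$trials$correct)
      est_sum <- est_sum + as.matrix(ses$trials[est_names])
    }
    list(correct = correct_sum / n_sessions, est = est_sum / n_sessions)
  }
  lesion <- arm(sched)
  control <- arm(NULL)

  curves <- data.frame(
    trial = seq_len(n_trials),
    phase = rep(c("lesion", "restored"),
                c(n_trials_lesion, n_trials_restore)),
    correct_lesion = lesion$correct, correct_control = control$correct
  )
  colnames(lesion$est) <- paste0("lesion_", est_names)
  colnames(control$est) <- paste0("control_", est_names)
  curves <- cbind(curves, lesion$est, control$est)
  list(curves = curves, clamp = clamp, n_sessions = as.integer(n_sessions),
       n_trials_lesion = as.integer(n_trials_lesion),
       n_trials_restore = as.integer(n_trials_restore))
}

#' Stimulation-induced false inference
#'
#' Replays the fixed sequence cue 1 / response 1 / no-win outcome through a
#' naive agent, once with precision inferred normally and once per clamp
#' value with precision fixed at the final epoch, and records the final
#' posterior mass on the win and no-win outcome states.
#'
#' @param task A [conditioning_task()].
#' @param cfg An [agent_config()].
#' @param clamp Headline stimulation value (default 16).
#' @param sweep Vector of clamp values for the dose-response sweep.
#' @return List with `unclamped` and `clamped` (named win/no-win posterior
#'   masses) and `sweep` (data.frame: clamp, p_win, p_nowin). Deterministic.
#' @export
stimulation_inference_experiment <- function(task = conditioning_task(),
                                             cfg = agent_config(),
                                             clamp = 16,
                                             sweep = seq(8, 16, by = 0.1)) {
  agent <- build_agent_model(task, cfg)
  obs <- c(1L, 1L, task$cue_obs[1L], 1L, 1L, task$nowin_obs)
  acts <- c(1L, 1L, 2L, 1L, 1L)

  posterior <- function(schedule) {
    rec <- replay_trial(agent$model, agent$beliefs, obs, acts,
                        schedule = schedule)
    s <- rec$s_hat_final[, agent$model$T]
    c(win = s[task$win_state], nowin = s[task$nowin_state])
  }
  unclamped <- posterior(NULL)
  clamped <- posterior(stimulation_schedule(value = clamp,
                                            final_epoch = task$T))
  sweep_df <- data.frame(clamp = sweep, p_win = NA_real_, p_nowin = NA_real_)
  for (i in seq_along(sweep)) {
    p <- posterior(stimulation_schedule(value = sweep[i],
                                        final_epoch = task$T))
    sweep_df$p_win[i] <- p[["win"]]
    sweep_df$p_nowin[i] <- p[["nowin"]]
  }
  list(unclamped = unclamped, clamped = clamped, sweep = sweep_df)
}

#' Stimulation-driven preference reversal
#'
#' Single-cue task in which response 1 is never rewarded but is always
#' followed by simulated stimulation at outcome time, while response 2 is
#' rewarded half the time. A control arm runs without stimulation. Returns
#' the per-trial frequency of choosing response 1 in each arm.
#'
#' @param task Single-cue task (default
#'   `conditioning_task(single_cue_contingencies(), cue_probs = c(1, 0))`).
#' @param cfg An [agent_config()].
#' @param n_sessions Sessions per arm (default 256).
#' @param n_trials Trials per session (default 48).
#' @param clamp Stimulation value (default 16).
#' @param seed Optional RNG seed.
#' @return List with `curves` (data.frame: trial, resp1_stim, resp1_control)
#'   and sizes.
#' @export
stimulation_learning_experiment <- function(
    task = conditioning_task(single_cue_contingencies(),
                             cue_probs = c(1, 0)),
    cfg = agent_config(), n_sessions = 256L, n_trials = 48L, clamp = 16,
    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sched <- stimulation_schedule(value = clamp, final_epoch = task$T,
                                contingent_on = 2L)   # control 2 = response 1
  arm <- function(schedule) {
    resp1_sum <- numeric(n_trials)
    for (s in seq_len(n_sessions)) {
      ses <- run_session(task, cfg, n_trials = n_trials, schedule = schedule)
      resp1_sum <- resp1_sum + as.numeric(ses$trials$choice == 1L)
    }
    resp1_sum / n_sessions
  }
  curves <- data.frame(trial = seq_len(n_trials),
                       resp1_stim = arm(sched), resp1_control = arm(NULL))
  list(curves = curves, clamp = clamp, n_sessions = as.integer(n_sessions),
       n_trials = as.integer(n_trials))
}

#' Dopamine dynamics: replay conditions and outcome-to-cue transfer
#'
#' Runs learning sessions, then (a) replays the four fixed trial types —
#' high-reward cue (cue 1, response 1) and low-reward cue (cue 2, response
#' 1), each with a win and a no-win outcome — through the naive agent and
#' through an agent with one session's learned beliefs, and (b) replays the
#' high-cue/correct/reward trial with the session-averaged parameters held
#' at the start of each of the first `n_blocks` trials. Precision traces are
#' deconvolved with the exponential kernel and summarized per epoch.
#'
#' @param task A [conditioning_task()].
#' @param cfg An [agent_config()].
#' @param n_sessions,n_trials Learning-simulation size.
#' @param n_blocks Number of per-trial parameter snapshots replayed for the
#'   transfer curves (default 64).
#' @param session_index Which session's final beliefs stand in for "after
#'   learning" in the replay conditions (default 1).
#' @param tau Deconvolution kernel time constant in iterations.
#' @param seed Optional RNG seed.
#' @return List with `responses` (data.frame: stage, condition, epoch,
#'   response), `transfer` (data.frame: block, cue, delay1, delay2,
#'   outcome), and `traces` (deconvolved signals of the replay conditions).
#' @export
dopamine_dynamics_experiment <- function(task = conditioning_task(),
                                         cfg = agent_config(),
                                         n_sessions = 256L, n_trials = 128L,
                                         n_blocks = 64L, session_index = 1L,
                                         tau = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(session_index >= 1L, session_index <= n_sessions,
            n_blocks <= n_trials)
  agent <- build_agent_model(task, cfg)
  model <- agent$model

  a_sum <- vector("list", n_blocks)
  b_sum <- vector("list", n_blocks)
  learned <- NULL
  for (s in seq_len(n_sessions)) {
    ses <- run_session(task, cfg, n_trials = n_trials,
                       snapshot_trials = seq_len(n_blocks))
    for (b in seq_len(n_blocks)) {
      snap <- ses$snapshots[[as.character(b)]]
      if (s == 1L) {
        a_sum[[b]] <- snap$a_post
        b_sum[[b]] <- snap$b_post
      } else {
        a_sum[[b]] <- a_sum[[b]] + snap$a_post
        b_sum[[b]] <- Map(`+`, b_sum[[b]], snap$b_post)
      }
    }
    if (s == session_index) learned <- ses$beliefs
  }

  beliefs_from <- function(a_post, b_post) {
    bel <- agent$beliefs
    bel$a_post <- a_post
    bel$b_post <- b_post
    refresh_beliefs(bel)
  }

  conditions <- list(
    expected_reward = list(cue = 1L, outcome = "win"),
    unexpected_omission = list(cue = 1L, outcome = "nowin"),
    unexpected_reward = list(cue = 2L, outcome = "win"),
    expected_omission = list(cue = 2L, outcome = "nowin")
  )
  acts <- c(1L, 1L, 2L, 1L, 1L)   # respond 1 at the choice point
  obs_for <- function(cond) {
    o_out <- if (cond$outcome == "win") task$win_obs else task$nowin_obs
    c(1L, 1L, task$cue_obs[cond$cue], 1L, 1L, o_out)
  }
  replay_responses <- function(beliefs, cond) {
    rec <- replay_trial(model, beliefs, obs_for(cond), acts)
    trace <- deconvolve_precision(rec$gamma_trace, tau = tau,
                                  iters_per_epoch = model$iters_per_epoch,
                                  drop_first_epoch = TRUE)
    list(responses = epoch_responses(trace), trace = trace)
  }

  responses <- NULL
  traces <- list()
  for (stage in c("naive", "learned")) {
    bel <- if (stage == "naive") agent$beliefs else learned
    for (cn in names(conditions)) {
      rr <- replay_responses(bel, conditions[[cn]])
      traces[[paste(stage, cn, sep = ".")]] <- rr$trace
      responses <- rbind(responses, data.frame(
        stage = stage, condition = cn, epoch = seq_len(model$T),
        response = rr$responses))
    }
  }

  transfer <- data.frame(block = seq_len(n_blocks), cue = NA_real_,
                         delay1 = NA_real_, delay2 = NA_real_,
                         outcome = NA_real_)
  for (b in seq_len(n_blocks)) {
    bel <- beliefs_from(a_sum[[b]] / n_sessions,
                        lapply(b_sum[[b]], `/`, n_sessions))
    rr <- replay_responses(bel, conditions$expected_reward)
    transfer$cue[b] <- rr$responses[task$choice_epoch]
    transfer$delay1[b] <- rr$responses[4L]
    transfer$delay2[b] <- rr$responses[5L]
    transfer$outcome[b] <- rr$responses[model$T]
  }

  list(responses = responses, transfer = transfer, traces = traces,
       n_sessions = as.integer(n_sessions))
}
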