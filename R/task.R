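#' Reward contingencies for the two-cue task
#'
#' Map from (cue, response) to the true probability of the win outcome. The
#' default is the symmetric arrangement in which each cue has one
#' high-probability and one low-probability response, with the high response
#' differing between cues.
#'
#' @param high,low Reward probabilities of the better and worse response.
#' @return 2 x 2 matrix `reward_probs[cue, response]`.
#' @export
make_contingencies <- function(high = 0.8, low = 0.2) {
  probs <- c(high, low)
  if (any(probs < 0) || any(probs > 1)) {
    stop("reward probabilities must lie in [0, 1]")
  }
  matrix(c(high, low, low, high), nrow = 2, byrow = TRUE,
         dimnames = list(cue = c("cue1", "cue2"),
                         response = c("resp1", "resp2")))
}

#' Reward contingencies for the single-cue stimulation task
#'
#' Only cue 1 is ever presented; response 1 is rewarded with probability `p1`
#' (never, by default) and response 2 with probability `p2`.
#'
#' @param p1,p2 Reward probabilities of responses 1 and 2.
#' @return 2 x 2 contingency matrix (cue 2's row is irrelevant but kept so
#'   the state space is unchanged).
#' @export
single_cue_contingencies <- function(p1 = 0, p2 = 0.5) {
  probs <- c(p1, p2)
  if (any(probs < 0) || any(probs > 1)) {
    stop("reward probabilities must lie in [0, 1]")
  }
  matrix(c(p1, p2, p1, p2), nrow = 2, byrow = TRUE,
         dimnames = list(cue = c("cue1", "cue2"),
                         response = c("resp1", "resp2")))
}

# Fixed state/observation/control layout of the trace-conditioning task.
# States: 1 pre-cue 1, 2 pre-cue 2, 3 cue 1, 4 cue 2,
#         5-6 delay pair (cue1,resp1), 7-8 (cue1,resp2),
#         9-10 (cue2,resp1), 11-12 (cue2,resp2), 13 win, 14 no-win.
# Observations: 1 null, 2 cue 1, 3 cue 2, 4 win, 5 no-win.
# Controls: 1 wait, 2 response 1, 3 response 2.
task_layout <- function() {
  list(
    n_states = 14L, n_obs = 5L, n_controls = 3L, T = 6L,
    state_labels = c("precue1", "precue2", "cue1", "cue2",
                     "delay1_c1r1", "delay2_c1r1", "delay1_c1r2",
                     "delay2_c1r2", "delay1_c2r1", "delay2_c2r1",
                     "delay1_c2r2", "delay2_c2r2", "win", "nowin"),
    obs_labels = c("null", "cue1", "cue2", "win", "nowin"),
    control_labels = c("wait", "resp1", "resp2"),
    cue_states = c(3L, 4L),
    # delay1/delay2 states per (cue, response) pair, pairs in the order
    # (c1,r1), (c1,r2), (c2,r1), (c2,r2)
    delay1_states = c(5L, 7L, 9L, 11L),
    delay2_states = c(6L, 8L, 10L, 12L),
    win_state = 13L, nowin_state = 14L,
    cue_obs = c(2L, 3L), win_obs = 4L, nowin_obs = 5L,
    choice_epoch = 3L   # cue is shown at epoch 3; transition 3 -> 4 responds
  )
}

# delay-pair index (1..4) for a (cue, response) combination
delay_pair_index <- function(cue, response) (cue - 1L) * 2L + response

#' Build the instrumental-conditioning task
#'
#' Constructs the true generative process of the trace-conditioning task: 14
#' hidden states (two pre-cue, two cue, four delay pairs — one per
#' cue-response combination — and win/no-win outcomes), five observations
#' (null, two cues, two outcomes) and three control states (wait, two
#' responses). Each trial has six epochs. The agent starts in pre-cue 1,
#' moves deterministically to pre-cue 2, sees one of the cues, responds at
#' the third transition, passes through the two delay states of the
#' cue-response pair it selected, and finally transitions stochastically to
#' win or no-win according to `reward_probs`.
#'
#' @param reward_probs 2 x 2 matrix of true win probabilities per
#'   (cue, response), e.g. from [make_contingencies()].
#' @param cue_probs Probabilities of presenting cue 1 and cue 2 (must sum to
#'   1); `c(1, 0)` gives the single-cue task.
#' @return Object of class `task_spec` with the true observation map
#'   (`true_A`), the per-control true transition maps (`true_B`), the layout
#'   and the contingencies.
#' @export
conditioning_task <- function(reward_probs = make_contingencies(),
                              cue_probs = c(0.5, 0.5)) {
  lay <- task_layout()
  reward_probs <- as.matrix(reward_probs)
  stopifnot(identical(dim(reward_probs), c(2L, 2L)),
            all(reward_probs >= 0), all(reward_probs <= 1),
            length(cue_probs) == 2L, all(cue_probs >= 0),
            abs(sum(cue_probs) - 1) < 1e-12)

  true_A <- matrix(0, lay$n_obs, lay$n_states)
  true_A[1L, c(1L, 2L, lay$delay1_states, lay$delay2_states)] <- 1
  true_A[lay$cue_obs[1L], lay$cue_states[1L]] <- 1
  true_A[lay$cue_obs[2L], lay$cue_states[2L]] <- 1
  true_A[lay$win_obs, lay$win_state] <- 1
  true_A[lay$nowin_obs, lay$nowin_state] <- 1

  true_B <- lapply(seq_len(lay$n_controls), function(u) {
    B <- matrix(0, lay$n_states, lay$n_states)
    B[2L, 1L] <- 1                                  # pre-cue 1 -> pre-cue 2
    B[lay$cue_states, 2L] <- cue_probs              # pre-cue 2 -> cues
    for (cue in 1:2) {
      from <- lay$cue_states[cue]
      if (u == 1L) {
        B[from, from] <- 1                          # waiting leaves the cue
      } else {
        resp <- u - 1L
        B[lay$delay1_states[delay_pair_index(cue, resp)], from] <- 1
      }
    }
    for (pair in 1:4) {
      B[lay$delay2_states[pair], lay$delay1_states[pair]] <- 1
      cue <- (pair - 1L) %/% 2L + 1L
      resp <- (pair - 1L) %% 2L + 1L
      p <- reward_probs[cue, resp]
      B[lay$win_state, lay$delay2_states[pair]] <- p
      B[lay$nowin_state, lay$delay2_states[pair]] <- 1 - p
    }
    B[lay$win_state, lay$win_state] <- 1            # outcomes absorb
    B[lay$nowin_state, lay$nowin_state] <- 1
    B
  })

  structure(
    c(lay, list(reward_probs = reward_probs, cue_probs = cue_probs,
                true_A = true_A, true_B = true_B)),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec> trace conditioning task\n")
  cat(sprintf("  %d states, %d observations, %d controls, %d epochs\n",
              x$n_states, x$n_obs, x$n_controls, x$T))
  cat(sprintf("  cue probabilities: %s\n",
              paste(format(x$cue_probs), collapse = ", ")))
  cat("  reward probabilities (cue x response):\n")
  print(x$reward_probs)
  invisible(x)
}

#' One step of the true environment
#'
#' Samples the next hidden state from the true transition matrix of the
#' chosen control and emits an observation from the true observation map.
#'
#' @param task A [conditioning_task()].
#' @param s_true Current true state index.
#' @param a Control index.
#' @return List with `state` (next true state) and `obs` (outcome index).
#' @export
environment_step <- function(task, s_true, a) {
  if (s_true < 1L || s_true > task$n_states) stop("invalid state index")
  if (a < 1L || a > task$n_controls) stop("invalid control index")
  col <- task$true_B[[a]][, s_true]
  s_next <- sample.int(task$n_states, 1L, prob = col)
  o <- sample.int(task$n_obs, 1L, prob = task$true_A[, s_next])
  list(state = s_next, obs = o)
}

#' Agent configuration
#'
#' Collects the tunable constants used when turning a task into an agent.
#' `conc_strong`/`conc_floor` set the concentration placed on transitions the
#' agent knows with near-certainty and on the "negligible" alternatives;
#' `a_floor` is the off-map concentration of the observation prior (strong
#' and accurate, but with a finite log-evidence penalty); `outcome_prior`
#' gives the weak (no-win, win) concentrations on the unknown transitions to
#' the outcome states; `pref_win` is the prior probability mass the
#' preference distribution puts on the win state; `prec_shape`/`prec_rate`
#' parameterize the Gamma prior on precision.
#'
#' @param conc_strong Concentration on transitions known with certainty.
#' @param conc_floor Concentration on negligible transitions.
#' @param a_floor Off-map concentration of the observation prior.
#' @param outcome_prior Length-2 numeric, concentrations on the (no-win,
#'   win) transitions from each final delay state.
#' @param pref_win Preference mass on the win state (rest goes to no-win,
#'   bar a floor spread over the other states).
#' @param prec_shape,prec_rate Gamma hyperparameters of the precision prior.
#' @param iters_per_epoch Variational iterations per epoch.
#' @param include_wait_policy Add the wait-throughout policy to the two
#'   respond-at-the-choice-point policies.
#' @return List of class `agent_config`.
#' @export
agent_config <- function(conc_strong = 512, conc_floor = 1e-6,
                         a_floor = 0.1, outcome_prior = c(1, 0.4),
                         pref_win = 0.95, prec_shape = 4, prec_rate = 1,
                         iters_per_epoch = 16,
                         include_wait_policy = FALSE) {
  stopifnot(conc_strong > 0, conc_floor > 0, a_floor > 0,
            length(outcome_prior) == 2L, all(outcome_prior > 0),
            pref_win > 0, pref_win < 1, prec_shape > 0, prec_rate > 0)
  structure(
    list(conc_strong = conc_strong, conc_floor = conc_floor,
         a_floor = a_floor, outcome_prior = outcome_prior,
         pref_win = pref_win, prec_shape = prec_shape,
         prec_rate = prec_rate, iters_per_epoch = as.integer(iters_per_epoch),
         include_wait_policy = include_wait_policy),
    class = "agent_config"
  )
}

#' Build the agent's generative model and prior beliefs for a task
#'
#' Transitions the agent knows with near-certainty get concentration
#' `conc_strong` on the true target and `conc_floor` elsewhere; the unknown
#' transitions from each final delay state to the outcomes get the weak
#' `outcome_prior` concentrations (no-win, win) under every control, a prior
#' mean win probability of `0.4 / 1.4 ~ 0.286`. The observation prior puts
#' `conc_strong` on the true outcome of each state and `a_floor` elsewhere.
#' The preference `exp(C)` places `pref_win` on the win state and the
#' remainder on no-win (bar a floor spread over the other states). The
#' policy set holds one policy per response — wait, wait, respond, wait,
#' wait — plus, optionally, a wait-throughout policy.
#'
#' @param task A [conditioning_task()].
#' @param cfg An [agent_config()].
#' @return List with elements `model` ([generative_model()]) and `beliefs`
#'   ([dirichlet_beliefs()]).
#' @export
build_agent_model <- function(task, cfg = agent_config()) {
  stopifnot(inherits(task, "task_spec"), inherits(cfg, "agent_config"))

  a_prior <- matrix(cfg$a_floor, task$n_obs, task$n_states)
  for (s in seq_len(task$n_states)) {
    a_prior[which(task$true_A[, s] == 1), s] <- cfg$conc_strong
  }

  b_prior <- lapply(seq_len(task$n_controls), function(u) {
    B <- matrix(cfg$conc_floor, task$n_states, task$n_states)
    for (j in seq_len(task$n_states)) {
      if (j %in% task$delay2_states) {
        B[task$nowin_state, j] <- cfg$outcome_prior[1L]
        B[task$win_state, j] <- cfg$outcome_prior[2L]
      } else {
        # transitions known to high certainty follow the true process;
        # stochastic known columns (the cue draw) split the mass
        tb <- task$true_B[[u]][, j]
        nz <- tb > 0
        B[nz, j] <- cfg$conc_strong * tb[nz]
      }
    }
    B
  })

  pref <- rep(cfg$conc_floor, task$n_states)
  pref[task$win_state] <- cfg$pref_win
  pref[task$nowin_state] <- 1 - cfg$pref_win -
    (task$n_states - 2L) * cfg$conc_floor
  C <- log(pref / sum(pref))

  n_trans <- task$T - 1L
  respond <- function(resp) {
    p <- rep(1L, n_trans)
    p[task$choice_epoch] <- resp + 1L
    p
  }
  policies <- rbind(respond(1L), respond(2L))
  if (cfg$include_wait_policy) {
    policies <- rbind(policies, rep(1L, n_trans))
  }

  model <- generative_model(
    n_states = task$n_states, n_obs = task$n_obs,
    n_controls = task$n_controls, T = task$T, C = C, policies = policies,
    prec_shape = cfg$prec_shape, prec_rate = cfg$prec_rate,
    iters_per_epoch = cfg$iters_per_epoch
  )
  list(model = model, beliefs = dirichlet_beliefs(a_prior, b_prior))
}

#' Posterior-expected win probabilities per contingency
#'
#' Reads the agent's current estimate of `P(win | cue, response)` from the
#' wait-control transition beliefs of the four final delay states.
#'
#' @param task A [conditioning_task()].
#' @param beliefs A [dirichlet_beliefs()] object.
#' @return 2 x 2 matrix matching the layout of `task$reward_probs`.
#' @export
estimated_win_probs <- function(task, beliefs) {
  est <- matrix(NA_real_, 2, 2,
                dimnames = dimnames(task$reward_probs))
  EB <- beliefs$EB[[1L]]
  for (cue in 1:2) {
    for (resp in 1:2) {
      j <- task$delay2_states[delay_pair_index(cue, resp)]
      est[cue, resp] <- EB[task$win_state, j]
    }
  }
  est
}

#' Objectively best response for a cue
#'
#' The response with the highest true win probability; ties break toward the
#' lower index.
#'
#' @param task A [conditioning_task()].
#' @param cue Cue index (1 or 2).
#' @return Response index (1 or 2).
#' @export
best_response <- function(task, cue) {
  unname(which.max(task$reward_probs[cue, ]))
}

#' Tiny fully-specified toy models for oracle tests
#'
#' Returns a deterministic two-state chain (control 1 stays, control 2
#' swaps) with one observation per state and two single-transition policies.
#' Used by tests in other modules; exported so fixtures are reproducible
#' from code.
#'
#' @param T Trial length (default 2: one transition).
#' @param conc Concentration placed on the believed transitions.
#' @param pref Preference probability of state 1 at the horizon.
#' @return List with `model` and `beliefs`.
#' @export
toy_swap_model <- function(T = 2, conc = 512, pref = 0.999) {
  stay <- diag(2) * conc + (1 - diag(2)) * 1e-6
  swap <- (1 - diag(2)) * conc + diag(2) * 1e-6
  a_prior <- diag(2) * conc + (1 - diag(2)) * 0.1
  policies <- rbind(rep(1L, T - 1L), rep(2L, T - 1L))
  model <- generative_model(
    n_states = 2, n_obs = 2, n_controls = 2, T = T,
    C = log(c(pref, 1 - pref)), policies = policies
  )
  list(model = model, beliefs = dirichlet_beliefs(a_prior, list(stay, swap)))
}
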