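#' Value every policy from every starting state
#'
#' Policy value is KL control: `Q(s, k) = -KL[ P(s_T | s_t = s, policy k) ||
#' exp(C) ]`, the negative divergence between the predictive distribution
#' over terminal states (propagating a delta at `s` through the expected
#' transition matrices for the policy's remaining controls) and the preferred
#' terminal distribution. Probability-domain expectations `E[B(u)]` are used
#' for the propagation; expected logs enter only the evidence terms of the
#' state update.
#'
#' @param model A [generative_model()].
#' @param beliefs A [dirichlet_beliefs()] object (its `EB` cache is used).
#' @param t Current epoch index, `1 <= t <= T`; at `t = T` the predictive
#'   distribution is a delta at the current state.
#' @return Matrix `n_states` x `n_policies` with all entries <= 0.
#' @export
compute_policy_values <- function(model, beliefs, t) {
  if (nrow(model$policies) < 1L) stop("the policy set is empty")
  if (t > model$T) stop("epoch index beyond the trial horizon")
  n_pol <- nrow(model$policies)
  pref <- exp(model$C)
  Q <- matrix(0, model$n_states, n_pol)
  for (k in seq_len(n_pol)) {
    # P[, s] = P(s_T | s_t = s, policy k); identity when no controls remain
    P <- diag(model$n_states)
    if (t <= model$T - 1L) {
      for (tr in t:(model$T - 1L)) {
        P <- beliefs$EB[[model$policies[k, tr]]] %*% P
      }
    }
    for (s in seq_len(model$n_states)) {
      Q[s, k] <- -kl_divergence(P[, s], pref)
    }
  }
  Q
}

#' Variational update of hidden-state beliefs
#'
#' One application of the state update: a softmax over the sum of the
#' expected log-likelihood of the current observation (the `o_t`-th row of
#' the expected-log observation matrix), the expected log-prediction from the
#' previous state under the action taken, and the precision-weighted
#' optimism term `gamma_hat * (Q %*% pi_hat)` that biases perception toward
#' valuable states.
#'
#' @param beliefs A [dirichlet_beliefs()] object.
#' @param o_t Observed outcome index at this epoch.
#' @param s_prev Posterior over states at the previous epoch, or `NULL` at
#'   the first epoch, in which case `log_init` replaces the prediction term.
#' @param a_prev Control index of the action taken into this epoch (ignored
#'   when `s_prev` is `NULL`).
#' @param Q Policy-value matrix from [compute_policy_values()].
#' @param pi_hat Posterior over policies.
#' @param gamma_hat Expected precision (positive scalar).
#' @param log_init Log of the known initial-state distribution (used only at
#'   the first epoch).
#' @return Posterior over states (simplex vector).
#' @export
update_states <- function(beliefs, o_t, s_prev, a_prev, Q, pi_hat, gamma_hat,
                          log_init = NULL) {
  if (o_t < 1L || o_t > nrow(beliefs$A_elog)) stop("invalid outcome index")
  if (is.null(s_prev)) {
    if (is.null(log_init)) stop("first epoch needs the initial-state log-prior")
    pred <- log_init
  } else {
    if (a_prev < 1L || a_prev > length(beliefs$B_elog)) {
      stop("invalid action index")
    }
    pred <- drop(beliefs$B_elog[[a_prev]] %*% s_prev)
  }
  softmax(beliefs$A_elog[o_t, ] + pred + gamma_hat * drop(Q %*% pi_hat))
}

#' Variational update of policy beliefs
#'
#' Softmax of the precision-weighted expected value of each policy under the
#' current state beliefs: `sigma(gamma_hat * t(Q) %*% s_hat)`. Higher
#' precision gives a lower-entropy (more deterministic) policy posterior.
#'
#' @param Q Policy-value matrix (`n_states` x `n_policies`).
#' @param s_hat Posterior over states.
#' @param gamma_hat Expected precision.
#' @return Posterior over policies (simplex vector).
#' @export
update_policies <- function(Q, s_hat, gamma_hat) {
  if (length(s_hat) != nrow(Q)) stop("state belief does not match Q")
  softmax(gamma_hat * drop(crossprod(Q, s_hat)))
}

#' Variational update of expected precision
#'
#' `gamma_hat = prec_shape / (prec_rate - pi_hat . (t(Q) s_hat))`. Because
#' policy values are nonpositive, the denominator is at least `prec_rate`,
#' so unclamped precision is bounded above by the prior mean
#' `prec_shape / prec_rate`; precision rises as the expected value of the
#' policies rises toward zero.
#'
#' @param model A [generative_model()].
#' @param Q Policy-value matrix.
#' @param s_hat Posterior over states.
#' @param pi_hat Posterior over policies.
#' @return Positive scalar.
#' @export
update_precision <- function(model, Q, s_hat, pi_hat) {
  expected_value <- sum(pi_hat * drop(crossprod(Q, s_hat)))
  g <- model$prec_shape / (model$prec_rate - expected_value)
  stopifnot(g > 0)
  g
}

#' Run the fixed-point iteration for one epoch
#'
#' Interleaves `iters_per_epoch` rounds of state, policy and precision
#' updates (in that order), appending the precision value to the trace after
#' every round. When `clamp` is supplied, precision is externally fixed at
#' that value for the whole epoch and the precision update is skipped, so the
#' trace shows a plateau at the clamp.
#'
#' @param model A [generative_model()].
#' @param beliefs A [dirichlet_beliefs()] object.
#' @param bstate A [belief_state()].
#' @param o_t Observed outcome index.
#' @param t Epoch index.
#' @param a_prev Control taken into this epoch (`NULL` at the first epoch).
#' @param Q Policy-value matrix for this epoch.
#' @param clamp Optional positive clamp value for precision.
#' @param log_init Log initial-state distribution (first epoch only).
#' @return The updated belief state.
#' @export
infer_epoch <- function(model, beliefs, bstate, o_t, t, a_prev, Q,
                        clamp = NULL, log_init = NULL) {
  s_prev <- if (t == 1L) NULL else bstate$s_hat[, t - 1L]
  pi_hat <- bstate$pi_hat
  if (!is.null(clamp)) {
    stopifnot(clamp > 0)
    gamma_hat <- clamp
    bstate$clamped[t] <- TRUE
  } else {
    gamma_hat <- bstate$gamma_hat
  }
  trace <- numeric(model$iters_per_epoch)
  for (i in seq_len(model$iters_per_epoch)) {
    s_hat <- update_states(beliefs, o_t, s_prev, a_prev, Q, pi_hat,
                           gamma_hat, log_init)
    pi_hat <- update_policies(Q, s_hat, gamma_hat)
    if (is.null(clamp)) {
      gamma_hat <- update_precision(model, Q, s_hat, pi_hat)
    }
    trace[i] <- gamma_hat
  }
  bstate$s_hat[, t] <- s_hat
  bstate$pi_hat <- pi_hat
  bstate$gamma_hat <- gamma_hat
  bstate$gamma_trace <- c(bstate$gamma_trace, trace)
  bstate
}

#' Sample an action from the policy posterior
#'
#' Marginalizes the policy posterior onto the control each policy prescribes
#' at transition `t`, then samples a control from that marginal.
#'
#' @param model A [generative_model()].
#' @param pi_hat Posterior over policies.
#' @param t Transition index, `1 <= t <= T - 1`.
#' @return A control index.
#' @export
sample_action <- function(model, pi_hat, t) {
  if (t < 1L || t > model$T - 1L) stop("transition index out of range")
  marg <- control_marginal(model, pi_hat, t)
  sample.int(model$n_controls, 1L, prob = marg)
}

#' Marginal distribution over controls at a transition
#'
#' @inheritParams sample_action
#' @return Probability vector over the `n_controls` control states.
#' @export
control_marginal <- function(model, pi_hat, t) {
  marg <- numeric(model$n_controls)
  for (k in seq_along(pi_hat)) {
    u <- model$policies[k, t]
    marg[u] <- marg[u] + pi_hat[k]
  }
  marg
}

#' Variational free energy of one epoch
#'
#' Standard (minimized) form: complexity minus accuracy. Accuracy is the
#' expected log-likelihood of the observation under the state posterior and
#' the expected-log observation matrix. Complexity sums the KL divergences
#' between posterior and prior marginals of the factorized distribution: the
#' state posterior against its prediction from the previous epoch (or the
#' initial-state prior), the policy posterior against a uniform prior, and
#' the precision posterior `Gamma(prec_shape, prec_shape / gamma_hat)`
#' against the prior `Gamma(prec_shape, prec_rate)`. Parameter complexity is
#' zero within a trial (concentrations update only at trial end) and is
#' accounted for per trial by [end_of_trial_update()].
#'
#' @param model A [generative_model()].
#' @param beliefs A [dirichlet_beliefs()] object.
#' @param s_hat State posterior at this epoch.
#' @param pi_hat Policy posterior.
#' @param gamma_hat Expected precision.
#' @param o_t Observed outcome index.
#' @param s_prev Previous epoch's state posterior, or `NULL` at epoch 1.
#' @param a_prev Control taken into this epoch (`NULL` at epoch 1).
#' @param log_init Log initial-state distribution (epoch 1 only).
#' @return Scalar free energy (nats).
#' @export
compute_free_energy <- function(model, beliefs, s_hat, pi_hat, gamma_hat,
                                o_t, s_prev = NULL, a_prev = NULL,
                                log_init = NULL) {
  accuracy <- sum(s_hat * beliefs$A_elog[o_t, ])
  if (is.null(s_prev)) {
    pred <- softmax(log_init)
  } else {
    pred <- softmax(drop(beliefs$B_elog[[a_prev]] %*% s_prev))
  }
  n_pol <- length(pi_hat)
  complexity <- kl_divergence(s_hat, pred) +
    kl_divergence(pi_hat, rep(1 / n_pol, n_pol)) +
    gamma_kl(model$prec_shape, model$prec_shape / gamma_hat,
             model$prec_shape, model$prec_rate)
  complexity - accuracy
}
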