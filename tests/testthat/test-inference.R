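test_that("policy values are negative KL to the preferred terminal distribution", {
  toy <- toy_swap_model(T = 2, pref = 0.999)
  Q <- compute_policy_values(toy$model, toy$beliefs, t = 1)
  expect_true(all(Q <= 1e-12))
  # staying in state 1 keeps the preferred state: divergence is just the
  # -log(0.999) cost of the preference floor
  expect_equal(Q[1, 1], 0, tolerance = 2e-3)
  expect_equal(Q[1, 2], -kl_divergence(c(0, 1), c(0.999, 0.001)),
               tolerance = 0.05)
  # swap policy from state 2 ends in state 1: near-zero divergence
  expect_equal(Q[2, 2], 0, tolerance = 2e-3)

  # at the horizon the predictive distribution is a delta at the state
  bel <- toy3_beliefs()
  model <- toy3_model()
  QT <- compute_policy_values(model, bel, t = model$T)
  expect_equal(QT[, 1], log(exp(model$C)), tolerance = 1e-10)
  expect_error(compute_policy_values(model, bel, t = model$T + 1))
})

test_that("per-epoch policy values from the backward recursion match the direct form", {
  task <- conditioning_task()
  ag <- build_agent_model(task)
  Qs <- policy_values_all(ag$model, ag$beliefs)
  for (t in seq_len(ag$model$T)) {
    expect_equal(Qs[[t]], compute_policy_values(ag$model, ag$beliefs, t),
                 tolerance = 1e-12)
  }
})

test_that("state update combines likelihood, prediction and optimism as written", {
  bel <- toy3_beliefs()
  model <- toy3_model()
  Q <- compute_policy_values(model, bel, t = 2)
  s_prev <- c(0.6, 0.3, 0.1)
  pi_hat <- c(0.5, 0.25, 0.25)

  # literal-formula oracle at 1e-10
  for (o in 1:3) {
    for (g in c(0.5, 2)) {
      got <- update_states(bel, o, s_prev, 1L, Q, pi_hat, g)
      want <- oracle_state_update(bel$A_elog, bel$B_elog[[1]], o, s_prev, Q,
                                  pi_hat, g)
      expect_equal(got, want, tolerance = 1e-10)
      expect_equal(sum(got), 1, tolerance = 1e-10)
    }
  }

  # flat likelihood and zeroed value term reduce to pure prediction
  flat <- dirichlet_beliefs(matrix(1, 3, 3), bel$b_post)
  Q0 <- matrix(0, 3, 3)
  got <- update_states(flat, 2L, s_prev, 2L, Q0, pi_hat, 1)
  want <- softmax(drop(flat$B_elog[[2]] %*% s_prev))
  expect_equal(got, want, tolerance = 1e-12)

  # near-delta likelihood dominates: outcome 1 only possible in state 1
  sharp_a <- matrix(0.001, 3, 3)
  diag(sharp_a) <- 512
  sharp <- dirichlet_beliefs(sharp_a, bel$b_post)
  got <- update_states(sharp, 1L, c(1, 1, 1) / 3, 1L, Q0, pi_hat, 1)
  expect_gt(got[1], 0.99)
  expect_error(update_states(bel, 9L, s_prev, 1L, Q, pi_hat, 1), "outcome")
  expect_error(update_states(bel, 1L, s_prev, 7L, Q, pi_hat, 1), "action")
})

test_that("raising precision biases state estimates toward the most valuable state", {
  bel <- toy3_beliefs()
  model <- toy3_model()
  Q <- compute_policy_values(model, bel, t = 2)
  pi_hat <- c(0.4, 0.3, 0.3)
  s_prev <- c(1, 1, 1) / 3
  best <- which.max(drop(Q %*% pi_hat))
  gammas <- c(0.1, 0.5, 1, 2, 4, 8)
  mass <- vapply(gammas, function(g) {
    update_states(bel, 2L, s_prev, 1L, Q, pi_hat, g)[best]
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("policy update is a softmax with precision as inverse temperature", {
  Q <- matrix(c(-1, -1, -1, -1), 2, 2)
  expect_equal(update_policies(Q, c(0.5, 0.5), 3), c(0.5, 0.5),
               tolerance = 1e-12)
  Q2 <- matrix(c(-0.1, -2), 1, 2)
  expect_equal(update_policies(Q2, 1, 10), softmax(c(-1, -20)),
               tolerance = 1e-12)
  expect_equal(update_policies(Q2, 1, 1e-9), c(0.5, 0.5), tolerance = 1e-6)
  # entropy decreases with precision for distinct values
  ent <- function(p) -sum(p * log(p))
  es <- vapply(c(0.5, 1, 2, 4), function(g) ent(update_policies(Q2, 1, g)),
               numeric(1))
  expect_true(all(diff(es) < 0))
  expect_equal(update_policies(toy3_beliefs()$A_elog * 0 - 1,
                               c(0.2, 0.3, 0.5), 2),
               rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("precision update follows the fixed-point formula and its bound", {
  m1 <- generative_model(1, 1, 1, 2, C = 0, policies = rbind(1L),
                         prec_shape = 8, prec_rate = 1)
  expect_equal(update_precision(m1, matrix(-1, 1, 1), 1, 1), 4)
  expect_equal(update_precision(m1, matrix(0, 1, 1), 1, 1), 8)

  bel <- toy3_beliefs()
  model <- toy3_model()
  Q <- compute_policy_values(model, bel, t = 1)
  set.seed(4)
  prior_mean <- model$prec_shape / model$prec_rate
  for (i in 1:20) {
    s <- random_simplex(3)
    p <- random_simplex(3)
    g <- update_precision(model, Q, s, p)
    expect_gt(g, 0)
    expect_lte(g, prior_mean + 1e-12)
    expect_equal(g, oracle_precision_update(model$prec_shape,
                                            model$prec_rate, Q, s, p),
                 tolerance = 1e-12)
  }
  # moving values toward zero raises precision
  expect_gt(update_precision(model, Q * 0.5, random_simplex(3), rep(1/3, 3)),
            update_precision(model, Q, random_simplex(3), rep(1/3, 3)))
})

test_that("epoch inference iterates the three updates and honors clamps", {
  bel <- toy3_beliefs()
  model <- toy3_model()
  Q <- compute_policy_values(model, bel, t = 1)
  log_init <- log(pmax(c(1, 0, 0), 1e-14))

  b1 <- infer_epoch(model, bel, belief_state(model), 1L, 1L, NULL, Q,
                    log_init = log_init)
  b2 <- infer_epoch(model, bel, belief_state(model), 1L, 1L, NULL, Q,
                    log_init = log_init)
  expect_identical(b1$s_hat[, 1], b2$s_hat[, 1])   # deterministic loop
  expect_identical(b1$gamma_trace, b2$gamma_trace)
  expect_length(b1$gamma_trace, model$iters_per_epoch)
  expect_false(b1$clamped[1])

  bc <- infer_epoch(model, bel, belief_state(model), 1L, 1L, NULL, Q,
                    clamp = 0.1, log_init = log_init)
  expect_equal(bc$gamma_trace, rep(0.1, model$iters_per_epoch))
  expect_true(bc$clamped[1])

  # one iteration of the loop equals the three oracle updates in order
  m1 <- generative_model(3, 3, 2, 3, C = toy3_model()$C,
                         policies = rbind(c(1L, 1L), c(2L, 1L), c(1L, 2L)),
                         prec_shape = 4, prec_rate = 1, iters_per_epoch = 1)
  b <- belief_state(m1)
  out <- infer_epoch(m1, bel, b, 2L, 1L, NULL, Q, log_init = log_init)
  s1 <- oracle_state_update(bel$A_elog, bel$B_elog[[1]], 2L,
                            rep(0, 3), Q, b$pi_hat, b$gamma_hat)
  # first epoch: prediction term is the initial log-prior, emulate directly
  v <- bel$A_elog[2L, ] + log_init + b$gamma_hat * drop(Q %*% b$pi_hat)
  s1 <- oracle_softmax(v - max(v))
  p1 <- oracle_policy_update(Q, s1, b$gamma_hat)
  g1 <- oracle_precision_update(m1$prec_shape, m1$prec_rate, Q, s1, p1)
  expect_equal(out$s_hat[, 1], s1, tolerance = 1e-10)
  expect_equal(out$pi_hat, p1, tolerance = 1e-10)
  expect_equal(out$gamma_hat, g1, tolerance = 1e-10)
})

test_that("beliefs stay on the simplex and precision stays within its ceiling", {
  task <- conditioning_task()
  ag <- build_agent_model(task)
  set.seed(21)
  bel <- ag$beliefs
  for (tr in 1:5) {
    res <- run_trial(ag$model, bel, task, trial = tr)
    bel <- res$beliefs
    r <- res$record
    expect_equal(colSums(r$s_hat_final), rep(1, ag$model$T),
                 tolerance = 1e-10)
    expect_equal(sum(r$pi_hat), 1, tolerance = 1e-10)
    expect_true(all(r$gamma_trace > 0))
    expect_true(all(r$gamma_trace <=
                      ag$model$prec_shape / ag$model$prec_rate + 1e-12))
  }
})

test_that("a precision clamp far below one flattens the policy posterior", {
  task <- conditioning_task()
  ag <- build_agent_model(task)
  # give the agent sharply different learned values so the contrast is real
  bel <- ag$beliefs
  bel$b_post[[1]][task$win_state, task$delay2_states[1]] <- 50
  bel <- refresh_beliefs(bel)
  obs <- c(1L, 1L, task$cue_obs[1], 1L, 1L, task$win_obs)
  acts <- c(1L, 1L, 2L, 1L, 1L)
  n_pol <- nrow(ag$model$policies)

  sched <- depletion_schedule(value = 0.01)
  Qs <- policy_values_all(ag$model, bel)
  log_init <- log(pmax(c(1, rep(0, 13)), 1e-14))
  bstate <- belief_state(ag$model)
  bstate <- infer_epoch(ag$model, bel, bstate, obs[1], 1L, NULL, Qs[[1]],
                        clamp = 0.01, log_init = log_init)
  ent <- -sum(bstate$pi_hat * log(bstate$pi_hat))
  expect_lt(log(n_pol) - ent, 1e-3)
  for (t in 2:6) {
    bstate <- infer_epoch(ag$model, bel, bstate, obs[t], t, acts[t - 1],
                          Qs[[t]], clamp = 0.01)
    ent <- -sum(bstate$pi_hat * log(bstate$pi_hat))
    expect_lt(log(n_pol) - ent, 1e-3)
  }

  # unclamped, the same learned agent is far from uniform at the cue epoch
  # (later epochs revalue policies equally, so compare at the choice point)
  bfree <- belief_state(ag$model)
  bfree <- infer_epoch(ag$model, bel, bfree, obs[1], 1L, NULL, Qs[[1]],
                       log_init = log_init)
  for (t in 2:3) {
    bfree <- infer_epoch(ag$model, bel, bfree, obs[t], t, acts[t - 1],
                         Qs[[t]])
  }
  ent_free <- -sum(bfree$pi_hat * log(pmax(bfree$pi_hat, 1e-300)))
  expect_gt(log(n_pol) - ent_free, 0.1)
})

test_that("actions are sampled from the policy-prescribed control marginal", {
  model <- toy3_model()   # policies prescribe controls (1,2,1) at transition 1
  expect_identical(sample_action(model, c(1, 0, 0), 1L), 1L)
  expect_identical(sample_action(model, c(0, 1, 0), 1L), 2L)
  # both policies 1 and 3 prescribe control 1 at transition 1
  expect_identical(sample_action(model, c(0.5, 0, 0.5), 1L), 1L)
  expect_equal(control_marginal(model, c(0.25, 0.75, 0), 1L), c(0.25, 0.75))

  set.seed(33)
  draws <- replicate(1e4, sample_action(model, c(0.25, 0.75, 0), 1L))
  freq2 <- mean(draws == 2L)
  expect_lt(abs(freq2 - 0.75), 3 * sqrt(0.75 * 0.25 / 1e4))
  expect_error(sample_action(model, c(1, 0, 0), model$T), "out of range")
})

test_that("free energy is accuracy minus complexity, matching Monte Carlo", {
  bel <- toy3_beliefs()
  model <- toy3_model()
  s_prev <- c(0.5, 0.3, 0.2)
  s_hat <- c(0.4, 0.35, 0.25)
  pi_hat <- c(0.5, 0.3, 0.2)
  gamma_hat <- 1.7
  o <- 2L
  a <- 1L
  fe <- compute_free_energy(model, bel, s_hat, pi_hat, gamma_hat, o,
                            s_prev = s_prev, a_prev = a)

  set.seed(55)
  n <- 1e5
  # accuracy: E over states and Dirichlet columns of log A[o, s]
  s_draw <- sample.int(3, n, replace = TRUE, prob = s_hat)
  acc <- numeric(n)
  for (j in 1:3) {
    idx <- s_draw == j
    if (!any(idx)) next
    g <- matrix(stats::rgamma(3 * sum(idx), shape = bel$a_post[, j]),
                nrow = 3)
    A_col <- sweep(g, 2, colSums(g), "/")
    acc[idx] <- log(A_col[o, ])
  }
  pred <- softmax(drop(bel$B_elog[[a]] %*% s_prev))
  kl_s <- mean(log(s_hat[s_draw]) - log(pred[s_draw]))
  k_draw <- sample.int(3, n, replace = TRUE, prob = pi_hat)
  kl_pi <- mean(log(pi_hat[k_draw]) - log(rep(1 / 3, 3)[k_draw]))
  gmma <- stats::rgamma(n, shape = model$prec_shape,
                        rate = model$prec_shape / gamma_hat)
  kl_g <- mean(stats::dgamma(gmma, model$prec_shape,
                             rate = model$prec_shape / gamma_hat,
                             log = TRUE) -
                 stats::dgamma(gmma, model$prec_shape,
                               rate = model$prec_rate, log = TRUE))
  fe_mc <- (kl_s + kl_pi + kl_g) - mean(acc)
  expect_equal(fe, fe_mc, tolerance = max(0.02 * abs(fe_mc), 0.02))

  # complexity is nonnegative: free energy is bounded below by -accuracy
  accuracy <- sum(s_hat * bel$A_elog[o, ])
  expect_gte(fe, -accuracy - 1e-12)

  # posterior equal to prior prediction with a deterministic correct
  # observation: free energy collapses to (near-zero) accuracy
  sharp_a <- matrix(1e-3, 3, 3)
  diag(sharp_a) <- 1e6
  sharp_b <- matrix(1e-3, 3, 3)
  diag(sharp_b) <- 1e6
  sharp <- dirichlet_beliefs(sharp_a, list(sharp_b, sharp_b))
  pred2 <- softmax(drop(sharp$B_elog[[1]] %*% c(1, 0, 0)))
  fe0 <- compute_free_energy(model, sharp, pred2, rep(1 / 3, 3),
                             model$prec_shape / model$prec_rate,
                             1L, s_prev = c(1, 0, 0), a_prev = 1L)
  expect_lt(abs(fe0), 0.02)
})
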