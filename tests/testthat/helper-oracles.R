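# Independent brute-force implementations used as oracles. These deliberately
# use plain loops and textbook formulas, not the package's vectorized paths.

oracle_softmax <- function(v) {
  e <- exp(v)
  e / sum(e)
}

# digamma via upward recurrence and the asymptotic series; accurate to ~1e-12
oracle_digamma <- function(x) {
  r <- 0
  while (x < 10) {
    r <- r - 1 / x
    x <- x + 1
  }
  r + log(x) - 1 / (2 * x) - 1 / (12 * x^2) + 1 / (120 * x^4) -
    1 / (252 * x^6)
}

oracle_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log(p[i] / max(q[i], 1e-16))
  }
  s
}

# literal evaluation of the three variational updates on small fixtures
oracle_state_update <- function(A_elog, B_elog_a, o, s_prev, Q, pi_hat,
                                gamma) {
  n <- length(s_prev)
  v <- numeric(n)
  for (i in seq_len(n)) {
    b <- 0
    for (j in seq_len(n)) b <- b + B_elog_a[i, j] * s_prev[j]
    qq <- 0
    for (k in seq_along(pi_hat)) qq <- qq + Q[i, k] * pi_hat[k]
    v[i] <- A_elog[o, i] + b + gamma * qq
  }
  oracle_softmax(v - max(v))
}

oracle_policy_update <- function(Q, s_hat, gamma) {
  n_pol <- ncol(Q)
  val <- numeric(n_pol)
  for (k in seq_len(n_pol)) {
    for (s in seq_along(s_hat)) val[k] <- val[k] + Q[s, k] * s_hat[s]
  }
  oracle_softmax(gamma * val - max(gamma * val))
}

oracle_precision_update <- function(prec_shape, prec_rate, Q, s_hat, pi_hat) {
  ev <- 0
  for (k in seq_along(pi_hat)) {
    for (s in seq_along(s_hat)) ev <- ev + pi_hat[k] * Q[s, k] * s_hat[s]
  }
  prec_shape / (prec_rate - ev)
}

random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# a small 3-state fixture with moderate concentrations (so expected logs and
# probabilities are well away from degeneracy)
toy3_beliefs <- function() {
  a <- matrix(c(5, 1, 0.5,
                1, 4, 1,
                0.5, 1, 3), 3, 3, byrow = TRUE)
  b1 <- matrix(c(4, 1, 1,
                 1, 4, 1,
                 1, 1, 4), 3, 3, byrow = TRUE)
  b2 <- matrix(c(1, 3, 1,
                 3, 1, 1,
                 1, 1, 3), 3, 3, byrow = TRUE)
  dirichlet_beliefs(a, list(b1, b2))
}

toy3_model <- function(prec_shape = 4, prec_rate = 1) {
  generative_model(
    n_states = 3, n_obs = 3, n_controls = 2, T = 3,
    C = log(c(0.8, 0.15, 0.05)),
    policies = rbind(c(1L, 1L), c(2L, 1L), c(1L, 2L)),
    prec_shape = prec_shape, prec_rate = prec_rate, iters_per_epoch = 8
  )
}
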