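#' Numerically stable softmax (normalized exponential)
#'
#' Maps a real vector of log-potentials onto the probability simplex. The
#' maximum is subtracted before exponentiation, so the result is invariant to
#' adding a constant and safe for inputs with very large negative entries
#' (e.g. log-evidence from near-deterministic transitions).
#'
#' @param v Finite numeric vector.
#' @return Nonnegative vector of the same length summing to 1.
#' @export
softmax <- function(v) {
  if (!is.numeric(v) || length(v) == 0L) {
    stop("softmax() needs a non-empty numeric vector")
  }
  if (any(!is.finite(v))) {
    stop("non-finite value in belief update")
  }
  e <- exp(v - max(v))
  e / sum(e)
}

#' Expected log-probabilities of a column-wise Dirichlet belief
#'
#' For a matrix of concentration parameters whose columns parameterize
#' independent Dirichlet distributions over the rows, returns the matrix of
#' expected log-probabilities `psi(c_ij) - psi(sum_k c_kj)`. This is the
#' quantity that enters the variational state update (as opposed to the log
#' of the expected probability, which normalizes the concentrations
#' directly); by Jensen's inequality it is the more pessimistic of the two.
#'
#' @param conc Matrix (or vector, treated as a single column) of strictly
#'   positive concentration parameters.
#' @return Matrix of the same shape with all entries <= 0.
#' @export
dirichlet_expected_log <- function(conc) {
  conc <- as.matrix(conc)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("concentration parameters must be strictly positive")
  }
  totals <- colSums(conc)
  digamma(conc) - rep(digamma(totals), each = nrow(conc))
}

#' Column-normalized expectation of a Dirichlet belief
#'
#' The expected probability matrix `E[P] = c_ij / sum_k c_kj`; each column is
#' on the simplex. Used where the updates call for probability-domain
#' expectations (policy valuation), as opposed to expected logs (evidence
#' accumulation).
#'
#' @param conc Matrix of strictly positive concentration parameters.
#' @return Column-stochastic matrix of the same shape.
#' @export
dirichlet_expectation <- function(conc) {
  conc <- as.matrix(conc)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("concentration parameters must be strictly positive")
  }
  sweep(conc, 2L, colSums(conc), "/")
}

#' Discrete Kullback-Leibler divergence
#'
#' `KL(p || q) = sum_i p_i log(p_i / q_i)` for two distributions on the same
#' support. The second argument is floored at `floor_q` before the log so
#' that predictive distributions carrying exact zeros (deterministic
#' transitions) stay usable; terms with `p_i = 0` contribute zero.
#'
#' @param p,q Probability vectors of equal length.
#' @param floor_q Floor applied to `q` (default 1e-16).
#' @return Nonnegative scalar.
#' @export
kl_divergence <- function(p, q, floor_q = 1e-16) {
  if (length(p) != length(q)) {
    stop("kl_divergence(): length mismatch")
  }
  q <- pmax(q, floor_q)
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(q[nz])))
}

#' Kullback-Leibler divergence between two Dirichlet distributions
#'
#' Closed form over a single column of concentration parameters, summed over
#' columns when matrices are supplied. Used for the parameter-complexity part
#' of the variational free energy.
#'
#' @param post,prior Strictly positive concentration vectors or matrices of
#'   identical shape (columns are independent Dirichlets).
#' @return Nonnegative scalar.
#' @export
dirichlet_kl <- function(post, prior) {
  post <- as.matrix(post)
  prior <- as.matrix(prior)
  stopifnot(identical(dim(post), dim(prior)))
  a0 <- colSums(post)
  b0 <- colSums(prior)
  elog <- digamma(post) - rep(digamma(a0), each = nrow(post))
  sum(lgamma(a0) - lgamma(b0)) -
    sum(lgamma(post) - lgamma(prior)) +
    sum((post - prior) * elog)
}

#' Kullback-Leibler divergence between two Gamma distributions
#'
#' Shape/rate parameterization. Used for the precision-complexity part of the
#' free energy, where the posterior over precision is Gamma with the prior
#' shape and rate `shape / gamma_hat`.
#'
#' @param shape1,rate1 Parameters of the first (posterior) Gamma.
#' @param shape2,rate2 Parameters of the second (prior) Gamma.
#' @return Nonnegative scalar.
#' @export
gamma_kl <- function(shape1, rate1, shape2, rate2) {
  stopifnot(shape1 > 0, rate1 > 0, shape2 > 0, rate2 > 0)
  (shape1 - shape2) * digamma(shape1) -
    lgamma(shape1) + lgamma(shape2) +
    shape2 * (log(rate1) - log(rate2)) +
    shape1 * (rate2 - rate1) / rate1
}

#' Construct a generative model
#'
#' Bundles the dimensions and fixed quantities of the agent's world model:
#' the number of hidden states, observations and control states, the trial
#' horizon, the log-preference vector over terminal states, the policy set,
#' and the Gamma hyperparameters of the prior over precision. The Dirichlet
#' beliefs about the observation/transition matrices live separately in a
#' [dirichlet_beliefs()] object because they are updated by learning.
#'
#' @param n_states,n_obs,n_controls Dimensions of the state, observation and
#'   control spaces.
#' @param T Number of epochs per trial (so `T - 1` transitions).
#' @param C Log-preference vector over terminal hidden states, length
#'   `n_states`; `exp(C)` must sum to 1 (it is the prior over the final
#'   state, whose log is the utility of each terminal state).
#' @param policies Integer matrix, one row per policy, `T - 1` columns; entry
#'   `(k, t)` is the control state policy `k` prescribes at transition `t`.
#' @param prec_shape,prec_rate Shape and rate of the Gamma prior on
#'   precision. Named to avoid collision with the Dirichlet concentration
#'   parameters, which the same Greek letters conventionally denote.
#' @param iters_per_epoch Number of variational iterations per epoch.
#' @return Object of class `generative_model`.
#' @export
generative_model <- function(n_states, n_obs, n_controls, T, C, policies,
                             prec_shape = 4, prec_rate = 1,
                             iters_per_epoch = 16) {
  policies <- as.matrix(policies)
  storage.mode(policies) <- "integer"
  m <- structure(
    list(
      n_states = as.integer(n_states),
      n_obs = as.integer(n_obs),
      n_controls = as.integer(n_controls),
      T = as.integer(T),
      C = as.numeric(C),
      policies = policies,
      prec_shape = as.numeric(prec_shape),
      prec_rate = as.numeric(prec_rate),
      iters_per_epoch = as.integer(iters_per_epoch)
    ),
    class = "generative_model"
  )
  validate_generative_model(m)
  m
}

validate_generative_model <- function(m) {
  stopifnot(
    m$n_states >= 1L, m$n_obs >= 1L, m$n_controls >= 1L, m$T >= 2L,
    length(m$C) == m$n_states,
    m$prec_shape > 0, m$prec_rate > 0,
    m$iters_per_epoch >= 1L
  )
  if (abs(sum(exp(m$C)) - 1) > 1e-8) {
    stop("C must be a log-probability vector: exp(C) must sum to 1")
  }
  if (nrow(m$policies) < 1L) {
    stop("the policy set is empty")
  }
  if (ncol(m$policies) != m$T - 1L) {
    stop("each policy must prescribe one control per transition (T - 1)")
  }
  if (any(m$policies < 1L) || any(m$policies > m$n_controls)) {
    stop("policy entries must be control indices in 1..n_controls")
  }
  invisible(m)
}

#' @export
print.generative_model <- function(x, ...) {
  cat("<generative_model>\n")
  cat(sprintf("  states: %d  observations: %d  controls: %d  epochs: %d\n",
              x$n_states, x$n_obs, x$n_controls, x$T))
  cat(sprintf("  policies: %d  precision prior: Gamma(shape=%g, rate=%g) (mean %g)\n",
              nrow(x$policies), x$prec_shape, x$prec_rate,
              x$prec_shape / x$prec_rate))
  invisible(x)
}

#' Construct Dirichlet beliefs over the observation and transition matrices
#'
#' Holds prior and posterior concentration arrays for the observation matrix
#' A (`n_obs` x `n_states`) and for each control's transition matrix B(u)
#' (`n_states` x `n_states`), together with cached expected-log and expected
#' probability matrices. Posteriors start at the priors; learning only ever
#' adds mass.
#'
#' @param a_prior Concentration matrix over A, shape `n_obs` x `n_states`.
#' @param b_prior List of `n_controls` concentration matrices over B(u),
#'   each `n_states` x `n_states` (columns index the current state).
#' @return Object of class `dirichlet_beliefs`.
#' @export
dirichlet_beliefs <- function(a_prior, b_prior) {
  a_prior <- as.matrix(a_prior)
  b_prior <- lapply(b_prior, as.matrix)
  bel <- structure(
    list(
      a_prior = a_prior, a_post = a_prior,
      b_prior = b_prior, b_post = b_prior,
      A_elog = NULL, B_elog = NULL, EA = NULL, EB = NULL
    ),
    class = "dirichlet_beliefs"
  )
  bel <- refresh_beliefs(bel)
  validate_dirichlet_beliefs(bel)
  bel
}

#' Recompute the cached expectation matrices of a belief object
#'
#' Called after any change to the posterior concentrations; fills `A_elog`,
#' `B_elog` (expected logs) and `EA`, `EB` (expected probabilities).
#'
#' @param beliefs A [dirichlet_beliefs()] object.
#' @return The beliefs with caches refreshed.
#' @export
refresh_beliefs <- function(beliefs) {
  beliefs$A_elog <- dirichlet_expected_log(beliefs$a_post)
  beliefs$B_elog <- lapply(beliefs$b_post, dirichlet_expected_log)
  beliefs$EA <- dirichlet_expectation(beliefs$a_post)
  beliefs$EB <- lapply(beliefs$b_post, dirichlet_expectation)
  beliefs
}

validate_dirichlet_beliefs <- function(bel) {
  stopifnot(
    all(bel$a_prior > 0), all(bel$a_post >= bel$a_prior),
    length(bel$b_prior) == length(bel$b_post)
  )
  for (u in seq_along(bel$b_prior)) {
    stopifnot(all(bel$b_prior[[u]] > 0),
              all(bel$b_post[[u]] >= bel$b_prior[[u]]))
  }
  invisible(bel)
}

#' @export
print.dirichlet_beliefs <- function(x, ...) {
  cat("<dirichlet_beliefs>\n")
  cat(sprintf("  A: %d x %d (added mass %.2f)\n",
              nrow(x$a_post), ncol(x$a_post), sum(x$a_post - x$a_prior)))
  cat(sprintf("  B(u): %d matrices %d x %d (added mass %.2f)\n",
              length(x$b_post), nrow(x$b_post[[1]]), ncol(x$b_post[[1]]),
              sum(vapply(seq_along(x$b_post),
                         function(u) sum(x$b_post[[u]] - x$b_prior[[u]]),
                         numeric(1)))))
  invisible(x)
}

#' Construct a per-trial belief state
#'
#' Holds the per-epoch posteriors over hidden states, the posterior over
#' policies, the current expected precision, the per-iteration precision
#' trace, and the per-epoch clamp flags.
#'
#' @param model A [generative_model()].
#' @return Object of class `belief_state` with uniform policy beliefs and
#'   precision at its prior mean.
#' @export
belief_state <- function(model) {
  n_pol <- nrow(model$policies)
  structure(
    list(
      s_hat = matrix(NA_real_, model$n_states, model$T),
      pi_hat = rep(1 / n_pol, n_pol),
      gamma_hat = model$prec_shape / model$prec_rate,
      gamma_trace = numeric(0),
      clamped = rep(FALSE, model$T)
    ),
    class = "belief_state"
  )
}

#' @export
print.belief_state <- function(x, ...) {
  done <- sum(!is.na(x$s_hat[1, ]))
  cat(sprintf("<belief_state> epochs inferred: %d/%d  gamma_hat: %.3f\n",
              done, ncol(x$s_hat), x$gamma_hat))
  invisible(x)
}

#' Serialize a generative model and its priors to JSON
#'
#' Writes a self-contained JSON document (dimensions, preferences, policies,
#' precision hyperparameters, Dirichlet priors, row-major nested arrays) from
#' which [read_model_json()] reconstructs the model and fresh beliefs
#' exactly.
#'
#' @param model A [generative_model()].
#' @param beliefs A [dirichlet_beliefs()] object (priors are serialized).
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, beliefs, path) {
  doc <- list(
    dims = list(n_states = model$n_states, n_obs = model$n_obs,
                n_controls = model$n_controls, T = model$T,
                iters_per_epoch = model$iters_per_epoch),
    C = model$C,
    policies = model$policies,
    prec_shape = model$prec_shape,
    prec_rate = model$prec_rate,
    a_prior = beliefs$a_prior,
    b_prior = beliefs$b_prior
  )
  jsonlite::write_json(doc, path, digits = NA, matrix = "rowmajor",
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a generative model and fresh beliefs back from JSON
#'
#' @param path File written by [write_model_json()].
#' @return List with elements `model` and `beliefs`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- doc$dims
  model <- generative_model(
    n_states = dims[["n_states"]], n_obs = dims[["n_obs"]],
    n_controls = dims[["n_controls"]], T = dims[["T"]],
    C = doc$C, policies = doc$policies,
    prec_shape = doc$prec_shape, prec_rate = doc$prec_rate,
    iters_per_epoch = dims[["iters_per_epoch"]]
  )
  b_prior <- doc$b_prior
  if (is.array(b_prior) && length(dim(b_prior)) == 3L) {
    # a homogeneous list of matrices simplifies to one array on reading
    b_prior <- lapply(seq_len(dim(b_prior)[1L]),
                      function(u) b_prior[u, , ])
  }
  beliefs <- dirichlet_beliefs(doc$a_prior, b_prior)
  list(model = model, beliefs = beliefs)
}
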