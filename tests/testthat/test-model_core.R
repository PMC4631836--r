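test_that("softmax maps log-potentials onto the simplex with shift invariance", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(softmax(c(0, log(2))), c(1 / 3, 2 / 3), tolerance = 1e-12)
  v <- c(-3.2, 0.5, 1.7, -800)
  expect_equal(softmax(v), softmax(v + 100), tolerance = 1e-12)
  expect_equal(sum(softmax(v)), 1, tolerance = 1e-10)
  expect_error(softmax(c(0, NaN)), "non-finite")
  expect_error(softmax(c(0, Inf)), "non-finite")
})

test_that("dirichlet_expected_log matches the digamma formula and its limits", {
  # psi(2) = psi(1) + 1, so a (1,1) column gives exactly -1
  expect_equal(as.numeric(dirichlet_expected_log(c(1, 1))), c(-1, -1),
               tolerance = 1e-12)
  # large concentrations approach the plain log of the mean
  p <- 0.3
  big <- dirichlet_expected_log(1e6 * c(p, 1 - p))
  expect_equal(as.numeric(big), log(c(p, 1 - p)), tolerance = 1e-5)
  # (0.4, 1.0) column against an independent digamma implementation
  got <- as.numeric(dirichlet_expected_log(c(0.4, 1.0)))
  want <- c(oracle_digamma(0.4) - oracle_digamma(1.4),
            oracle_digamma(1.0) - oracle_digamma(1.4))
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(dirichlet_expected_log(c(1, 0)), "positive")
  expect_error(dirichlet_expected_log(c(1, -2)), "positive")
})

test_that("expected logs are monotone in own entry, decreasing in total, below the log-expectation", {
  set.seed(71)
  for (i in 1:20) {
    conc <- matrix(rexp(6) + 0.05, 3, 2)
    el <- dirichlet_expected_log(conc)
    expect_true(all(el <= 0))
    # Jensen gap: E[log p] <= log E[p]
    expect_true(all(el <= log(dirichlet_expectation(conc)) + 1e-12))
    # increasing an entry raises its own expected log
    bump <- conc
    bump[1, 1] <- bump[1, 1] + 0.1
    expect_gt(dirichlet_expected_log(bump)[1, 1], el[1, 1])
    # increasing another entry of the same column lowers it
    other <- conc
    other[2, 1] <- other[2, 1] + 0.1
    expect_lt(dirichlet_expected_log(other)[1, 1], el[1, 1])
  }
})

test_that("kl_divergence matches closed forms and a brute-force sum", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0, tolerance = 1e-14)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:25) {
    p <- random_simplex(5)
    q <- random_simplex(5)
    expect_equal(kl_divergence(p, q), oracle_kl(p, q), tolerance = 1e-12)
    expect_gte(kl_divergence(p, q), 0)
  }
  expect_error(kl_divergence(c(1, 0), c(1, 0, 0)), "length")
})

test_that("Dirichlet and Gamma KL closed forms agree with numerical integration", {
  # Beta marginals are the two-row Dirichlet case
  kl_beta_num <- function(a1, b1, a2, b2) {
    stats::integrate(function(x) {
      stats::dbeta(x, a1, b1) *
        (stats::dbeta(x, a1, b1, log = TRUE) -
           stats::dbeta(x, a2, b2, log = TRUE))
    }, 0, 1, rel.tol = 1e-10)$value
  }
  expect_equal(dirichlet_kl(c(3, 2), c(1.2, 0.7)),
               kl_beta_num(3, 2, 1.2, 0.7), tolerance = 1e-6)
  expect_equal(dirichlet_kl(c(0.4, 1), c(0.4, 1)), 0, tolerance = 1e-12)

  kl_gamma_num <- function(s1, r1, s2, r2) {
    stats::integrate(function(x) {
      stats::dgamma(x, s1, rate = r1) *
        (stats::dgamma(x, s1, rate = r1, log = TRUE) -
           stats::dgamma(x, s2, rate = r2, log = TRUE))
    }, 0, Inf, rel.tol = 1e-10)$value
  }
  expect_equal(gamma_kl(4, 2.5, 4, 1), kl_gamma_num(4, 2.5, 4, 1),
               tolerance = 1e-6)
  expect_equal(gamma_kl(4, 1, 4, 1), 0, tolerance = 1e-12)
})

test_that("generative_model validates preferences, policies and hyperparameters", {
  good <- toy3_model()
  expect_s3_class(good, "generative_model")
  expect_error(
    generative_model(3, 3, 2, 3, C = c(0, 0, 0),
                     policies = rbind(c(1L, 1L))),
    "exp\\(C\\)")
  expect_error(
    generative_model(3, 3, 2, 3, C = log(c(0.5, 0.3, 0.2)),
                     policies = rbind(c(1L, 3L))),
    "control indices")
  expect_error(
    generative_model(3, 3, 2, 3, C = log(c(0.5, 0.3, 0.2)),
                     policies = rbind(1L)),
    "one control per transition")
  expect_error(
    generative_model(3, 3, 2, 3, C = log(c(0.5, 0.3, 0.2)),
                     policies = rbind(c(1L, 1L)), prec_shape = -1))
})

test_that("dirichlet_beliefs caches simplex expectations and accumulates mass only", {
  bel <- toy3_beliefs()
  expect_equal(colSums(bel$EA), rep(1, 3), tolerance = 1e-10)
  for (u in 1:2) {
    expect_equal(colSums(bel$EB[[u]]), rep(1, 3), tolerance = 1e-10)
    expect_true(all(bel$B_elog[[u]] <= 0))
  }
  expect_true(all(bel$A_elog <= 0))
  bel2 <- accumulate_observation_counts(bel, 1L, c(0.2, 0.3, 0.5))
  expect_silent(actinf:::validate_dirichlet_beliefs(bel2))
})

test_that("model JSON serialization round-trips exactly", {
  task <- conditioning_task()
  ag <- build_agent_model(task)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(ag$model, ag$beliefs, path)
  back <- read_model_json(path)
  expect_equal(back$model$C, ag$model$C, tolerance = 1e-12)
  expect_identical(back$model$policies, ag$model$policies)
  expect_equal(back$model$prec_shape, ag$model$prec_shape)
  expect_equal(back$beliefs$a_prior, ag$beliefs$a_prior, tolerance = 1e-12,
               ignore_attr = TRUE)
  for (u in 1:3) {
    expect_equal(back$beliefs$b_prior[[u]], ag$beliefs$b_prior[[u]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})
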