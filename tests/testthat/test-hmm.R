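test_that("observation strings parse and the FIFO window shifts by one", {
  expect_identical(parse_seqobs("1111112311"),
                   c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 3L, 1L, 1L))
  w <- obs_window("1111112311")
  w2 <- push_obs(w, 2)
  expect_identical(as.integer(w2), parse_seqobs("1111123112"))
  expect_length(w2, 10)
  # two pushes equal one two-symbol shift
  w3 <- push_obs(push_obs(w, 2), 4)
  expect_identical(as.integer(w3), c(parse_seqobs("1111112311")[-(1:2)],
                                  2L, 4L))
  expect_error(parse_seqobs("12x1"), "digits")
})

test_that("stationary distributions match closed forms", {
  # identity chain stays where it starts
  expect_equal(unname(stationary(diag(3), initial = c(1, 0, 0))),
               c(1, 0, 0))
  # two-state chain: pi = (b, a) / (a + b)
  a <- 0.3; b <- 0.12
  P <- matrix(c(1 - a, a, b, 1 - b), 2, byrow = TRUE)
  expect_equal(unname(stationary(P)), c(b, a) / (a + b), tolerance = 1e-10)
  # doubly stochastic: uniform
  D <- matrix(c(.2, .3, .5, .5, .2, .3, .3, .5, .2), 3, byrow = TRUE)
  expect_equal(unname(stationary(D)), rep(1 / 3, 3), tolerance = 1e-10)
})

test_that("stationary fixed-point residual is at solver precision on
           random chains", {
  set.seed(101)
  for (rep in 1:10) {
    P <- rand_stochastic(sample(2:5, 1))
    pi <- stationary(P)
    expect_lt(max(abs(drop(pi %*% P) - pi)), 1e-12)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
  }
})

test_that("expected visits propagate the initial distribution and sum to
           the horizon", {
  expect_equal(unname(expected_visits(diag(3), c(1, 0, 0), 10)),
               c(10, 0, 0))
  U <- matrix(0.5, 2, 2)
  expect_equal(unname(expected_visits(U, c(1, 0), 10)), c(5, 5))
  set.seed(7)
  P <- rand_stochastic(3)
  v <- expected_visits(P, c(1, 0, 0), 10)
  expect_equal(sum(v), 10, tolerance = 1e-12)
  # Monte-Carlo occupancy oracle
  nrep <- 2e4
  set.seed(8)
  cum <- t(apply(P, 1, cumsum))
  occ <- numeric(3)
  state <- rep(1L, nrep)
  for (step in 1:10) {
    u <- runif(nrep)
    state <- max.col(cum[state, ] - u >= 0, ties.method = "first")
    occ <- occ + tabulate(state, 3)
  }
  expect_equal(unname(v), occ / nrep, tolerance = 0.02)
})

test_that("first-passage times match closed forms and flag unreachable
           targets", {
  # geometric: single exit with probability a
  a <- 0.25
  P <- matrix(c(1 - a, a, 0, 1), 2, byrow = TRUE)
  m <- first_passage(P, 2)
  expect_equal(unname(m[1]), 1 / a)
  # absorbing target reached in one step from everywhere
  P1 <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, byrow = TRUE)
  expect_equal(unname(first_passage(P1, 3)[1:2]), c(1, 1))
  # unreachable target
  P2 <- diag(3)
  m2 <- first_passage(P2, 3)
  expect_true(is.na(m2[1]) && is.na(m2[2]))
  expect_true(attr(m2, "unreachable")[1])
})

test_that("the linear-system first-passage solver agrees with the
           fundamental-matrix solution for an absorbing chain", {
  Q <- matrix(c(0.6, 0.2, 0.1, 0.5), 2, byrow = TRUE)
  P <- rbind(cbind(Q, 1 - rowSums(Q)), c(0, 0, 1))
  m <- first_passage(P, 3)
  oracle <- solve(diag(2) - Q, c(1, 1))  # N %*% 1, N = (I-Q)^-1
  expect_equal(unname(m[1:2]), oracle)
})

test_that("Baum-Welch improves the likelihood monotonically and
           concentrates on a repeated symbol", {
  pr <- hmm_spec(matrix(c(.7, .3, .4, .6), 2, byrow = TRUE),
                 matrix(c(.9, .1, .1, .9), 2, byrow = TRUE))
  fit <- baum_welch(pr, rep(1L, 12))
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  # posterior transition concentrates on the matching state's self-loop
  expect_gt(fit$spec$transition[1, 1], 0.95)
  expect_error(baum_welch(pr, integer(0)), "empty")
  expect_error(baum_welch(pr, c(1L, 3L)), "alphabet")
})

test_that("Baum-Welch log-likelihood is nondecreasing on random priors
           and windows", {
  set.seed(202)
  for (rep in 1:8) {
    pr <- rand_hmm_spec(3, 4)
    obs <- sample.int(4, 10, replace = TRUE)
    fit <- baum_welch(pr, obs)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_true(all(abs(rowSums(fit$spec$transition) - 1) < 1e-9))
    expect_true(all(abs(rowSums(fit$spec$emission) - 1) < 1e-9))
  }
})

test_that("the fitted worked-case chain reproduces the reported occupation
           pattern under a near-diagnostic emission", {
  pr <- hmm_spec(matrix(c(.8, .15, .05, .1, .7, .2, .05, .15, .8), 3,
                        byrow = TRUE),
                 matrix(c(.8, .1, .05, .05,
                          .1, .7, .1, .1,
                          .05, .1, .7, .15), 3, byrow = TRUE),
                 hidden_states = c("SF1", "SF2", "SF3"),
                 observed_symbols = c("V1", "V2", "V3", "V4"))
  fit <- baum_welch(pr, worked_case_fixture()$seqobs[["end_states"]])
  occ <- stationary(fit$spec$transition, fit$spec$initial)
  # empirical symbol frequencies of 1111112311 are 0.8 / 0.1 / 0.1
  expect_equal(unname(occ), c(0.8, 0.1, 0.1), tolerance = 0.1)
  expect_gt(occ[1], occ[2])
})

test_that("the recurrent update hands the posterior on as the next prior", {
  pr <- rand_hmm_spec(3, 4)
  fit <- baum_welch(pr, obs_window("1111112311"))
  up <- recurrent_hmm_update(fit, 2)
  expect_identical(as.integer(up$window), parse_seqobs("1111123112"))
  expect_identical(up$prior$transition, fit$spec$transition)
  expect_error(recurrent_hmm_update(fit, 9), "alphabet")
})

test_that("simulated HMM sequences support parameter recovery", {
  truth <- recovery_truth()
  sim <- simulate_hmm(truth, 500, seed = 31)
  expect_identical(sim$symbols, simulate_hmm(truth, 500, seed = 31)$symbols)
  # identity emission: symbols equal the hidden path
  ident <- hmm_spec(truth$transition, diag(3))
  sim_id <- simulate_hmm(ident, 100, seed = 5)
  expect_identical(sim_id$symbols, sim_id$path)

  set.seed(77)
  pr <- hmm_spec(perturb_stochastic(truth$transition, 0.15),
                 perturb_stochastic(truth$emission, 0.15))
  fit <- baum_welch(pr, sim$symbols)
  expect_lt(max(abs(fit$spec$transition - truth$transition)), 0.12)
  expect_lt(max(abs(fit$spec$emission - truth$emission)), 0.12)
})
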