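test_that("Poisson-gamma conjugate update gives the exact gamma posterior", {
  pr <- gamma_prior(0.001, 0.001)
  p4 <- poisson_gamma_update(pr, s = 1, n_intervals = 4)
  expect_equal(p4$params$shape, 1.001)
  expect_equal(p4$params$rate, 4.001)
  expect_equal(round(p4$mean, 2), 0.25)
  expect_equal(round(p4$sd, 2), 0.25)

  p8 <- poisson_gamma_update(pr, s = 3, n_intervals = 8)
  expect_equal(round(p8$mean, 2), 0.38)
  expect_equal(round(p8$sd, 2), 0.22)

  p2 <- poisson_gamma_update(pr, s = 0, n_intervals = 2)
  expect_equal(round(p2$mean, 2), 0)
  expect_equal(round(p2$sd, 3), 0.016)

  # no-event limit drives the mean to zero
  expect_lt(poisson_gamma_update(pr, 0, 1e6)$mean, 1e-8)
})

test_that("sequential conjugate updating equals the cumulative update", {
  y <- worked_counts
  pr <- gamma_prior(0.001, 0.001)
  seq_prior <- pr
  for (i in seq_along(y)) {
    post <- poisson_gamma_update(seq_prior, y[i], 1)
    seq_prior <- gamma_prior(post$params$shape, post$params$rate)
  }
  cum <- poisson_gamma_update(pr, sum(y), length(y))
  expect_equal(seq_prior$alpha, cum$params$shape)
  expect_equal(seq_prior$beta, cum$params$rate)
})

test_that("Poisson-gamma posterior sd is strictly decreasing in Nt", {
  pr <- gamma_prior(0.5, 10)
  sds <- vapply(1:30, function(n) poisson_gamma_update(pr, 3, n)$sd,
                numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("exponential-gamma log-posterior matches its conjugate form", {
  pr <- gamma_prior(0.5, 10)
  lp <- exponential_gamma_logpost(pr, t = 4)
  oracle <- attr(lp, "conjugate")
  expect_equal(oracle$params$shape, 1.5)
  expect_equal(oracle$params$rate, 14)
  expect_equal(oracle$mean, 1.5 / 14)
  # log-kernel equals the gamma(1.5, 14) log-density up to a constant
  grid <- seq(0.01, 1, length.out = 50)
  diffs <- lp(grid) - dgamma(grid, 1.5, 14, log = TRUE)
  expect_lt(diff(range(diffs)), 1e-10)
  expect_equal(lp(0), -Inf)
  expect_error(exponential_gamma_logpost(pr, t = 0), "> 0")
})

test_that("Weibull log-posterior reduces to exponential at c = 1 and has
           the analytic mode", {
  pr <- gamma_prior(0.5, 10)
  grid <- seq(0.01, 2, length.out = 80)
  w1 <- weibull_gamma_logpost(pr, t = 4, c = 1)
  e <- exponential_gamma_logpost(pr, t = 4)
  expect_equal(w1(grid), e(grid), tolerance = 1e-12)

  # alpha = 1, beta -> 0, c = 2, t = 1: d/dl log f = 2/l - 2l = 0 at l = 1
  w <- weibull_gamma_logpost(gamma_prior(1, 1e-12), t = 1, c = 2)
  opt <- optimize(w, c(0.01, 10), maximum = TRUE)
  expect_equal(opt$maximum, 1, tolerance = 1e-4)
  expect_error(weibull_gamma_logpost(pr, 1, c = 0), "c must be")
})

test_that("normal-prior log-posteriors have positive support and the
           flat-prior limit recovers the likelihood mode", {
  wide <- normal_prior(0.05, 1e6)
  en <- exponential_normal_logpost(wide, t = 2)
  expect_equal(optimize(en, c(1e-4, 10), maximum = TRUE)$maximum, 0.5,
               tolerance = 1e-3)
  expect_equal(en(-1), -Inf)
  expect_equal(en(0), -Inf)

  pn <- poisson_normal_logpost(wide, events = 1, exposure = 4)
  expect_equal(optimize(pn, c(1e-4, 10), maximum = TRUE)$maximum, 0.25,
               tolerance = 1e-3)
  # literal reading swaps the count/exposure binding
  pn_lit <- poisson_normal_logpost(wide, events = 4, exposure = 1,
                                   literal = TRUE)
  grid <- seq(0.01, 1, length.out = 40)
  expect_equal(pn_lit(grid), pn(grid), tolerance = 1e-12)
  # zero count: pure prior shrinkage; the exposure term shifts the mode
  # to mu - exposure * sigma^2 (set the derivative of the kernel to zero)
  tight <- normal_prior(0.05, 0.01)
  pn0 <- poisson_normal_logpost(tight, events = 0, exposure = 3)
  expect_equal(optimize(pn0, c(1e-4, 1), maximum = TRUE)$maximum,
               0.05 - 3 * 0.01^2, tolerance = 1e-3)
})

test_that("every log-posterior kernel is integrable on (0, Inf)", {
  kernels <- list(
    exponential_gamma_logpost(gamma_prior(0.5, 10), t = 4),
    weibull_gamma_logpost(gamma_prior(0.5, 10), t = 4, c = 1.5),
    exponential_normal_logpost(normal_prior(0.05, 0.05), t = 4),
    poisson_normal_logpost(normal_prior(0.05, 0.05), 1, 4)
  )
  for (lp in kernels) {
    z <- integrate(function(l) exp(lp(l)), 0, Inf)$value
    expect_true(is.finite(z) && z > 0)
  }
})

test_that("posterior mean comparison is a relative percent difference", {
  mk <- function(m) posterior_estimate("gamma", mean = m, sd = 0.1)
  expect_equal(compare_posteriors(mk(0.25), mk(0.25)), 0)
  expect_equal(compare_posteriors(mk(0.20), mk(0.25)), 25)
  expect_equal(compare_posteriors(mk(0.29), mk(0.33)), 13.8, tolerance = 0.01)
  expect_error(compare_posteriors(mk(1e-12 * 0), mk(0.1)), "zero")
})

test_that("rates print at 2 dp, 3 dp below 0.1", {
  expect_identical(format_rate(c(0.25, 0.016, 0.3334)),
                   c("0.25", "0.016", "0.33"))
})
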