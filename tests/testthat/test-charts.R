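test_that("the event-based observed rate follows the waiting-time rule", {
  y <- worked_counts
  expect_equal(observed_rate(y, 4), 0.25)
  expect_equal(observed_rate(y, 7), 1 / 3)
  expect_equal(observed_rate(y, 8), 1)
  # carried forward between events, undefined before the first
  expect_true(is.na(observed_rate(y, 3)))
  expect_equal(observed_rate(y, 6), 0.25)
  expect_equal(observed_rate(y, 10), 1)
  # two incidences in one interval double the rate
  expect_equal(observed_rate(c(0, 2, 0), 2), 1)
})

test_that("recurrent mean-prior Poisson-gamma chart equals the cumulative
           conjugate posterior at every interval", {
  pr <- gamma_prior(0.001, 0.001)
  ch <- build_chart(worked_counts, "poisson", pr)
  for (i in 1:10) {
    ref <- poisson_gamma_update(pr, sum(worked_counts[1:i]), i)
    expect_equal(ch$points$posterior_mean[i], ref$mean)
    expect_equal(ch$points$posterior_sd[i], ref$sd)
  }
})

test_that("an all-zero series stays in control with a vanishing posterior", {
  ch <- build_chart(rep(0L, 12), "poisson", gamma_prior(0.001, 0.001),
                    chart = chart_config(horizon = 12))
  expect_true(all(ch$points$flag == "in_control"))
  expect_true(all(diff(ch$points$posterior_mean) < 0))
  expect_lt(ch$points$posterior_mean[12], 1e-4)
})

test_that("control limits respect the floor and k-sigma monotonicity", {
  pr <- gamma_prior(0.001, 0.001)
  out_count <- function(k) {
    ch <- build_chart(worked_counts, "poisson", pr,
                      chart = chart_config(k_sigma = k))
    expect_true(all(ch$points$lcl >= 0))
    expect_true(all(ch$points$lcl <= ch$points$center + 1e-12))
    expect_true(all(ch$points$center <= ch$points$ucl + 1e-12))
    sum(ch$points$flag == "out_of_limits")
  }
  counts_by_k <- vapply(c(0.5, 1, 2, 4, 8), out_count, numeric(1))
  expect_true(all(diff(counts_by_k) <= 0))
})

test_that("direct and recurrent gamma modes agree for the counts model and
           mean_posterior centers track the posterior", {
  pr <- gamma_prior(0.001, 0.001)
  rec <- build_chart(worked_counts, "poisson", pr,
                     chart = chart_config("recurrent_mean_prior"))
  dir <- build_chart(worked_counts, "poisson", pr,
                     chart = chart_config("direct_mean_prior"))
  expect_equal(rec$points$posterior_mean, dir$points$posterior_mean)
  expect_equal(rec$points$posterior_sd, dir$points$posterior_sd)

  mp <- build_chart(worked_counts, "poisson", pr,
                    chart = chart_config("recurrent_mean_posterior"))
  expect_equal(mp$points$center, mp$points$posterior_mean)
  expect_equal(rec$points$center, rep(0, 10))
})

test_that("chart tables round-trip through export", {
  ch <- build_chart(worked_counts, "poisson", gamma_prior(0.001, 0.001))
  path <- withr::local_tempfile(fileext = ".csv")
  export_chart(ch, path)
  back <- read_chart_table(path)
  expect_equal(nrow(back), 10)
  expect_equal(back$posterior_mean, ch$points$posterior_mean,
               tolerance = 1e-12)
  expect_identical(back$flag, ch$points$flag)
  # plot rendering produces a file
  pdf_path <- withr::local_tempfile(fileext = ".pdf")
  export_chart(ch, path, plot_path = pdf_path)
  expect_true(file.size(pdf_path) > 0)
})

test_that("model/prior mismatches are configuration errors", {
  expect_error(build_chart(worked_counts, "weibull",
                           normal_prior(0.05, 0.05)),
               "gamma prior")
  expect_error(build_chart(worked_counts[1:5], "poisson",
                           gamma_prior(1, 1),
                           chart = chart_config(horizon = 10)),
               "horizon")
})
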