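#' Chart configuration
#'
#' Four updating modes are supported. `recurrent` modes thread each
#' interval's posterior into the next interval's prior; `direct` modes
#' recompute from the accumulated raw data under the original prior.
#' `mean_prior` variants hold the center line at the stated target mean
#' while `mean_posterior` variants move it with the posterior mean. Limits
#' are `center +/- k_sigma * sigma_post`, the lower limit floored at zero.
#'
#' @param mode one of `"direct_mean_prior"`, `"direct_mean_posterior"`,
#'   `"recurrent_mean_prior"`, `"recurrent_mean_posterior"`.
#' @param k_sigma limit multiplier, > 0. The default 1 is deliberately
#'   tight: the monitored accident rate is required to be near zero, and
#'   narrow limits surface a deviation well before an accident.
#' @param target_mean target rate for the `mean_prior` center line.
#' @param horizon number of observation intervals.
#' @return An object of class `src_chart_config`.
#' @export
chart_config <- function(mode = c("recurrent_mean_prior",
                                  "recurrent_mean_posterior",
                                  "direct_mean_prior",
                                  "direct_mean_posterior"),
                         k_sigma = 1, target_mean = 0, horizon = 10) {
  mode <- match.arg(mode)
  stopifnot(k_sigma > 0, horizon >= 1, target_mean >= 0)
  structure(list(mode = mode, k_sigma = k_sigma,
                 target_mean = target_mean, horizon = as.integer(horizon)),
            class = "src_chart_config")
}

#' Event-based observed rate at an interval
#'
#' At an interval carrying `y_i > 0` incidences the observed rate is
#' `y_i / w` where `w` is the number of intervals elapsed since the
#' previous interval with incidences (since interval 0 for the first
#' event). At an interval with no incidences the previous observed value
#' is carried forward for plotting continuity (`NA` before the first
#' event).
#'
#' @param y integer vector of counts per interval.
#' @param i interval index, 1-based.
#' @return Observed rate (events per interval) or `NA` if no event has
#'   occurred by interval `i`.
#' @examples
#' y <- c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0)
#' observed_rate(y, 4)  # 1/4  = 0.25
#' observed_rate(y, 7)  # 1/3  = 0.33
#' observed_rate(y, 8)  # 1/1  = 1
#' @export
observed_rate <- function(y, i) {
  stopifnot(i >= 1, i <= length(y))
  events <- which(y[seq_len(i)] > 0)
  if (!length(events)) return(NA_real_)
  last <- events[length(events)]
  prev <- if (length(events) > 1) events[length(events) - 1] else 0
  y[last] / (last - prev)
}

round2 <- function(x) round(x, 2)

# flag one monitored value against the limits; equality after display
# rounding (2 dp) is "at_limit", strict exceedance is "out_of_limits"
flag_value <- function(value, ucl, lcl) {
  if (is.na(value)) return("in_control")
  if (round2(value) == round2(ucl) || round2(value) == round2(lcl))
    return("at_limit")
  if (value > ucl || value < lcl) return("out_of_limits")
  "in_control"
}

# posterior for a batch of waiting times under one prior; always sampled
# with MH (the conjugate exponential-gamma form stays a test oracle)
waiting_time_posterior <- function(times, model, prior, sampler, fatigue_c,
                                   literal_poisson_normal, seed) {
  post <- NULL
  cur_prior <- prior
  ar <- NA_real_
  for (t in times) {
    lp <- switch(
      model,
      exponential = if (cur_prior$family == "gamma")
        exponential_gamma_logpost(cur_prior, t)
      else exponential_normal_logpost(cur_prior, t),
      weibull = {
        if (cur_prior$family != "gamma")
          stop("the Weibull likelihood is paired with a gamma prior")
        weibull_gamma_logpost(cur_prior, t, fatigue_c)
      },
      poisson = {
        if (cur_prior$family != "normal")
          stop("per-event Poisson updating uses the normal prior; ",
               "use the conjugate count model with a gamma prior")
        poisson_normal_logpost(cur_prior, events = 1, exposure = t,
                               literal = literal_poisson_normal)
      },
      stop("unknown model '", model, "'")
    )
    cfg <- sampler
    cfg$seed <- seed
    tr <- suppressWarnings(metropolis_hastings(lp, cfg))
    post <- tr$summary
    ar <- tr$acceptance_rate
    cur_prior <- reprior(post, cur_prior)
  }
  list(posterior = post, prior = cur_prior, acceptance_rate = ar)
}

# carry a posterior forward as the next prior, preserving the prior family
reprior <- function(post, prior) {
  if (prior$family == "gamma") {
    if (post$family == "gamma")
      gamma_prior(post$params$shape, post$params$rate)
    else {
      # moment-match a sampled posterior onto the gamma family
      m <- post$mean; s <- post$sd
      gamma_prior((m / s)^2, m / s^2)
    }
  } else {
    normal_prior(post$mean, post$sd)
  }
}

#' Build a statistical risk control chart
#'
#' Runs one of the five rate models over a per-interval incidence series
#' and assembles the control chart: per-interval posterior mean/sd,
#' event-based observed rate, center line, k-sigma limits and an
#' in-control / at-limit / out-of-limits flag.
#'
#' The conjugate Poisson-gamma pair (counts likelihood, gamma prior) is
#' computed in closed form; the waiting-time models (exponential or
#' Weibull likelihood, and the per-event Poisson-normal model) update at
#' event intervals from the waiting time since the previous event with
#' seeded, acceptance-rate-tuned Metropolis-Hastings (for the
#' exponential-gamma pair the conjugate closed form exists and is used to
#' validate the sampler, but the chart follows the sampling protocol).
#'
#' Flags are evaluated at event intervals by comparing the event-based
#' observed rate against the limits; intervals without new incidences are
#' in control. Equality with a limit after display rounding (2 dp) is
#' reported as `at_limit`, distinct from strict `out_of_limits`.
#'
#' @param counts integer vector of incidences per interval (e.g. from
#'   [counts_per_interval()]).
#' @param model `"poisson"`, `"exponential"`, or `"weibull"`.
#' @param prior a [gamma_prior()] or [normal_prior()]. `"poisson"` with a
#'   gamma prior uses the conjugate count model; `"poisson"` with a normal
#'   prior uses the per-event sampled model.
#' @param chart a [chart_config()]; its horizon defaults to
#'   `length(counts)`.
#' @param sampler a [sampler_config()] for the non-conjugate models.
#' @param fatigue_c Weibull fatigue parameter (default 1.5, a conservative
#'   increasing-failure-rate choice).
#' @param literal_poisson_normal see [poisson_normal_logpost()].
#' @return An object of class `src_chart`: a list with `config`, `model`,
#'   `prior`, and `points` (one data.frame row per interval).
#' @examples
#' y <- c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0)
#' ch <- build_chart(y, model = "poisson", prior = gamma_prior(0.001, 0.001))
#' subset(ch$points, flag != "in_control")
#' @export
build_chart <- function(counts,
                        model = c("poisson", "exponential", "weibull"),
                        prior,
                        chart = NULL,
                        sampler = sampler_config(),
                        fatigue_c = 1.5,
                        literal_poisson_normal = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(prior, "src_prior"), all(counts >= 0))
  if (is.null(chart)) chart <- chart_config(horizon = length(counts))
  stopifnot(inherits(chart, "src_chart_config"))
  horizon <- chart$horizon
  if (length(counts) < horizon)
    stop("counts series shorter than the chart horizon")
  counts <- as.integer(counts[seq_len(horizon)])
  recurrent <- grepl("^recurrent", chart$mode)
  center_prior <- grepl("mean_prior$", chart$mode)
  conjugate_counts <- model == "poisson" && prior$family == "gamma"
  if (model %in% c("exponential", "weibull") && prior$family == "normal" &&
      model == "weibull")
    stop("the Weibull likelihood requires a gamma prior")

  seeds <- derive_seeds(sampler$seed, horizon)
  pts <- data.frame(
    interval = seq_len(horizon), count = counts,
    posterior_mean = NA_real_, posterior_sd = NA_real_,
    q05 = NA_real_, q95 = NA_real_,
    observed_rate = NA_real_, center = NA_real_,
    ucl = NA_real_, lcl = NA_real_,
    flag = NA_character_, acceptance_rate = NA_real_,
    stringsAsFactors = FALSE
  )

  cur_prior <- prior
  # posterior carried between event intervals for the waiting-time models
  carried <- if (prior$family == "gamma")
    posterior_estimate("gamma",
                       list(shape = prior$alpha, rate = prior$beta),
                       mean = prior$alpha / prior$beta,
                       sd = sqrt(prior$alpha) / prior$beta,
                       ci = stats::qgamma(c(0.05, 0.95), prior$alpha,
                                          prior$beta))
  else
    posterior_estimate("normal", list(mu = prior$mu, sigma = prior$sigma),
                       mean = prior$mu, sd = prior$sigma,
                       ci = stats::qnorm(c(0.05, 0.95), prior$mu,
                                         prior$sigma))
  last_event <- 0L
  obs_prev <- NA_real_

  for (i in seq_len(horizon)) {
    ar_i <- NA_real_
    if (conjugate_counts) {
      if (recurrent) {
        post <- poisson_gamma_update(cur_prior, counts[i], 1)
        cur_prior <- reprior(post, cur_prior)
        # mean_prior threading keeps the cumulative conjugate posterior;
        # the rate parameter beta + Nt already carries the elapsed time
      } else {
        post <- poisson_gamma_update(prior, sum(counts[seq_len(i)]), i)
      }
    } else {
      if (counts[i] > 0) {
        w <- i - last_event
        times <- rep(w / counts[i], counts[i])
        base_prior <- if (recurrent) cur_prior else prior
        if (!recurrent && last_event > 0) {
          # direct modes refit from every recorded waiting time
          ev <- which(counts[seq_len(i)] > 0)
          gaps <- diff(c(0L, ev))
          times <- unlist(mapply(function(g, k) rep(g / k, k),
                                 gaps, counts[ev], SIMPLIFY = FALSE))
        }
        res <- waiting_time_posterior(times, model, base_prior, sampler,
                                      fatigue_c, literal_poisson_normal,
                                      seeds[i])
        post <- res$posterior
        ar_i <- res$acceptance_rate
        if (recurrent) cur_prior <- res$prior
        last_event <- i
      } else {
        post <- carried
      }
    }
    carried <- post

    center <- if (center_prior) chart$target_mean else post$mean
    ucl <- center + chart$k_sigma * post$sd
    lcl <- max(0, center - chart$k_sigma * post$sd)

    obs <- observed_rate(counts, i)
    new_event <- counts[i] > 0
    flag <- if (new_event) flag_value(obs, ucl, lcl) else "in_control"

    pts$posterior_mean[i] <- post$mean
    pts$posterior_sd[i] <- post$sd
    pts$q05[i] <- post$ci[1]
    pts$q95[i] <- post$ci[2]
    pts$observed_rate[i] <- obs
    pts$center[i] <- center
    pts$ucl[i] <- ucl
    pts$lcl[i] <- lcl
    pts$flag[i] <- flag
    pts$acceptance_rate[i] <- ar_i
    obs_prev <- obs
  }

  structure(list(config = chart, model = model, prior = prior,
                 fatigue_c = if (model == "weibull") fatigue_c else NA_real_,
                 points = pts),
            class = "src_chart")
}

#' @export
print.src_chart <- function(x, ...) {
  cat(sprintf("Risk control chart: %s likelihood, %s prior, mode %s, k = %g\n",
              x$model, x$prior$family, x$config$mode, x$config$k_sigma))
  shown <- x$points[, c("interval", "count", "posterior_mean",
                        "posterior_sd", "observed_rate", "ucl", "flag")]
  shown$posterior_mean <- format_rate(shown$posterior_mean)
  shown$posterior_sd <- format_rate(shown$posterior_sd)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' @export
plot.src_chart <- function(x, main = NULL, ...) {
  p <- x$points
  if (is.null(main))
    main <- sprintf("%s-%s chart (%s)", x$model, x$prior$family,
                    x$config$mode)
  ylim <- range(0, p$ucl, p$posterior_mean, p$observed_rate, na.rm = TRUE)
  graphics::plot(p$interval, p$posterior_mean, type = "b", pch = 16,
                 ylim = ylim, xlab = "interval",
                 ylab = expression(lambda), main = main, ...)
  graphics::lines(p$interval, p$ucl, lty = 2, col = "red3")
  graphics::lines(p$interval, p$lcl, lty = 2, col = "red3")
  graphics::lines(p$interval, p$center, lty = 3)
  graphics::points(p$interval, p$observed_rate, pch = 4, col = "blue3")
  out <- p$flag != "in_control"
  if (any(out))
    graphics::points(p$interval[out], p$observed_rate[out], pch = 1,
                     cex = 2.2, col = "red3")
  graphics::legend("topleft", bty = "n", cex = 0.8,
                   legend = c("posterior mean", "observed rate",
                              "limits", "center"),
                   pch = c(16, 4, NA, NA), lty = c(NA, NA, 2, 3),
                   col = c("black", "blue3", "red3", "black"))
  invisible(x)
}

#' Export and re-import a chart table
#'
#' Writes one row per chart point as delimited text (full precision) and
#' optionally renders the chart to a PDF file. `read_chart_table()`
#' restores the data rows losslessly.
#'
#' @param chart an `src_chart`.
#' @param path output path for the CSV table.
#' @param plot_path optional output path for a PDF rendering.
#' @return `path`, invisibly.
#' @export
export_chart <- function(chart, path, plot_path = NULL) {
  stopifnot(inherits(chart, "src_chart"))
  utils::write.csv(chart$points, path, row.names = FALSE, quote = FALSE)
  if (!is.null(plot_path)) {
    grDevices::pdf(plot_path, width = 8, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(chart)
  }
  invisible(path)
}

#' @rdname export_chart
#' @export
read_chart_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
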