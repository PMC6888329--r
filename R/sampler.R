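#' Sampler configuration
#'
#' Defaults follow the published protocol: 4500 draws per cycle, the first
#' 500 discarded as burn-in, and 10 independent replicate cycles whose
#' retained draws are pooled. Acceptance rates between 48% and 68% are
#' treated as the indicator of a good random-walk scale.
#'
#' @param n_draws draws per cycle.
#' @param burn_in discarded draws per cycle, < `n_draws`.
#' @param cycles number of independent replicate chains.
#' @param proposal_scale random-walk standard deviation; `NA` to start from
#'   a Laplace (curvature-at-mode) estimate.
#' @param seed master seed; per-cycle seeds are derived deterministically.
#' @param auto_tune tune the proposal scale into `ar_band` before sampling.
#' @param ar_band target acceptance-rate band.
#' @return An object of class `src_sampler_config`.
#' @export
sampler_config <- function(n_draws = 4500, burn_in = 500, cycles = 10,
                           proposal_scale = NA_real_, seed = 1L,
                           auto_tune = TRUE, ar_band = c(0.48, 0.68)) {
  stopifnot(burn_in < n_draws, cycles >= 1,
            length(ar_band) == 2, ar_band[1] < ar_band[2])
  structure(list(n_draws = as.integer(n_draws),
                 burn_in = as.integer(burn_in),
                 cycles = as.integer(cycles),
                 proposal_scale = proposal_scale,
                 seed = as.integer(seed),
                 auto_tune = isTRUE(auto_tune),
                 ar_band = ar_band),
            class = "src_sampler_config")
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

# crude global mode search followed by local refinement; used for the
# chain starting point and the Laplace scale guess
find_mode <- function(logpost, upper = 1e3) {
  grid <- exp(seq(log(1e-8), log(upper), length.out = 400))
  vals <- logpost(grid)
  if (!any(is.finite(vals)))
    stop("log-posterior is not finite anywhere on (0, ", upper, ")")
  g0 <- grid[which.max(vals)]
  opt <- stats::optimize(logpost, lower = g0 / 20, upper = min(upper, g0 * 20),
                         maximum = TRUE)
  opt$maximum
}

laplace_scale <- function(logpost, mode) {
  h <- max(mode * 1e-4, 1e-8)
  d2 <- (logpost(mode + h) - 2 * logpost(mode) + logpost(mode - h)) / h^2
  if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else max(mode, 0.1)
}

# one random-walk chain with reflection at zero; proposal is symmetric so
# the acceptance ratio involves the target only
mh_chain <- function(logpost, n, scale, init, seed) {
  set.seed(seed)
  steps <- stats::rnorm(n, 0, scale)
  logu <- log(stats::runif(n))
  draws <- numeric(n)
  cur <- init
  cur_lp <- logpost(cur)
  if (!is.finite(cur_lp)) stop("chain initialised where log-posterior is -Inf")
  acc <- 0L
  for (i in seq_len(n)) {
    prop <- abs(cur + steps[i])
    lp <- logpost(prop)
    if (is.finite(lp) && lp - cur_lp > logu[i]) {
      cur <- prop
      cur_lp <- lp
      acc <- acc + 1L
    }
    draws[i] <- cur
  }
  list(draws = draws, accepted = acc)
}

#' Random-walk Metropolis-Hastings sampling of a rate posterior
#'
#' Runs `cycles` independent chains on the positive half-line with a
#' symmetric random-walk proposal reflected at zero, discards the burn-in
#' of each, and pools the retained draws. The pooled mean, sd and 5-95
#' percentile interval form the posterior summary. Fully reproducible from
#' the configuration seed.
#'
#' An acceptance rate outside the configured band produces a warning, not
#' an error: the band is a sampling-quality indicator.
#'
#' @param logpost log-posterior function of lambda (e.g. from
#'   [exponential_gamma_logpost()]).
#' @param cfg a [sampler_config()].
#' @param init optional starting value; defaults to the posterior mode.
#' @return An object of class `src_trace`: pooled `draws`, per-cycle draw
#'   matrix `cycle_draws`, `acceptance_rate`, `cycle_means`,
#'   `proposal_scale`, and `summary` (an `src_posterior`).
#' @examples
#' lp <- exponential_gamma_logpost(gamma_prior(0.5, 10), t = 4)
#' tr <- metropolis_hastings(lp, sampler_config(seed = 7))
#' tr$summary$mean            # close to the conjugate (0.5+1)/(10+4)
#' attr(lp, "conjugate")$mean
#' @export
metropolis_hastings <- function(logpost, cfg = sampler_config(), init = NULL) {
  stopifnot(inherits(cfg, "src_sampler_config"))
  mode <- find_mode(logpost)
  if (is.null(init)) init <- mode
  scale <- cfg$proposal_scale
  if (is.na(scale)) scale <- laplace_scale(logpost, mode)
  if (cfg$auto_tune)
    scale <- tune_proposal(logpost, cfg, init = init, start_scale = scale)
  if (scale <= 0) stop("degenerate proposal scale (<= 0)")

  seeds <- derive_seeds(cfg$seed, cfg$cycles)
  keep <- cfg$n_draws - cfg$burn_in
  cycle_draws <- matrix(NA_real_, nrow = keep, ncol = cfg$cycles)
  accepted <- 0L
  for (cy in seq_len(cfg$cycles)) {
    ch <- mh_chain(logpost, cfg$n_draws, scale, init, seeds[cy])
    if (ch$accepted == 0L)
      stop("all proposals rejected in cycle ", cy,
           "; proposal scale ", signif(scale, 3), " is unusable")
    cycle_draws[, cy] <- ch$draws[(cfg$burn_in + 1):cfg$n_draws]
    accepted <- accepted + ch$accepted
  }
  pooled <- as.vector(cycle_draws)
  ar <- accepted / (cfg$n_draws * cfg$cycles)
  if (ar < cfg$ar_band[1] || ar > cfg$ar_band[2])
    warning(sprintf("acceptance rate %.2f outside the [%.2f, %.2f] band",
                    ar, cfg$ar_band[1], cfg$ar_band[2]))
  structure(list(
    draws = pooled,
    cycle_draws = cycle_draws,
    acceptance_rate = ar,
    cycle_means = colMeans(cycle_draws),
    proposal_scale = scale,
    config = cfg,
    summary = posterior_estimate(
      family = "sampled",
      mean = mean(pooled),
      sd = stats::sd(pooled),
      ci = unname(stats::quantile(pooled, c(0.05, 0.95)))
    )
  ), class = "src_trace")
}

#' @export
print.src_trace <- function(x, ...) {
  cat(sprintf(
    "MH trace: %d cycles x %d retained draws, AR = %.0f%%, scale = %.4g\n",
    ncol(x$cycle_draws), nrow(x$cycle_draws), 100 * x$acceptance_rate,
    x$proposal_scale))
  print(x$summary)
  invisible(x)
}

#' Tune the random-walk proposal scale into the acceptance-rate band
#'
#' Pilot chains of `n_draws / 4` are run; the acceptance rate is a
#' decreasing function of the scale, so a rate above the band doubles the
#' scale and a rate below it halves it. Once the band is bracketed the
#' scale is bisected in log space. If the band cannot be reached within
#' the step budget the nearest-achieved scale is returned with a warning.
#'
#' @param logpost log-posterior function of lambda.
#' @param cfg a [sampler_config()].
#' @param init chain starting value; defaults to the posterior mode.
#' @param start_scale initial scale; defaults to
#'   `cfg$proposal_scale` or a Laplace estimate.
#' @param max_steps step budget.
#' @return The tuned proposal scale (numeric scalar) with attribute
#'   `"pilot_ar"`, the acceptance rate achieved at that scale.
#' @export
tune_proposal <- function(logpost, cfg = sampler_config(), init = NULL,
                          start_scale = NULL, max_steps = 30) {
  stopifnot(inherits(cfg, "src_sampler_config"))
  if (is.null(init)) init <- find_mode(logpost)
  scale <- start_scale
  if (is.null(scale) || is.na(scale)) {
    scale <- cfg$proposal_scale
    if (is.na(scale)) scale <- laplace_scale(logpost, init)
  }
  n_pilot <- max(250L, cfg$n_draws %/% 4L)
  pilot_seeds <- derive_seeds(cfg$seed + 1L, max_steps)
  band <- cfg$ar_band

  pilot_ar <- function(s, k) {
    ch <- mh_chain(logpost, n_pilot, s, init, pilot_seeds[k])
    ch$accepted / n_pilot
  }

  lo_scale <- NA_real_  # scale whose AR is above the band (too small steps)
  hi_scale <- NA_real_  # scale whose AR is below the band (too large steps)
  best <- scale; best_dist <- Inf; best_ar <- NA_real_
  for (k in seq_len(max_steps)) {
    ar <- pilot_ar(scale, k)
    dist <- max(band[1] - ar, ar - band[2], 0)
    if (dist < best_dist) { best <- scale; best_dist <- dist; best_ar <- ar }
    if (ar >= band[1] && ar <= band[2]) {
      attr(scale, "pilot_ar") <- ar
      return(scale)
    }
    if (ar > band[2]) lo_scale <- scale else hi_scale <- scale
    scale <- if (is.na(lo_scale) || is.na(hi_scale)) {
      if (ar > band[2]) scale * 2 else scale / 2
    } else {
      exp((log(lo_scale) + log(hi_scale)) / 2)
    }
  }
  warning(sprintf(
    "acceptance band [%.2f, %.2f] not reached in %d pilot steps; using scale %.4g (AR %.2f)",
    band[1], band[2], max_steps, best, best_ar))
  attr(best, "pilot_ar") <- best_ar
  best
}
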