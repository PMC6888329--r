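#' Gamma prior for the event rate
#'
#' @param alpha shape parameter, > 0.
#' @param beta rate parameter, > 0. The prior mean is `alpha / beta`.
#' @return An object of class `src_prior` (family `"gamma"`).
#' @examples
#' gamma_prior(0.5, 10)   # prior mean 0.05: one event per 20 intervals
#' @export
gamma_prior <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha > 0, beta > 0)
  structure(list(family = "gamma", alpha = alpha, beta = beta),
            class = "src_prior")
}

#' Normal prior for the event rate
#'
#' The prior is a normal density centered at `mu` (the running estimate of
#' the rate, in events per interval) with spread `sigma`, truncated to
#' lambda > 0 since all likelihoods have positive support.
#'
#' @param mu prior center for the rate, events per interval.
#' @param sigma prior spread, > 0.
#' @return An object of class `src_prior` (family `"normal"`).
#' @export
normal_prior <- function(mu, sigma) {
  stopifnot(is.numeric(mu), is.numeric(sigma), sigma > 0)
  structure(list(family = "normal", mu = mu, sigma = sigma),
            class = "src_prior")
}

#' @export
print.src_prior <- function(x, ...) {
  if (x$family == "gamma")
    cat(sprintf("gamma prior: shape %.4g, rate %.4g (mean %.4g)\n",
                x$alpha, x$beta, x$alpha / x$beta))
  else
    cat(sprintf("normal prior (truncated to lambda > 0): mu %.4g, sigma %.4g\n",
                x$mu, x$sigma))
  invisible(x)
}

#' Posterior estimate container
#'
#' @param family `"gamma"`, `"normal"`, or `"sampled"`.
#' @param params named list of family parameters when closed-form.
#' @param mean posterior mean of the rate.
#' @param sd posterior standard deviation.
#' @param ci numeric length-2: 5th and 95th percentiles.
#' @return An object of class `src_posterior`.
#' @export
posterior_estimate <- function(family, params = list(), mean, sd,
                               ci = c(NA_real_, NA_real_)) {
  stopifnot(mean >= 0 || is.na(mean), sd >= 0 || is.na(sd))
  if (!any(is.na(ci))) stopifnot(ci[1] <= ci[2])
  structure(list(family = family, params = params, mean = mean, sd = sd,
                 ci = ci),
            class = "src_posterior")
}

#' @export
print.src_posterior <- function(x, ...) {
  cat(sprintf("posterior (%s): mean %s, sd %s, CI[5%%-95%%] [%s, %s]\n",
              x$family, format_rate(x$mean), format_rate(x$sd),
              format_rate(x$ci[1]), format_rate(x$ci[2])))
  invisible(x)
}

#' Display rounding for rates
#'
#' Rates are printed to 2 decimals, 3 decimals below 0.1, the precision
#' used throughout chart annotation. Internal computation is never rounded.
#'
#' @param x numeric vector.
#' @return character vector.
#' @export
format_rate <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) return(NA_character_)
    if (abs(xi) < 0.1) sprintf("%.3f", xi) else sprintf("%.2f", xi)
  }, character(1))
}

#' Conjugate Poisson-gamma posterior update
#'
#' For counts `y_i` per interval with total `s = sum(y_i)` observed over
#' `Nt` intervals, a gamma(alpha, beta) prior on the rate yields the gamma
#' posterior with shape `alpha + s` and rate `beta + Nt`. Sequential
#' updating (posterior of one interval reused as prior of the next) is
#' exactly equivalent to this single cumulative update.
#'
#' @param prior a [gamma_prior()].
#' @param s total incidence count, nonnegative integer.
#' @param n_intervals `Nt`, number of observed intervals, >= 1.
#' @return An `src_posterior` with gamma family parameters, exact mean
#'   `(alpha+s)/(beta+Nt)`, sd `sqrt(alpha+s)/(beta+Nt)` and 5-95 percentile
#'   interval.
#' @examples
#' poisson_gamma_update(gamma_prior(0.001, 0.001), s = 1, n_intervals = 4)
#' @export
poisson_gamma_update <- function(prior, s, n_intervals) {
  stopifnot(inherits(prior, "src_prior"), prior$family == "gamma",
            s >= 0, s == round(s), n_intervals >= 1)
  shape <- prior$alpha + s
  rate <- prior$beta + n_intervals
  posterior_estimate(
    family = "gamma",
    params = list(shape = shape, rate = rate),
    mean = shape / rate,
    sd = sqrt(shape) / rate,
    ci = stats::qgamma(c(0.05, 0.95), shape = shape, rate = rate)
  )
}

# wrap a raw log-kernel into a support-aware log-posterior closure
make_logpost <- function(kernel) {
  f <- function(lambda) {
    out <- rep(-Inf, length(lambda))
    ok <- lambda > 0
    if (any(ok)) out[ok] <- kernel(lambda[ok])
    out
  }
  class(f) <- c("src_logpost", class(f))
  f
}

#' Exponential-gamma log-posterior
#'
#' Unnormalized log-density of the rate given one observed waiting time `t`
#' between events under an exponential likelihood and gamma(alpha, beta)
#' prior: `alpha*log(lambda) - lambda*(beta + t)`. The model is conjugate;
#' the closed-form gamma posterior (shape `alpha + 1`, rate `beta + t`) is
#' attached as attribute `"conjugate"` and serves as the sampler oracle.
#'
#' @param prior a [gamma_prior()].
#' @param t waiting time since the previous event, in intervals, > 0.
#' @return A vectorized log-posterior function of lambda (class
#'   `src_logpost`) with attribute `conjugate` (an `src_posterior`).
#' @export
exponential_gamma_logpost <- function(prior, t) {
  stopifnot(inherits(prior, "src_prior"), prior$family == "gamma")
  if (t <= 0) stop("waiting time t must be > 0")
  a <- prior$alpha; b <- prior$beta
  f <- make_logpost(function(l) a * log(l) - l * (b + t))
  shape <- a + 1; rate <- b + t
  attr(f, "conjugate") <- posterior_estimate(
    family = "gamma", params = list(shape = shape, rate = rate),
    mean = shape / rate, sd = sqrt(shape) / rate,
    ci = stats::qgamma(c(0.05, 0.95), shape = shape, rate = rate)
  )
  f
}

#' Weibull-gamma log-posterior with fatigue parameter
#'
#' Unnormalized log-density of the rate given a waiting time `t` under a
#' Weibull likelihood with shape (fatigue parameter) `c` and a gamma prior:
#' `(alpha-1)*log(lambda) - lambda*beta + c*log(lambda) - (lambda*t)^c`.
#' `c > 1` models an increasing failure-rate function (fatigue
#' accumulation), `c = 1` a constant one — the expression then coincides
#' with the exponential-gamma log-posterior — and `0 < c < 1` a decreasing
#' one. A conservative default of `c = 1.5` is used by the chart engine.
#'
#' @param prior a [gamma_prior()].
#' @param t waiting time, > 0.
#' @param c fatigue (Weibull shape) parameter, > 0.
#' @return A vectorized log-posterior function of lambda.
#' @export
weibull_gamma_logpost <- function(prior, t, c = 1.5) {
  stopifnot(inherits(prior, "src_prior"), prior$family == "gamma")
  if (t <= 0) stop("waiting time t must be > 0")
  if (c <= 0) stop("fatigue parameter c must be > 0")
  a <- prior$alpha; b <- prior$beta
  make_logpost(function(l)
    (a - 1) * log(l) - l * b + c * log(l) - (l * t)^c)
}

#' Exponential-normal log-posterior
#'
#' Unnormalized log-density of the rate given a waiting time `t` under an
#' exponential likelihood and a normal prior centered at the running
#' parameter value `mu` with spread `sigma`, truncated to lambda > 0:
#' `log(lambda) - lambda*t - (mu - lambda)^2 / (2*sigma^2)`.
#'
#' @param prior a [normal_prior()].
#' @param t waiting time, > 0.
#' @return A vectorized log-posterior function of lambda.
#' @export
exponential_normal_logpost <- function(prior, t) {
  stopifnot(inherits(prior, "src_prior"), prior$family == "normal")
  if (t <= 0) stop("waiting time t must be > 0")
  mu <- prior$mu; sg <- prior$sigma
  make_logpost(function(l) log(l) - l * t - (mu - l)^2 / (2 * sg^2))
}

#' Poisson-normal log-posterior
#'
#' Unnormalized log-density of the rate for `events` events observed over
#' `exposure` intervals under a Poisson likelihood and a truncated normal
#' prior: `events*log(lambda*exposure) - lambda*exposure -
#' (mu - lambda)^2 / (2*sigma^2)`. The published form of this kernel is
#' ambiguous about which symbol is the count and which the exposure; the
#' default binds `events` to the count. Set `literal = TRUE` to swap the
#' two roles (the kernel is symmetric in the product, so only the binding
#' changes).
#'
#' @param prior a [normal_prior()].
#' @param events nonnegative event count.
#' @param exposure exposure, in intervals, > 0.
#' @param literal swap the count/exposure binding.
#' @return A vectorized log-posterior function of lambda. With
#'   `events = 0` the likelihood term reduces to the exposure factor only
#'   (pure-prior shrinkage toward `mu`).
#' @export
poisson_normal_logpost <- function(prior, events, exposure, literal = FALSE) {
  stopifnot(inherits(prior, "src_prior"), prior$family == "normal",
            events >= 0, exposure > 0)
  if (literal) { tmp <- events; events <- exposure; exposure <- tmp }
  mu <- prior$mu; sg <- prior$sigma
  if (events == 0)
    make_logpost(function(l) -l * exposure - (mu - l)^2 / (2 * sg^2))
  else
    make_logpost(function(l)
      events * log(l * exposure) - l * exposure - (mu - l)^2 / (2 * sg^2))
}

#' Relative percent difference between two posterior means
#'
#' @param a reference `src_posterior` (or a list with a `mean` element).
#' @param b comparison posterior.
#' @return `100 * |a$mean - b$mean| / a$mean`.
#' @export
compare_posteriors <- function(a, b) {
  stopifnot(is.finite(a$mean), is.finite(b$mean))
  if (a$mean == 0) stop("reference posterior mean is zero")
  100 * abs(a$mean - b$mean) / a$mean
}
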