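#' Hidden-Markov specification for barrier / end-state analysis
#'
#' Two complementary analysis modes share this container: hidden
#' mitigative barriers emitting observed injury end states, or hidden end
#' states emitting the observed active barrier. Rows of the transition and
#' emission matrices must be stochastic.
#'
#' @param transition square row-stochastic matrix; `transition[i, j]` is
#'   the probability of moving from hidden state i to j.
#' @param emission row-stochastic matrix, one row per hidden state and one
#'   column per observed symbol.
#' @param initial initial hidden-state probability vector; defaults to
#'   uniform.
#' @param hidden_states labels for the hidden states; defaults to
#'   rownames of `transition`.
#' @param observed_symbols labels for the observed symbols; defaults to
#'   colnames of `emission`.
#' @return An object of class `hmm_spec`.
#' @export
hmm_spec <- function(transition, emission, initial = NULL,
                     hidden_states = NULL, observed_symbols = NULL) {
  transition <- as.matrix(transition)
  emission <- as.matrix(emission)
  n <- nrow(transition)
  stopifnot(ncol(transition) == n, nrow(emission) == n)
  if (is.null(initial)) initial <- rep(1 / n, n)
  stopifnot(length(initial) == n)
  check_stochastic(transition, "transition")
  check_stochastic(emission, "emission")
  if (abs(sum(initial) - 1) > 1e-8 || any(initial < 0))
    stop("initial distribution must be a probability vector")
  if (is.null(hidden_states))
    hidden_states <- rownames(transition) %||% paste0("H", seq_len(n))
  if (is.null(observed_symbols))
    observed_symbols <- colnames(emission) %||%
      paste0("O", seq_len(ncol(emission)))
  dimnames(transition) <- list(hidden_states, hidden_states)
  dimnames(emission) <- list(hidden_states, observed_symbols)
  structure(list(transition = transition, emission = emission,
                 initial = stats::setNames(initial, hidden_states),
                 hidden_states = hidden_states,
                 observed_symbols = observed_symbols),
            class = "hmm_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_stochastic <- function(m, what, tol = 1e-6) {
  if (any(m < -1e-12) || any(m > 1 + 1e-12))
    stop(what, " matrix entries must lie in [0, 1]")
  if (any(abs(rowSums(m) - 1) > tol))
    stop(what, " matrix rows must sum to 1")
  invisible(m)
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat("HMM spec:", length(x$hidden_states), "hidden states (",
      paste(x$hidden_states, collapse = ", "), ") emitting",
      length(x$observed_symbols), "symbols\n")
  cat("transition:\n"); print(round(x$transition, 3))
  cat("emission:\n"); print(round(x$emission, 3))
  invisible(x)
}

#' Parse a compact observation string
#'
#' Observation sequences are written as digit strings such as
#' `"1111112311"`, each digit the 1-based index of an observed symbol.
#'
#' @param s character scalar of digits (or an already-numeric vector,
#'   returned as integers).
#' @return Integer vector of symbol indices.
#' @export
parse_seqobs <- function(s) {
  if (is.numeric(s)) return(as.integer(s))
  stopifnot(is.character(s), length(s) == 1)
  if (!grepl("^[0-9]+$", s)) stop("observation string must be digits only")
  as.integer(strsplit(s, "")[[1]])
}

#' Rolling FIFO observation window
#'
#' Barrier/end-state observations are kept in a rolling group of ten:
#' each new observation enters and the oldest one leaves.
#'
#' @param symbols initial symbols (indices or digit string).
#' @param capacity window capacity.
#' @return Object of class `obs_window` (an integer vector with a
#'   capacity attribute).
#' @examples
#' w <- obs_window("1111112311")
#' push_obs(w, 2)  # 1111123112
#' @export
obs_window <- function(symbols = integer(0), capacity = 10) {
  symbols <- parse_seqobs(symbols)
  if (length(symbols) > capacity)
    symbols <- symbols[(length(symbols) - capacity + 1):length(symbols)]
  structure(symbols, capacity = as.integer(capacity), class = "obs_window")
}

#' @rdname obs_window
#' @param window an `obs_window`.
#' @param symbol new observed symbol index.
#' @export
push_obs <- function(window, symbol) {
  stopifnot(inherits(window, "obs_window"))
  cap <- attr(window, "capacity")
  out <- c(unclass(window), as.integer(symbol))
  if (length(out) > cap) out <- out[(length(out) - cap + 1):length(out)]
  structure(out, capacity = cap, class = "obs_window")
}

#' @export
print.obs_window <- function(x, ...) {
  cat("FIFO window [", paste(unclass(x), collapse = ""), "] (capacity ",
      attr(x, "capacity"), ")\n", sep = "")
  invisible(x)
}

# scaled forward-backward; returns alpha, beta, per-step scalings and the
# log-likelihood
forward_backward <- function(spec, obs) {
  A <- spec$transition; B <- spec$emission; p0 <- spec$initial
  Tn <- length(obs); N <- nrow(A)
  alpha <- matrix(0, N, Tn); beta <- matrix(0, N, Tn); cs <- numeric(Tn)
  a <- p0 * B[, obs[1]]
  cs[1] <- sum(a)
  if (cs[1] == 0) stop("observation sequence has zero probability under the prior")
  alpha[, 1] <- a / cs[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- drop(crossprod(A, alpha[, t - 1])) * B[, obs[t]]
    cs[t] <- sum(a)
    if (cs[t] == 0) stop("observation sequence has zero probability under the prior")
    alpha[, t] <- a / cs[t]
  }
  beta[, Tn] <- 1
  if (Tn > 1) for (t in (Tn - 1):1)
    beta[, t] <- drop(A %*% (B[, obs[t + 1]] * beta[, t + 1])) / cs[t + 1]
  list(alpha = alpha, beta = beta, scale = cs, loglik = sum(log(cs)))
}

#' Log-likelihood of an observation window under an HMM
#'
#' @param spec an [hmm_spec()].
#' @param obs observation window, symbol indices, or digit string.
#' @return Log-likelihood (scalar).
#' @export
hmm_loglik <- function(spec, obs) {
  obs <- parse_seqobs(obs)
  forward_backward(spec, obs)$loglik
}

#' Baum-Welch fitting of the barrier/end-state HMM
#'
#' Standard EM re-estimation from forward-backward statistics: the prior
#' transition and emission matrices are updated from the expected
#' transition and occupancy counts of the observation window until the
#' log-likelihood improves by less than `tol` or `max_iter` is reached.
#' Rows that collapse to zero during re-estimation are regularized by
#' adding 1e-8 and renormalizing so that every fitted matrix remains a
#' proper stochastic matrix (and hence a usable recurrent prior).
#'
#' @param prior an [hmm_spec()] holding the prior matrices.
#' @param obs observation window (see [obs_window()]), symbol indices, or
#'   a digit string.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap.
#' @return An object of class `hmm_fit`: `spec` (fitted matrices),
#'   `loglik_trace` (one value per iteration, nondecreasing), and
#'   `iterations`.
#' @examples
#' pr <- hmm_spec(matrix(c(.8, .1, .1, .2, .7, .1, .1, .2, .7), 3,
#'                       byrow = TRUE),
#'                diag(3) * 0.94 + 0.02)
#' fit <- baum_welch(pr, "1111123")
#' @export
baum_welch <- function(prior, obs, tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(prior, "hmm_spec"))
  obs <- parse_seqobs(obs)
  if (!length(obs)) stop("empty observation window")
  M <- ncol(prior$emission)
  if (any(obs < 1 | obs > M))
    stop("observation symbol outside the emission alphabet (1..", M, ")")
  A <- prior$transition; B <- prior$emission; p0 <- prior$initial
  N <- nrow(A); Tn <- length(obs)
  trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  spec <- prior
  repeat {
    iter <- iter + 1L
    fb <- forward_backward(spec, obs)
    trace <- c(trace, fb$loglik)
    gamma <- fb$alpha * fb$beta
    gamma <- sweep(gamma, 2, colSums(gamma), "/")
    if (Tn > 1) {
      xi_sum <- matrix(0, N, N)
      A <- spec$transition; B <- spec$emission
      for (t in seq_len(Tn - 1)) {
        xi <- A * (fb$alpha[, t] %o% (B[, obs[t + 1]] * fb$beta[, t + 1]))
        xi_sum <- xi_sum + xi / sum(xi)
      }
      A_new <- regularize_rows(xi_sum)
    } else {
      A_new <- spec$transition
    }
    B_new <- matrix(0, N, ncol(spec$emission))
    for (k in seq_len(ncol(B_new)))
      B_new[, k] <- rowSums(gamma[, obs == k, drop = FALSE])
    B_new <- regularize_rows(B_new)
    p0_new <- gamma[, 1]
    spec <- hmm_spec(A_new, B_new, p0_new,
                     hidden_states = prior$hidden_states,
                     observed_symbols = prior$observed_symbols)
    if (fb$loglik - ll_old < tol || iter >= max_iter) break
    ll_old <- fb$loglik
  }
  structure(list(spec = spec, loglik_trace = trace, iterations = iter,
                 window = obs_window(obs,
                                     capacity = max(10L, length(obs)))),
            class = "hmm_fit")
}

regularize_rows <- function(m, eps = 1e-8) {
  zero <- rowSums(m) < eps
  if (any(zero)) m[zero, ] <- eps
  m / rowSums(m)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Baum-Welch fit:", x$iterations, "iterations, log-likelihood",
      sprintf("%.4f", utils::tail(x$loglik_trace, 1)), "\n")
  print(x$spec)
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Left fixed point `pi %*% P = pi` with `sum(pi) = 1`: the steady-state
#' occupation of every state after an unbounded number of transitions.
#' The reachable recurrent support is located by power iteration from the
#' initial distribution (so reducible chains return the fixed point of the
#' recurrent class their initial mass reaches), then the fixed point is
#' solved exactly on that support.
#'
#' @param transition row-stochastic matrix.
#' @param initial initial distribution; defaults to uniform.
#' @return Probability vector with fixed-point residual at machine
#'   precision for irreducible chains.
#' @export
stationary <- function(transition, initial = NULL) {
  P <- as.matrix(transition)
  check_stochastic(P, "transition")
  n <- nrow(P)
  mu <- if (is.null(initial)) rep(1 / n, n) else initial / sum(initial)
  tail_avg <- rep(0, n)
  n_iter <- 3000L; tail_from <- n_iter - 20L
  for (k in seq_len(n_iter)) {
    mu <- drop(mu %*% P)
    if (k > tail_from) tail_avg <- tail_avg + mu
  }
  tail_avg <- tail_avg / (n_iter - tail_from)
  supp <- which(tail_avg > 1e-10)
  Ps <- P[supp, supp, drop = FALSE]
  Ps <- Ps / rowSums(Ps)
  m <- length(supp)
  A <- rbind(t(Ps) - diag(m), rep(1, m))
  x <- tryCatch(qr.solve(A, c(rep(0, m), 1)),
                error = function(e) tail_avg[supp] / sum(tail_avg[supp]))
  if (any(!is.finite(x)) || any(x < -1e-9))
    x <- tail_avg[supp] / sum(tail_avg[supp])
  pi <- rep(0, n)
  pi[supp] <- x / sum(x)
  stats::setNames(pi, rownames(P))
}

#' Expected state visits over a finite horizon
#'
#' Expected occupancy of every state over transition steps 1..`horizon`:
#' the initial distribution is propagated through the transition matrix
#' and the per-step distributions are summed, so the entries always sum
#' to `horizon`.
#'
#' @param transition row-stochastic matrix.
#' @param initial initial distribution; defaults to uniform.
#' @param horizon number of steps (default 10, the observation-window
#'   length).
#' @return Numeric vector of expected visit counts.
#' @export
expected_visits <- function(transition, initial = NULL, horizon = 10) {
  P <- as.matrix(transition)
  check_stochastic(P, "transition")
  stopifnot(horizon >= 1)
  n <- nrow(P)
  mu <- if (is.null(initial)) rep(1 / n, n) else initial / sum(initial)
  visits <- rep(0, n)
  for (k in seq_len(horizon)) {
    mu <- drop(mu %*% P)
    visits <- visits + mu
  }
  stats::setNames(visits, rownames(P))
}

#' Mean first-passage times to a target state
#'
#' Solves `m_i = 1 + sum_{k != j} p_ik m_k` for the expected number of
#' steps to first reach target state `j` from every other state. States
#' from which the target is unreachable are returned as `NA` (flagged in
#' the `"unreachable"` attribute); states that can fall into a region
#' from which the target is unreachable have infinite expectation and are
#' returned as `Inf`.
#'
#' @param transition row-stochastic matrix.
#' @param target target state index (or row label).
#' @return Numeric vector of mean passage steps (the target's own entry is
#'   0), with attribute `unreachable`.
#' @export
first_passage <- function(transition, target) {
  P <- as.matrix(transition)
  check_stochastic(P, "transition")
  n <- nrow(P)
  if (is.character(target)) target <- match(target, rownames(P))
  stopifnot(target >= 1, target <= n)
  adj <- P > 0
  # states from which the target is reachable: reverse BFS from target
  reach <- rep(FALSE, n); reach[target] <- TRUE
  repeat {
    new <- reach | apply(adj[, reach, drop = FALSE], 1, any)
    if (identical(new, reach)) break
    reach <- new
  }
  # states with a path into the unreachable region have infinite mean
  bad <- !reach
  divergent <- rep(FALSE, n)
  if (any(bad)) {
    divergent <- bad
    repeat {
      new <- divergent | apply(adj[, divergent, drop = FALSE], 1, any)
      new[target] <- FALSE
      if (identical(new, divergent)) break
      divergent <- new
    }
    divergent <- divergent & reach
  }
  solve_set <- setdiff(which(reach & !divergent), target)
  m <- rep(NA_real_, n)
  m[target] <- 0
  m[divergent] <- Inf
  if (length(solve_set)) {
    Q <- P[solve_set, solve_set, drop = FALSE]
    m[solve_set] <- drop(solve(diag(length(solve_set)) - Q,
                                rep(1, length(solve_set))))
  }
  out <- stats::setNames(m, rownames(P))
  attr(out, "unreachable") <- !reach
  out
}

#' Chain summary of a fitted HMM
#'
#' Bundles the steady-state occupations, the expected visits over the
#' observation window, and the mean first-passage times to the most
#' critical hidden state (the last one, e.g. the last mitigative barrier
#' or the fatality end state).
#'
#' @param fit an `hmm_fit` (or an `hmm_spec`).
#' @param horizon visit horizon (default 10).
#' @param target target state for first passage; defaults to the last
#'   hidden state.
#' @return List with elements `stationary`, `expected_visits`,
#'   `first_passage`, of class `src_chain_summary`.
#' @export
chain_summary <- function(fit, horizon = 10, target = NULL) {
  spec <- if (inherits(fit, "hmm_fit")) fit$spec else fit
  stopifnot(inherits(spec, "hmm_spec"))
  if (is.null(target)) target <- length(spec$hidden_states)
  structure(list(
    stationary = stationary(spec$transition, spec$initial),
    expected_visits = expected_visits(spec$transition, spec$initial,
                                      horizon),
    first_passage = first_passage(spec$transition, target),
    target = spec$hidden_states[target]
  ), class = "src_chain_summary")
}

#' @export
print.src_chain_summary <- function(x, ...) {
  cat("steady-state occupations:\n")
  print(round(x$stationary, 3))
  cat("expected visits over the window:\n")
  print(round(x$expected_visits, 2))
  cat("mean first passage to", x$target, ":\n")
  print(round(x$first_passage, 1))
  invisible(x)
}

#' Recurrent HMM update
#'
#' The fitted posterior matrices become the prior for the next fit, and
#' the FIFO window shifts by the newly observed symbol.
#'
#' @param fit an `hmm_fit`.
#' @param new_symbol observed symbol index (1-based).
#' @return List with `prior` (an `hmm_spec`) and `window` (the shifted
#'   `obs_window`).
#' @export
recurrent_hmm_update <- function(fit, new_symbol) {
  stopifnot(inherits(fit, "hmm_fit"))
  M <- ncol(fit$spec$emission)
  new_symbol <- as.integer(new_symbol)
  if (new_symbol < 1 || new_symbol > M)
    stop("symbol outside the emission alphabet (1..", M, ")")
  list(prior = fit$spec, window = push_obs(fit$window, new_symbol))
}
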