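# shared fixture builders; everything is generated in code

worked_counts <- c(0L, 0L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 0L)

# random row-stochastic matrix via normalized uniforms, entries bounded
# away from zero so chains stay irreducible
rand_stochastic <- function(n, m = n, min_p = 0.02) {
  x <- matrix(stats::runif(n * m, min = min_p), n, m)
  x / rowSums(x)
}

rand_hmm_spec <- function(n_hidden = 3, n_symbols = 4) {
  hmm_spec(rand_stochastic(n_hidden), rand_stochastic(n_hidden, n_symbols))
}

# a well-separated 3-state truth for recovery experiments
recovery_truth <- function() {
  A <- matrix(c(0.80, 0.15, 0.05,
                0.10, 0.80, 0.10,
                0.05, 0.15, 0.80), 3, byrow = TRUE)
  B <- matrix(c(0.85, 0.10, 0.05,
                0.10, 0.85, 0.05,
                0.05, 0.10, 0.85), 3, byrow = TRUE)
  hmm_spec(A, B, initial = c(1, 0, 0) * 0 + 1/3)
}

# perturb a stochastic matrix and renormalize
perturb_stochastic <- function(m, amount = 0.1) {
  p <- abs(m + matrix(stats::runif(length(m), -amount, amount), nrow(m)))
  p / rowSums(p)
}

# vectorised Monte-Carlo mean hitting time oracle, independent of the
# linear-system solver
mc_first_passage <- function(P, from, target, nrep = 1e4, seed = 1,
                             max_steps = 1e5) {
  set.seed(seed)
  cum <- t(apply(P, 1, cumsum))
  state <- rep(from, nrep)
  steps <- rep(0L, nrep)
  active <- state != target
  steps[!active] <- 0L
  it <- 0L
  while (any(active) && it < max_steps) {
    it <- it + 1L
    idx <- which(active)
    u <- stats::runif(length(idx))
    nxt <- max.col(cum[state[idx], , drop = FALSE] - u >= 0,
                   ties.method = "first")
    steps[idx] <- steps[idx] + 1L
    state[idx] <- nxt
    active[idx] <- nxt != target
  }
  mean(steps)
}
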