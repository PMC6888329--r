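---
title: "Statistical risk control: models, charts and barrier analysis"
author: "srcontrol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical risk control: models, charts and barrier analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcontrol)
```

## The surveillance problem

Occupational accidents are rare, but their precursors are not: sensor and
equipment failures, lapses in job or safety self-control and supervision,
and failed tests of mitigative systems are observable well before anyone is
hurt. `srcontrol` treats these precursors as the data of a surveillance
problem. A workplace is described as a bow-tie: initiation causes (basic
equipment failures `ba`, human errors `ha`, and hard-to-predict potential
causes `pot`) strike preventive barriers before an accident event and
ordered mitigative barriers after it, with `n` mitigative barriers bounding
`n + 1` injury end states (no injury when the first barrier acts, the worst
outcome when all fail). Observation proceeds on a fixed grid of time
intervals; each interval contributes a count $y_i$ of causes and barrier
incidences.

The monitored quantity is the rate $\lambda$ of precursor events per
interval. Three components track it:

1. **Bayesian updating** of $\lambda$ from the counts (or from the waiting
   times between events) under five likelihood/prior pairs;
2. a **control chart** on $\lambda$ with center line and $\pm k\sigma$
   limits, flagging intervals whose observations leave the limits;
3. a **hidden Markov model** of the mitigative barriers (or of the end
   states), refitted over a rolling window of categorical observations.

## The five rate models

All models instantiate $f(\lambda \mid \mathrm{data}) \propto
g(\mathrm{data} \mid \lambda)\, f(\lambda)$.

**Poisson–gamma** (counts). With a $\mathrm{gamma}(\alpha, \beta)$ prior
and total count $s = \sum y_i$ over $N_t$ intervals the posterior is
$\mathrm{gamma}(\alpha + s,\; \beta + N_t)$, so mean and sd are exact:
$\lambda_{post} = (\alpha+s)/(\beta+N_t)$,
$\sigma_{post} = \sqrt{\alpha+s}/(\beta+N_t)$. Sequential updating —
posterior of one interval as prior of the next — is identical to the single
cumulative update; the chart exploits this.

**Exponential–gamma** (waiting times $t$ between events). The kernel is
$\lambda^{\alpha} e^{-\lambda(\beta + t)}$, again conjugate:
$\mathrm{gamma}(\alpha + 1, \beta + t)$. The closed form is kept attached to
the log-kernel as the oracle against which the sampler is validated.

**Weibull–gamma** adds the fatigue parameter $c$ (Weibull shape):
$(\lambda)^{\alpha-1} e^{-\lambda\beta} \lambda^{c}
e^{-(\lambda t)^{c}}$. $c > 1$ models an increasing failure-rate function
(fatigue accumulating between events), $c = 1$ recovers the
exponential–gamma kernel exactly, $0 < c < 1$ a decreasing one. The package
default $c = 1.5$ is the conservative increasing-rate choice.

**Exponential–normal** and **Poisson–normal** replace the gamma prior with
a normal density centered at the running parameter value $\mu$ with spread
$\sigma$, truncated to $\lambda > 0$ because every likelihood lives on the
positive half-line. These pairs are not conjugate and are always sampled.
The published form of the Poisson–normal kernel is ambiguous about which
symbol is the count and which the exposure; `poisson_normal_logpost()`
defaults to count-over-exposure semantics and offers `literal = TRUE` to
swap the binding — the kernel value is unchanged, only the argument roles
differ, and no validated quantity depends on the choice.

The prior spread for the normal models is not dictated by the reference
case, which only fixes the 0.05 prior mean. The package's worked examples
use $\sigma = 0.05$, i.e. a coefficient of variation of 1 — the same
weakly-informative strength as the $\mathrm{gamma}(0.5, 10)$ prior used by
the gamma-family models at that target.

## The sampler

`metropolis_hastings()` is a random-walk sampler on $\lambda$ with a
symmetric Gaussian proposal reflected at zero; reflection keeps the
proposal symmetric, so acceptance depends on the target alone. The
protocol is 4500 draws per cycle with the first 500 discarded, repeated
over 10 independent cycles whose retained draws are pooled into the
posterior mean, sd and 5–95% interval. "Cycles" are independent replicate
chains (all started from the posterior mode, each with a seed derived
deterministically from the master seed) because a single acceptance rate
and interval are reported per update.

The proposal scale starts from a Laplace (curvature-at-mode) estimate and
is tuned by `tune_proposal()` on pilot chains of a quarter length:
doubling/halving until the 48–68% acceptance band is bracketed, then
bisection in log scale. The band is a quality indicator, not a constraint
— a final run outside it warns rather than fails. ARs observed on the
worked case sit in the mid-band (50–66%).

## Chart construction and flagging

`build_chart()` supports four modes. *Recurrent* modes thread each
interval's posterior into the next interval's prior (for sampled posteriors
the gamma prior is moment-matched from the pooled mean and sd); *direct*
modes refit from the accumulated raw data under the original prior.
*Mean-prior* variants hold the center line at the stated target rate (0 for
a zero-accident target, 0.05 for one event in twenty intervals);
*mean-posterior* variants move the center with $\lambda_{post}$. Limits are
$\mathrm{center} \pm k\,\sigma_{post}$ with the lower limit floored at 0;
the default $k = 1$ is deliberately restrictive so that deviations surface
well before an accident.

Two series are carried per interval: the posterior mean, and the
*event-based observed rate* — at an interval with $y_i > 0$ incidences,
$y_i$ divided by the intervals elapsed since the previous event (carried
forward between events for plotting). Because the target rate is near zero
and the limits are short, both series share the same limits.

**Flagging.** A flag is raised only when a new observation arrives: at an
event interval the observed rate is compared against the limits, and
equality after display rounding (2 dp) is reported as `at_limit`, distinct
from strict `out_of_limits`. This is the reading under which the reference
case behaves as published: at the first incidence (interval 4,
$\lambda_{post} = \sigma_{post} = 0.25$, target 0) the observed 0.25 sits
exactly on the UCL, the later incidences (observed 0.33 and 1) are out of
limits, and the quiet intervals in between raise nothing. Monitoring the
posterior mean itself would instead flag every interval after the first
event marginally (for $\alpha + s > 1$ the gamma mean always slightly
exceeds its sd), and would *miss* interval 4 under the waiting-time models,
whose posterior means (≈ 0.11–0.24) stay inside their limits while the
observation does not. The posterior mean, sd and 5–95% interval are
exported alongside and drive nothing.

For the direct modes at intervals before any data, $\sigma$ is seeded from
the prior.

```{r}
fx <- worked_case_fixture()
ch <- build_chart(fx$counts, "poisson", gamma_prior(0.001, 0.001))
subset(ch$points, flag != "in_control",
       select = c(interval, posterior_mean, posterior_sd, observed_rate,
                  ucl, flag))
```

## Hidden-Markov barrier analysis

Mode A hides the mitigative barriers (SF1..SFn) and observes the end
states (V1..Vn+1); mode B hides the end states and observes the active
barrier. One engine serves both — only the label bindings differ.
Observations are compact digit strings (`"1111112311"`) held in a FIFO
window of ten: each new symbol enters, the oldest leaves. Ten observations
is the window length at which refitted matrices were found representative.

`baum_welch()` is standard scaled EM: forward–backward statistics
re-estimate the transition and emission matrices until the log-likelihood
gains less than `tol` (default 1e-6) or `max_iter` (500) is hit. Rows that
collapse to zero are regularized by adding 1e-8 and renormalizing so every
fitted matrix remains row-stochastic and usable as the next recurrent
prior (`recurrent_hmm_update()` hands the posterior on and shifts the
window). Short ten-symbol windows can and do drive entries to the
0/1 boundary — EM may produce absorbing states from little data; that is a
property of the method, not a defect, and the regularization keeps the
matrices proper.

Chain summaries are computed from the fitted transition matrix alone:

- `stationary()` — steady-state occupations, found by power iteration from
  the initial distribution to identify the reachable recurrent support,
  then an exact linear solve on that support (fixed-point residual at
  machine precision; reducible chains return the class their initial mass
  reaches, and in the degenerate case of mass split across several
  recurrent classes the iterative estimate is returned).
- `expected_visits()` — expected occupancy over the 10-step window,
  defined as the sum of the propagated state distribution over steps
  1..horizon (it always sums to the horizon). The window-occupancy
  definition is used because it is well-defined from the fitted matrices
  alone.
- `first_passage()` — mean steps $m_i$ to first reach the most critical
  state, solving $m_i = 1 + \sum_{k \ne j} p_{ik} m_k$; states from which
  the target is unreachable are flagged `NA`, and states that can fall
  into a region that never reaches the target are `Inf`.

On the reference window `1111112311` with a plausible diagonally-dominant
prior, the fitted chain's occupations land near the empirical symbol
frequencies (80/10/10) and the first passage from SF1 to SF3 is about 8
intervals:

```{r}
pr <- hmm_spec(matrix(c(.8, .15, .05, .1, .7, .2, .05, .15, .8), 3,
                      byrow = TRUE),
               matrix(c(.8, .1, .05, .05, .1, .7, .1, .1,
                        .05, .1, .7, .15), 3, byrow = TRUE),
               hidden_states = c("SF1", "SF2", "SF3"),
               observed_symbols = c("V1", "V2", "V3", "V4"))
fit <- baum_welch(pr, fx$seqobs[["end_states"]])
chain_summary(fit)
```

The exact published posterior matrices, occupations and passage values
cannot be regenerated because the prior matrices behind them appear only
in figures whose numbers are not printed; they serve here as qualitative
plausibility checks while the solvers themselves are validated against
closed forms and Monte-Carlo oracles.

## What the synthetic generator does and does not emulate

`simulate_incidences()` draws per-interval counts from a Poisson process,
or from exponential/Weibull renewal processes simulated in continuous time
and binned to the interval grid (the Weibull scale is set so the mean
waiting time is $1/\lambda$). `simulate_hmm()` samples a hidden path and
emitted symbols from known matrices. Both take explicit seeds and never
touch global state beyond R's seeded RNG.

The generator reproduces the *statistical* structure of the observation
process — known constant rates, renewal waiting times, Markov barrier
dynamics — but none of the operational structure of a real plant:
no shift patterns, no cause clustering after maintenance, no
rate drift, no misclassification of observed end states. Passing tests
therefore demonstrate that the estimators recover the parameters of the
assumed processes, not that those processes describe any particular
workplace.

## Numerical and design choices

- Display precision is 2 dp (3 dp below 0.1); all internal computation is
  full precision. The `at_limit` flag uses the 2-dp display rounding.
- Waiting times are whole observation intervals since the previous event
  (since interval 0 for the first), e.g. one incidence three intervals
  after the last gives $t = 3$ and an observed rate of 0.33. An interval
  with $y_i > 1$ events is treated as $y_i$ waiting times of $w/y_i$.
- The sampler's per-cycle and per-interval seeds derive from one master
  seed; identical configurations regenerate byte-identical outputs.
- Validation problem sizes: sampler-oracle checks pool 40 000 draws;
  rate-recovery uses horizons of $10^4$–$10^5$ with the bias taken as an
  average over 30 replicates; HMM recovery fits 20 replicate sequences of
  500 symbols; first-passage solvers are checked against $10^5$
  Monte-Carlo hitting-time runs.

## Limitations

- The chart assumes a constant true rate within the monitored horizon;
  drifting rates are only tracked through the recurrent prior.
- The waiting-time models condition on events only: quiet intervals carry
  no censoring information into those posteriors.
- Ten-symbol HMM windows estimate many parameters from little data; the
  recurrent prior is what stabilizes the sequence of fits, and summaries
  from a single window should be read as plausibility statements.
- The bow-tie is an observation-routing structure here; no fault-tree or
  event-tree probability propagation is performed.
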