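#' Simulate a precursor incidence stream
#'
#' Generates per-interval incidence counts from a process with known rate,
#' for end-to-end testing of the inference and chart stages. The Poisson
#' process draws counts directly per interval; the exponential and
#' Weibull processes are simulated as renewal processes in continuous
#' time (waiting times between causes) and binned onto the interval grid.
#'
#' @param process `"poisson"`, `"exponential"`, or `"weibull"`.
#' @param true_lambda events per interval, > 0.
#' @param horizon number of intervals, >= 1.
#' @param fatigue_c Weibull shape (used only for `process = "weibull"`);
#'   the Weibull scale is set so that the mean waiting time is
#'   `1 / true_lambda`.
#' @param seed integer seed; the stream is deterministic given the seed.
#' @param item_id,item_kind labels written into the observation records.
#' @return data.frame of observation records (`interval`, `item_id`,
#'   `item_kind`), one row per event, with attribute `counts` (the
#'   per-interval count vector).
#' @examples
#' obs <- simulate_incidences("poisson", 0.05, horizon = 100, seed = 7)
#' sum(attr(obs, "counts")) / 100  # empirical rate near 0.05
#' @export
simulate_incidences <- function(process = c("poisson", "exponential",
                                            "weibull"),
                                true_lambda, horizon, fatigue_c = 1.5,
                                seed = 1L, item_id = "sim_ic",
                                item_kind = "ic") {
  process <- match.arg(process)
  stopifnot(true_lambda > 0, horizon >= 1)
  set.seed(seed)
  counts <- switch(
    process,
    poisson = stats::rpois(horizon, true_lambda),
    exponential = renewal_counts(function(n) stats::rexp(n, true_lambda),
                                 horizon, true_lambda),
    weibull = {
      # scale chosen so the mean waiting time is 1/lambda
      scl <- 1 / (true_lambda * gamma(1 + 1 / fatigue_c))
      renewal_counts(function(n) stats::rweibull(n, shape = fatigue_c,
                                                 scale = scl),
                     horizon, true_lambda)
    }
  )
  intervals <- rep(seq_len(horizon), counts)
  records <- data.frame(interval = intervals,
                        item_id = rep(item_id, length(intervals)),
                        item_kind = rep(item_kind, length(intervals)),
                        stringsAsFactors = FALSE)
  attr(records, "counts") <- as.integer(counts)
  records
}

# bin renewal-process event times onto 1..horizon
renewal_counts <- function(rwait, horizon, lambda) {
  expected <- max(32, ceiling(horizon * lambda * 1.5))
  times <- numeric(0)
  t_end <- 0
  while (t_end <= horizon) {
    w <- rwait(expected)
    times <- c(times, t_end + cumsum(w))
    t_end <- times[length(times)]
  }
  times <- times[times <= horizon]
  tabulate(ceiling(times), nbins = horizon)
}

#' Simulate an observation sequence from a known HMM
#'
#' Standard generative sampling: a hidden path from the transition matrix
#' and one emitted symbol per step. Both the observable sequence (for
#' fitting) and the hidden path (for recovery scoring) are returned.
#'
#' @param spec an [hmm_spec()] with the true matrices.
#' @param length_out sequence length.
#' @param seed integer seed.
#' @return List with integer vectors `symbols` and `path`.
#' @export
simulate_hmm <- function(spec, length_out, seed = 1L) {
  stopifnot(inherits(spec, "hmm_spec"), length_out >= 1)
  set.seed(seed)
  n <- nrow(spec$transition)
  m <- ncol(spec$emission)
  path <- integer(length_out)
  symbols <- integer(length_out)
  state <- sample.int(n, 1, prob = spec$initial)
  for (t in seq_len(length_out)) {
    path[t] <- state
    symbols[t] <- sample.int(m, 1, prob = spec$emission[state, ])
    state <- sample.int(n, 1, prob = spec$transition[state, ])
  }
  list(symbols = symbols, path = path)
}

#' Worked-case fixture: MDF-plant first-level scenario
#'
#' The in-package reference case: a fiberboard manufacturing plant
#' monitored at 10 intervals, with three ordered mitigative safety
#' barriers (general workplace protections; safety controls, alarms and
#' shutdowns; emergency power, fire systems and rescue), four injury end
#' states (no injury, minor, serious, fatality), four preventive
#' job/safety control and supervision barriers plus the general automated
#' barrier, and three observed incidences: a sensor failure in the first
#' mitigative barrier's sub-function at interval 4, a job self-control
#' failure at interval 7, and a failed rescue test in the third barrier
#' at interval 8.
#'
#' @return List with `scenario` (an `src_scenario`, first-level analysis),
#'   `records` (observation data.frame), `counts` (the incidence series
#'   `0,0,0,1,0,0,1,1,0,0`), and `seqobs` (the two compact categorical
#'   observation strings: end states observed for hidden barriers, and
#'   active barriers observed for hidden end states).
#' @export
worked_case_fixture <- function() {
  barriers <- data.frame(
    id = c("IS_JSC", "IS_JSU", "IS_SSC", "IS_SSU", "SF_ISg",
           "SF1", "SF2", "SF3"),
    role = c(rep("preventive", 5), rep("mitigative", 3)),
    order = c(rep(NA_integer_, 5), 1L, 2L, 3L),
    stringsAsFactors = FALSE
  )
  subfunctions <- data.frame(
    id = c("SF11", "SF21", "SF31", "SF12"),
    barrier = c("SF1", "SF2", "SF3", "SF1"),
    level = c(1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  causes <- data.frame(
    id = c("ic_sensor", "ic_jsc", "ic_rescue", "ic_pot"),
    cause_class = c("ba", "ha", "ba", "pot"),
    description = c(
      "pressure sensor failure in the hot pressing section",
      "job self-control failure in the hot pressing process",
      "failed rescue simulation test",
      "unexpected process deviation"
    ),
    attached_to = c("SF11", "IS_JSC", "SF31", "SF_ISg"),
    stringsAsFactors = FALSE
  )
  end_states <- data.frame(
    id = c("V1", "V2", "V3", "V4"),
    severity_rank = 1:4,
    label = c("no injury", "minor injury", "serious injury", "fatality"),
    stringsAsFactors = FALSE
  )
  scenario <- src_scenario(causes, barriers, subfunctions, end_states,
                           analysis_level = "first_level")
  records <- data.frame(
    interval = c(4L, 7L, 8L),
    item_id = c("ic_sensor", "ic_jsc", "ic_rescue"),
    item_kind = c("ic", "ic", "ic"),
    end_state = c("", "", ""),
    stringsAsFactors = FALSE
  )
  list(
    scenario = scenario,
    records = records,
    counts = counts_per_interval(scenario, records, horizon = 10),
    seqobs = c(end_states = "1111112311", barriers = "1111112211")
  )
}
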