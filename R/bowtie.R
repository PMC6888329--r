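#' Construct a bow-tie risk scenario
#'
#' A scenario describes the observation-routing structure used for
#' occupational-accident surveillance: a catalogue of initiation causes
#' (basic equipment/control failures, human errors, and hard-to-predict
#' potential causes), preventive and mitigative safety barriers with their
#' sub-functions, and the ordered injury end states produced by the
#' mitigative barrier cascade.
#'
#' For `n` mitigative barriers there must be exactly `n + 1` end states:
#' the cascade is bounded by "no injury" when the first mitigative barrier
#' acts correctly and by the worst outcome when every barrier fails.
#'
#' @param causes data.frame with columns `id`, `cause_class` (one of
#'   `"ba"`, `"ha"`, `"pot"`), `description`, `attached_to` (a declared
#'   barrier or sub-function id).
#' @param barriers data.frame with columns `id`, `role` (`"preventive"` or
#'   `"mitigative"`), `order` (integer rank for mitigative barriers,
#'   `NA` for preventive ones).
#' @param subfunctions data.frame with columns `id`, `barrier` (owning
#'   barrier id), `level` (integer depth, 1 = first level).
#' @param end_states data.frame with columns `id`, `severity_rank`
#'   (1 = no injury, n+1 = worst), `label`.
#' @param analysis_level `"full"` to count every declared item,
#'   `"first_level"` to keep only items attached at the first level of the
#'   barrier sub-function tree.
#' @return An object of class `src_scenario`.
#' @seealso [validate_scenario()], [end_state_from_outcomes()],
#'   [counts_per_interval()], [worked_case_fixture()]
#' @export
src_scenario <- function(causes, barriers, subfunctions, end_states,
                         analysis_level = c("full", "first_level")) {
  analysis_level <- match.arg(analysis_level)
  s <- structure(
    list(
      causes = as.data.frame(causes, stringsAsFactors = FALSE),
      barriers = as.data.frame(barriers, stringsAsFactors = FALSE),
      subfunctions = as.data.frame(subfunctions, stringsAsFactors = FALSE),
      end_states = as.data.frame(end_states, stringsAsFactors = FALSE),
      analysis_level = analysis_level
    ),
    class = "src_scenario"
  )
  s
}

#' @export
print.src_scenario <- function(x, ...) {
  n_mit <- sum(x$barriers$role == "mitigative")
  cat("Bow-tie scenario:",
      nrow(x$causes), "initiation causes,",
      nrow(x$barriers), "barriers (", n_mit, "mitigative ),",
      nrow(x$end_states), "end states; analysis level:",
      x$analysis_level, "\n")
  invisible(x)
}

# all declared item ids with kind and first-level status
scenario_items <- function(s) {
  first_level_sf <- s$subfunctions$id[s$subfunctions$level == 1]
  items <- rbind(
    data.frame(id = s$barriers$id, kind = "barrier",
               first_level = TRUE, stringsAsFactors = FALSE),
    data.frame(id = s$subfunctions$id, kind = "subfunction",
               first_level = s$subfunctions$level == 1,
               stringsAsFactors = FALSE)
  )
  cause_fl <- s$causes$attached_to %in% c(s$barriers$id, first_level_sf)
  rbind(items,
        data.frame(id = s$causes$id, kind = "ic",
                   first_level = cause_fl, stringsAsFactors = FALSE))
}

#' Validate the structural invariants of a scenario
#'
#' Checks id uniqueness, cause classes, attachment resolution, the ordering
#' of mitigative barriers, and the end-state count/rank invariants. Problems
#' are returned, not raised, so a configuration front-end can report all of
#' them at once.
#'
#' @param s an `src_scenario`.
#' @return Character vector of violation messages; `character(0)` when the
#'   scenario is well-formed.
#' @export
validate_scenario <- function(s) {
  stopifnot(inherits(s, "src_scenario"))
  v <- character(0)
  all_ids <- c(s$causes$id, s$barriers$id, s$subfunctions$id, s$end_states$id)
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup))
    v <- c(v, paste0("duplicated id(s): ", paste(dup, collapse = ", ")))

  bad_class <- setdiff(unique(s$causes$cause_class), c("ba", "ha", "pot"))
  if (length(bad_class))
    v <- c(v, paste0("unknown cause_class: ", paste(bad_class, collapse = ", ")))

  targets <- c(s$barriers$id, s$subfunctions$id)
  dangling <- s$causes$id[!(s$causes$attached_to %in% targets)]
  for (id in dangling)
    v <- c(v, paste0("cause '", id, "' attached to undeclared item '",
                     s$causes$attached_to[s$causes$id == id], "'"))

  orphan_sf <- s$subfunctions$id[!(s$subfunctions$barrier %in% s$barriers$id)]
  for (id in orphan_sf)
    v <- c(v, paste0("sub-function '", id, "' belongs to undeclared barrier"))

  mit <- s$barriers[s$barriers$role == "mitigative", , drop = FALSE]
  n <- nrow(mit)
  ord <- sort(mit$order)
  if (n > 0 && !identical(as.integer(ord), seq_len(n)))
    v <- c(v, "mitigative barrier order ranks are not consecutive from 1")
  if (any(!is.na(s$barriers$order[s$barriers$role == "preventive"])))
    v <- c(v, "preventive barriers must not carry an order rank")

  if (nrow(s$end_states) != n + 1)
    v <- c(v, paste0("end-state count ", nrow(s$end_states),
                     " != n+1 = ", n + 1))
  if (nrow(s$end_states) == n + 1 &&
      !identical(sort(as.integer(s$end_states$severity_rank)),
                 seq_len(n + 1)))
    v <- c(v, "end-state severity ranks are not a permutation of 1..n+1")
  v
}

#' Map mitigative-barrier outcomes to an injury end state
#'
#' The mitigative barriers act in cascade: each barrier is called on only if
#' every barrier before it has failed. The resulting end state is therefore
#' determined by the number of leading failures before the first barrier
#' that works: zero leading failures give the no-injury state (rank 1), and
#' failure of every barrier gives the worst state (rank n+1). Outcome bits
#' after the first success are ignored.
#'
#' @param s an `src_scenario`.
#' @param outcomes integer/logical vector of length n (number of mitigative
#'   barriers), ordered by barrier rank; 0 = barrier acts correctly,
#'   1 = barrier fails.
#' @return One row of `s$end_states` (the reached end state).
#' @examples
#' fx <- worked_case_fixture()
#' end_state_from_outcomes(fx$scenario, c(0, 0, 0))$id  # "V1", no injury
#' end_state_from_outcomes(fx$scenario, c(1, 1, 1))$id  # "V4", fatality
#' @export
end_state_from_outcomes <- function(s, outcomes) {
  stopifnot(inherits(s, "src_scenario"))
  n <- sum(s$barriers$role == "mitigative")
  outcomes <- as.integer(outcomes)
  if (length(outcomes) != n)
    stop("outcome vector has length ", length(outcomes),
         " but the scenario declares ", n, " mitigative barriers")
  if (any(!outcomes %in% c(0L, 1L)))
    stop("outcomes must be 0 (correct/active) or 1 (fail)")
  first_success <- match(0L, outcomes)
  rank <- if (is.na(first_success)) n + 1L else first_success
  s$end_states[s$end_states$severity_rank == rank, , drop = FALSE]
}

#' Per-interval incidence counts from an observation log
#'
#' Sums the initiation-cause and barrier incidences recorded in each time
#' interval into the count vector `y` used by the rate models. When the
#' scenario's `analysis_level` is `"first_level"`, only barriers,
#' first-level sub-functions, and causes attached at the first level are
#' counted.
#'
#' @param s an `src_scenario`.
#' @param records data.frame of observation records with columns `interval`
#'   (integer >= 1) and `item_id` (a declared cause/barrier/sub-function id).
#' @param horizon number of intervals; records beyond it are an error.
#' @return Integer vector `y` of length `horizon`; intervals without
#'   records are 0.
#' @export
counts_per_interval <- function(s, records, horizon) {
  stopifnot(inherits(s, "src_scenario"), horizon >= 1)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0)
    return(integer(horizon))
  if (any(records$interval < 1) || any(records$interval != round(records$interval)))
    stop("record intervals must be positive integers")
  if (any(records$interval > horizon))
    stop("record interval beyond horizon ", horizon)
  items <- scenario_items(s)
  unknown <- setdiff(records$item_id, items$id)
  if (length(unknown))
    stop("record references unknown id(s): ", paste(unknown, collapse = ", "))
  if (s$analysis_level == "first_level") {
    keep_ids <- items$id[items$first_level]
    records <- records[records$item_id %in% keep_ids, , drop = FALSE]
  }
  tabulate(records$interval, nbins = horizon)
}
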