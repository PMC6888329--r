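#' Read and write observation logs
#'
#' Observation logs are delimited text with a header and columns
#' `interval`, `item_id`, `item_kind`, and optionally `end_state` (blank
#' allowed). Malformed rows are rejected with the offending line number;
#' nothing is silently coerced.
#'
#' @param path file path.
#' @return data.frame of observation records.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  required <- c("interval", "item_id", "item_kind")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("observation file misses column(s): ",
         paste(missing_cols, collapse = ", "))
  iv <- suppressWarnings(as.numeric(df$interval))
  bad <- which(is.na(iv) | iv < 1 | iv != round(iv))
  if (length(bad))
    stop("malformed interval at line ", bad[1] + 1, ": '",
         df$interval[bad[1]], "'")
  known_kinds <- c("ic", "barrier", "subfunction", "end_state")
  bad_kind <- which(!(df$item_kind %in% known_kinds))
  if (length(bad_kind))
    stop("unknown item_kind at line ", bad_kind[1] + 1, ": '",
         df$item_kind[bad_kind[1]], "'")
  out <- data.frame(interval = as.integer(iv),
                    item_id = df$item_id,
                    item_kind = df$item_kind,
                    end_state = if ("end_state" %in% names(df))
                      df$end_state else rep("", nrow(df)),
                    stringsAsFactors = FALSE)
  out
}

#' @rdname read_observations
#' @param records observation data.frame.
#' @export
write_observations <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"end_state" %in% names(records)) records$end_state <- ""
  utils::write.csv(records[, c("interval", "item_id", "item_kind",
                               "end_state")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a scenario as structured text
#'
#' Scenarios round-trip through a YAML tree with `causes`, `barriers`,
#' `subfunctions`, `end_states` and `analysis_level` blocks.
#'
#' @param path file path.
#' @return An `src_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  to_df <- function(lst) do.call(rbind, lapply(lst, function(r)
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)))
  s <- src_scenario(
    causes = to_df(raw$causes),
    barriers = to_df(raw$barriers),
    subfunctions = to_df(raw$subfunctions),
    end_states = to_df(raw$end_states),
    analysis_level = raw$analysis_level %||% "full"
  )
  s
}

#' @rdname read_scenario
#' @param s an `src_scenario`.
#' @export
write_scenario <- function(s, path) {
  stopifnot(inherits(s, "src_scenario"))
  df_to_list <- function(df) lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    lapply(row, function(v) if (is.na(v)) NULL else unname(v))
  })
  yaml::write_yaml(list(
    analysis_level = s$analysis_level,
    causes = df_to_list(s$causes),
    barriers = df_to_list(s$barriers),
    subfunctions = df_to_list(s$subfunctions),
    end_states = df_to_list(s$end_states)
  ), path)
  invisible(path)
}

#' Read and write labeled probability matrices
#'
#' Matrices travel as CSV with row labels in the first column and symbol
#' labels in the header.
#'
#' @param path file path.
#' @return Numeric matrix with dimnames.
#' @export
read_hmm_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_hmm_matrix
#' @param m matrix.
#' @export
write_hmm_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Run the full surveillance pipeline from a configuration
#'
#' Reads the scenario and observation log, derives the per-interval
#' counts, builds the configured control chart, writes the chart table, a
#' flag summary and a PDF rendering into the output directory, and — when
#' an `hmm` block is present — fits the barrier/end-state HMM and writes
#' the fitted matrices plus the chain summary. Every output is
#' regenerable byte-identically from the configuration and seed.
#'
#' @param config path to a YAML configuration file, or an equivalent
#'   named list. Blocks: `scenario`, `observations`, `model`, `prior`
#'   (`family`, `alpha`/`beta` or `mu`/`sigma`), `chart` (`mode`,
#'   `k_sigma`, `target_mean`, `horizon`), `sampler` (`n_draws`,
#'   `burn_in`, `cycles`, `seed`), optional `fatigue_c`, optional `hmm`
#'   (`transition`, `emission`, `seq`), and `out_dir`.
#' @param quiet suppress per-interval logging.
#' @return Invisibly, a list with the built `chart`, the optional
#'   `hmm_fit` and `chain_summary`, and `out_of_limits` (the flagged
#'   interval indices).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (block in c("scenario", "observations", "model", "prior", "chart"))
    if (is.null(config[[block]]))
      stop("configuration misses the '", block, "' block")
  scenario <- read_scenario(config$scenario)
  v <- validate_scenario(scenario)
  if (length(v)) stop("invalid scenario: ", paste(v, collapse = "; "))
  records <- read_observations(config$observations)

  pr_cfg <- config$prior
  prior <- switch(pr_cfg$family,
                  gamma = gamma_prior(pr_cfg$alpha, pr_cfg$beta),
                  normal = normal_prior(pr_cfg$mu, pr_cfg$sigma),
                  stop("unknown prior family '", pr_cfg$family, "'"))
  ch_cfg <- config$chart
  chart_conf <- chart_config(mode = ch_cfg$mode %||% "recurrent_mean_prior",
                             k_sigma = ch_cfg$k_sigma %||% 1,
                             target_mean = ch_cfg$target_mean %||% 0,
                             horizon = ch_cfg$horizon)
  sm_cfg <- config$sampler %||% list()
  sampler_conf <- sampler_config(
    n_draws = sm_cfg$n_draws %||% 4500,
    burn_in = sm_cfg$burn_in %||% 500,
    cycles = sm_cfg$cycles %||% 10,
    seed = sm_cfg$seed %||% 1L
  )
  counts <- counts_per_interval(scenario, records, chart_conf$horizon)
  chart <- build_chart(counts, model = config$model, prior = prior,
                       chart = chart_conf, sampler = sampler_conf,
                       fatigue_c = config$fatigue_c %||% 1.5)
  if (!quiet)
    for (i in seq_len(nrow(chart$points)))
      message(sprintf("interval %d: lambda_post = %s, sigma_post = %s [%s]",
                      i, format_rate(chart$points$posterior_mean[i]),
                      format_rate(chart$points$posterior_sd[i]),
                      chart$points$flag[i]))

  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  export_chart(chart, file.path(out_dir, "chart.csv"),
               plot_path = file.path(out_dir, "chart.pdf"))
  flagged <- chart$points$interval[chart$points$flag != "in_control"]
  writeLines(c("interval,flag",
               sprintf("%d,%s", chart$points$interval,
                       chart$points$flag)),
             file.path(out_dir, "flags.csv"))

  hmm_fit <- NULL; summ <- NULL
  if (!is.null(config$hmm)) {
    tr <- read_hmm_matrix(config$hmm$transition)
    em <- read_hmm_matrix(config$hmm$emission)
    prior_spec <- hmm_spec(tr, em)
    hmm_fit <- baum_welch(prior_spec, config$hmm$seq)
    summ <- chain_summary(hmm_fit)
    write_hmm_matrix(hmm_fit$spec$transition,
                     file.path(out_dir, "posterior_transition.csv"))
    write_hmm_matrix(hmm_fit$spec$emission,
                     file.path(out_dir, "posterior_emission.csv"))
    utils::write.csv(
      data.frame(state = names(summ$stationary),
                 stationary = summ$stationary,
                 expected_visits = summ$expected_visits,
                 first_passage = as.numeric(summ$first_passage)),
      file.path(out_dir, "chain_summary.csv"), row.names = FALSE,
      quote = FALSE)
  }
  invisible(list(chart = chart, hmm_fit = hmm_fit, chain_summary = summ,
                 out_of_limits = flagged))
}
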