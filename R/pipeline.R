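# End-to-end orchestration: simulate -> synchronization analysis -> motor
# metrics -> monitoring scores -> group summaries, with a JSON run manifest
# recording every parameter actually used.

#' Default analysis parameters
#'
#' The numeric constants of the analysis chain: acquisition latency 1 ms,
#' matching window +/-120 ms, peak threshold 40% of the maximal peak,
#' minimal inter-peak distance 100 ms, envelope smoothing window 11 ms,
#' inter-repetition pause 400 ms, first analysed repetition 3.
#'
#' @return Named list of defaults.
#' @export
default_parameters <- function() {
  list(latency_ms = 1,
       window_ms = 120,
       rel_threshold = 0.40,
       min_distance_ms = 100,
       envelope_window_ms = 11,
       pause_ms = 400,
       first_analyzed_repetition = 3,
       bandwidth_ms = 20,
       dedup_ms = 1,
       response_window_start_ms = 150)
}

#' Run the full simulated-study pipeline
#'
#' Generates a cohort, stimuli, synchronization and monitoring data from
#' the given seed, runs every analysis stage, and writes the stage outputs
#' plus a reproducibility manifest to `out_dir`. Re-running with the same
#' config and seed reproduces all outputs.
#'
#' @param config A YAML file path or a list with optional elements `seed`
#'   (default 1), `parameters` (overrides for [default_parameters()]),
#'   `cohort` / `stimulus` (argument lists for [cohort_spec()] /
#'   [stimulus_spec()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_parameter("config must be a list or a YAML path")
  known <- c("seed", "parameters", "cohort", "stimulus")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    stop_parameter(sprintf("unknown config key(s): %s",
                           paste(unknown, collapse = ", ")))
  }
  pars <- utils::modifyList(default_parameters(), config$parameters %||% list())
  bad <- names(pars)[vapply(pars, function(v) !is.numeric(v) || v < 0,
                            logical(1))]
  if (length(bad) > 0L) {
    stop_parameter(sprintf("config error at parameters.%s: must be a non-negative number",
                           bad[1L]))
  }
  seed <- config$seed %||% 1L
  cohort <- do.call(cohort_spec, config$cohort %||% list())
  stim_spec <- do.call(stimulus_spec, config$stimulus %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stimuli <- generate_stimuli(stim_spec, seed = seed)
  participants <- generate_participants(cohort, seed = seed)
  sim <- generate_taps(participants, stimuli, cohort, seed = seed)
  mon <- generate_monitoring(participants, cohort, seed = seed)

  sms_results <- analyze_sms(sim$taps, stimuli,
                             latency_ms = pars$latency_ms,
                             bandwidth = pars$bandwidth_ms,
                             rel_threshold = pars$rel_threshold,
                             min_distance_ms = pars$min_distance_ms,
                             window_ms = pars$window_ms)
  rates <- do.call(rbind, lapply(split(sms_results,
                                       sms_results$participant_id),
                                 function(d) {
    strat <- sms_rate(d, by = "weight")
    data.frame(participant_id = d$participant_id[1L],
               sms_rate = sms_rate(d),
               rate_strong = strat$rate[strat$stratum == "strong"],
               rate_weak = strat$rate[strat$stratum == "weak"],
               stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL

  scored <- do.call(rbind, lapply(split(mon$trials,
                                        mon$trials$participant_id),
                                  function(tr) {
    pid <- tr$participant_id[1L]
    tp <- mon$taps[mon$taps$participant_id == pid, , drop = FALSE]
    score_monitoring(tp, tr,
                     response_window_start_ms = pars$response_window_start_ms)
  }))
  rownames(scored) <- NULL
  dprimes <- do.call(rbind, lapply(split(scored, scored$participant_id),
                                   function(tr) {
    data.frame(participant_id = tr$participant_id[1L],
               group = tr$group[1L],
               dprime = dprime(sdt_counts(tr)),
               stringsAsFactors = FALSE)
  }))
  rownames(dprimes) <- NULL

  paths <- list(
    participants = file.path(out_dir, "participants.csv"),
    taps = file.path(out_dir, "taps.csv"),
    sms_results = file.path(out_dir, "sms_results.csv"),
    sms_rates = file.path(out_dir, "sms_rates.csv"),
    monitoring = file.path(out_dir, "monitoring_scored.csv"),
    dprime = file.path(out_dir, "dprime.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_results(participants, paths$participants)
  write_results(sim$taps, paths$taps)
  write_results(sms_results, paths$sms_results)
  write_results(rates, paths$sms_rates)
  write_results(scored, paths$monitoring)
  write_results(dprimes, paths$dprime)

  data_files <- setdiff(names(paths), "manifest")
  manifest <- list(
    package = "speechsync",
    version = as.character(utils::packageVersion("speechsync")),
    seed = seed,
    parameters = pars,
    n_participants = nrow(participants),
    n_sentences = length(stimuli),
    checksums = lapply(paths[data_files],
                       function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(participants = participants, stimuli = stimuli,
                 sms_results = sms_results, sms_rates = rates,
                 monitoring = scored, dprime = dprimes,
                 parameters = pars, paths = paths))
}
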