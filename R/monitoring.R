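# Phoneme-monitoring scoring: classify taps into hits / misses / false
# alarms / correct rejections, and summarize per-participant sensitivity
# as signal-detection d-prime.

#' Score phoneme-monitoring trials against a tap log
#'
#' Trials present a nonsense string; on target trials the listener must tap
#' as soon as the monitored phoneme occurs. For a target trial the first
#' tap from `response_window_start_ms` after the target onset up to trial
#' end is a hit (RT = tap minus target onset); no qualifying tap is a miss.
#' For a distractor trial any tap during the trial is a false alarm,
#' otherwise a correct rejection.
#'
#' @param taps Tap table; rows with `task == "monitoring"` and matching
#'   `stimulus_id` are used, times referenced to trial onset.
#' @param trials `data.frame` with columns `stimulus_id`, `is_target`
#'   (logical), `target_onset_ms` (`NA` on distractor trials),
#'   `trial_duration_ms`; other columns (block, covariates) pass through.
#' @param response_window_start_ms Earliest plausible response latency
#'   (default 150 ms; faster taps cannot be reactions to the target).
#' @return The trials table with `response`
#'   (`hit`/`miss`/`false_alarm`/`correct_rejection`) and `rt_ms` filled.
#' @export
score_monitoring <- function(taps, trials, response_window_start_ms = 150) {
  if (any(trials$is_target & is.na(trials$target_onset_ms))) {
    stop_validation("target trials must carry a target onset")
  }
  bad <- trials$is_target &
    trials$target_onset_ms + response_window_start_ms >= trials$trial_duration_ms
  if (any(bad)) {
    stop_parameter("response window starts at or after trial end for some trial(s)")
  }
  taps <- taps[taps$task == "monitoring", , drop = FALSE]
  trials$response <- NA_character_
  trials$rt_ms <- NA_real_
  for (i in seq_len(nrow(trials))) {
    tt <- sort(taps$time_ms[taps$stimulus_id == trials$stimulus_id[i]])
    tt <- tt[tt <= trials$trial_duration_ms[i]]
    if (trials$is_target[i]) {
      lo <- trials$target_onset_ms[i] + response_window_start_ms
      qual <- tt[tt >= lo]
      if (length(qual) > 0L) {
        trials$response[i] <- "hit"
        trials$rt_ms[i] <- qual[1L] - trials$target_onset_ms[i]
      } else {
        trials$response[i] <- "miss"
      }
    } else {
      if (length(tt) > 0L) {
        trials$response[i] <- "false_alarm"
        trials$rt_ms[i] <- tt[1L]
      } else {
        trials$response[i] <- "correct_rejection"
      }
    }
  }
  trials
}

#' Signal-detection counts from scored trials
#'
#' @param trials A [score_monitoring()] result.
#' @return List with `n_hits`, `n_misses`, `n_fas`, `n_crs`.
#' @export
sdt_counts <- function(trials) {
  list(n_hits = sum(trials$response == "hit"),
       n_misses = sum(trials$response == "miss"),
       n_fas = sum(trials$response == "false_alarm"),
       n_crs = sum(trials$response == "correct_rejection"))
}

#' Sensitivity d-prime
#'
#' `d' = z(H) - z(F)` with extreme rates corrected: under the default
#' `"2N"` convention a rate of 0 becomes `1/(2N)` and a rate of 1 becomes
#' `1 - 1/(2N)` for the relevant trial count N; the `"loglinear"`
#' convention adds 0.5 to each count and 1 to each N before forming rates.
#' Responses to all target phonemes are pooled.
#'
#' @param counts An [sdt_counts()] list (or any list with those fields).
#' @param correction `"2N"` (default) or `"loglinear"`.
#' @return d-prime, or `NA` with a classed warning if either trial class is
#'   empty.
#' @export
dprime <- function(counts, correction = c("2N", "loglinear")) {
  correction <- match.arg(correction)
  n_t <- counts$n_hits + counts$n_misses
  n_d <- counts$n_fas + counts$n_crs
  if (n_t < 1L || n_d < 1L) {
    insufficient_data("d-prime needs at least 1 target and 1 distractor trial")
    return(NA_real_)
  }
  if (correction == "loglinear") {
    h <- (counts$n_hits + 0.5) / (n_t + 1)
    f <- (counts$n_fas + 0.5) / (n_d + 1)
  } else {
    h <- counts$n_hits / n_t
    f <- counts$n_fas / n_d
    if (h == 0) h <- 1 / (2 * n_t)
    if (h == 1) h <- 1 - 1 / (2 * n_t)
    if (f == 0) f <- 1 / (2 * n_d)
    if (f == 1) f <- 1 - 1 / (2 * n_d)
  }
  stats::qnorm(h) - stats::qnorm(f)
}

#' Reaction-time table for mixed-model analysis
#'
#' Keeps hit trials only and adds the natural-log RT column the RT models
#' are fitted on; covariate columns pass through (missing values stay
#' missing).
#'
#' @param trials A [score_monitoring()] result.
#' @return `data.frame` of hit trials with `log_rt`; zero hits yield an
#'   empty table with the same schema.
#' @export
rt_table <- function(trials) {
  hits <- trials[!is.na(trials$response) & trials$response == "hit", ,
                 drop = FALSE]
  hits$log_rt <- log(hits$rt_ms)
  rownames(hits) <- NULL
  hits
}
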