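# Core computation: looped-sentence tap streams -> per-syllable
# synchronization likelihood and asynchrony, via kernel density estimation,
# relative-threshold peak detection and windowed matching to nucleus onsets.

#' Correct tap times for acquisition latency
#'
#' Subtracts the fixed hardware delay of the tap-detection chain (default
#' 1 ms, a microcontroller's transmission latency) from every tap time,
#' clipping at 0.
#'
#' @param taps Numeric vector of times, or a tap table with a `time_ms`
#'   column.
#' @param delay_ms Non-negative delay in ms (default 1).
#' @return Object of the same shape with shifted times.
#' @export
correct_latency <- function(taps, delay_ms = 1) {
  assert_number(delay_ms, "delay_ms", lower = 0)
  if (is.data.frame(taps)) {
    taps$time_ms <- pmax(taps$time_ms - delay_ms, 0)
    taps
  } else {
    pmax(taps - delay_ms, 0)
  }
}

#' Fold loop-referenced taps onto sentence-relative time
#'
#' The sentence loop has period `duration_ms + pause_ms`. Each tap is
#' assigned to a repetition and mapped to its offset within that
#' repetition. Taps from repetitions before `first_analyzed_repetition`
#' (participants start tapping at the third repetition) or after the last
#' repetition are discarded. Offsets falling in the silent pause are kept
#' only if within `window_ms` of a sentence edge: up to
#' `duration_ms + window_ms` they stay positive (lag on the final nucleus),
#' and within `window_ms` before the next repetition they wrap to negative
#' offsets (anticipation of the sentence-initial nucleus, counted toward
#' the following repetition); pause taps in between are discarded.
#'
#' @param times_ms Numeric tap times referenced to loop onset.
#' @param stimulus A [sentence_stimulus()].
#' @param window_ms Matching window (default 120 ms), which bounds how far
#'   into the pause a tap can still be anchored to a nucleus.
#' @return Object of class `folded_taps`: list with `offsets_ms`,
#'   `n_repetitions_used`, `n_discarded`.
#' @export
fold_taps <- function(times_ms, stimulus, window_ms = 120) {
  stopifnot(inherits(stimulus, "sentence_stimulus"))
  period <- stimulus$duration_ms + stimulus$pause_ms
  rep_idx <- floor(times_ms / period) + 1
  offset <- times_ms - (rep_idx - 1) * period
  # taps late in a pause anticipate the next repetition's first nucleus
  wrap <- offset >= period - window_ms
  rep_idx[wrap] <- rep_idx[wrap] + 1
  offset[wrap] <- offset[wrap] - period
  in_reps <- rep_idx >= stimulus$first_analyzed_repetition &
    rep_idx <= stimulus$n_repetitions
  in_range <- offset <= stimulus$duration_ms + window_ms
  keep <- in_reps & in_range
  n_late <- sum(rep_idx > stimulus$n_repetitions)
  if (n_late > 0L) {
    warning(sprintf("%d tap(s) beyond repetition %d discarded", n_late,
                    stimulus$n_repetitions))
  }
  structure(list(
    offsets_ms = sort(offset[keep]),
    n_repetitions_used =
      stimulus$n_repetitions - stimulus$first_analyzed_repetition + 1L,
    n_discarded = sum(!keep)
  ), class = "folded_taps")
}

#' Gaussian kernel density of folded tap offsets
#'
#' Exact Gaussian kernel sum evaluated on a 1 ms grid spanning
#' `[-window_ms, duration_ms + window_ms]`, normalized to integrate to 1
#' over the grid. The density summarizes where taps accumulated across
#' repetitions; its peaks are the participant's synchronization anchors.
#'
#' @param folded A [fold_taps()] result or a numeric vector of offsets.
#' @param duration_ms Sentence duration (grid upper anchor).
#' @param bandwidth Kernel bandwidth in ms (default 20, the timescale of
#'   motor timing jitter in finger tapping, which resolves tap clusters at
#'   adjacent nuclei), or `"silverman"` for the rule-of-thumb. The global
#'   rule-of-thumb is computed on the whole multimodal offset distribution
#'   and typically oversmooths to the point where neighbouring anchors
#'   merge, so it is not the default.
#' @param window_ms Grid margin beyond the sentence edges (default 120 ms).
#' @param grid_step_ms Grid resolution (default 1 ms).
#' @return Object of class `tap_density` (list with `grid_ms`, `density`,
#'   `bandwidth_ms`, `n_taps`), or `NULL` with a classed warning when fewer
#'   than 2 offsets are available (no density can be formed; the sentence
#'   then contributes zero synchronized syllables).
#' @export
estimate_density <- function(folded, duration_ms, bandwidth = 20,
                             window_ms = 120, grid_step_ms = 1) {
  offsets <- if (inherits(folded, "folded_taps")) folded$offsets_ms else folded
  if (length(offsets) < 2L) {
    insufficient_data("fewer than 2 tap offsets: no density estimated")
    return(NULL)
  }
  if (identical(bandwidth, "silverman")) {
    bw <- stats::bw.nrd0(offsets)
    if (!is.finite(bw) || bw <= 0) bw <- grid_step_ms  # degenerate spread
  } else {
    assert_number(bandwidth, "bandwidth", lower = 1e-9)
    bw <- bandwidth
  }
  grid <- seq(-window_ms, duration_ms + window_ms, by = grid_step_ms)
  dens <- rowMeans(stats::dnorm(outer(grid, offsets, "-"), sd = bw))
  total <- sum(dens) * grid_step_ms
  if (total <= 0) {
    insufficient_data("degenerate density (all mass outside the grid)")
    return(NULL)
  }
  structure(list(grid_ms = grid, density = dens / total, bandwidth_ms = bw,
                 n_taps = length(offsets)),
            class = "tap_density")
}

#' Detect synchronization peaks in a tap density
#'
#' Candidate peaks are strict local maxima of the density. Candidates lower
#' than `rel_threshold` times the highest candidate are dropped; the
#' remainder are kept by greedy suppression in order of descending height
#' (ties to the earlier time): a candidate closer than `min_distance_ms` to
#' an already retained peak is discarded.
#'
#' @param density A [estimate_density()] result (or `NULL`, which yields an
#'   empty peak set).
#' @param rel_threshold Height threshold relative to the maximal peak
#'   (default 0.40).
#' @param min_distance_ms Minimal distance between retained peaks
#'   (default 100 ms).
#' @return `data.frame` with `time_ms` and `height`, ordered by time.
#' @export
find_peaks <- function(density, rel_threshold = 0.40, min_distance_ms = 100) {
  if (is.null(density)) {
    return(data.frame(time_ms = numeric(0), height = numeric(0)))
  }
  stopifnot(inherits(density, "tap_density"))
  assert_number(rel_threshold, "rel_threshold", lower = 0, upper = 1)
  assert_number(min_distance_ms, "min_distance_ms", lower = 0)
  y <- density$density
  n <- length(y)
  if (n < 3L) return(data.frame(time_ms = numeric(0), height = numeric(0)))
  is_max <- y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]
  cand <- which(is_max) + 1L
  if (length(cand) == 0L) {
    return(data.frame(time_ms = numeric(0), height = numeric(0)))
  }
  t <- density$grid_ms[cand]
  h <- y[cand]
  keep <- h >= rel_threshold * max(h)
  t <- t[keep]; h <- h[keep]
  ord <- order(-h, t)
  sel_t <- numeric(0)
  sel_h <- numeric(0)
  for (i in ord) {
    if (all(abs(t[i] - sel_t) >= min_distance_ms)) {
      sel_t <- c(sel_t, t[i])
      sel_h <- c(sel_h, h[i])
    }
  }
  o <- order(sel_t)
  data.frame(time_ms = sel_t[o], height = sel_h[o])
}

#' Match density peaks to syllable-nucleus onsets
#'
#' One-to-one greedy matching by ascending |peak time - nucleus onset|:
#' each peak anchors at most one nucleus and vice versa, and only pairs
#' within `window_ms` qualify. A nucleus with a matched peak counts as
#' synchronized; its signed asynchrony is peak time minus nucleus onset
#' (negative = anticipation) and the absolute asynchrony its magnitude.
#'
#' @param peaks A [find_peaks()] result.
#' @param stimulus A [sentence_stimulus()].
#' @param window_ms Matching window around each nucleus onset
#'   (default 120 ms).
#' @return `data.frame` with one row per syllable: annotation columns plus
#'   `synchronized`, `signed_asynchrony_ms`, `absolute_asynchrony_ms`
#'   (asynchronies `NA` for unsynchronized syllables).
#' @export
match_peaks_to_nuclei <- function(peaks, stimulus, window_ms = 120) {
  stopifnot(inherits(stimulus, "sentence_stimulus"))
  syl <- stimulus$syllables
  n_s <- nrow(syl)
  out <- data.frame(stimulus_id = stimulus$stimulus_id,
                    label = syl$label, weight = syl$weight,
                    nucleus_type = syl$nucleus_type,
                    nucleus_onset_ms = syl$nucleus_onset_ms,
                    synchronized = FALSE,
                    signed_asynchrony_ms = NA_real_,
                    absolute_asynchrony_ms = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || n_s == 0L) return(out)
  pairs <- expand.grid(peak = seq_len(nrow(peaks)), syl = seq_len(n_s))
  pairs$dist <- abs(peaks$time_ms[pairs$peak] -
                      syl$nucleus_onset_ms[pairs$syl])
  pairs <- pairs[pairs$dist <= window_ms, , drop = FALSE]
  # ties in distance resolved toward the earlier nucleus, then earlier peak
  pairs <- pairs[order(pairs$dist, pairs$syl, pairs$peak), , drop = FALSE]
  peak_used <- logical(nrow(peaks))
  syl_used <- logical(n_s)
  for (k in seq_len(nrow(pairs))) {
    p <- pairs$peak[k]; s <- pairs$syl[k]
    if (peak_used[p] || syl_used[s]) next
    peak_used[p] <- TRUE
    syl_used[s] <- TRUE
    out$synchronized[s] <- TRUE
    out$signed_asynchrony_ms[s] <- peaks$time_ms[p] - syl$nucleus_onset_ms[s]
    out$absolute_asynchrony_ms[s] <- abs(out$signed_asynchrony_ms[s])
  }
  out
}

#' Synchronization rate
#'
#' The proportion of syllable nuclei a participant synchronized with,
#' optionally stratified by an annotation column (e.g. metrical `weight` or
#' `nucleus_type`).
#'
#' @param results A [match_peaks_to_nuclei()]-style table (possibly row-bound
#'   over sentences).
#' @param by Optional stratifier column name.
#' @return Unstratified: a single proportion. Stratified: `data.frame` with
#'   the stratum, `n_syllables`, `n_synchronized`, `rate` (`NA` rate for an
#'   empty stratum never occurs since strata come from the data).
#' @export
sms_rate <- function(results, by = NULL) {
  if (nrow(results) == 0L) {
    insufficient_data("no syllable results: SMS rate undefined")
    return(NA_real_)
  }
  if (is.null(by)) {
    return(mean(results$synchronized))
  }
  agg <- stats::aggregate(results$synchronized,
                          by = list(stratum = results[[by]]),
                          FUN = function(z) c(n = length(z), k = sum(z)))
  data.frame(stratum = agg$stratum,
             n_syllables = agg$x[, "n"],
             n_synchronized = agg$x[, "k"],
             rate = agg$x[, "k"] / agg$x[, "n"],
             stringsAsFactors = FALSE)
}

#' Full per-participant synchronization analysis
#'
#' Runs the complete reduction for every participant x sentence series of
#' an `sms`-task tap log: latency correction, folding across analysed
#' repetitions, kernel density estimation, peak detection and matching to
#' nucleus onsets.
#'
#' @param taps Tap table (see [read_tap_log()]); only `task == "sms"` rows
#'   are used.
#' @param stimuli Named list of [sentence_stimulus()] objects keyed by
#'   `stimulus_id`.
#' @param latency_ms Hardware latency subtracted up front (default 1 ms).
#' @param bandwidth,rel_threshold,min_distance_ms,window_ms Stage parameters
#'   (see the respective stage functions).
#' @return `data.frame`, one row per participant x syllable, with columns
#'   of [match_peaks_to_nuclei()] plus `participant_id`.
#' @export
analyze_sms <- function(taps, stimuli, latency_ms = 1,
                        bandwidth = 20, rel_threshold = 0.40,
                        min_distance_ms = 100, window_ms = 120) {
  taps <- taps[taps$task == "sms", , drop = FALSE]
  taps <- correct_latency(taps, latency_ms)
  res <- list()
  for (pid in unique(taps$participant_id)) {
    for (sid in names(stimuli)) {
      stim <- stimuli[[sid]]
      tt <- taps$time_ms[taps$participant_id == pid &
                           taps$stimulus_id == sid]
      folded <- fold_taps(tt, stim, window_ms = window_ms)
      dens <- withCallingHandlers(
        estimate_density(folded, stim$duration_ms, bandwidth = bandwidth,
                         window_ms = window_ms),
        speechsync_insufficient_data = function(w) invokeRestart("muffleWarning")
      )
      peaks <- find_peaks(dens, rel_threshold = rel_threshold,
                          min_distance_ms = min_distance_ms)
      matched <- match_peaks_to_nuclei(peaks, stim, window_ms = window_ms)
      matched$participant_id <- pid
      res[[length(res) + 1L]] <- matched
    }
  }
  if (length(res) == 0L) {
    return(data.frame(participant_id = character(0),
                      stimulus_id = character(0), label = character(0),
                      weight = character(0), nucleus_type = character(0),
                      nucleus_onset_ms = numeric(0),
                      synchronized = logical(0),
                      signed_asynchrony_ms = numeric(0),
                      absolute_asynchrony_ms = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("participant_id", setdiff(names(out), "participant_id"))]
}
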