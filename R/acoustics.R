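# Acoustic-prosodic covariates measured per syllable: amplitude-envelope
# rise-time, nucleus duration, and sentence-normalized intensity.

#' Smoothed amplitude envelope of a waveform
#'
#' The envelope is built from the absolute signal amplitude: the waveform is
#' cut into successive frames of `window_ms`, the local |amplitude| maximum
#' of each frame becomes a knot, and a cubic spline through the knots is
#' evaluated on a 1 ms grid (negative spline excursions are clipped to 0).
#'
#' @param samples Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param window_ms Smoothing window (default 11 ms).
#' @return Object of class `envelope`: list with `times_ms`, `values`,
#'   `window_ms`.
#' @export
compute_envelope <- function(samples, sample_rate, window_ms = 11) {
  assert_number(sample_rate, "sample_rate", lower = 1)
  win_n <- round(window_ms * sample_rate / 1000)
  if (win_n < 2) stop_parameter("smoothing window must span at least 2 samples")
  if (length(samples) <= win_n) {
    stop_parameter("waveform must be longer than the smoothing window")
  }
  a <- abs(samples)
  n_frames <- ceiling(length(a) / win_n)
  idx <- rep(seq_len(n_frames), each = win_n, length.out = length(a))
  knot_i <- vapply(split(seq_along(a), idx), function(ii) ii[which.max(a[ii])],
                   integer(1))
  knot_t <- (knot_i - 1) / sample_rate * 1000
  knot_v <- a[knot_i]
  dur_ms <- (length(a) - 1) / sample_rate * 1000
  grid <- seq(0, floor(dur_ms), by = 1)
  if (all(knot_v == 0)) {
    values <- rep(0, length(grid))
  } else {
    values <- stats::spline(knot_t, knot_v, xout = grid, method = "fmm")$y
    values <- pmax(values, 0)
  }
  structure(list(times_ms = grid, values = values, window_ms = window_ms),
            class = "envelope")
}

#' Envelope rise-time around a syllable onset
#'
#' Rise-time is the interval between a local envelope minimum just before
#' the syllable onset and the first local maximum the envelope reaches
#' afterwards within the syllable. The minimum is the lowest envelope value
#' in `[onset - search_before_ms, onset + search_after_ms]` (ties resolved
#' to the latest time, i.e. the foot of the rise); the maximum is the first
#' point after it where the envelope stops increasing, searched up to
#' `syllable_end_ms` (a still-rising envelope at the boundary takes the
#' boundary value).
#'
#' @param envelope An [compute_envelope()] result.
#' @param syllable_onset_ms Anchor time in ms.
#' @param syllable_end_ms End of the max-search region.
#' @param search_before_ms,search_after_ms Extent of the min-search window
#'   around the onset (defaults 50 and 10 ms).
#' @return Rise-time in ms, or `NA` (with a classed warning) when the
#'   envelope is flat around the onset and no distinct rise exists.
#' @export
measure_rise_time <- function(envelope, syllable_onset_ms, syllable_end_ms,
                              search_before_ms = 50, search_after_ms = 10) {
  stopifnot(inherits(envelope, "envelope"))
  t <- envelope$times_ms
  v <- envelope$values
  lo <- max(min(t), syllable_onset_ms - search_before_ms)
  hi <- min(max(t), syllable_onset_ms + search_after_ms)
  end <- min(max(t), syllable_end_ms)
  win <- which(t >= lo & t <= hi)
  if (length(win) == 0L || end <= lo) {
    stop_parameter("rise-time search window lies outside the envelope domain")
  }
  vmin <- min(v[win])
  region_max <- max(v[t >= lo & t <= end])
  # the foot of the rise: latest point still within 1% of the local range
  # above the minimum (the smoothed envelope leaves the floor gradually)
  foot_tol <- max(0.01 * (region_max - vmin), 1e-12)
  i_min <- win[max(which(v[win] <= vmin + foot_tol))]
  search <- which(t > t[i_min] & t <= end)
  if (length(search) < 2L) {
    return(undefined_feature("no room for a rise after the envelope minimum"))
  }
  scale <- max(v[c(i_min, search)])
  height_tol <- 1e-6 * max(scale, .Machine$double.eps)
  if (max(v[search]) - vmin <= height_tol) {
    return(undefined_feature("flat envelope around onset: rise-time undefined"))
  }
  i_max <- NA_integer_
  for (j in search) {
    if (v[j] <= vmin + height_tol) next
    nxt <- if (j < max(search)) v[j + 1L] else -Inf
    if (nxt <= v[j]) { i_max <- j; break }
  }
  if (is.na(i_max)) i_max <- search[which.max(v[search])]
  t[i_max] - t[i_min]
}

#' Nucleus duration of an annotated syllable
#'
#' @param syllable One row of a [syllable_annotations()] table (or a list
#'   with `nucleus_onset_ms` and `nucleus_end_ms`).
#' @return Duration in ms.
#' @export
measure_duration <- function(syllable) {
  d <- syllable$nucleus_end_ms - syllable$nucleus_onset_ms
  if (any(d <= 0)) stop_validation("nucleus duration must be positive")
  d
}

#' Sentence-normalized segment intensity
#'
#' Intensity is frame-wise RMS level expressed in dB re `db_ref`, averaged
#' over 10 ms frames; the feature is the segment mean divided by the
#' sentence mean (so values sit near 1, louder-than-average segments above
#' it). A linear-RMS ratio is available via `scale = "linear"`.
#'
#' @param samples,sample_rate Waveform and rate (Hz).
#' @param segment_ms Length-2 numeric, segment interval in ms.
#' @param sentence_ms Length-2 numeric, sentence interval in ms (defaults to
#'   the whole waveform).
#' @param frame_ms RMS frame length (default 10 ms).
#' @param scale `"dB"` (default) or `"linear"`.
#' @param db_ref Reference amplitude for dB conversion (default 2e-5, the
#'   auditory convention; waveforms on [-1, 1] then land in the usual
#'   60-90 dB speech range).
#' @return Relative intensity (> 0), or `NA` with a classed warning for a
#'   digitally silent segment.
#' @export
measure_relative_intensity <- function(samples, sample_rate, segment_ms,
                                       sentence_ms = NULL, frame_ms = 10,
                                       scale = c("dB", "linear"),
                                       db_ref = 2e-5) {
  scale <- match.arg(scale)
  dur_ms <- length(samples) / sample_rate * 1000
  sentence_ms <- sentence_ms %||% c(0, dur_ms)
  if (segment_ms[1] < sentence_ms[1] || segment_ms[2] > sentence_ms[2]) {
    stop_parameter("segment must lie within the sentence interval")
  }
  seg <- mean_level(samples, sample_rate, segment_ms, frame_ms, scale, db_ref)
  sen <- mean_level(samples, sample_rate, sentence_ms, frame_ms, scale, db_ref)
  if (is.na(seg) || is.na(sen)) {
    return(undefined_feature("digitally silent segment: intensity undefined"))
  }
  seg / sen
}

mean_level <- function(samples, sample_rate, interval_ms, frame_ms, scale,
                       db_ref) {
  i0 <- max(1L, floor(interval_ms[1] * sample_rate / 1000) + 1L)
  i1 <- min(length(samples), ceiling(interval_ms[2] * sample_rate / 1000))
  if (i1 <= i0) return(NA_real_)
  x <- samples[i0:i1]
  frame_n <- max(1L, round(frame_ms * sample_rate / 1000))
  n_frames <- max(1L, length(x) %/% frame_n)
  idx <- pmin((seq_along(x) - 1L) %/% frame_n + 1L, n_frames)
  rms <- vapply(split(x, idx), function(f) sqrt(mean(f^2)), numeric(1))
  rms <- rms[rms > 0]
  if (length(rms) == 0L) return(NA_real_)
  if (scale == "dB") mean(20 * log10(rms / db_ref)) else mean(rms)
}

#' Extract all acoustic features for a stimulus
#'
#' Computes rise-time, nucleus duration and relative intensity for every
#' syllable of a sentence from its waveform and annotation.
#'
#' @param wave List with `samples` and `sample_rate` (see [read_wav()]).
#' @param stimulus A [sentence_stimulus()].
#' @param window_ms Envelope smoothing window (default 11 ms).
#' @param rise_anchor Anchor of the rise-time search: `"syllable"` (default)
#'   or `"nucleus"` onset.
#' @param ... Passed to [measure_relative_intensity()].
#' @return `data.frame` with one row per syllable: `label`, `weight`,
#'   `nucleus_type`, `nucleus_onset_ms`, `rise_time_ms`, `duration_ms`,
#'   `relative_intensity`. Unmeasurable features are `NA`.
#' @export
extract_acoustics <- function(wave, stimulus, window_ms = 11,
                              rise_anchor = c("syllable", "nucleus"), ...) {
  stopifnot(inherits(stimulus, "sentence_stimulus"))
  rise_anchor <- match.arg(rise_anchor)
  env <- compute_envelope(wave$samples, wave$sample_rate, window_ms)
  syl <- stimulus$syllables
  anchor <- if (rise_anchor == "syllable") syl$syllable_onset_ms else syl$nucleus_onset_ms
  rise <- vapply(seq_len(nrow(syl)), function(i) {
    suppressWarnings(
      measure_rise_time(env, anchor[i], syl$nucleus_end_ms[i])
    )
  }, numeric(1))
  intensity <- vapply(seq_len(nrow(syl)), function(i) {
    suppressWarnings(
      measure_relative_intensity(wave$samples, wave$sample_rate,
                                 c(syl$nucleus_onset_ms[i],
                                   syl$nucleus_end_ms[i]),
                                 c(0, stimulus$duration_ms), ...)
    )
  }, numeric(1))
  data.frame(stimulus_id = stimulus$stimulus_id,
             label = syl$label, weight = syl$weight,
             nucleus_type = syl$nucleus_type,
             nucleus_onset_ms = syl$nucleus_onset_ms,
             rise_time_ms = rise,
             duration_ms = measure_duration(syl),
             relative_intensity = intensity,
             stringsAsFactors = FALSE)
}
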