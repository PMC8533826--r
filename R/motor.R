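# Screening-task metrics: unpaced tapping (inter-tap interval mean and CV)
# and paced tapping to an isochronous verbal prompt (signed/absolute
# asynchrony, also as proportion of the inter-onset interval).

#' Inter-tap-interval statistics for unpaced tapping
#'
#' @param times_ms Numeric tap times (ms), at least 3.
#' @return List with `mean_iti_ms`, `cv` (sample SD of the ITIs divided by
#'   their mean) and `n_itis`. With fewer than 3 taps both statistics are
#'   `NA` and a classed warning is raised.
#' @export
iti_stats <- function(times_ms) {
  times_ms <- sort(times_ms)
  if (length(times_ms) < 3L) {
    insufficient_data("at least 3 taps required for ITI statistics")
    return(list(mean_iti_ms = NA_real_, cv = NA_real_,
                n_itis = max(0L, length(times_ms) - 1L)))
  }
  iti <- diff(times_ms)
  m <- mean(iti)
  list(mean_iti_ms = m, cv = stats::sd(iti) / m, n_itis = length(iti))
}

#' Isochronous prompt onsets for a paced tapping trial
#'
#' @param ioi_ms Inter-onset interval (300 or 600 ms in the design, any
#'   positive value accepted).
#' @param n_prompts Number of prompt repetitions (default 25).
#' @param start_ms Onset of the first prompt (default 0).
#' @return Numeric vector of onsets.
#' @export
prompt_onsets <- function(ioi_ms, n_prompts = 25, start_ms = 0) {
  assert_number(ioi_ms, "ioi_ms", lower = 1e-9)
  start_ms + ioi_ms * (seq_len(n_prompts) - 1)
}

#' Paced-tapping asynchrony statistics
#'
#' Each prompt onset is matched to the nearest tap within `window_ms`
#' (default half the IOI, so windows cannot overlap), one tap per prompt.
#' Per-prompt signed asynchrony is tap minus onset; means are taken over
#' matched prompts and also expressed as proportions of the IOI.
#'
#' @param times_ms Tap times (ms).
#' @param onsets_ms Prompt onsets (see [prompt_onsets()]).
#' @param ioi_ms Inter-onset interval of the prompt sequence.
#' @param window_ms Matching window (default `ioi_ms / 2`).
#' @param min_matched Minimum number of matched prompts (default 5).
#' @return List with `ioi_ms`, `mean_signed_ms`, `mean_absolute_ms`,
#'   `signed_prop`, `absolute_prop`, `n_matched`. All statistics `NA` (with
#'   a classed warning) when fewer than `min_matched` prompts match.
#' @export
paced_asynchronies <- function(times_ms, onsets_ms, ioi_ms,
                               window_ms = ioi_ms / 2, min_matched = 5) {
  assert_number(ioi_ms, "ioi_ms", lower = 1e-9)
  times_ms <- sort(times_ms)
  signed <- rep(NA_real_, length(onsets_ms))
  taken <- logical(length(times_ms))
  if (length(times_ms) > 0L) {
    pairs <- expand.grid(tap = seq_along(times_ms),
                         prompt = seq_along(onsets_ms))
    pairs$dist <- abs(times_ms[pairs$tap] - onsets_ms[pairs$prompt])
    pairs <- pairs[pairs$dist <= window_ms, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, pairs$prompt, pairs$tap), , drop = FALSE]
    prompt_used <- logical(length(onsets_ms))
    for (k in seq_len(nrow(pairs))) {
      tp <- pairs$tap[k]; pr <- pairs$prompt[k]
      if (taken[tp] || prompt_used[pr]) next
      taken[tp] <- TRUE
      prompt_used[pr] <- TRUE
      signed[pr] <- times_ms[tp] - onsets_ms[pr]
    }
  }
  matched <- !is.na(signed)
  if (sum(matched) < min_matched) {
    insufficient_data(sprintf("only %d prompt(s) matched (need %d)",
                              sum(matched), min_matched))
    return(list(ioi_ms = ioi_ms, mean_signed_ms = NA_real_,
                mean_absolute_ms = NA_real_, signed_prop = NA_real_,
                absolute_prop = NA_real_, n_matched = sum(matched)))
  }
  ms <- mean(signed[matched])
  ma <- mean(abs(signed[matched]))
  list(ioi_ms = ioi_ms, mean_signed_ms = ms, mean_absolute_ms = ma,
       signed_prop = ms / ioi_ms, absolute_prop = ma / ioi_ms,
       n_matched = sum(matched))
}

#' Express a mean asynchrony as a proportion of the inter-onset interval
#'
#' @param mean_ms Mean (signed or absolute) asynchrony in ms.
#' @param ioi_ms Inter-onset interval in ms.
#' @return `mean_ms / ioi_ms`.
#' @export
proportion_of_ioi <- function(mean_ms, ioi_ms) {
  assert_number(ioi_ms, "ioi_ms", lower = 1e-9)
  mean_ms / ioi_ms
}
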