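rate <- 16000

tone <- function(dur_ms, amp = 1, freq = 300, rate. = rate) {
  n <- round(dur_ms / 1000 * rate.)
  amp * sin(2 * pi * freq * seq_len(n) / rate.)
}

test_that("the envelope tracks constant and modulated amplitudes", {
  x <- tone(500, amp = 0.8)
  env <- compute_envelope(x, rate)
  inner <- env$values[env$times_ms > 30 & env$times_ms < 470]
  expect_true(all(abs(inner - 0.8) < 0.05 * 0.8))

  # slow known modulator: envelope must follow it within 5% of peak
  n <- round(0.5 * rate)
  mod <- 0.5 + 0.4 * sin(2 * pi * 3 * seq_len(n) / rate)
  x <- mod * sin(2 * pi * 300 * seq_len(n) / rate)
  env <- compute_envelope(x, rate)
  keep <- env$times_ms > 30 & env$times_ms < 470
  mod_at <- 0.5 + 0.4 * sin(2 * pi * 3 * env$times_ms[keep] / 1000)
  expect_lt(max(abs(env$values[keep] - mod_at)), 0.05 * 0.9)

  expect_equal(compute_envelope(rep(0, 4000), rate)$values,
               rep(0, length(compute_envelope(rep(0, 4000), rate)$values)))
  expect_error(compute_envelope(tone(100), rate, window_ms = 0.05),
               class = "speechsync_parameter_error")
})

test_that("rise-time recovers programmed ramps and bounds step responses", {
  # 200 ms silence, then a linear 0 -> 1 ramp over 80 ms, then sustain
  n_sil <- round(0.2 * rate)
  n_ramp <- round(0.08 * rate)
  n_sus <- round(0.2 * rate)
  carrier <- sin(2 * pi * 300 * seq_len(n_sil + n_ramp + n_sus) / rate)
  amp <- c(rep(0, n_sil), seq(0, 1, length.out = n_ramp), rep(1, n_sus))
  env <- compute_envelope(amp * carrier, rate)
  rt <- measure_rise_time(env, 200, 200 + 200)
  expect_lte(abs(rt - 80), 11)

  # instantaneous step: the smoothing window bounds the measured rise
  amp_step <- c(rep(0, n_sil), rep(1, n_ramp + n_sus))
  env_step <- compute_envelope(amp_step * carrier, rate)
  rt_step <- measure_rise_time(env_step, 200, 400)
  expect_lte(rt_step, 2 * 11)

  # flat envelope: no distinct rise
  env_flat <- compute_envelope(tone(500, amp = 0.5), rate)
  expect_warning(
    rt_flat <- measure_rise_time(env_flat, 250, 450),
    class = "speechsync_undefined_feature")
  expect_true(is.na(rt_flat))
})

test_that("rise-time is invariant to amplitude scaling and sign flip", {
  n_sil <- round(0.2 * rate)
  n_ramp <- round(0.06 * rate)
  carrier <- sin(2 * pi * 300 * seq_len(n_sil + n_ramp + n_sil) / rate)
  amp <- c(rep(0, n_sil), seq(0, 1, length.out = n_ramp), rep(1, n_sil))
  x <- amp * carrier
  rt1 <- measure_rise_time(compute_envelope(x, rate), 200, 400)
  rt2 <- measure_rise_time(compute_envelope(7.3 * x, rate), 200, 400)
  rt3 <- measure_rise_time(compute_envelope(-x, rate), 200, 400)
  expect_equal(rt2, rt1)
  expect_equal(rt3, rt1)
})

test_that("rise-times are monotone in the programmed ramp duration", {
  measured <- vapply(c(30, 60, 120), function(ramp) {
    n_sil <- round(0.2 * rate)
    n_ramp <- round(ramp / 1000 * rate)
    n_sus <- round(0.25 * rate)
    carrier <- sin(2 * pi * 300 * seq_len(n_sil + n_ramp + n_sus) / rate)
    amp <- c(rep(0, n_sil), seq(0, 1, length.out = n_ramp), rep(1, n_sus))
    measure_rise_time(compute_envelope(amp * carrier, rate), 200, 450)
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("nucleus duration comes straight from the annotation", {
  expect_equal(measure_duration(list(nucleus_onset_ms = 350,
                                     nucleus_end_ms = 440)), 90)
  expect_equal(measure_duration(list(nucleus_onset_ms = 0,
                                     nucleus_end_ms = 94.39)), 94.39)
  expect_error(measure_duration(list(nucleus_onset_ms = 100,
                                     nucleus_end_ms = 100)),
               class = "speechsync_validation_error")
})

test_that("relative intensity matches an independent frame-dB computation", {
  withr::local_seed(9)
  x <- c(0.3 * rnorm(rate), 0.08 * rnorm(rate))  # loud then soft second
  ri <- measure_relative_intensity(x, rate, segment_ms = c(1000, 2000),
                                   sentence_ms = c(0, 2000))
  level <- function(seg) {
    frames <- split(seg, rep(seq_len(length(seg) %/% 160),
                             each = 160)[seq_along(seg)])
    mean(vapply(frames, function(f) 20 * log10(sqrt(mean(f^2)) / 2e-5),
                numeric(1)))
  }
  expect_equal(ri, level(x[(rate + 1):(2 * rate)]) / level(x),
               tolerance = 1e-6)
  # a segment acoustically identical to the sentence self-normalizes to 1
  expect_equal(measure_relative_intensity(x, rate, c(0, 2000), c(0, 2000)), 1)
  expect_warning(
    ri0 <- measure_relative_intensity(c(rep(0, rate), 0.1 * rnorm(rate)),
                                      rate, c(0, 900), c(0, 2000)),
    class = "speechsync_undefined_feature")
  expect_true(is.na(ri0))
})

test_that("extract_acoustics reflects programmed levels and ramps", {
  stim <- make_stimulus(onsets = c(250, 600, 950), duration = 1300)
  # syllable 2 is 6 dB below the others
  wave <- synthesize_audio(stim, ramp_ms = c(30, 50, 80),
                           levels = c(0.4, 0.2, 0.4))
  feats <- extract_acoustics(wave, stim)
  expect_equal(nrow(feats), 3L)
  expect_true(all(is.finite(feats$rise_time_ms)))
  expect_lt(feats$relative_intensity[2], feats$relative_intensity[1])
  expect_lt(feats$relative_intensity[2], feats$relative_intensity[3])
  expect_true(all(abs(feats$relative_intensity - 1) < 0.2))
})
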