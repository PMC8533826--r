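test_that("latency correction shifts and clips tap times", {
  expect_equal(correct_latency(c(101, 201), 1), c(100, 200))
  expect_equal(correct_latency(c(101, 201), 0), c(101, 201))
  expect_equal(correct_latency(0.5, 1), 0)
  df <- data.frame(time_ms = c(10, 0.2))
  expect_equal(correct_latency(df)$time_ms, c(9, 0))
})

test_that("folding keeps analysed repetitions and wraps pause taps", {
  stim <- make_stimulus(duration = 1000)  # period 1400
  period <- 1400
  f <- fold_taps(c(2 * period + 350), stim)
  expect_equal(f$offsets_ms, 350)
  expect_equal(f$n_repetitions_used, 8L)
  # repetitions 1-2 are excluded by contract
  f <- fold_taps(c(0 * period + 350, 1 * period + 350), stim)
  expect_equal(length(f$offsets_ms), 0L)
  expect_equal(f$n_discarded, 2L)
  # a tap 60 ms before repetition 4 wraps to a negative offset
  f <- fold_taps(3 * period - 60, stim)
  expect_equal(f$offsets_ms, -60)
  # mid-pause taps are discarded; late-sentence lag taps are kept
  f <- fold_taps(c(2 * period + 1200, 2 * period + 1100), stim)
  expect_equal(f$offsets_ms, 1100)
  # taps beyond the loop are discarded with a warning
  expect_warning(f <- fold_taps(11 * period + 100, stim), "beyond")
  expect_equal(length(f$offsets_ms), 0L)
})

test_that("the tap density equals a brute-force kernel sum and normalizes", {
  withr::local_seed(7)
  offsets <- c(rnorm(8, 300, 10), rnorm(8, 900, 10))
  d <- estimate_density(offsets, duration_ms = 1000, bandwidth = 15)
  expect_equal(d$density,
               oracle_kde(d$grid_ms, offsets, 15),
               tolerance = 1e-9)
  expect_equal(sum(d$density) * 1, 1, tolerance = 1e-3)
  # Silverman rule delegates to the standard rule-of-thumb
  ds <- estimate_density(offsets, 1000, bandwidth = "silverman")
  expect_equal(ds$bandwidth_ms, stats::bw.nrd0(offsets))
})

test_that("degenerate tap sets yield a point-mass mode or no density", {
  d <- estimate_density(rep(500, 16), duration_ms = 1000)
  expect_equal(d$grid_ms[which.max(d$density)], 500)
  expect_warning(d1 <- estimate_density(500, duration_ms = 1000),
                 class = "speechsync_insufficient_data")
  expect_null(d1)
  expect_equal(nrow(find_peaks(NULL)), 0L)
})

test_that("peak detection applies threshold and greedy suppression", {
  # single mode
  d <- density_with_modes(250, 1)
  expect_equal(find_peaks(d)$time_ms, 250)
  # two candidates 50 ms apart: the higher wins, the other is suppressed
  d <- density_with_modes(c(100, 150), c(1.0, 0.9))
  expect_equal(find_peaks(d)$time_ms, 100)
  # far-apart but sub-threshold candidate is dropped (0.3 < 0.4)
  d <- density_with_modes(c(100, 400), c(1.0, 0.3))
  expect_equal(find_peaks(d)$time_ms, 100)
  # both retained when far apart and above threshold
  d <- density_with_modes(c(100, 400), c(1.0, 0.5))
  expect_equal(find_peaks(d)$time_ms, c(100, 400))
})

test_that("peak-nucleus matching is one-to-one within the window", {
  stim <- make_stimulus(onsets = c(200, 500, 800))
  pk <- data.frame(time_ms = 200 + 130, height = 1)
  res <- match_peaks_to_nuclei(pk, stim)
  expect_false(any(res$synchronized))
  pk <- data.frame(time_ms = 200 - 50, height = 1)
  res <- match_peaks_to_nuclei(pk, stim)
  expect_true(res$synchronized[1])
  expect_equal(res$signed_asynchrony_ms[1], -50)
  expect_equal(res$absolute_asynchrony_ms[1], 50)
  # a single peak cannot satisfy two nuclei: nearest wins
  stim2 <- make_stimulus(onsets = c(200, 380), duration = 600)
  pk <- data.frame(time_ms = 280, height = 1)
  res <- match_peaks_to_nuclei(pk, stim2)
  expect_equal(res$synchronized, c(TRUE, FALSE))
  expect_equal(res$signed_asynchrony_ms[1], 80)
  # matched asynchronies always respect the window bound
  expect_true(all(abs(res$signed_asynchrony_ms[res$synchronized]) <= 120))
})

test_that("SMS rates are exact ratios, optionally stratified", {
  res <- data.frame(synchronized = c(rep(TRUE, 7), rep(FALSE, 3)),
                    weight = c(rep("strong", 5), rep("weak", 5)))
  expect_equal(sms_rate(res), 0.7)
  strat <- sms_rate(res, by = "weight")
  expect_equal(strat$rate[strat$stratum == "strong"], 1.0)
  expect_equal(strat$rate[strat$stratum == "weak"], 0.4)
  expect_equal(sms_rate(data.frame(synchronized = rep(TRUE, 4))), 1.0)
})

test_that("results are equivariant under a common time shift", {
  withr::local_seed(11)
  onsets <- c(200, 450, 700)
  offsets <- c(rnorm(8, 180, 12), rnorm(8, 690, 12))
  run <- function(delta) {
    stim <- make_stimulus(onsets = onsets + delta, duration = 1000 + delta)
    d <- estimate_density(offsets + delta, 1000 + delta)
    match_peaks_to_nuclei(find_peaks(d), stim)
  }
  base <- run(0)
  shifted <- run(25)
  expect_equal(shifted$synchronized, base$synchronized)
  expect_equal(shifted$signed_asynchrony_ms, base$signed_asynchrony_ms)
})

test_that("taps in repetitions 1-2 never change the analysis", {
  withr::local_seed(5)
  stimuli <- generate_stimuli(stimulus_spec(n_sentences = 3), seed = 5)
  cohort <- cohort_spec(n_dyslexic = 1, n_control = 1)
  participants <- generate_participants(cohort, seed = 5)
  without <- generate_taps(participants, stimuli, cohort, seed = 9)
  # graft extra taps into repetitions 1-2 of every series
  early <- do.call(rbind, lapply(names(stimuli), function(sid) {
    stim <- stimuli[[sid]]
    period <- stim$duration_ms + stim$pause_ms
    expand.grid(participant_id = participants$participant_id,
                task = "sms", stimulus_id = sid,
                time_ms = as.vector(outer(stim$syllables$nucleus_onset_ms,
                                          (1:2 - 1) * period, "+")),
                stringsAsFactors = FALSE)
  }))
  res_a <- suppressWarnings(analyze_sms(rbind(without$taps, early), stimuli))
  res_b <- suppressWarnings(analyze_sms(without$taps, stimuli))
  key <- c("participant_id", "stimulus_id", "label")
  a <- res_a[do.call(order, res_a[key]), ]
  b <- res_b[do.call(order, res_b[key]), ]
  expect_equal(a$synchronized, b$synchronized)
  expect_equal(a$signed_asynchrony_ms, b$signed_asynchrony_ms)
})
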