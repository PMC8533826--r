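# Fully seeded synthetic-data generators emulating the experimental design:
# sentence stimuli with annotated nuclei, a two-group cohort, loop-task tap
# streams, phoneme-monitoring responses, and ramped audio for the acoustics
# stage. Every generator is a pure function of (spec, seed).

#' Cohort specification for the synthetic generators
#'
#' Defaults describe the study design this package analyses: 13 dyslexic
#' and 11 control adults; controls synchronize with strong/weak syllable
#' nuclei with probability 0.9/0.6; the dyslexic group matches on strong
#' syllables but sits 0.61 log-odds lower on weak ones; tap asynchronies
#' are Gaussian with mean -20 ms (anticipation) and SD 30 ms in both
#' groups; modest participant- and sentence-level variation on the
#' log-odds scale; equal d-prime in both groups (no group difference in
#' phoneme monitoring).
#'
#' @param n_dyslexic,n_control Group sizes.
#' @param p_sync Named list `control`/`dyslexic`, each a named vector
#'   `c(strong=, weak=)` of synchronization probabilities.
#' @param asynchrony Named list `control`/`dyslexic`, each `c(mean=, sd=)`
#'   in ms.
#' @param extra_tap_rate Spurious (non-anchor) taps per second.
#' @param participant_sd,sentence_sd SDs of logit-scale random intercepts.
#' @param musicality Named list `control`/`dyslexic`, each `c(mean=, sd=)`
#'   for the integer musicality score (truncated to [0, 21]).
#' @param dyslexia_score Named list per group, `c(mean=, sd=)` for the
#'   checklist score.
#' @param dprime,criterion Named vectors per group for the monitoring-task
#'   observer.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters (ms).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_dyslexic = 13, n_control = 11,
                        p_sync = list(
                          control = c(strong = 0.9, weak = 0.6),
                          dyslexic = c(strong = 0.9,
                                       weak = stats::plogis(stats::qlogis(0.6) - 0.61))),
                        asynchrony = list(control = c(mean = -20, sd = 30),
                                          dyslexic = c(mean = -20, sd = 30)),
                        extra_tap_rate = 0.05,
                        participant_sd = 0.5, sentence_sd = 0.3,
                        musicality = list(control = c(mean = 4.0, sd = 3.7),
                                          dyslexic = c(mean = 7.4, sd = 6.4)),
                        dyslexia_score = list(control = c(mean = 35.0, sd = 3.9),
                                              dyslexic = c(mean = 58.2, sd = 9.5)),
                        dprime = c(control = 2.0, dyslexic = 2.0),
                        criterion = c(control = 0, dyslexic = 0),
                        rt_meanlog = log(450), rt_sdlog = 0.3) {
  probs <- unlist(p_sync)
  if (any(probs < 0 | probs > 1)) stop_validation("p_sync must lie in [0, 1]")
  if (any(c(asynchrony$control["sd"], asynchrony$dyslexic["sd"]) <= 0)) {
    stop_validation("asynchrony SDs must be positive")
  }
  structure(list(n_dyslexic = n_dyslexic, n_control = n_control,
                 p_sync = p_sync, asynchrony = asynchrony,
                 extra_tap_rate = extra_tap_rate,
                 participant_sd = participant_sd, sentence_sd = sentence_sd,
                 musicality = musicality, dyslexia_score = dyslexia_score,
                 dprime = dprime, criterion = criterion,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
            class = "cohort_spec")
}

#' Stimulus-set specification for the synthetic generators
#'
#' Defaults mirror the materials: 20 sentences of 7-13 syllables and
#' 1.2-2.3 s duration, about 61% metrically weak syllables, one or two
#' sonorant nuclei per sentence (always in weak syllables).
#'
#' @param n_sentences Number of sentences.
#' @param n_syllables Length-2 integer range of syllables per sentence.
#' @param duration_ms Length-2 range of sentence durations.
#' @param prop_weak Proportion of weak syllables.
#' @param sonorants_per_sentence Length-2 integer range of sonorant nuclei
#'   per sentence.
#' @return Object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(n_sentences = 20, n_syllables = c(7, 13),
                          duration_ms = c(1200, 2300), prop_weak = 0.61,
                          sonorants_per_sentence = c(1, 2)) {
  if (n_syllables[1] > n_syllables[2] || duration_ms[1] > duration_ms[2]) {
    stop_validation("ranges must be non-empty (low <= high)")
  }
  assert_number(prop_weak, "prop_weak", lower = 0, upper = 1)
  structure(list(n_sentences = n_sentences, n_syllables = n_syllables,
                 duration_ms = duration_ms, prop_weak = prop_weak,
                 sonorants_per_sentence = sonorants_per_sentence),
            class = "stimulus_spec")
}

#' Generate an annotated synthetic stimulus set
#'
#' Nucleus onsets are placed with jittered (non-isochronous) inter-nucleus
#' intervals that are at least 120 ms apart by construction, so adjacent
#' nuclei never share a matching window side. Nucleus durations follow the
#' weight/type pattern of natural sentence material (strong and sonorant
#' nuclei longer than weak vocalic ones).
#'
#' @param spec A [stimulus_spec()].
#' @param seed Integer seed.
#' @return Named list of [sentence_stimulus()] objects.
#' @export
generate_stimuli <- function(spec = stimulus_spec(), seed = 1) {
  stopifnot(inherits(spec, "stimulus_spec"))
  withr::with_seed(seed, {
    out <- list()
    for (s in seq_len(spec$n_sentences)) {
      n <- sample(seq(spec$n_syllables[1], spec$n_syllables[2]), 1L)
      head_ms <- stats::runif(1, 50, 150)
      tail_ms <- 150
      dur_lo <- max(spec$duration_ms[1], head_ms + tail_ms + 150 * (n - 1))
      if (dur_lo > spec$duration_ms[2]) {
        stop_validation(sprintf(
          "cannot pack %d syllables into at most %g ms", n,
          spec$duration_ms[2]))
      }
      dur <- stats::runif(1, dur_lo, spec$duration_ms[2])
      span <- dur - head_ms - tail_ms
      # jitter factors in [0.9, 1.1] keep every gap >= 0.9/1.1 * mean gap
      # >= 122 ms given the packing bound above
      u <- stats::runif(n - 1, 0.9, 1.1)
      gaps <- span * u / sum(u)
      onsets <- head_ms + c(0, cumsum(gaps))
      n_weak <- min(max(round(spec$prop_weak * n), 1L), n - 1L)
      weak_pos <- sort(sample(n, n_weak))
      weight <- rep("strong", n)
      weight[weak_pos] <- "weak"
      n_son <- min(sample(seq(spec$sonorants_per_sentence[1],
                              spec$sonorants_per_sentence[2]), 1L), n_weak)
      son_pos <- sample(weak_pos, n_son)
      ntype <- rep("vowel", n)
      ntype[son_pos] <- "sonorant"
      mean_dur <- ifelse(weight == "strong", 93,
                         ifelse(ntype == "sonorant", 94, 52))
      sd_dur <- ifelse(weight == "strong", 20,
                       ifelse(ntype == "sonorant", 24, 15))
      ndur <- pmax(25, stats::rnorm(n, mean_dur, sd_dur))
      max_end <- c(onsets[-1] - 20, dur)
      nucleus_end <- pmin(onsets + ndur, max_end)
      syl_onset <- pmax(onsets - stats::runif(n, 10, 40),
                        c(0, nucleus_end[-n]))
      sid <- sprintf("s%02d", s)
      syl <- data.frame(label = sprintf("syl%02d", seq_len(n)),
                        syllable_onset_ms = syl_onset,
                        nucleus_onset_ms = onsets,
                        nucleus_end_ms = nucleus_end,
                        weight = weight, nucleus_type = ntype,
                        stringsAsFactors = FALSE)
      out[[sid]] <- sentence_stimulus(sid, dur, syl)
    }
    out
  })
}

#' Generate a synthetic participant cohort
#'
#' @param cohort A [cohort_spec()].
#' @param seed Integer seed.
#' @return `data.frame` with `participant_id`, `group`, `musicality_score`,
#'   `dyslexia_score`, `dprime_true`, `logit_intercept` (the participant's
#'   latent synchronization propensity on the log-odds scale).
#' @export
generate_participants <- function(cohort = cohort_spec(), seed = 1) {
  stopifnot(inherits(cohort, "cohort_spec"))
  withr::with_seed(seed, {
    group <- c(rep("dyslexic", cohort$n_dyslexic),
               rep("control", cohort$n_control))
    id <- c(sprintf("d%02d", seq_len(cohort$n_dyslexic)),
            sprintf("c%02d", seq_len(cohort$n_control)))
    mus <- vapply(group, function(g) {
      m <- cohort$musicality[[g]]
      round(min(21, max(0, stats::rnorm(1, m["mean"], m["sd"]))))
    }, numeric(1))
    dys <- vapply(group, function(g) {
      m <- cohort$dyslexia_score[[g]]
      round(stats::rnorm(1, m["mean"], m["sd"]))
    }, numeric(1))
    data.frame(participant_id = id, group = group,
               musicality_score = as.integer(mus),
               dyslexia_score = as.integer(dys),
               dprime_true = unname(cohort$dprime[group]),
               logit_intercept = stats::rnorm(length(id), 0,
                                              cohort$participant_sd),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

# Latent sentence effects on the log-odds scale, deterministic in the seed.
sentence_effects <- function(stimuli, sentence_sd, seed) {
  withr::with_seed(seed + 1L, {
    stats::setNames(stats::rnorm(length(stimuli), 0, sentence_sd),
                    names(stimuli))
  })
}

#' Generate synchronization-task tap streams
#'
#' For each participant x sentence x syllable, a latent "synchronized"
#' state is drawn from the group- and weight-specific probability (shifted
#' by the participant's and sentence's log-odds intercepts). A synchronized
#' syllable emits one tap per analysed repetition at
#' `nucleus onset + Normal(mean, sd)` asynchrony; spurious taps arrive as a
#' Poisson process over the analysed part of the loop. Tap times are
#' referenced to loop onset and include the loop structure (sentence
#' duration plus pause per repetition).
#'
#' @param participants A [generate_participants()] table.
#' @param stimuli A [generate_stimuli()] list.
#' @param cohort A [cohort_spec()].
#' @param seed Integer seed.
#' @param include_early_repetitions If `TRUE`, repetitions before the first
#'   analysed one also emit taps (useful for testing their exclusion).
#' @param acquisition_delay_ms Constant delay the simulated recording chain
#'   adds to every logged tap (default 1 ms, matching the latency the
#'   analysis corrects for).
#' @return List with `taps` (tap table, task `"sms"`) and `truth`
#'   (`data.frame` of the latent synchronized states per participant x
#'   syllable).
#' @export
generate_taps <- function(participants, stimuli, cohort = cohort_spec(),
                          seed = 1, include_early_repetitions = FALSE,
                          acquisition_delay_ms = 1) {
  stopifnot(inherits(cohort, "cohort_spec"))
  sent_eff <- sentence_effects(stimuli, cohort$sentence_sd, seed)
  withr::with_seed(seed, {
    taps <- list()
    truth <- list()
    for (i in seq_len(nrow(participants))) {
      pid <- participants$participant_id[i]
      grp <- participants$group[i]
      u_p <- participants$logit_intercept[i]
      asyn <- cohort$asynchrony[[grp]]
      for (sid in names(stimuli)) {
        stim <- stimuli[[sid]]
        syl <- stim$syllables
        period <- stim$duration_ms + stim$pause_ms
        p_base <- cohort$p_sync[[grp]][syl$weight]
        p <- stats::plogis(stats::qlogis(p_base) + u_p + sent_eff[[sid]])
        sync <- stats::runif(nrow(syl)) < p
        first_rep <- if (include_early_repetitions) 1L else
          stim$first_analyzed_repetition
        reps <- seq(first_rep, stim$n_repetitions)
        t_list <- list()
        for (r in reps) {
          base <- (r - 1) * period
          if (any(sync)) {
            t_list[[length(t_list) + 1L]] <-
              base + syl$nucleus_onset_ms[sync] +
              stats::rnorm(sum(sync), asyn["mean"], asyn["sd"])
          }
        }
        span_ms <- length(reps) * period
        n_extra <- stats::rpois(1, cohort$extra_tap_rate * span_ms / 1000)
        if (n_extra > 0) {
          t_list[[length(t_list) + 1L]] <-
            (first_rep - 1) * period + stats::runif(n_extra, 0, span_ms)
        }
        tt <- sort(pmax(unlist(t_list) %||% numeric(0), 0) +
                     acquisition_delay_ms)
        if (length(tt) > 0L) {
          taps[[length(taps) + 1L]] <-
            data.frame(participant_id = pid, task = "sms",
                       stimulus_id = sid, time_ms = tt,
                       stringsAsFactors = FALSE)
        }
        truth[[length(truth) + 1L]] <-
          data.frame(participant_id = pid, group = grp, stimulus_id = sid,
                     label = syl$label, weight = syl$weight,
                     nucleus_type = syl$nucleus_type, synchronized = sync,
                     stringsAsFactors = FALSE)
      }
    }
    list(taps = do.call(rbind, taps), truth = do.call(rbind, truth))
  })
}

#' Simulate synchronization outcomes at the syllable level
#'
#' Draws the binary per-syllable synchronized outcome directly from the
#' latent model the tap generator uses (group/weight probabilities plus
#' participant and sentence log-odds intercepts), with the group contrast
#' for weak syllables set to `effect_weak_logodds`. This is the generator
#' the statistical-stage simulations (power, type-I error) run on; the
#' tap-level pipeline is exercised separately.
#'
#' @param participants A [generate_participants()] table.
#' @param stimuli A [generate_stimuli()] list.
#' @param cohort A [cohort_spec()]; its control probabilities anchor the
#'   model.
#' @param effect_weak_logodds Log-odds deficit of the dyslexic group on
#'   weak syllables (default: the gap implied by the cohort's own
#'   probabilities; 0 gives a null simulation).
#' @param seed Integer seed.
#' @return `data.frame` with `participant_id`, `group`, `stimulus_id`,
#'   `weight`, `nucleus_type`, `synchronized` (0/1), group and weight as
#'   factors with control/strong reference levels.
#' @export
simulate_sync_outcomes <- function(participants, stimuli,
                                   cohort = cohort_spec(),
                                   effect_weak_logodds = NULL, seed = 1) {
  stopifnot(inherits(cohort, "cohort_spec"))
  effect <- effect_weak_logodds %||%
    (stats::qlogis(cohort$p_sync$control["weak"]) -
       stats::qlogis(cohort$p_sync$dyslexic["weak"]))
  sent_eff <- sentence_effects(stimuli, cohort$sentence_sd, seed)
  syl_all <- do.call(rbind, lapply(names(stimuli), function(sid) {
    s <- stimuli[[sid]]$syllables
    data.frame(stimulus_id = sid, weight = s$weight,
               nucleus_type = s$nucleus_type, stringsAsFactors = FALSE)
  }))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(participants)), function(i) {
      grp <- participants$group[i]
      eta <- stats::qlogis(cohort$p_sync$control[syl_all$weight]) +
        (grp == "dyslexic") * (syl_all$weight == "weak") * (-effect) +
        participants$logit_intercept[i] + sent_eff[syl_all$stimulus_id]
      data.frame(participant_id = participants$participant_id[i],
                 group = grp, stimulus_id = syl_all$stimulus_id,
                 weight = syl_all$weight,
                 nucleus_type = syl_all$nucleus_type,
                 synchronized = as.integer(stats::runif(nrow(syl_all)) <
                                             stats::plogis(eta)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$group <- stats::relevel(factor(out$group), ref = "control")
    out$weight <- stats::relevel(factor(out$weight), ref = "strong")
    out
  })
}

#' Generate phoneme-monitoring trials and responses
#'
#' Trials follow the task design: blocks of 5 target and 5 distractor
#' nonsense strings, one monitored phoneme per block (each phoneme gets an
#' equal share of blocks). Responses come from an equal-variance Gaussian
#' signal-detection observer with the participant's group d-prime and
#' criterion; hits produce a log-normal reaction time after the target
#' onset, false alarms a uniform tap within the trial.
#'
#' @param participants A [generate_participants()] table.
#' @param cohort A [cohort_spec()].
#' @param n_targets,n_distractors Trial counts per participant (default
#'   40 + 40, i.e. 8 blocks of 5 + 5).
#' @param seed Integer seed.
#' @return List with `trials` (one row per participant x trial, covariates
#'   included) and `taps` (task `"monitoring"`, times referenced to trial
#'   onset).
#' @export
generate_monitoring <- function(participants, cohort = cohort_spec(),
                                n_targets = 40, n_distractors = 40,
                                seed = 1) {
  stopifnot(inherits(cohort, "cohort_spec"))
  phonemes <- c("p", "k", "m", "l")
  block_size <- 5L
  n_blocks <- ceiling((n_targets + n_distractors) / (2L * block_size))
  withr::with_seed(seed, {
    trials_all <- list()
    taps_all <- list()
    for (i in seq_len(nrow(participants))) {
      pid <- participants$participant_id[i]
      grp <- participants$group[i]
      dp <- cohort$dprime[[grp]]
      cc <- cohort$criterion[[grp]]
      is_target <- c(rep(TRUE, n_targets), rep(FALSE, n_distractors))
      is_target <- sample(is_target)
      n_tr <- length(is_target)
      block_id <- rep(seq_len(n_blocks), each = 2L * block_size,
                      length.out = n_tr)
      phon <- phonemes[(block_id - 1L) %% length(phonemes) + 1L]
      dur <- stats::runif(n_tr, 2000, 2600)
      onset <- ifelse(is_target, stats::runif(n_tr, 300, 800), NA_real_)
      # equal-variance SDT observer: evidence ~ N(+-d'/2, 1), respond if
      # evidence exceeds the criterion
      evidence <- stats::rnorm(n_tr, ifelse(is_target, dp / 2, -dp / 2), 1)
      respond <- evidence > cc
      rt <- 150 + stats::rlnorm(n_tr, cohort$rt_meanlog, cohort$rt_sdlog)
      tap_time <- ifelse(is_target, onset + rt,
                         stats::runif(n_tr, 200, dur - 100))
      tap_time <- pmin(tap_time, dur - 1)
      trial <- data.frame(
        participant_id = pid, group = grp,
        stimulus_id = sprintf("%s_m%03d", pid, seq_len(n_tr)),
        block_id = block_id, target_phoneme = phon,
        is_target = is_target, target_onset_ms = onset,
        trial_duration_ms = dur,
        target_type = ifelse(phon %in% c("m", "l"), "sonorant", "obstruent"),
        syllable_position = sample(c("onset", "coda"), n_tr, replace = TRUE),
        cluster = sample(0:1, n_tr, replace = TRUE),
        stringsAsFactors = FALSE)
      trials_all[[i]] <- trial
      resp <- which(respond)
      if (length(resp) > 0L) {
        taps_all[[length(taps_all) + 1L]] <- data.frame(
          participant_id = pid, task = "monitoring",
          stimulus_id = trial$stimulus_id[resp],
          time_ms = tap_time[resp], stringsAsFactors = FALSE)
      }
    }
    list(trials = do.call(rbind, trials_all),
         taps = do.call(rbind, taps_all))
  })
}

#' Synthesize sentence audio with programmed rise ramps
#'
#' Each syllable becomes a tone burst running from the syllable onset to
#' the nucleus end: amplitude rises linearly over `ramp_ms`, sustains at
#' the syllable's level, and falls over a short decay; silence elsewhere.
#' Because the rise ramp is programmed, the acoustics stage can be checked
#' against ground truth.
#'
#' @param stimulus A [sentence_stimulus()].
#' @param ramp_ms Rise-ramp duration(s), scalar or one per syllable.
#' @param levels Sustain amplitude(s) in (0, 1], scalar or per syllable.
#' @param sample_rate Hz (default 44100).
#' @param carrier_hz Tone frequency (default 220).
#' @return List with `samples` and `sample_rate`.
#' @export
synthesize_audio <- function(stimulus, ramp_ms = 50, levels = 0.3,
                             sample_rate = 44100, carrier_hz = 220) {
  stopifnot(inherits(stimulus, "sentence_stimulus"))
  syl <- stimulus$syllables
  n <- nrow(syl)
  ramp_ms <- rep_len(ramp_ms, n)
  levels <- rep_len(levels, n)
  burst_start <- syl$syllable_onset_ms
  burst_end <- syl$nucleus_end_ms
  if (any(ramp_ms >= burst_end - burst_start)) {
    stop_validation("rise ramp longer than its syllable burst")
  }
  if (n > 1L && any(burst_start[-1] < burst_end[-n])) {
    stop_validation("syllable bursts overlap")
  }
  n_samp <- ceiling(stimulus$duration_ms * sample_rate / 1000)
  t_ms <- (seq_len(n_samp) - 1) / sample_rate * 1000
  amp <- numeric(n_samp)
  decay_ms <- 15
  for (i in seq_len(n)) {
    seg <- t_ms >= burst_start[i] & t_ms < burst_end[i]
    rel <- t_ms[seg] - burst_start[i]
    len <- burst_end[i] - burst_start[i]
    a <- pmin(rel / ramp_ms[i], 1)
    tail_in <- len - rel
    a <- pmin(a, pmax(tail_in / decay_ms, 0))
    amp[seg] <- pmax(amp[seg], levels[i] * a)
  }
  carrier <- sin(2 * pi * carrier_hz * t_ms / 1000)
  list(samples = amp * carrier, sample_rate = sample_rate)
}
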