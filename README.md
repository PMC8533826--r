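# speechsync

Analysis tools for sensorimotor synchronization (SMS) experiments with
natural speech: participants tap a finger in time with the perceived beat
of looped spoken sentences, and the analysis asks *which syllable nuclei
attracted their taps, how accurately, and how this differs between groups*
(e.g. dyslexic vs. control adults). The package also scores the companion
screening tasks of such studies — unpaced and metronome-paced tapping,
and phoneme monitoring — and provides the group-level statistical stage.

Because raw behavioural recordings from tapping studies are rarely
shareable, the package ships a fully seeded synthetic-data generator that
emulates the experimental design end to end, so every analysis stage is
testable and demonstrable without any external data.

## The core computation

For each participant × sentence, the tap stream is reduced to per-syllable
synchronization measures:

1. **Latency correction** — tap timestamps are shifted by the acquisition
   chain's fixed delay (default 1 ms).
2. **Folding** — the sentence is looped (10 repetitions, 400 ms pauses);
   taps from the analysed repetitions (3–10 by default) are mapped to
   sentence-relative offsets. Taps late in a pause wrap to negative
   offsets so anticipation of the sentence-initial nucleus is preserved.
3. **Kernel density estimation** — the folded offsets are smoothed with a
   Gaussian kernel (exact kernel sum on a 1 ms grid, default bandwidth
   20 ms). The density's peaks are the participant's synchronization
   anchors: time points that consistently attracted taps across
   repetitions.
4. **Peak detection** — strict local maxima, discarding candidates below
   40% of the maximal peak and enforcing a 100 ms minimal inter-peak
   distance by greedy suppression.
5. **Matching** — peaks are matched one-to-one to annotated syllable
   nucleus onsets within a ±120 ms window. A matched nucleus counts as
   synchronized; its *signed asynchrony* is peak time − nucleus onset
   (negative = anticipation) and its *absolute asynchrony* the magnitude.
6. **Rates** — the SMS rate is the proportion of nuclei a participant
   synchronized with, optionally stratified by metrical weight
   (strong/weak) or nucleus type (vowel/sonorant).

Around this core sit: acoustic covariate extraction (amplitude-envelope
rise-time via an 11 ms spline-through-peaks envelope, nucleus duration,
sentence-normalized intensity in dB), motor-task metrics (inter-tap
interval mean and CV = SD/mean; paced-tapping asynchronies in ms and as
proportions of the inter-onset interval), signal-detection *d′* =
z(H) − z(F) with 1/(2N) extreme-rate correction for phoneme monitoring,
and the statistical stage (Welch *t* and pooled-SD Cohen's *d* from group
summaries, lme4 mixed-effects models with backward interaction reduction
by likelihood-ratio test, emmeans group contrasts, simulation-based
power).

## Worked example

Simulate a small cohort, run the tap-to-syllable pipeline, and fit the
group × metrical-weight model:

```r
library(speechsync)

stimuli      <- generate_stimuli(stimulus_spec(n_sentences = 5), seed = 42)
cohort       <- cohort_spec(n_dyslexic = 3, n_control = 3)
participants <- generate_participants(cohort, seed = 42)
taps         <- generate_taps(participants, stimuli, cohort, seed = 42)$taps

results <- analyze_sms(taps, stimuli)
head(results[, c("participant_id", "stimulus_id", "label", "weight",
                 "synchronized", "signed_asynchrony_ms")], 3)
#>   participant_id stimulus_id label weight synchronized signed_asynchrony_ms
#> 1            d01         s01 syl01   weak        FALSE                   NA
#> 2            d01         s01 syl02 strong        FALSE                   NA
#> 3            d01         s01 syl03 strong         TRUE             11.31398
```

Per-participant stratified SMS rates show the simulated group structure
(the dyslexic group synchronizes less often with weak syllables):

```r
#>   participant_id rate_strong rate_weak    group
#> 1            c01   0.9523810 0.6551724  control
#> 2            c02   0.8571429 0.4827586  control
#> 3            c03   0.6666667 0.1379310  control
#> 4            d01   0.7142857 0.2068966 dyslexic
#> 5            d02   0.7619048 0.3103448 dyslexic
#> 6            d03   0.8095238 0.4137931 dyslexic
```

The statistical stage fits the synchronization-likelihood model (logistic
mixed-effects regression with participant and sentence intercepts):

```r
dat  <- simulate_sync_outcomes(participants, stimuli, cohort, seed = 42)
spec <- model_spec("synchronized", family = "binomial",
                   fixed = c("group", "weight"), interactions = "weight")
fit_mixed_model(dat, spec)$coefficients
#>                       term   estimate        se  statistic            p
#> 1              (Intercept)  1.8758939 0.4663437  4.0225566 5.756981e-05
#> 2            groupdyslexic -0.1244443 0.6500047 -0.1914514 8.481719e-01
#> 3               weightweak -1.7076864 0.4306797 -3.9650962 7.336636e-05
#> 4 groupdyslexic:weightweak -1.0047491 0.6118280 -1.6422083 1.005468e-01
```

At this toy size (6 participants, 5 sentences) the interaction is not
significant; `power_by_simulation()` quantifies detectability at realistic
sizes. `run_pipeline()` orchestrates all stages from a config (or YAML
file) and writes stage CSVs plus a JSON manifest recording every parameter
used.

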