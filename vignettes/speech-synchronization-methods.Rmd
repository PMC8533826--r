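---
title: "Measuring sensorimotor synchronization with natural speech: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sensorimotor synchronization with natural speech: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechsync)
```

## The measurement problem

When listeners tap "in time" with a spoken sentence, their taps are not
locked to a metronome: natural speech has no isochronous beat, and the
perceptual anchor of a syllable (its p-center) is best approximated by
the onset of the syllable nucleus — the vowel, or a syllabic sonorant in
some unstressed syllables. A single trial therefore gives a sparse,
jittery point process of taps, and the question "did this participant
synchronize with this syllable?" is only answerable by aggregating
evidence across repeated presentations of the same sentence.

The design this package analyses loops each sentence 10 times with a
400 ms silent pause, instructs tapping from the third repetition, and
aggregates the analysed repetitions (8 by default) into one
sentence-relative tap distribution per participant × sentence. A
synchronized syllable shows up as a *consistent* concentration of taps
near its nucleus onset; isolated taps do not count. The pipeline
operationalizes "consistent concentration" as a peak of a Gaussian
kernel density estimate of the folded tap offsets.

## Pipeline stages and their parameters

| stage | parameter | default | why |
|---|---|---|---|
| latency correction | `latency_ms` | 1 ms | fixed delay of the tap acquisition chain (piezo sensor + microcontroller) |
| tap-log reading | `dedup_ms` | 1 ms | sensor double-triggers within ~1 ms collapse to one tap |
| folding | `first_analyzed_repetition` | 3 | participants start tapping at the third repetition |
| folding | `pause_ms` | 400 ms | inter-repetition silence of the loop |
| density | `bandwidth` | 20 ms | kernel bandwidth at the motor-jitter timescale (see below) |
| peaks | `rel_threshold` | 0.40 | a peak must reach 40% of the maximal peak of its density |
| peaks | `min_distance_ms` | 100 ms | two anchors closer than this are one burst, not two |
| matching | `window_ms` | 120 ms | a nucleus is synchronized only if a peak lies within ±120 ms |
| envelope | `window_ms` | 11 ms | smoothing window of the amplitude envelope |
| monitoring | `response_window_start_ms` | 150 ms | sub-150 ms taps cannot be reactions to the target |

All of these surface as arguments and are recorded in the run manifest
written by `run_pipeline()`, so any analysis is reproducible from its
manifest alone.

### Folding and the pause

Folding maps a tap at absolute time $t$ to repetition
$k = \lfloor t / P \rfloor + 1$ (period $P$ = sentence duration + pause)
and offset $t \bmod P$. Two boundary rules matter. A tap up to
`window_ms` after the sentence ends keeps its positive offset: it may
lag the final nucleus. A tap within `window_ms` *before* the next
repetition begins wraps to a negative offset and counts toward the next
repetition: it anticipates the sentence-initial nucleus. Taps deeper in
the pause are discarded, as are taps from unanalysed repetitions. These
rules make the analysis exactly invariant to adding or removing taps in
repetitions 1–2, which the tests assert.

### Why the density bandwidth is fixed, not rule-based

The obvious default — Silverman's rule-of-thumb on the folded offsets —
is wrong for this signal, and measurably so. The offsets form a strongly
multimodal distribution: tight clusters (within-cluster SD around
20–40 ms, the participant's motor jitter) at anchors spaced 120–250 ms
apart. Global bandwidth rules see the *between*-cluster spread (hundreds
of ms) and return bandwidths of 150–220 ms, which merge every anchor
into one or two broad modes; no per-syllable statement survives. A fixed
20 ms bandwidth matches the within-cluster scale: combined with 30 ms
motor jitter it yields effective peak widths of ~36 ms, resolving
anchors ≥120 ms apart with a wide margin while single stray taps produce
bumps well below the 40% peak threshold. `bandwidth = "silverman"`
remains available for comparison, and any numeric bandwidth can be set;
the choice used is logged per run.

### Peak detection semantics

Candidates are strict local maxima of the gridded density. Two
constraints follow: a relative height threshold (≥ 40% of the tallest
candidate) and a minimal separation (100 ms), enforced by greedy
suppression in order of descending height with ties broken toward the
earlier time. The test suite proves this implementation identical to a
brute-force enumerate–threshold–suppress oracle on 1,000 random
multimodal densities.

### Matching and the sign convention

Peaks and nucleus onsets are matched one-to-one, greedily by ascending
absolute distance, only within ±120 ms. Exclusive matching prevents one
burst of taps from satisfying two adjacent nuclei. Signed asynchrony is
*peak minus onset*: negative values mean the tap anticipated the
nucleus, the usual finding in paced tapping (negative mean asynchrony).

## Acoustic covariates

Three per-syllable covariates enter the statistical models:

- **Rise-time.** The amplitude envelope is a cubic spline through the
  per-frame maxima of |amplitude| (11 ms frames), evaluated on a 1 ms
  grid. Rise-time is the interval from the envelope's local minimum just
  before the syllable onset (search window [onset − 50, onset + 10] ms)
  to the first local maximum within the syllable. The minimum is taken
  at the latest point within 1% of the local range above the floor:
  the smoothed envelope leaves the floor up to one frame early, and the
  1% foot rule keeps programmed ramps recoverable within one smoothing
  window (±11 ms), which the tests assert. Rise-time is invariant to
  amplitude scaling and sign flips. A flat envelope yields a missing
  value, never zero. Whether the anchor is the syllable onset or the
  nucleus onset is ambiguous in practice; both are supported
  (`rise_anchor`), with the syllable onset as default.
- **Duration.** Nucleus end − nucleus onset, straight from the
  annotation.
- **Relative intensity.** Frame-wise RMS level in dB (10 ms frames,
  reference 2 × 10⁻⁵ so unit-scale waveforms land in the conversational
  60–90 dB range), averaged per segment, divided by the sentence mean.
  The dB-ratio convention puts values near 1 with louder-than-average
  segments above it, the range summary tables of such experiments show
  (≈ 0.89–1.09); a linear-RMS ratio is available. Digitally silent
  segments propagate as missing values.

## The monitoring task and d′

Phoneme-monitoring trials are scored from the same tap stream: on target
trials the first tap between 150 ms after the target onset and trial end
is a hit (RT = tap − target onset); on distractor trials any tap is a
false alarm. Sensitivity is d′ = z(H) − z(F) pooled over all target
phonemes. Extreme rates are corrected by the 1/(2N) convention (0 →
1/(2N), 1 → 1 − 1/(2N)); the log-linear correction is available. At the
design's 40 + 40 trials the sampling SD of d̂′ around a true d′ = 1.5 is
≈ 0.30 — exact enumeration over the hit/false-alarm lattice puts only
~88% of estimates within ±0.5 regardless of the correction used — so
individual d′ values at this trial count carry substantial measurement
noise, a caveat that applies to any study of this size.

## The statistical stage

Group summaries use Welch's t (with Welch–Satterthwaite df) and pooled-SD
Cohen's d computed directly from per-group mean/SD/n, so published
summary tables can be checked without raw data; both equal their
raw-data counterparts to 10⁻¹⁰ by construction (tested against
`t.test()` and the definitional formulas).

Mixed models are declared via `model_spec()` (response, family,
transform, main effects, candidate group × covariate interactions,
random terms) and fitted with lme4: logistic models with the bobyqa
optimizer and 10⁵ function evaluations, linear models by REML with
Satterthwaite-type p-values via lmerTest, with optimizer fallbacks on
convergence failure. "An interaction that does not improve the fit" is
operationalized as: drop when the likelihood-ratio test against the
fuller model (ML-refit) is non-significant at α = 0.05 *and* the AIC
does not worsen; the reported table lists each candidate with the AIC of
the model lacking it, the LRT df, χ² and p. Group contrasts come from
emmeans, at factor levels or at mean ± 1 SD of a continuous moderator.
Marginal/conditional variance-explained summaries are not reported: they
are convention-dependent approximations and not part of this package's
acceptance surface.

`power_by_simulation()` estimates power for the group × weight
interaction by refitting the focal logistic model to replicates of the
outcome-level generator and counting Wald-significant interactions; the
Wald test (rather than a per-replicate LRT) keeps hundreds of replicates
affordable at identical asymptotic behaviour.

## What the synthetic generator does and does not emulate

The generator is the package's substitute for unreleasable raw data. Its
latent model is the *minimal* one under which every reported measure is
identifiable: each participant × sentence × syllable draws a Bernoulli
"synchronized" state with probability set by group and metrical weight
(shifted by participant and sentence log-odds intercepts); a
synchronized syllable emits one tap per analysed repetition at nucleus
onset + Normal(μ, σ); spurious taps arrive as a Poisson process; the
recording chain adds the 1 ms acquisition delay the analysis removes.
Monitoring responses come from an equal-variance Gaussian SDT observer
with group-level d′ and criterion, log-normal RTs.

Defaults encode the study conditions: 13 + 11 participants, 20 sentences
of 7–13 syllables and 1.2–2.3 s, ~61% weak syllables, 1–2 sonorant
nuclei per sentence, control synchronization probabilities 0.9 (strong)
and 0.6 (weak), a 0.61 log-odds weak-syllable deficit in the dyslexic
group with no strong-syllable difference, asynchrony Normal(−20, 30) ms
in both groups, equal d′ = 2.0 observers, and musicality/checklist score
distributions matching the published group summaries. Participant and
sentence intercept SDs (0.5 and 0.3 on the logit scale) were chosen once
to produce the modest conditional-over-marginal variance surplus such
designs report. Inter-nucleus intervals are ≥ 120 ms by construction, so
adjacent matching windows never swallow each other — a property of the
real materials' syllable rate, not an artifact.

Not emulated: learning or drift across repetitions, serial dependence
between taps (phase correction), naturalistic acoustics (bursts are
ramped tones, not speech), annotation error, or missing data beyond
what the task structure produces. Passing recovery tests therefore shows
the *pipeline* is correct under the stated generative assumptions — not
that those assumptions exhaust real tapping behaviour.

## Numerical choices and degenerate inputs

- Densities are exact Gaussian kernel sums on a 1 ms grid (no FFT
  binning), normalized on the grid; the tests require pointwise 10⁻⁹
  agreement with a direct mixture sum and grid mass 1 ± 10⁻³.
- A degenerate rule-of-thumb bandwidth (all offsets identical) falls
  back to the 1 ms grid step, so point masses still localize.
- Fewer than 2 offsets, fewer than 3 taps (ITI), fewer than 5 matched
  prompts (paced), or an empty trial class (d′) raise a classed
  `insufficient_data` warning and return missing values, never zeros.
- Ties: equal-height peaks retain the earlier one; equidistant
  peak–nucleus pairs resolve toward the earlier nucleus, then the
  earlier peak.
- Problem sizes in the shipped tests — 24 × 20 sentences for the
  end-to-end recovery, 100 replicates each for the power and type-I
  checks, 1,000 densities for the peak-finder equivalence, 2,000 + 2,000
  trials for d′ recovery — were chosen as the smallest sizes at which
  the checked tolerances are meaningful.

## Known limitations

- The density-peak reading of asynchrony (asynchronies measured from KDE
  peaks, not raw taps) is the only one implemented; tap-level asynchrony
  series and circular-statistics phase analyses are out of scope.
- TextGrid support covers interval tiers in the long text format with
  the documented `syllable`/`nucleus` tier convention.
- The WAV reader handles uncompressed PCM and 32-bit float RIFF files
  only.
- d′ at 40 + 40 trials is noisy (see above); models using it as a
  predictor inherit that noise.
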