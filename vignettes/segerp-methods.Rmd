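---
title: "Methods: simulating and analysing infant speech-segmentation ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing infant speech-segmentation ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segerp)
```

## The paradigm and the analysis model

segerp implements the analysis chain of a two-phase infant ERP
speech-segmentation experiment. In each block an infant hears ten isolated
tokens of a target word (*familiarization*), then eight sentences of which
four contain the familiarized word and four a matched control word
(*test*). EEG is recorded from 27 scalp electrodes at 200 Hz, referenced
online to the left mastoid. The quantity of interest at every stage is the
**familiarity effect**: the familiarized-minus-unfamiliar difference in
mean amplitude over a latency window, whose *polarity* carries the
developmental signal — a left-frontal negative-going difference is the
mature segmentation marker seen in older infants, a positive-going
difference the typical 7-month response.

The analysis chain is:

1. zero-phase 1–30 Hz Butterworth band-pass on the continuous signal
   (4th order per pass, forward–backward; the 1 Hz edge removes the slow
   activity that otherwise swamps infant ERPs);
2. re-referencing to linked mastoids (mean of the two mastoid channels
   subtracted from every scalp channel; bipolar EOG channels untouched);
3. epoching into half-open `[-200, 800)` ms windows around word onset
   (200 samples; sample *i* sits at `-200 + 5 i` ms), with subtraction of
   each epoch's `[-200, 0)` ms baseline;
4. artifact screening: a trial is dropped when any analysis electrode
   exceeds ±150 µV, or when an analysis electrode correlates with an EOG
   channel at |r| ≥ 0.8 while that EOG channel swings ≥ 50 µV
   peak-to-peak;
5. condition averaging per subject, difference waves
   (familiar − unfamiliar), unweighted grand averages, and window means
   over the analysis windows (familiarization 200–500 ms; test 350–450 ms
   and 430–530 ms);
6. repeated-measures ANOVA with Familiarity (2) × Quadrant (4) ×
   Electrode (5, the position within each quadrant) as within-subject
   factors, Huynh–Feldt-adjusted p-values reported with the original
   degrees of freedom;
7. onset scanning of difference waves in 50 ms bins stepped by 10 ms, a
   per-bin one-sample t against zero, and onset defined as the start of
   the first run of five consecutive significant bins sharing a sign;
8. responder classification by the sign of the left-frontal 350–450 ms
   test-phase difference (strictly negative → "negative responder");
9. linkage to 3-year language outcomes: pooled-variance Student t tests
   between responder groups, and bivariate plus partial Pearson
   correlations between the left-frontal effect and the word-production
   language quotient (LQ).

### Statistical choices worth stating

* **Sphericity corrections.** For each within-subject effect the
  orthonormal-contrast score covariance `C` gives
  `eps_GG = tr(C)^2 / (d tr(C^2))` and the single-group Huynh–Feldt form
  `eps_HF = min(1, (n d eps_GG − 2) / (d (n − 1 − d eps_GG)))`. Several
  HF variants circulate; fixing this one makes results bit-reproducible,
  and the test suite cross-checks it against an independent
  implementation.
* **Pooled-variance t.** Group comparisons of 9 vs 14 children report
  `df = 21`, which identifies the classical Student form rather than
  Welch; `two_sample_t()` implements exactly that.
* **Onset rule.** The sign-consistency requirement across the five bins
  is a package addition (configurable off): it prevents alternating-sign
  noise runs from qualifying as an onset. Because consecutive bins
  overlap by 40 ms, bin-level t statistics are strongly correlated and
  the run-of-five family criterion is *not* strictly conservative: its
  measured null false-positive rate is about 0.07 at a per-bin alpha of
  0.05 (see the onset tests). A related grid property matters when
  interpreting detected latencies: with 10 ms steps, the first bin that
  *contains* post-onset samples starts 40 ms before the true onset, and
  at high signal-to-noise that partially overlapping bin is already
  significant, so the detector resolves a sharp step planted at 300 ms to
  a reported onset of 260 ms. Detected onsets are therefore grid-limited
  lower bounds, not unbiased latency estimates.
* **No multiplicity correction** across electrodes or windows, matching
  standard practice in this literature; p-values are descriptive at the
  follow-up level.
* **Zero-variance bins** are declared non-significant (p = 1) rather than
  an error, so noise-free validation data passes cleanly through the
  onset scan.

## What the synthetic cohort generator emulates

`generate_cohort()` produces, per subject, a continuous 200 Hz multichannel
recording with event markers, built from four ingredients.

**Design.** Each subject contributes `8 + Binomial(12, 5/12)` blocks
(mean 13, range 8–20, matching the reported presentation counts); each
block holds 10 familiarization tokens and 8 test events (4 familiarized,
4 control, randomly ordered). A configurable responder split (default
9 negative / 14 positive of 23) fixes which subpopulation each subject
belongs to.

**Planted effects** (`default_effects()`):

| effect | carrier | topography | time course | scored window | mean (µV) | SD |
|---|---|---|---|---|---|---|
| `fam_repetition` | everyone | frontal, left-weighted | 200–500 ms plateau | 200–500 | −3.71 | 6.2 |
| `test_positive` | positive group | right-frontal | onset 300 ms | 350–450 | +2.49·23/14 ≈ +4.09 | 3.0 |
| `test_negative` | negative group | left-frontal + left-posterior | plateau 350–530 ms | 350–450 | −3.8 | 3.0 |

The familiarization effect builds up across tokens (tokens 1–2 carry
none, 9–10 the full kernel, linear in between), so the scored difference
between the last and first token pairs equals the planted amplitude. The
published values fix the shared familiarization effect directly. The
test-phase *group-level* means are not published separately, so they are
calibration choices constrained by two published facts: the pooled
right-frontal effect of a 9/14 cohort must equal +2.49 µV (negative
responders contribute nothing there, giving +2.49·23/14 for the positive
group), and the left-frontal responses of the two groups should roughly
cancel in the pooled average (the stated reason no left-frontal effect
appears in the full-sample analysis), giving −3.8 µV for the negative
group against the positive group's 0.6-weighted left-frontal projection.
Group-specific between-subject SDs (3.0 µV) are likewise calibration
choices: the published pooled SDs conflate between-subject spread with
measurement noise, so the generator plants spread only and
parameter-recovery targets the means, not the SDs.

Two conventions make planted amplitudes *measured* quantities rather than
raw kernel heights:

* electrode weights are normalized to mean 1 over each effect's reference
  electrode set, so the set-mean window amplitude is the planted value;
* kernels are divided by the deterministic gain of the measurement chain
  (`filter_gain_for_effect()`): a 1 Hz zero-phase high-pass removes about
  half of a 300 ms plateau's window mean (gain ≈ 0.49 for the
  familiarization kernel including baseline correction), and because the
  whole chain is linear this loss is a fixed scalar per kernel that can
  be compensated exactly. Recovery of the configured amplitudes by the
  full pipeline is then unbiased; disabling the filter sets the gain
  to 1.

Per-subject amplitudes are drawn `Normal(mean, SD)`; for group-specific
test-phase effects the draw is sign-truncated (negative responders
strictly negative, positive responders non-negative) with the location
solved numerically so the *post-truncation* mean equals the configured
value. The sign constraint is what makes polarity classification a
well-posed recovery problem at high SNR.

**Noise** is a per-channel sum of 1/f ("pink") noise (30 µV RMS, the
dominant infant-EEG background), a 0.3 Hz sinusoidal drift of 20 µV with
random phase (exercising the 1 Hz high-pass), and 5 µV white sensor
noise. Channels are independent; the online-reference left mastoid is
identically zero and the right mastoid carries noise, so linked-mastoid
re-referencing injects a realistic common-mode component.

**Artifacts** are epoch-locked: blinks (probability 0.42 per epoch) are
400 ms half-sines of 300–500 µV on the vertical EOG, propagated to the
scalp with frontally decaying gains capped at 0.45; excursions
(probability 0.33) are 100 ms, 400 µV biphasic pulses on one random
analysis electrode. Blink sizing is deliberate, and instructive about
correlation-based screening in general. A planted condition effect adds
kernel variance to the scalp signal that is uncorrelated with the EOG,
so *marginally* detectable blinks are detected at slightly different
rates in the two conditions — a selection that attenuates recovered
effects by up to ~10 % when many blinks sit near the |r| = 0.8
boundary, and that also appears (with opposite sign) when blink scalp
projections straddle the ±150 µV threshold instead. The defaults
therefore make blinks large enough that the correlation rule detects
them essentially independently of the planted kernel, while their scalp
projection stays below the amplitude threshold; measured recovery bias
is then indistinguishable from zero (|bias| < 0.1 µV over 320
subjects). The two probabilities were calibrated once against the
published rejection rates (55.6 % / 62.5 %) and kept per-condition trial
means (11.4 familiarization, 19.6 test) and then frozen.

**Outcomes.** Word-production LQ is generated on the cohort scale
(mean 118.9, SD 11.2) as
`LQ_w = m_w + s_w (−β z(a) + c g⊥ + sqrt(1 − β² − c²) ε)`, where `z(a)`
standardizes the planted left-frontal amplitude across the cohort, β is
the configured link (0.47, applied negatively: more negative effect,
higher LQ), and `g⊥` is the in-sample standardized component of
negative-group membership orthogonal to `z(a)` with `c` solved so the
negative group's expected mean lands at `100 + 15 × 1.5`. Orthogonality
keeps the amplitude–LQ correlation at −β while the unit variance budget
keeps the configured SD, so the three published facts — r = −0.47, the
1.5 SD elevation, and the cohort moments — coexist by construction.
Comprehension and sentence LQs and the SLAS parent ratings (mean 4.7,
SD 0.9, clipped to 1–7) load on the shared systematic ability with
loading 0.65, chosen to reproduce the published inter-test correlation
magnitudes (≈ 0.4–0.67).

**Stimulus timing.** The `"paper"` profile reproduces the published
presentation rate (isolated tokens every ≈ 3.2 s, sentence targets every
≈ 8.3 s). The `"compact"` profile shortens silent gaps to 2.5 s
onset-to-onset. Dead time between events carries no statistical
information — epochs never overlap and residual filter-transient leakage
between neighbouring epochs is below 0.02 µV at this spacing — so
replicate simulation studies (tests and the acceptance script) use the
compact profile; generator defaults stay faithful to the published
timing. For the same reason, large replication runs skip simulating the
seven never-analysed electrodes (`simulate_excluded = FALSE`).

## What passing tests do and do not show

Ground truth (`SubjectTruth`: group labels, planted amplitudes, latent
ability) is stored beside the data and read *only* by tests — the
analysis stages never see it. Parameter recovery on this generator
demonstrates that the pipeline is an unbiased, correctly wired
implementation of the stated analysis under a plausible noise model. It
does **not** validate the noise model against real infant EEG: real data
have spatially correlated backgrounds, non-stationary artifact rates,
volume-conducted effect topographies and age-dependent skull effects,
none of which are modelled. Classification accuracy and correlation
attenuation measured here are therefore best-case figures for the given
SNR, not clinical estimates.

## Problem sizes and numerical choices

Simulation studies are sized for a single CPU. The bundled acceptance
script averages 50 replicate 23-subject cohorts at default noise for the
two effect-recovery quantities (Monte-Carlo SE ≈ 0.2 µV, against
between-subject SD 6.2 µV planted per subject), and 50 noise-free
cohorts for the outcome-linkage quantities (SE ≈ 0.02 on r). The
noise-free linkage cohorts are analysed with the filter stage off and
uncompensated kernels — a coherent measurement chain in which window
means are exact, so correlation attenuation from measurement error is
zero and the per-cohort spread in r comes only from the outcome model's
own sampling noise. The test suite uses smaller replicate counts with
tolerances of three Monte-Carlo standard errors computed from the runs
themselves.

Other numerical fixtures: windows are half-open in ms and mapped to
samples by `t >= lo & t < hi`; ties in responder classification (basis
exactly 0) go to the positive group so the rule is deterministic;
orthonormal contrasts come from QR-normalized Helmert matrices (F and ε
are invariant to the choice of orthonormal basis); all randomness flows
from one integer seed through named substreams (design, one per subject,
outcomes), so adding or toggling a downstream stage can never change the
simulated data; Box–Muller normals drawn from R's uniform stream inside
the compiled noise generator keep byte-identical reproducibility under
`set.seed()`.

## Known limitations

* Channel-independent background noise understates spatial correlation;
  the EOG-correlation rejection rule is therefore somewhat easier here
  than on real data.
* An early familiarization-phase window is mentioned in the source
  literature with inconsistent endpoints ("from 40 to 20 ms"); the
  package exposes early windows only as user-configurable parameters and
  ships no default for that analysis.
* The onset detector inherits the bin grid's resolution limits discussed
  above; onsets are comparable between conditions analysed with the same
  grid, not absolute latencies.
* Whether the original analysis baseline-corrected epochs, and whether
  the left-frontal responder basis averaged all five electrodes, are not
  stated in the source; both package defaults (baseline on; all five)
  are assumptions and are configurable.
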