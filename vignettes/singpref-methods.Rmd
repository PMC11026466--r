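---
title: "Methods: acoustic analysis, rater simulation, and preference models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic analysis, rater simulation, and preference models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(singpref)
```

## The scientific question

Why do listeners prefer some singing voices over others? One hypothesis is
that preferences are grounded in objective, measurable properties of the
voice — pitch accuracy, vibrato, resonance, voice quality. The competing
hypothesis is that preferences are grounded in how listeners *perceive*
those properties, a perception that is noisy and strongly idiosyncratic.
The two hypotheses can be separated statistically: regress liking ratings
of short a cappella excerpts once on acoustic measurements of the stimuli
and once on the raters' own perceptual ratings, and compare the variance
each model explains.

`singpref` implements that full analysis chain — acoustic feature
extraction, inter-rater reliability statistics, and mixed-effects
preference models with variance decomposition — together with a synthetic
performance generator and rater simulator. The simulator gives every
stage a ground truth, so the package's claims are established by
*parameter recovery*: the extractors are tested against the generator's
known settings, the reliability statistics against brute-force oracles,
and the modeling layer against data simulated from its own family with
known variance components.

## Acoustic features

All pitch scoring works in cents relative to a reference of 261.626 Hz
(middle C): `hz_to_cents(f) = 1200 log2(f / 261.626)`; 100 cents is one
equal-tempered semitone.

**Pitch interval deviation.** Performances are segmented into notes using
a label track with half-open `[start, end)` intervals and 0-based note
indices. Each note's mean f0 is estimated from the central 80% of its
voiced frames (to avoid onset/offset glides, which bias very short
notes), with the mean taken in the cents domain so that symmetric vibrato
cancels. Successive sung intervals are compared with the notated
intervals of the melody score; the mean absolute deviation in cents is
the performance's pitch interval deviation. Singing 250 cents where the
score expects a major second (200 cents) scores 50 cents. Intervals
touching a note flagged `exclude_from_pitch` are dropped entirely — the
conservative reading when an excluded note makes both of its adjacent
intervals unreliable.

**f0 tracking** is frame-wise normalized autocorrelation (25 ms window,
10 ms hop) with parabolic peak interpolation and an octave-error guard
(the shortest lag within 85% of the best peak wins). Frames whose peak
correlation falls below 0.5 are unvoiced; white noise is >90% unvoiced
under this threshold.

**Vibrato.** On the score's designated sustained note, the f0 contour in
cents is linearly detrended and the dominant modulation in 3–9 Hz is
located on a zero-padded periodogram with parabolic interpolation; the
extent is the amplitude of a least-squares sinusoid at that rate.
*Convention:* extent is the ± excursion, i.e. half the peak-to-peak f0
swing; the generator uses the same convention, which is what makes
recovery tests well-posed. Below a 5-cent modulation floor the note is
reported as unmodulated, `(0, 0)`.

**Energy ratio** (singer's formant strength): spectral energy in
2.4–5.4 kHz divided by energy in 0–10 kHz, requiring a sample rate of at
least 20 kHz.

**Jitter and shimmer (local).** Both are cycle-to-cycle perturbation
quotients, `100 · mean|x[i+1] − x[i]| / mean(x)`, over glottal periods
and cycle amplitudes respectively. Cycle detection earned the most
numerical care in the package:

* rough boundaries are upward zero crossings of the band-passed
  fundamental (4th-order Butterworth, 0.65–1.45 f0), amplitude-gated so
  silent articulation gaps contribute no spurious cycles;
* the timing landmark is the crossing of a *quarter-period* Hann-smoothed
  waveform, interpolated to sub-sample accuracy. The landmark must sit at
  the cycle boundary: any landmark at a fractional position inside the
  cycle (e.g. the excitation peak) measures a weighted mix of adjacent
  periods and systematically shrinks jitter. The kernel must also be
  short: longer smoothers mix the per-cycle amplitude step (shimmer)
  into the crossing position and raise the jitter floor;
* cycle amplitude is the waveform's energy over the cycle normalized by
  the exact fractional period — proportional to the cycle's amplitude
  scale and immune to sample-quantized boundaries, unlike a raw peak
  sample on a pulse-like waveform.

Note-level jitter/shimmer values are pooled within each performance,
trimmed one-sidedly at mean + 2 SD (aberrant values arise on short
notes), and averaged. A single outlier among very few values can never
exceed the mean + 2 SD threshold (the maximum z-score among n values is
(n−1)/√n), so trimming is only effective with a handful of notes or more
— which is the situation it is designed for.

**HNR (0–3.5 kHz).** After a 3.5 kHz low-pass, each 40 ms frame's
normalized cross-correlation r at the f0 lag gives
`10 log10(r / (1 − r))`, averaged over periodic frames and capped at
+40 dB to keep the noiseless limit finite.

**CPP.** Per 40 ms Hamming frame the real cepstrum of the log-magnitude
spectrum is computed; the log-cepstra are *averaged across frames first*,
then the peak in the quefrency band for f0 ∈ [60, 880] Hz is measured
against a linear regression baseline over that band. Averaging before
peak-picking matters: picking a per-frame maximum over ~200 noisy
quefrency bins gives even white noise a large positive prominence, while
on the averaged cepstrum random fluctuations cancel and only a true f0
peak survives. Absolute CPP values depend on these conventions (window,
baseline, averaging order), which are configurable; the package's claims
about CPP are therefore relative (periodic ≫ noise; monotone in breath
noise), not absolute.

**Spectral tilt** (H1–H2, H1–A1/A2/A3) uses spectral peaks nearest the
harmonics and fixed formant search bands for a sung /u/ (250–600,
600–1400, 1800–3200 Hz), uncorrected for formant influence — corrected
variants are deliberately out of scope, since tilt is excluded from the
preference models for collinearity anyway. Missing harmonics yield `NA`
rather than an error.

**Loudness** follows ITU BS.1770/EBU R128: K-weighting (high-shelf +
RLB high-pass, coefficients derived analytically for the actual sample
rate), 400 ms blocks with 75% overlap, −70 LUFS absolute and −10 LU
relative gating. A full-scale 997 Hz sine measures −3.01 LUFS. All
synthesized stimuli are normalized to −14 LUFS, so loudness is a
controlled constant, not a predictor.

## The synthetic performance generator

`synthesize_performance()` is harmonic additive synthesis, not a physical
voice model: per note, a harmonic source (all harmonics to Nyquist,
≥ 20 at the default 22.05 kHz rate) with a dB/octave source slope and a
gain applied to harmonics in the 2.4–5.4 kHz singer's-formant band;
sinusoidal FM vibrato on the designated note; cycle-accurate jitter and
shimmer (period and amplitude perturbations applied cycle by cycle, with
SDs chosen so the *measured* perturbation quotients equal the nominal
percentages: for i.i.d. normal perturbations,
`E|x[i+1] − x[i]| = 2σ/√π`); additive broadband breath noise; and an
articulation gap (a silent fraction at each note's end). This carries
every feature the extractors measure while remaining fully controllable
and fast.

Population defaults emulate trained singers performing 6–9 s excerpts:
per-interval pitch error lognormal with realized median deviation near
20 cents (range roughly 5–55), vibrato 5.5 ± 0.6 Hz and ~45 cents median
extent, jitter median 0.8%, shimmer median 3%, breath noise −28 ± 4 dB,
source slope −12 ± 1.5 dB/oct, tempo 0.56 ± 0.045 s/beat (13-beat
excerpts therefore last 6.1–8.8 s). Between-take variability is not
documented anywhere authoritative, so takes re-draw tempo (±3%), vibrato
extent (±10%), jitter/shimmer (±10%) and articulation around the
singer's values; these are documented guesses exposed in
`build_stimulus_set()`.

The default melody scores approximate two well-known song excerpts — one with
a sustained octave jump as its first interval (vibrato measured on the
sustained first note, fourth note excluded from pitch scoring) and one
whistled-theme-like melody (vibrato on the sustained last note, seventh
note excluded). The true excerpts' full note lists are not published, so
these are placeholders; every scoring operation is score-driven and any
score can be supplied as JSON.

## The rater simulator and the mediation structure

The simulator's central design commitment is *mediation*: liking depends
on acoustics only through perception.

For participant *p*, stimulus *i* and scale *s*, the latent percept is

```
percept[p,i,s] = sens[p,s] · z[i,f(s)] + common[i,s] + λ · idio[p,i] + ε
```

where `z[i,f(s)]` is the standardized true value of the scale's driving
acoustic feature, `common[i,s]` is a stimulus-level percept component
shared by all raters but *not* driven by any measured feature,
`idio[p,i]` is a participant × stimulus impression shared across scales,
and ε is trial noise. Percepts are censored into the participant's used
subrange of the 1–7 scale and rounded — different raters use different
sections of the scale, which is exactly what within-participant 0–1
normalization is later meant to absorb. Liking is a weighted sum of the
censored percepts plus a singer quality offset, a participant intercept,
and residual noise, mapped into the participant's used subrange of 1–9.

Three structural choices follow from the phenomena the simulator must
reproduce, and their magnitudes were fixed once from this variance
budget:

* **Small individual-level sensitivities** (population means 0.10–0.35
  in SD units, between-participant SD 0.3). Mean ratings aggregated over
  ~40 raters then correlate with their acoustic drivers at r ≈ 0.4–0.7
  while single raters correlate weakly and heterogeneously — matching
  how group-mean perception can look acoustically grounded even when
  individual perception is mostly idiosyncratic.
* **A common non-acoustic stimulus component** (`stim_percept_sd`,
  default 0.45). Without it, mean percepts would be almost perfectly
  predictable from the features, and mean liking could not agree across
  rater panels more than acoustics explain — which is precisely the
  puzzle the analysis is designed to expose. This component flows into
  liking through the perceptual weights, is fully visible to the
  perceptual model, and is invisible to the acoustic model.
* **A modest singer quality offset** (SD 0.2). With only 16 singers,
  nine stimulus-level predictors can absorb a sizable share of
  singer-level variance by chance; a large quality offset would make the
  acoustic model's marginal R² fluctuate wildly between simulated
  datasets.

Under these defaults the perceptual mixed model's marginal R² lands
around 0.40–0.47 and the acoustic model's around 0.05–0.14, a gap of at
least 0.25 — the package's headline structural result, asserted in the
acceptance suite. Liking weights differ by melody, including an
articulation weight with opposite signs for the two melodies (legato
preferred for one, staccato for the other) and a pitch-accuracy weight
that is larger for the melody with the octave jump.

Repeat trials in the online design re-draw the liking latent with
correlation equal to the participant's `consistency` parameter (latent
shrunk toward the participant's mean and re-noised). This directly
parameterizes the test–retest statistic: simulating 200 raters with
consistency 0.8 recovers a mean test–retest r of ~0.8 (rounding and
censoring attenuate it slightly).

What the simulator does **not** emulate: naturalistic vocal timbre,
vowels or lyrics; serial-position and context effects in rating
behavior; ordinal response thresholds (the link is linear-censored);
inattentive or adversarial raters beyond the constant-rating degenerates
that `filter_participants()` removes. Passing recovery tests on these
data therefore shows the pipeline is correct and well-calibrated, not
that real voices or real raters obey the generative model.

## Reliability statistics

Ratings are normalized to [0, 1] within participant × scale
(`(x − min)/(max − min)`), after excluding degenerate raters (fewer than
3 distinct liking values; the threshold adapts to very small designs).
Exclusion happens *before* normalization — a constant rater has no
usable range to normalize by.

* **Krippendorff's α** (interval metric) is computed from all pairable
  values: within-item ordered pairs weighted by `1/(m_u − 1)` for the
  observed disagreement, all pooled pairs for the expected disagreement.
  Missing entries are allowed natively. The implementation is verified
  against a literal double-loop enumeration to 1e−12.
* **ICC(2,1)** (two-way random effects, absolute agreement, single
  rater) is computed from the classical mean squares with listwise
  deletion.
* **MM1** correlates each rater with the mean of all others, pools via
  Fisher z (with |r| clamped at 1 − 1e−12 so the pooling stays finite),
  and back-transforms. Constant raters yield `NA`, never a silent zero.

The missing-data policies differ by statistic (pairable values for α,
listwise for ICC, pairwise within each rater for MM1) because that is
standard practice for each; no single policy fits all three.

## Preference models

The model suite mirrors the experimental design the simulator emulates: a **null model** (random
intercepts for participant, singer, and stimulus nested in singer — the
stimulus identifier is unique within singer, so a plain stimulus
intercept realizes the nesting), an **acoustic model** adding nine
stimulus-level acoustic features as fixed effects, and a **perceptual
model** adding the ten perceptual ratings, melody, melody interactions
with articulation, pitch accuracy, resonance and vibrato, and a random
melody slope over participants. Predictors are mean-centered and scaled
by one sample SD. Reported fits use REML; fits entering a likelihood
ratio test are ML refits, and the LRT of the acoustic model against the
null has 9 degrees of freedom by construction.

The variance decomposition is computed in-package rather than delegated:
`var_fixed` is the variance of the fixed-effect linear predictor over
the data; each random term contributes its variance component (for the
random slope, the mean row-wise `z'Vz` over the term's model matrix);
marginal R² is `var_fixed / (var_fixed + Σ var_random + var_residual)`
and conditional R² adds the random variance to the numerator. On data
simulated from the model's own family with components in ratio 2:1:1
(fixed:random:residual), the decomposition recovers marginal 0.5 and
conditional 0.75 within ±0.05 over ten seeds at the full design size
(42 × 96).

Collinearity is screened with correlation-based VIFs on the fixed-effect
design; any VIF ≥ 5 makes `fit_mixed()` refuse unless the caller
downgrades the action to a warning (the suite does, because melody
interactions are inherently correlated with their main effects).
Singular random-effect fits are reported with a warning rather than
refused — small synthetic designs legitimately hit variance boundaries.
Wald 95% intervals accompany the coefficients.

Per-participant ordinary regressions give the "individual level of
prediction" (adjusted R², Fisher z-transformed where it enters further
modeling); the acoustic vs perceptual comparison is a paired t-test.
"Acoustic sensitivities" are each participant's correlations between
their ratings and the corresponding measurement for five
feature–scale pairs (pitch deviation ↔ pitch accuracy, BPM ↔ tempo,
loudness ↔ loudness, vibrato extent ↔ vibrato, CPP ↔ breathiness),
pooled as mean Fisher z; on normalized stimuli the loudness pair is
degenerate (the feature is constant at the target) and yields `NA` by
design. The participant-characteristics regression reduces a full model
(music sophistication, TIPI, STOMP dimensions, age, mean MM1, mean
sensitivity) by backward stepwise AIC via `stats::step` — backward-AIC
being that function's default behavior.

## Problem sizes and determinism

The test suite exercises the full reference design geometry where the claim depends
on it (42 participants × 96 stimuli for the rating simulations and
variance decomposition; a 20-performance sweep for extractor recovery;
96 rendered stimuli for loudness) and smaller geometries elsewhere;
a complete end-to-end pipeline at reduced size (2 singers, 5
participants, audio rendered and extracted) runs in a few seconds. Every
stochastic stage takes an explicit seed; `run_pipeline()` fans a single
master seed out to per-stage seeds by a fixed affine scheme, so a config
reproduces its numbers exactly. Audio synthesis with the same take seed
is bit-identical.

## Known limitations

* The cycle detector assumes a dominant fundamental; it is tuned for
  the generator's source model and for clean monophonic singing, not
  for rough or diplophonic voices.
* Jitter measurements retain a small noise floor (roughly 0.1–0.3
  percentage points at high breath-noise levels) — consistent with how
  perturbation measures behave on noisy voices generally.
* The spectral-tilt formant bands are fixed /u/ defaults, not tracked
  formants; on the vibrato note the FM slightly smears harmonic peaks.
* The simulator's linear-censored response link ignores ordinal
  threshold effects; agreement statistics on simulated data are
  therefore somewhat optimistic relative to coarse ordinal raters.
* Melody score defaults are approximations; analyses of real recordings
  should supply the actual notated scores.
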