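---
title: "Grading facial palsy from bilateral surface EMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading facial palsy from bilateral surface EMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facialEMG)
```

## Overview

`facialEMG` analyses bilateral facial surface EMG (sEMG) recorded under a
fixed MOVE/REST protocol with the goal of (a) grading facial-palsy severity
on the ordinal House–Brackmann (HB) scale and (b) identifying which
time-domain features separate movement from rest well enough to drive EMG
biofeedback. This vignette is the package's own account of the model, its
assumptions, the tunable parameters, and the limits of what the synthetic
validation can show.

## Acquisition model and protocol

The montage is six bipolar channels: forehead, eye and mouth regions on
each facial side. A run is `n_trials = 20` repetitions of a 3 s MOVE
interval followed by a 4 s REST interval at `fs_hz = 2000` Hz — 140 s and
280,000 samples. Six runs cover three instructed movements (smile, close
eyes, raise forehead) at two intensities (strong, light). Each movement
recruits one region, and the analysis restricts itself to the two channels
(left/right) of that region (`relevantChannels()`).

All of these are `ProtocolSpec` parameters and can be changed; the defaults
above are the study conditions the package assumes everywhere.

## Signal conditioning

Each channel is filtered with a 4th-order Butterworth band-pass
(10–250 Hz) and a 4th-order Butterworth band-stop (48.5–51.5 Hz) to remove
electrode drift, out-of-band noise and 50 Hz mains interference.

Design choices:

* **Zero-phase (forward–backward) application.** The analysis is offline,
  and causal filtering would delay and skew MOVE onsets relative to the
  protocol clock that drives segmentation. The amplitude consequence is
  that the effective attenuation is the *squared* single-pass response
  (−6 dB rather than −3 dB at the band edges); `filterGain()` exposes the
  single-pass response for inspection.
* **Transients.** No steady-state initialisation is attempted. The
  conditioning transient at the start of the recording overlaps the first
  trial's MOVE onset; a configurable `lead_in_s` pad exists (default 0) for
  recordings made with a pre-roll. Tests that measure filter behaviour do
  so on central windows.
* **Notch ringing.** The 3 Hz-wide band-stop has an impulse response of a
  few hundred milliseconds. A small amount of MOVE-interval energy
  therefore leaks into the beginning of each REST interval, which biases
  REST-interval asymmetry slightly away from zero for strongly asymmetric
  subjects (a few percent at most in the synthetic cohorts). A configurable
  `trim_s` guard band is available in `segmentIntervals()`; the default is
  0 (no guard band), keeping intervals exactly as the protocol defines
  them.

## Segmentation

Segmentation is purely protocol-clock-driven: no onset detection, no
artifact rejection. Sample indices are 0-based with half-open intervals
internally, so the per-channel segments partition the protocol span exactly
— concatenating them reconstructs the signal. MOVE segments have
`round(move_s * fs)` samples and REST segments `round(rest_s * fs)`
(6000 and 8000 at the defaults). `rest_first = TRUE` flips the in-trial
order for protocols that begin with rest.

## The twenty time-domain features

`extractFeatures()` computes, per interval: iEMG, MAV, MMAV1, MMAV2, SSI,
VAR, RMS, STD, WL, DASDV, AAC, LOG, IAV, VORDER, ZC, SSC, WAMP, MYOP, KURT
and SKEW. Exact definitions are in the function documentation; conventions
that genuinely vary across the myoelectric literature were fixed as
follows:

* **VAR and SSI on raw samples** (no mean subtraction): after band-pass
  conditioning the signal is zero-mean by construction, and this keeps the
  exact identities `SSI = (N−1)·VAR` and `RMS = √(SSI/N)`. STD is the
  ordinary mean-subtracted sample standard deviation (ddof 1), so STD and
  √VAR differ only through the residual mean.
* **KURT/SKEW as population moment ratios** (`m₄/m₂²`, `m₃/m₂^1.5`), not
  bias-corrected estimators; segment lengths are thousands of samples, so
  the bias correction is immaterial, and the ratio form keeps the exact
  scale invariance used in the tests. Zero-variance segments yield `NaN`
  with a warning — never a silent zero.
* **IAV as the trapezoidal integral of |x|** at unit sample spacing. iEMG
  and IAV are listed as distinct features, so they are implemented with
  genuinely distinct integration rules (rectangular vs trapezoidal); they
  differ by the half-weight of the two boundary samples.
* **VORDER with v = 3** by default: v = 2 would duplicate RMS exactly.
* **Thresholds.** ZC (5 µV), SSC (5 µV²), WAMP (10 µV) and MYOP (16 µV)
  follow common myoelectric practice; no published values exist for this
  protocol, so all are `ThresholdSpec` parameters and every analysis logs
  them. SSC additionally requires a strictly positive slope product, so a
  flat run never counts as a slope sign change even at threshold 0.
* **Completing the set.** Eighteen of the twenty features are named
  explicitly in the motivating analysis; AAC and MYOP complete the set as
  the standard time-domain companions. The canonical order is exposed by
  `featureNames()`; the set is fixed rather than pluggable — swapping a
  feature means editing `extractFeatures()` and its loop oracle in the
  tests, which is deliberate friction for a validated feature set.

Per subject, side and condition, features are aggregated as the arithmetic
mean over the run's trials (`aggregateTrials()`), with the across-trial SD
reported as dispersion. Severity statistics operate on these per-subject
means; per-trial tables are exported alongside.

## Asymmetry index

For a feature value on the healthy side `H` and lesioned side `L`:

`AI = (H − L) / (H + L) × 100`

* **Signed by default.** A lesioned side *stronger* than the healthy side
  (synkinesis, compensation) is informative, so the sign is kept. For
  feature-ranking runs the pipeline uses magnitude mode (`|H|`, `|L|`),
  because sign-crossing features (SKEW) otherwise have no meaningful AI;
  with magnitude mode off such features are refused (NA with a warning).
* **Controls have no lesioned side**; the pipeline assigns a pseudo-lesioned
  side by convention (default left, configurable). Since both sides are
  statistically identical in controls, the convention only relabels noise;
  sensitivity to it is limited to the sign of near-zero AIs.
* **Both MOVE and REST AIs are produced.** MOVE AI carries the severity
  signal; REST AI is a negative control centred near zero (up to the notch
  ringing noted above).
* A zero denominator (both sides exactly zero, e.g. count features at REST
  under aggressive thresholds) yields `NaN` with a warning, and such rows
  are dropped from ranking statistics with their `n` reported.

## Severity statistics

Subjects are grouped on the five-level ordinal used throughout:
HB I controls (0), HB I patients (1), HB II+III (2), HB IV+V (3),
HB VI (4); the raw six-level grade is retained in all metadata.

* **Fisher score** `FS = Σ nᵢ(μᵢ−μ)²/Σ nᵢσᵢ²` with *population*
  within-class variances (÷ nᵢ). The variance convention is not fixed by
  the usual formula statement, so it is explicit, documented, and
  switchable (`variance = "sample"`); the worked example FS = 4.0 for
  classes {0,1} vs {2,3} holds under the population convention. Ranked
  feature lists break Fisher-score ties lexicographically by feature name.
  The default highlight threshold for "discriminative" features is 0.2.
* **Spearman correlation** of AI with the ordinal group code, average-rank
  tie handling, two-tailed p from the t approximation. For n ≤ 8 an exact
  permutation p is available (`exact = TRUE`); beyond that the permutation
  space (n! > 40,000) buys nothing over the approximation at the cohort
  sizes this package targets.
* **MOVE-vs-REST contrast**: a paired t on per-subject (MOVE − REST) means
  with `partial_eta_sq = t²/(t²+df)`. This is the two-level within-subject
  contrast behind the headline "MOTION" effect; the full multi-factor
  repeated-measures ANOVA (multivariate statistics, sphericity
  corrections) is deliberately out of scope — with MOTION and SIDE being
  within-subject pairings and HB a between-subject grouping, the paired
  contrast answers the biofeedback question directly, and interaction-style
  questions are answered descriptively on the synthetic cohorts.
* **Multiple testing**: raw two-tailed p-values by default (matching how
  such feature screens are usually reported), with an optional, clearly
  labelled Benjamini–Hochberg column (`adjust_p = TRUE`).

## The synthetic cohort generator

Per channel the generator produces

`x(t) = e(t) · g · b(t) + n(t) + m · sin(2π·50·t + φ)`

where `b(t)` is zero-mean, unit-variance Gaussian noise band-shaped to
20–250 Hz (inside the analysis band, so conditioning does not destroy the
signal of interest); `e(t)` is the protocol envelope — `burst_amplitude`
during MOVE with 100 ms linear on/off ramps (avoiding unphysical step
onsets), 0 during REST, applied only to the movement-relevant region;
`g` is the lesioned-side attenuation; `n(t)` white baseline noise; `m` the
50 Hz mains amplitude with random phase.

Defaults, chosen once as physiologically plausible values for facial sEMG:

| parameter | default | meaning |
|---|---|---|
| `burst_amplitude` | 50 µV | healthy-side MOVE process SD |
| `baseline_noise_sd` | 2 µV | instrumentation + resting tone |
| `mains_amplitude` | 10 µV | 50 Hz interference (removed by the notch) |
| attenuation map | 1.00, 0.80, 0.55, 0.35, 0.20, 0.05 | HB I…VI lesioned-side multiplier |
| envelope ramps | 100 ms | MOVE on/off transitions |
| intensity "light" | ×0.5 | halves the burst amplitude |
| cohort jitter | sdlog 0.3 (burst), 0.2 (noise) | inter-subject amplitude variability |

No published amplitude-vs-HB relation exists, so the attenuation map is an
invented, configurable modelling choice; the only claims made of it are
structural (strictly decreasing, grade I = 1). Inter-subject log-normal
jitter emulates the large absolute-amplitude variability that motivates
normalising to the healthy side in the first place — absolute feature
values are not comparable across subjects, their asymmetry indices are.

Determinism: per-channel noise streams derive from the subject seed, the
channel and the movement (not the intensity, so a strong and a light run
of one movement differ exactly by the halved amplitude — which is also
what makes the scale-equivariance tests exact). `shared_noise = TRUE`
collapses left/right streams of each region into one, producing
sample-identical sides for symmetric profiles — the exact-symmetry test
case. Cohort generation restores the caller's RNG state.

What the generator does **not** model: motor-unit action-potential trains
(amplitude-modulated Gaussian noise is the stated model), synkinetic
co-activation (the `fars` profile flag is reserved and generation refuses
it), electrode impedance, inter-channel cross-talk, movement artifacts, or
imperfect protocol compliance. Consequently, passing the cohort-level tests
shows that the *pipeline* recovers the structure the model encodes —
monotone severity, MOVE/REST separability, amplitude-over-shape feature
ranking — not that real facial EMG satisfies that model.

## Numerical and degenerate-input policy

* Filters are designed per recording rate; band edges at or above Nyquist
  are errors. At low sampling rates (< ~560 Hz) the generator clips its
  burst band below Nyquist.
* EDF storage is 16-bit: round trips are exact to the per-channel
  quantisation step (physical range / 65535). Delimited-text round trips
  are exact.
* Zero-variance segments: `NaN` KURT/SKEW with a warning. Zero AI
  denominators: `NaN` with a warning. Zero-variance paired differences:
  degenerate contrast flag (all-zero differences report t = 0, η²ₚ = 0).
* Segmentation refuses recordings shorter than the protocol span, naming
  the number of missing samples.

## Problem sizes used for validation

The cohort-level tests use 5 HB groups × 10 subjects with two strong
movement runs each (100 full 280,000-sample recordings) under a fixed
master seed — large enough that the Spearman/Fisher assertions are stable,
small enough to run routinely. Unit tests use shortened protocols
(2–5 trials, 0.5–1 s intervals, 500–1000 Hz) except where the contract is
about the default protocol itself.

## Known limitations

* The attenuation map and all generator amplitudes are synthetic stand-ins;
  none of the quantitative AI values produced here validate against
  clinical data.
* REST-interval asymmetry is slightly biased by notch ringing (see above)
  rather than exactly centred at zero.
* The exact identity of two of the twenty features in the motivating
  feature set is not documented there; AAC and MYOP are this package's
  completion choice.
* Only the two-level MOVE/REST contrast is implemented; users needing the
  full repeated-measures decomposition should export the per-subject
  aggregated tables and fit it in a dedicated ANOVA tool.
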