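---
title: "Models and methods behind neonirs"
author: "neonirs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neonirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`neonirs` implements, end to end, the analysis workflow of an event-related
fNIRS study of rapid auditory learning in neonates: three participant
groups (experimental, active control, passive control; default sizes
22/23/21), three test phases (T0 baseline, T1 immediately post-training, T2
after a two-hour consolidation period), 52 optical channels sampled at
10 Hz with two wavelengths (760/850 nm), and per test session 12 forward
plus 12 backward 6-second vowel trials separated by 12-16 s silent
intervals, preceded by a 3-minute resting window. Because no recordings of
this design are publicly deposited, the package is built around a
synthetic-data generator that emulates the design with a plantable effect
structure, so every analysis stage has a recoverable target. The repository
is organized as an analysis workflow: the numbered drivers under
`analysis/` narrate one demonstration run, while all computation lives in
the package so that tests and the verification script exercise the same
code paths.

# Signal model

## Haemodynamic responses

The generator uses a gamma-density response kernel (`hrf_kernel()`)
normalized to attain its `amplitude` exactly at `peak_time` (default 8 s)
with a scale/dispersion parameter (default 1 s). A parametric kernel —
rather than a fixed canonical adult shape — is used deliberately: infant
haemodynamic timing varies, and the analysis itself makes no HRF
assumption (it summarizes each trial by its 6-16 s mean amplitude and its
peak latency). The default kernel places essentially all response energy
inside the 6-16 s post-onset window and decays below 1% of its peak by
20 s, so the epoching window (-2..20 s) captures the full response.

Each simulated session superimposes one kernel per scheduled trial. The
cell parameters (amplitude and peak time per group x phase x stimulus) are
taken from a `ground_truth()` object, split into a `base` value shared by
all channels and an `effect` increment applied to a configurable channel
set, so region-specific learning effects can be planted. The canonical
defaults (`default_ground_truth()`) are a 1 umol/l evoked response
everywhere; +0.5 umol/l for forward trials of the experimental group at T2
over temporo-parietal channels {7, 10, 19, 25, 37, 45}; a -1.5 s peak
shift for forward trials of the experimental group at T1 and T2 over
inferior frontal channels {2, 6, 16, 43, 44}; and a +0.2 resting
correlation increment at T2 for both trained groups on pairs among the
fronto-temporal channels. The deoxyhaemoglobin trace is modelled as
-0.3 times the oxy trace delayed by 1 s — a qualitative mirror-image
coupling; its magnitude carries no analysis weight.

## Noise

`noise_spec()` defines additive noise on the oxy trace, in concentration
units, before the forward optical model: a slow drift (linear slope plus a
~0.005 Hz oscillation), three sinusoidal physiological oscillators with
slowly wandering phase (cardiac ~2.5 Hz, respiratory ~0.7 Hz, Mayer waves
~0.1 Hz), white measurement noise, brief spike "jumps" (0.5/min, 3-6
umol/l, 1-3 samples), and large slow motion artifacts (half-sine bumps of
2-5 s). Artifact amplitudes (15-40 umol/l) are calibrated so that, after
conversion to intensity, they exceed 20% of the device dynamic range — the
preprocessing rejection rule — while spikes stay below it but above the
6-robust-s.d. spike-detection threshold. The artifact rate (0.33 events
per minute per channel, scaled per subject by a lognormal multiplier with
sigma 0.6) was chosen so that artifact-epoch masking removes on average
roughly 18% +- 8% of trial x channel cells across subjects, the
data-loss regime the preprocessing is expected to operate in.

## Optics

The forward modified Beer-Lambert model maps concentrations to optical
densities, `OD_l = (e_l,HbO dHbO + e_l,Hb dHb) d DPF_l`, and intensities
`I = i0 b^-OD` (base 10 by default). Default extinction coefficients are
standard literature values for 760/850 nm, DPF 5.0 at both wavelengths,
source-detector distance 2.3 cm; all are configurable, and the pipeline
asserts only forward/inverse consistency, never the constants themselves.
The OD conversion on the analysis side references each channel's mean
intensity — the convention for relative concentration changes — so
recovered concentrations are defined up to a per-channel constant; the
high-pass filter removes that constant, and exact round-trip checks use a
known reference intensity instead.

## Resting-state generator

`simulate_resting()` draws white noise per channel, low-pass filters it at
0.2 Hz, and mixes it through the Cholesky factor of the target correlation
matrix (base correlation plus the cell's planted increments, projected to
the positive-semidefinite cone with a unit diagonal). The planted
correlation is therefore a property of the band-limited haemodynamic
process; added physiological components are deliberately out-of-band
(cardiac, respiration) plus white noise, so the raw-series correlation is
attenuated only a few percent and the analysis band-pass essentially
restores the target. The unbiasedness check in the test suite accordingly
measures the noiseless process; the noisy single-window check uses the
wider sampling-error tolerance.

# Preprocessing

`run_preprocessing()` applies, in this order, and logs exactly six steps:

1. **Saturation screen** — a channel is excluded when either wavelength
   sits pinned at the dynamic-range maximum for >= 10 consecutive samples.
   The screen looks for values clipped *at* the maximum; simulated data
   with clipping disabled therefore yield zero flags by construction.
2. **Artifact-epoch masking** — on the trial epoch grid (-2..20 s), a
   trial x channel cell is masked when peak-to-peak intensity exceeds 20%
   of the dynamic-range width. The rule operates on device-input
   intensity, and masking is monotone in the threshold. For recordings
   without events the grid tiles the recording.
3. **Spike correction** — sliding 1-s windows whose peak-to-peak exceeds
   6 robust standard deviations (median absolute deviation x 1.4826 over
   the valid samples, computed after masking) are flagged; flagged spans
   are replaced by linear interpolation between the surrounding clean
   samples, with hold-extrapolation (and a log entry) at the recording
   boundary. Clean data pass through bit-identically.
4. **OD conversion** — `-log10(I / mean(I))` per channel and wavelength;
   non-positive samples are masked, not propagated.
5. **Band-pass** — zero-phase (forward-backward) 3rd-order Butterworth,
   0.01-0.2 Hz. Cutoffs are pre-warped by `(sqrt(2)-1)^(1/6)` so the
   *two-pass* -3 dB points land on the nominal edges; without this the
   0.15 Hz edge of the passband loses ~1.4 dB and the filter misses its
   <1 dB ripple specification. Odd-reflection padding (one high-pass time
   constant long) suppresses edge transients.
6. **MBLL inversion** — per-channel 2x2 solve to Δ[HbO]/Δ[Hb] in umol/l.

# Trial features

Epochs span -2..20 s around each onset (221 samples at 10 Hz); trials
whose window overruns the recording are dropped and logged — because the
generator appends a final 12-16 s ITI, a session occasionally contributes
23 of its 24 trials. A channel is valid within an epoch only if none of
its samples are masked (all-or-none retention; no partial-epoch features).
Baseline correction subtracts the pre-stimulus [-2, 0) s mean and is
idempotent. Mean amplitude averages Δ[HbO] over 6-16 s with both endpoints
inclusive (a bit-reproducibility convention). Peak latency is the time of
the maximum sample within [0, 20] s — the pre-stimulus segment is excluded
by default because a baseline maximum is physiologically meaningless,
configurable to the full epoch — with ties broken to the earliest sample
at 0.1 s resolution.

# Statistical models

## Contrast coding

Stimulus type: backward -1/2, forward +1/2. Group, Helmert pair:
(passive -2/3, active +1/3, experimental +1/3) and (passive 0, active
-1/2, experimental +1/2). Phase, Helmert pair: (T0 -2/3, T1 +1/3, T2
+1/3) and (T0 0, T1 -1/2, T2 +1/2). All five columns are centred on their
observed means, and the 12 between-factor interaction columns are products
of the centred columns (no within-factor products), giving 17 slopes plus
the intercept. Under a balanced design the columns are mutually
orthogonal, which gives the key identity used by the tests: planting a
forward-backward difference `d` in the experimental group at T2 alone
implies a stimulus x group-2 x phase-2 coefficient of exactly `d`. Note
the betas are scale-dependent: a different (but equivalent) Helmert
scaling would rescale them.

## Mixed models

Both trial-level analyses fit, by REML via `lme4` with Satterthwaite
degrees of freedom via `lmerTest`, the 17-term fixed design with
uncorrelated random effects: by participant, the intercept plus the
within-subject terms (stimulus, the two phase contrasts, and their
products with stimulus — between-participant contrasts cannot vary within
a participant); by channel, the intercept plus every fixed term
("maximal"). Random-effect correlations are omitted to aid convergence;
singular fits are returned and flagged rather than failing, with variance
components estimated at zero left at zero. The critical terms are
stimulus x group-2 x phase-2 for mean amplitude (learning expressed after
consolidation) and stimulus x group-2 x phase-1 for peak latency
(learning expressed immediately after training).

Channel-level inference is provided along both routes: BLUPs (fixed beta
plus per-channel conditional mode, with complete shrinkage to the fixed
effect when the slope variance collapses) and per-channel refits with
participant random effects only, which emit the per-channel report rows
(channel, region, beta, sem, df, t, p). The refits are the default seed
-selection route. Seed channels are the union, across the two analyses, of
channels surviving Benjamini-Hochberg FDR at q* = 0.15 on the per-channel
p-values of each critical term; q* is configurable (0.05 and 1 are the
standard sensitivity settings).

## Connectivity

Resting windows are the exact 1800 samples (3 min at 10 Hz) ending at
each test onset. Pearson correlations are computed between the band-passed
Δ[HbO] series of every seed pair (pairs with at least one seed member;
7 seeds among 52 channels give 7x51 - 7x6/2 = 336 pairs), dropping masked
samples pairwise, and Fisher z-transformed. The reduced mixed model drops
all stimulus terms (no stimuli at rest): fixed effects are the four group
and phase contrasts plus their four products; random effects are, by
participant, intercept and phase terms and, by channel pair, intercept
and all fixed terms, uncorrelated. Per-pair tests refit the reduced model
within each pair (participant random effects only) and report the
group-1 x phase-2 interaction at uncorrected alpha = 0.05 with a sign
split. The display threshold for network summaries is the absolute value
of the most negative mean-z edge of the experimental group at T0 (zero
when no negative edge exists); "at rest" is read as the baseline resting
window, configurable.

# Calibration studies and their scale

The repeated estimator-calibration studies run at a reduced scale chosen
to finish in minutes on one CPU: 100 replicates of 8 subjects/group, 8
channels and 12 trials/condition for amplitude-effect recovery and
coverage; 200 replicates under the null for the type-I error rate; 100
replicates of 6 subjects/group, 10 channels and 3 seeds for connectivity
recovery. These studies generate data directly at the feature level
(`simulate_feature_table()`, `simulate_pair_table()`) from the mixed
model's own generative process — subject and channel random effects plus
trial noise around the planted coefficient — because signal-level
simulation adds nothing to what they test and would multiply the cost a
hundredfold. Their fits use the random structure that matches the
generative process (subject intercept + stimulus slope, channel
intercept): the full per-term by-channel structure costs minutes per fit
at this scale, and fitting a correctly-specified model is precisely what
a coverage calibration requires. Simulation noise levels (residual s.d.
0.3 umol/l against planted effects of 0.1-0.3) were fixed once so that
the design has adequate precision for a 100-replicate bias check.

The demonstration pipeline configuration (4 subjects/group, 12 channels,
6 trials/condition) uses the by-channel intercept structure; the maximal
structure remains the default for study-scale analyses.

# What the generator does and does not emulate

It emulates the session structure, sampling, montage metadata, plantable
group x phase x stimulus effects on amplitude, latency and resting
connectivity, and the major noise families including device-scale motion
artifacts. It does not model photon transport through tissue (a single
global DPF stands in for wavelength- and region-specific path lengths),
non-stationary sleep-state physiology, the 5-hour training exposure
itself (represented only through the planted ground-truth differences
between phases), spatially correlated motion across channels, or real
scalp-coupling drift. Passing tests therefore demonstrate that the
analysis code recovers what it claims under the stated assumptions — not
that those assumptions exhaust real neonatal data.

# Known limitations

- The latency response is analysed with the same linear model as
  amplitude although latencies are bounded within the epoch; at the
  planted effect sizes this truncation is negligible, but it would bias
  extreme shifts.
- Satterthwaite degrees of freedom are approximate under singular fits;
  the package falls back to the normal approximation (df = Inf, with a
  warning) only when the computation is unavailable.
- Undefined correlations (constant channels) are excluded pairwise with a
  logged count; a montage-wide dead channel will silently shrink the pair
  set rather than fail.
- The dataset layout keeps full-precision text; at the full study scale
  (66 subjects x 3 phases x 52 channels) a dataset is ~1 GB of TSV and is
  better simulated in memory per subject, as `run_pipeline()` does.
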