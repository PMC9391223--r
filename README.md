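# neonirs

Event-related fNIRS analysis of rapid auditory learning in neonates — as a
tested, reusable R pipeline with a synthetic-data generator, so every stage
can be verified without access to clinical recordings.

The scientific setting: three groups of newborns (experimental, active
control, passive control) are tested at three phases (T0 baseline, T1
immediately after a 5-hour exposure to forward/backward vowel strings, T2
after a 2-hour consolidation sleep) while 52 optical channels record
two-wavelength (760/850 nm) intensities at 10 Hz. Each 8-minute test
presents 12 forward and 12 backward 6-s vowel trials with 12-16 s silent
intervals, preceded by a 3-minute resting window. The analysis asks whether
trained neonates discriminate forward from backward vowels — expressed as a
stimulus x group x phase interaction on the evoked oxyhaemoglobin response
— and whether training reshapes resting-state functional connectivity.

## What the package computes

1. **Synthetic studies** (`simulate_study()`): raw intensity recordings
   with plantable group x phase x stimulus effects on response amplitude,
   response latency and inter-channel resting correlations, plus
   physiological noise, spikes and motion artifacts.
2. **Preprocessing** (`run_preprocessing()`): saturation screen; removal of
   epochs whose peak-to-peak intensity exceeds 20% of the device dynamic
   range; spike correction (peak-to-peak > 6 robust s.d., linear
   interpolation); conversion to optical density; zero-phase 0.01-0.2 Hz
   Butterworth band-pass; modified Beer-Lambert inversion to Δ[HbO]/Δ[Hb]
   (μmol/l):

   `ΔOD_λ(t) = (ε_λ,HbO·Δ[HbO] + ε_λ,Hb·Δ[Hb]) · d · DPF_λ`

3. **Trial features** (`build_feature_table()`): epochs of -2..20 s,
   baseline-corrected on [-2, 0) s; mean Δ[HbO] amplitude over 6-16 s and
   peak latency (earliest-tie argmax over 0-20 s) per trial x channel.
4. **Mixed-effects inference** (`run_amplitude_analysis()`,
   `run_latency_analysis()`): centred Helmert/sum contrasts — stimulus
   (±1/2), group (passive vs trained: -2/3/+1/3; active vs experimental:
   ∓1/2), phase (T0 vs post: -2/3/+1/3; T1 vs T2: ∓1/2) — full factorial
   fixed effects, uncorrelated by-participant and by-channel random
   effects (REML, lme4), Satterthwaite tests (lmerTest), per-channel
   BLUPs and refits, Benjamini-Hochberg seed selection at q* = 0.15.
5. **Connectivity** (`fit_connectivity_lmm()`, `per_pair_tests()`):
   Pearson r between seed-pair Δ[HbO] series in the 1800-sample pre-test
   windows, Fisher z = artanh(r), the reduced group x phase mixed model,
   per-pair tests at α = 0.05, and thresholded network summaries.

## Worked example

The numbered drivers under `analysis/` run a demonstration-scale study
(4 subjects/group, 12 channels, 6 trials per stimulus type) end to end
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # raw dataset (TSV + JSON layout)
Rscript analysis/02_preprocess.R     # preprocessing + trial features
Rscript analysis/03_fit_amplitude.R  # amplitude mixed model + FDR channels
Rscript analysis/04_fit_latency.R    # latency mixed model + FDR channels
Rscript analysis/05_connectivity.R   # resting-state connectivity
Rscript analysis/06_run_all.R        # the same, as one reproducible run
```

With the default seed this prints, along the way:

```
artifact masking removed 17.4% +- 4.9% of epoch cells
amplitude three-way interaction: beta = 0.303 umol/l, sem = 0.069, t(9.1) = 4.36, p = 0.00175
latency three-way interaction: beta = -1.774 s, sem = 0.208, t(3025.8) = -8.52, p = 2.52e-17
group-1 x phase-2 interaction on z: beta = 0.068, sem = 0.037, t(9.0) = 1.85, p = 0.0967
```

Reading these numbers: the generator planted a +0.5 μmol/l forward-response
gain for the experimental group at T2; after band-pass filtering and
6-16 s averaging that corresponds to a three-way coefficient near 0.3
μmol/l on the coding scale, which the amplitude model recovers. The
planted -1.5 s latency shift at T1/T2 appears in the latency model's
stimulus x group-2 x phase-1 coefficient. The connectivity increment is
planted only on pairs among four channels, so the model-wide group-1 x
phase-2 coefficient is diluted accordingly at demonstration scale.

The same computation is available in one call:

```r
library(neonirs)
res <- run_pipeline(demo_config(), seed = 1)
res$amplitude$fit            # full coefficient table
res$connectivity$seeds       # FDR-selected seed channels
```

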