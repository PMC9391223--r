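#' Physiological and instrumental noise specification
#'
#' Parameters of the additive noise model used by the generator, expressed
#' in concentration units (umol/l) on the oxyhaemoglobin trace before the
#' forward optical model maps them to device intensities. Components:
#' slow drift (linear slope plus a very-low-frequency oscillation),
#' sinusoidal physiological oscillators (cardiac ~2.5 Hz, respiratory
#' ~0.7 Hz, Mayer waves ~0.1 Hz) with slowly wandering phase, white
#' measurement noise, brief spike "jumps", and large slow motion artifacts
#' whose amplitude is calibrated to exceed 20% of the device dynamic range
#' after conversion to intensity.
#'
#' @param drift_amplitude amplitude of the ~0.005 Hz drift oscillation, umol/l
#' @param drift_slope_sd s.d. of the per-channel linear drift slope,
#'   umol/l per s
#' @param oscillators data.frame (freq_hz, amplitude, phase_jitter); all
#'   frequencies must be below the Nyquist frequency
#' @param white_noise_sd white noise s.d., umol/l
#' @param spike_rate spikes per minute per channel
#' @param spike_amplitude length-2 range of |spike| amplitude, umol/l
#' @param artifact_rate motion artifacts per minute per channel
#' @param artifact_amplitude length-2 range of |artifact| amplitude, umol/l
#' @param artifact_duration length-2 range of artifact duration, s
#' @param subject_artifact_sd lognormal s.d. of the per-subject artifact-rate
#'   multiplier (captures between-subject spread in data loss)
#' @export
noise_spec <- function(drift_amplitude = 0.25, drift_slope_sd = 0.001,
                       oscillators = data.frame(
                         freq_hz = c(2.5, 0.7, 0.1),
                         amplitude = c(0.1, 0.15, 0.25),
                         phase_jitter = c(0.1, 0.1, 0.05)),
                       white_noise_sd = 0.1,
                       spike_rate = 0.5, spike_amplitude = c(3, 6),
                       artifact_rate = 0.33,
                       artifact_amplitude = c(15, 40),
                       artifact_duration = c(2, 5),
                       subject_artifact_sd = 0.6) {
  amps <- c(drift_amplitude, oscillators$amplitude, white_noise_sd,
            spike_amplitude, artifact_amplitude)
  if (any(amps < 0)) stop("noise amplitudes must be >= 0")
  if (any(oscillators$freq_hz >= 5)) {
    stop("oscillator frequencies must be < 5 Hz (Nyquist at 10 Hz)")
  }
  structure(list(drift_amplitude = drift_amplitude,
                 drift_slope_sd = drift_slope_sd,
                 oscillators = oscillators,
                 white_noise_sd = white_noise_sd,
                 spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 artifact_duration = artifact_duration,
                 subject_artifact_sd = subject_artifact_sd),
            class = "noise_spec")
}

#' Ground-truth effect structure for a simulated study
#'
#' Defines the per-cell (group x phase x stimulus) evoked-response
#' parameters and the resting-state connectivity targets that the
#' generator plants and the analysis pipeline is expected to recover.
#' Amplitude and latency cells are split into a `base` value shared by all
#' channels and an `effect` increment applied only at the listed channels,
#' so region-specific learning effects can be planted.
#'
#' @param amp_cells data.frame (group, phase, stimulus, base, effect):
#'   evoked peak Delta-HbO amplitude, umol/l
#' @param amp_channels channel ids receiving the amplitude `effect`
#' @param lat_cells data.frame (group, phase, stimulus, base, effect):
#'   response peak time, s
#' @param lat_channels channel ids receiving the latency `effect`
#' @param dispersion kernel dispersion, s
#' @param conn_base baseline inter-channel resting correlation
#' @param conn_cells data.frame (group, phase, increment): correlation
#'   increments planted on `conn_pairs`
#' @param conn_pairs two-column matrix of channel-id pairs receiving the
#'   connectivity increments
#' @param noise a [noise_spec()]
#' @param hb_ratio,hb_delay deoxyhaemoglobin model: dHb is `hb_ratio` times
#'   dHbO delayed by `hb_delay` s
#' @param resting_sd s.d. of the band-limited resting signal, umol/l
#' @export
ground_truth <- function(amp_cells, amp_channels = integer(),
                         lat_cells, lat_channels = integer(),
                         dispersion = 1,
                         conn_base = 0.2, conn_cells = NULL,
                         conn_pairs = NULL, noise = noise_spec(),
                         hb_ratio = -0.3, hb_delay = 1, resting_sd = 0.5) {
  need <- c("group", "phase", "stimulus", "base", "effect")
  stopifnot(all(need %in% names(amp_cells)), all(need %in% names(lat_cells)))
  peak <- lat_cells$base + lat_cells$effect
  if (any(peak <= 0) || any(peak > 20)) {
    stop("latency cells must keep the response peak inside the epoch window")
  }
  structure(list(amp_cells = amp_cells, amp_channels = amp_channels,
                 lat_cells = lat_cells, lat_channels = lat_channels,
                 dispersion = dispersion, conn_base = conn_base,
                 conn_cells = conn_cells, conn_pairs = conn_pairs,
                 noise = noise, hb_ratio = hb_ratio, hb_delay = hb_delay,
                 resting_sd = resting_sd),
            class = "ground_truth")
}

study_cells <- function(groups = c("experimental", "active", "passive"),
                        phases = c("T0", "T1", "T2"),
                        stimuli = c("forward", "backward")) {
  expand.grid(group = groups, phase = phases, stimulus = stimuli,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Default study ground truth
#'
#' The canonical planted-effect structure: every cell evokes a 1 umol/l
#' response peaking at 8 s; the experimental group's forward trials gain
#' +0.5 umol/l at T2 over temporo-parietal channels (the amplitude
#' learning-by-consolidation effect) and peak 1.5 s earlier at T1 and T2
#' over inferior frontal channels (the latency learning effect); resting
#' connectivity sits at r = 0.2 everywhere and gains +0.2 at T2 in both
#' trained groups on pairs among the fronto-temporal channels.
#'
#' @param montage montage from [make_montage()]; for the 52-channel layout
#'   the canonical region channel sets are used, otherwise effects apply to
#'   all channels (pairs among the first four channels for connectivity)
#' @param amp_effect,lat_effect,conn_increment planted effect sizes
#' @param noise a [noise_spec()]
#' @export
default_ground_truth <- function(montage = make_montage(),
                                 amp_effect = 0.5, lat_effect = -1.5,
                                 conn_increment = 0.2,
                                 noise = noise_spec()) {
  nch <- nrow(montage)
  cells <- study_cells()
  amp_cells <- cbind(cells, base = 1.0, effect = 0)
  amp_cells$effect[with(amp_cells, group == "experimental" &
                          phase == "T2" & stimulus == "forward")] <- amp_effect
  lat_cells <- cbind(cells, base = 8.0, effect = 0)
  lat_cells$effect[with(lat_cells, group == "experimental" &
                          phase %in% c("T1", "T2") &
                          stimulus == "forward")] <- lat_effect
  conn_cells <- data.frame(group = c("experimental", "active"),
                           phase = "T2", increment = conn_increment,
                           stringsAsFactors = FALSE)
  if (nch == 52L) {
    amp_channels <- c(7L, 10L, 19L, 25L, 37L, 45L)
    lat_channels <- c(2L, 6L, 16L, 43L, 44L)
    conn_set <- c(2L, 6L, 7L, 10L, 25L, 43L, 44L, 45L)
  } else {
    amp_channels <- seq_len(nch)
    lat_channels <- seq_len(nch)
    conn_set <- seq_len(min(4L, nch))
  }
  conn_pairs <- t(utils::combn(conn_set, 2))
  ground_truth(amp_cells = amp_cells, amp_channels = amp_channels,
               lat_cells = lat_cells, lat_channels = lat_channels,
               conn_cells = conn_cells, conn_pairs = conn_pairs,
               noise = noise)
}

gt_cell <- function(cells, group, phase, stimulus) {
  row <- cells[cells$group == group & cells$phase == phase &
                 cells$stimulus == stimulus, , drop = FALSE]
  if (nrow(row) != 1) {
    stop(sprintf("no ground-truth cell for (%s, %s, %s)",
                 group, phase, stimulus))
  }
  row
}
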