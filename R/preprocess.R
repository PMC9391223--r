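#' Detector saturation screen
#'
#' Flags a channel when either wavelength's intensity sits pinned at the
#' device dynamic-range maximum (the clipped value) for at least
#' `run_length` consecutive samples. Flagged channels are excluded from
#' all downstream stages.
#'
#' @param raw a [raw_recording()]
#' @param run_length minimum saturated run, samples
#' @return logical vector, one flag per channel
#' @export
screen_saturation <- function(raw, run_length = 10L) {
  top <- raw$dynamic_range[2]
  d <- dim(raw$intensity)
  flags <- logical(d[1])
  for (ch in seq_len(d[1])) {
    for (wl in 1:2) {
      at_max <- abs(raw$intensity[ch, wl, ] - top) <= 1e-9 * abs(top)
      r <- rle(at_max)
      if (any(r$values & r$lengths >= run_length)) flags[ch] <- TRUE
    }
  }
  flags
}

# trial-epoch sample grid; falls back to tiling when there are no events
epoch_grid <- function(raw, epoch_window = c(-2, 20)) {
  n <- n_samples(raw)
  fs <- raw$fs
  if (!is.null(raw$events) && nrow(raw$events) > 0) {
    lapply(seq_len(nrow(raw$events)), function(e) {
      i0 <- round(raw$events$onset[e] * fs) + 1L
      idx <- i0 + seq(round(epoch_window[1] * fs), round(epoch_window[2] * fs))
      idx[idx >= 1L & idx <= n]
    })
  } else {
    w <- round(diff(epoch_window) * fs)
    starts <- seq(1L, n, by = w)
    lapply(starts, function(s) s:min(n, s + w - 1L))
  }
}

#' Mask artifact-contaminated epochs
#'
#' An epoch x channel cell is masked when the peak-to-peak intensity within
#' the trial epoch (at either wavelength) exceeds `fraction` of the device
#' dynamic-range width. Masking operates on the device-input intensity
#' scale. Returns the recording with its validity mask updated and the
#' removed data fraction recorded.
#'
#' @param raw a [raw_recording()]
#' @param fraction peak-to-peak threshold as a proportion of the dynamic
#'   range width (default 0.2)
#' @param epoch_window trial epoch bounds relative to onset, s
#' @return the recording, with `mask` and `removed_fraction` set
#' @export
remove_artifact_epochs <- function(raw, fraction = 0.2,
                                   epoch_window = c(-2, 20)) {
  grid <- epoch_grid(raw, epoch_window)
  if (!length(grid)) stop("empty epoch grid")
  d <- dim(raw$intensity)
  if (is.null(raw$mask)) raw$mask <- matrix(TRUE, d[1], d[3])
  thr <- fraction * diff(raw$dynamic_range)
  removed <- 0L
  total <- 0L
  for (idx in grid) {
    if (length(idx) < 2) next
    for (ch in seq_len(d[1])) {
      total <- total + 1L
      pp <- max(
        diff(range(raw$intensity[ch, 1, idx])),
        diff(range(raw$intensity[ch, 2, idx]))
      )
      if (pp > thr) {
        raw$mask[ch, idx] <- FALSE
        removed <- removed + 1L
      }
    }
  }
  raw$removed_fraction <- removed / max(1L, total)
  raw$log <- c(raw$log,
               sprintf("remove_artifact_epochs: fraction=%g, removed %.1f%% of epoch cells",
                       fraction, 100 * raw$removed_fraction))
  raw
}

# rolling peak-to-peak over a w-sample window (positions 1..n-w+1)
rolling_pp <- function(x, w) {
  n <- length(x)
  if (w >= n) return(diff(range(x)))
  E <- stats::embed(x, w)  # rows are reversed windows, newest first
  apply(E, 1, max) - apply(E, 1, min)
}

#' Detect and correct spike jumps
#'
#' Sliding-window peak-to-peak excursions exceeding `sd_threshold` robust
#' standard deviations (median absolute deviation x 1.4826, computed over
#' the valid samples of the recording) are flagged and the affected span is
#' replaced by linear interpolation between the last clean sample before
#' and the first clean sample after. Spans touching the recording boundary
#' are hold-extrapolated and logged. The operation is idempotent on clean
#' data and never alters samples outside flagged spans.
#'
#' @param raw a [raw_recording()]
#' @param sd_threshold peak-to-peak threshold in robust s.d. units
#' @param window_s sliding window length, s
#' @return the recording with corrected intensities and a spike log
#' @export
correct_spikes <- function(raw, sd_threshold = 6, window_s = 1) {
  d <- dim(raw$intensity)
  fs <- raw$fs
  w <- max(2L, round(window_s * fs))
  if (w < 2) stop("window_s must span at least 2 samples")
  n <- d[3]
  mask <- if (is.null(raw$mask)) matrix(TRUE, d[1], n) else raw$mask
  n_spikes <- 0L
  boundary <- 0L
  for (ch in seq_len(d[1])) {
    for (wl in 1:2) {
      x <- raw$intensity[ch, wl, ]
      rsd <- stats::mad(x[mask[ch, ]], constant = 1.4826)
      if (!is.finite(rsd) || rsd <= 0 || !is.finite(sd_threshold)) next
      pp <- rolling_pp(x, w)
      hot <- which(pp > sd_threshold * rsd)
      if (!length(hot)) next
      flag <- logical(n)
      for (i in hot) flag[i:min(n, i + w - 1)] <- TRUE  # window i..i+w-1
      runs <- rle(flag)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        n_spikes <- n_spikes + 1L
        if (starts[r] == 1L || ends[r] == n) boundary <- boundary + 1L
      }
      keep <- which(!flag)
      if (length(keep) >= 2) {
        x[flag] <- stats::approx(keep, x[keep], xout = which(flag),
                                 rule = 2)$y
        raw$intensity[ch, wl, ] <- x
      }
    }
  }
  raw$log <- c(raw$log,
               sprintf("correct_spikes: threshold=%g sd, window=%gs, corrected %d spans (%d at boundary)",
                       sd_threshold, window_s, n_spikes, boundary))
  raw
}

# zero-phase Butterworth band-pass with odd-reflection padding; cutoffs are
# pre-warped so the two-pass -3 dB points land on (low, high)
butter_bandpass <- function(x, low, high, fs, order = 3) {
  n <- length(x)
  if (n < 30) stop("series too short for band-pass filtering")
  corr <- (sqrt(2) - 1)^(1 / (2 * order))
  wc <- c(low * corr, high / corr) / (fs / 2)
  bf <- signal::butter(order, wc, type = "pass")
  pad <- min(n - 1, round(fs / low))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter a multichannel series
#'
#' Zero-phase (forward-backward) 3rd-order Butterworth band-pass applied to
#' each row. Cutoffs are corrected for the double pass so the effective
#' -3 dB band edges equal `low` and `high`; odd-reflection padding
#' suppresses edge transients. Passband components keep their peak times
#' (zero phase).
#'
#' @param x numeric matrix (series in rows) or an `od_series`
#' @param low,high band edges, Hz
#' @param fs sampling rate, Hz (taken from the object when available)
#' @export
bandpass <- function(x, low = 0.01, high = 0.2, fs = 10) {
  if (fs <= 2 * high) stop("sampling rate must exceed twice the high cutoff")
  if (inherits(x, "od_series")) {
    for (wl in 1:2) {
      m <- matrix(x$od[, wl, ], nrow = dim(x$od)[1])
      x$od[, wl, ] <- t(apply(m, 1, butter_bandpass, low = low, high = high,
                              fs = x$fs))
    }
    x$log <- c(x$log, sprintf("bandpass: %g-%g Hz zero-phase Butterworth",
                              low, high))
    return(x)
  }
  x <- as.matrix(x)
  t(apply(x, 1, butter_bandpass, low = low, high = high, fs = fs))
}

#' Run the full preprocessing chain
#'
#' Applies, in order: saturation screen, artifact-epoch masking, spike
#' correction, intensity-to-optical-density conversion, band-pass
#' filtering, and the modified Beer-Lambert inversion. The provenance log
#' of the returned series lists exactly these six steps with their
#' parameters.
#'
#' @param raw a [raw_recording()]
#' @param params [mbll_params()]
#' @param config list of stage parameters; recognized fields:
#'   `saturation_run_length` (10), `artifact_fraction` (0.2),
#'   `epoch_window` (c(-2, 20)), `spike_sd` (6), `spike_window_s` (1),
#'   `band` (c(0.01, 0.2); NULL disables filtering), `distance` (2.3 cm)
#' @return a [hemo_series()] with mask and provenance log
#' @export
run_preprocessing <- function(raw, params = mbll_params(), config = list()) {
  defaults <- list(saturation_run_length = 10L, artifact_fraction = 0.2,
                   epoch_window = c(-2, 20), spike_sd = 6,
                   spike_window_s = 1, band = c(0.01, 0.2), distance = 2.3)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown preprocessing config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  d <- dim(raw$intensity)
  if (is.null(raw$mask)) raw$mask <- matrix(TRUE, d[1], d[3])

  flags <- screen_saturation(raw, cfg$saturation_run_length)
  if (all(flags)) stop("all channels flagged as saturated; nothing to process")
  raw$mask[flags, ] <- FALSE
  raw$log <- c(raw$log, sprintf("screen_saturation: run_length=%d, %d channel(s) flagged",
                                as.integer(cfg$saturation_run_length),
                                sum(flags)))

  raw <- remove_artifact_epochs(raw, cfg$artifact_fraction, cfg$epoch_window)
  raw <- correct_spikes(raw, cfg$spike_sd, cfg$spike_window_s)
  od <- intensity_to_od(raw, params)
  if (!is.null(cfg$band)) {
    od <- bandpass(od, cfg$band[1], cfg$band[2])
  } else {
    od$log <- c(od$log, "bandpass: disabled")
  }
  hemo <- od_to_hemo(od, params, distance = cfg$distance)
  hemo$saturated <- flags
  hemo$removed_fraction <- raw$removed_fraction
  hemo
}
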