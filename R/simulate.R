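#' @importFrom stats rnorm runif rpois sd
NULL

# deterministic per-subject/phase seed derivation from a master seed,
# kept inside the 32-bit integer range
derive_seed <- function(master, i, j = 0L, k = 0L) {
  as.integer((as.double(master) * 2654435 + i * 97561 + j * 1013 + k * 7) %%
               2147483629)
}

# additive noise on the oxyhaemoglobin trace (umol/l); artifact_mult scales
# the motion-artifact rate for a given subject
gen_noise <- function(nch, n, fs, spec, artifact_mult = 1,
                      include_artifacts = TRUE) {
  t <- (seq_len(n) - 1) / fs
  dur_min <- n / fs / 60
  noise <- matrix(rnorm(nch * n, 0, spec$white_noise_sd), nch, n)
  for (ch in seq_len(nch)) {
    x <- numeric(n)
    # slow drift: linear slope + very-low-frequency oscillation
    x <- x + rnorm(1, 0, spec$drift_slope_sd) * t +
      spec$drift_amplitude * sin(2 * pi * 0.005 * t + runif(1, 0, 2 * pi))
    for (o in seq_len(nrow(spec$oscillators))) {
      f <- spec$oscillators$freq_hz[o]
      a <- spec$oscillators$amplitude[o]
      jit <- spec$oscillators$phase_jitter[o]
      phase <- runif(1, 0, 2 * pi) +
        cumsum(rnorm(n, 0, jit / sqrt(fs)))
      x <- x + a * sin(2 * pi * f * t + phase)
    }
    # brief spike jumps
    nspk <- rpois(1, spec$spike_rate * dur_min)
    if (nspk > 0) {
      for (s in seq_len(nspk)) {
        pos <- sample.int(n, 1)
        w <- sample(1:3, 1)
        idx <- pos:min(n, pos + w - 1)
        x[idx] <- x[idx] + sample(c(-1, 1), 1) *
          runif(1, spec$spike_amplitude[1], spec$spike_amplitude[2])
      }
    }
    # large slow motion artifacts (half-sine bumps)
    if (include_artifacts) {
      nart <- rpois(1, spec$artifact_rate * dur_min * artifact_mult)
      if (nart > 0) {
        for (a_i in seq_len(nart)) {
          dur <- runif(1, spec$artifact_duration[1], spec$artifact_duration[2])
          w <- max(2L, round(dur * fs))
          pos <- sample.int(max(1L, n - w), 1)
          idx <- pos:(pos + w - 1)
          amp <- sample(c(-1, 1), 1) *
            runif(1, spec$artifact_amplitude[1], spec$artifact_amplitude[2])
          x[idx] <- x[idx] + amp * sin(pi * seq(0, 1, length.out = w))
        }
      }
    }
    noise[ch, ] <- noise[ch, ] + x
  }
  noise
}

# dHb as a scaled, delayed copy of dHbO
hb_from_hbo <- function(hbo, ratio, delay_s, fs) {
  d <- round(delay_s * fs)
  n <- ncol(hbo)
  hb <- matrix(0, nrow(hbo), n)
  if (d < n) hb[, (d + 1):n] <- ratio * hbo[, 1:(n - d), drop = FALSE]
  hb
}

#' Simulate one test session
#'
#' Superimposes one haemodynamic response kernel per scheduled event, with
#' the cell-specific (group x phase x stimulus) amplitude and peak time
#' from the ground truth; channels listed in the ground truth's effect sets
#' additionally receive the planted effect increments. The deoxy trace is a
#' negatively scaled, delayed copy of the oxy trace. Returns both the clean
#' series and (optionally) a noisy version with all noise components added.
#'
#' @param montage [make_montage()]
#' @param schedule [make_test_schedule()]
#' @param gt [ground_truth()]
#' @param group,phase design cell of this session
#' @param seed RNG seed for the noise draw
#' @param duration session duration, s (default: the schedule's total)
#' @param noise add the noise components?
#' @param artifact_mult subject-level artifact-rate multiplier
#' @return list(clean = hemo_series, noisy = hemo_series or NULL)
#' @export
simulate_session <- function(montage, schedule, gt, group, phase,
                             seed = NULL, duration = NULL, noise = TRUE,
                             artifact_mult = 1, fs = 10) {
  if (is.null(duration)) duration <- attr(schedule, "total_duration")
  if (max(schedule$onset + schedule$duration) > duration + 1e-9) {
    stop("schedule extends beyond the requested duration")
  }
  if (!is.null(seed)) set.seed(seed)
  nch <- nrow(montage)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  amp_in <- montage$channel_id %in% gt$amp_channels
  lat_in <- montage$channel_id %in% gt$lat_channels
  hbo <- matrix(0, nch, n)
  for (e in seq_len(nrow(schedule))) {
    stim <- schedule$trial_type[e]
    acell <- gt_cell(gt$amp_cells, group, phase, stim)
    lcell <- gt_cell(gt$lat_cells, group, phase, stim)
    t_rel <- t - schedule$onset[e]
    sel <- which(t_rel > 0 & t_rel < 30)
    if (!length(sel)) next
    # up to four distinct (amplitude, peak-time) channel profiles
    for (a_eff in unique(amp_in)) {
      for (l_eff in unique(lat_in)) {
        chans <- which(amp_in == a_eff & lat_in == l_eff)
        if (!length(chans)) next
        amp <- acell$base + if (a_eff) acell$effect else 0
        peak <- lcell$base + if (l_eff) lcell$effect else 0
        if (amp == 0) next
        kern <- hrf_kernel(t_rel[sel], peak_time = peak,
                           dispersion = gt$dispersion, amplitude = amp)
        hbo[chans, sel] <- hbo[chans, sel] +
          matrix(kern, length(chans), length(sel), byrow = TRUE)
      }
    }
  }
  clean <- hemo_series(hbo, hb_from_hbo(hbo, gt$hb_ratio, gt$hb_delay, fs),
                       fs = fs, log = "simulate_session: clean")
  noisy <- NULL
  if (noise) {
    tot <- hbo + gen_noise(nch, n, fs, gt$noise, artifact_mult)
    noisy <- hemo_series(tot, hb_from_hbo(tot, gt$hb_ratio, gt$hb_delay, fs),
                         fs = fs, log = "simulate_session: noisy")
  }
  list(clean = clean, noisy = noisy)
}

# target resting correlation matrix for one (group, phase) cell,
# projected to the positive-semidefinite cone and unit diagonal
resting_target_corr <- function(montage, gt, group, phase) {
  nch <- nrow(montage)
  R <- matrix(gt$conn_base, nch, nch)
  diag(R) <- 1
  if (!is.null(gt$conn_cells) && !is.null(gt$conn_pairs)) {
    hit <- gt$conn_cells$group == group & gt$conn_cells$phase == phase
    for (inc in gt$conn_cells$increment[hit]) {
      for (p in seq_len(nrow(gt$conn_pairs))) {
        i <- match(gt$conn_pairs[p, 1], montage$channel_id)
        j <- match(gt$conn_pairs[p, 2], montage$channel_id)
        if (is.na(i) || is.na(j)) next
        R[i, j] <- R[i, j] + inc
        R[j, i] <- R[i, j]
      }
    }
  }
  R[R > 0.97] <- 0.97
  R[R < -0.97] <- -0.97
  diag(R) <- 1
  eg <- eigen(R, symmetric = TRUE)
  if (any(eg$values < 1e-8)) {
    vals <- pmax(eg$values, 1e-6)
    R <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
    s <- 1 / sqrt(diag(R))
    R <- R * (s %o% s)
  }
  if (any(!is.finite(R))) stop("resting correlation target projection failed")
  R
}

#' Simulate a resting-state window
#'
#' Generates band-limited (<= 0.2 Hz dominant) haemoglobin series whose
#' population inter-channel correlation matrix equals the ground truth's
#' base matrix plus the (group, phase) connectivity increments, enforced by
#' mixing identically low-pass-filtered white noise through the Cholesky
#' factor of the (PSD-projected) target matrix. Out-of-band physiological
#' oscillators and white measurement noise are added on top; in-band
#' independent noise is kept small so planted correlations survive the
#' analysis band-pass.
#'
#' @inheritParams simulate_session
#' @param duration_s window length, s (>= 10)
#' @export
simulate_resting <- function(montage, duration_s = 180, gt = NULL,
                             group = "experimental", phase = "T0",
                             seed = NULL, fs = 10, noise = TRUE) {
  if (duration_s < 10) stop("resting duration must be >= 10 s")
  if (is.null(gt)) gt <- default_ground_truth(montage)
  if (!is.null(seed)) set.seed(seed)
  nch <- nrow(montage)
  n <- round(duration_s * fs)
  R <- resting_target_corr(montage, gt, group, phase)
  pad <- 200L  # discard filter warm-up
  Z <- matrix(rnorm(nch * (n + 2 * pad)), nch)
  bf <- signal::butter(3, 0.2 / (fs / 2), type = "low")
  Z <- t(apply(Z, 1, function(x) signal::filtfilt(bf, x)))
  Z <- Z[, (pad + 1):(pad + n), drop = FALSE]
  Z <- Z / apply(Z, 1, sd)
  X <- gt$resting_sd * crossprod(chol(R), Z)
  if (noise) {
    t <- (seq_len(n) - 1) / fs
    for (ch in seq_len(nch)) {
      osc <- gt$noise$oscillators
      fast <- osc$freq_hz > 0.3  # out-of-band components only
      for (o in which(fast)) {
        X[ch, ] <- X[ch, ] + osc$amplitude[o] *
          sin(2 * pi * osc$freq_hz[o] * t + runif(1, 0, 2 * pi))
      }
    }
    X <- X + matrix(rnorm(nch * n, 0, gt$noise$white_noise_sd), nch, n)
  }
  hemo_series(X, hb_from_hbo(X, gt$hb_ratio, gt$hb_delay, fs), fs = fs,
              log = sprintf("simulate_resting: %s/%s, %g s", group, phase,
                            duration_s))
}

#' Simulate a complete study
#'
#' Emits, for every subject x phase, a raw two-wavelength recording
#' consisting of a resting window followed by one randomized test session,
#' with the ground truth attached. All randomness derives from the master
#' seed through per-subject/phase streams, so subsetting subjects leaves
#' other subjects' data unchanged.
#'
#' @param config list; see [study_config()] for fields and defaults
#' @param seed master integer seed
#' @return list of class `study` with montage, config, ground_truth,
#'   subjects table and `recordings[[subject_id]][[phase]]`
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  config <- utils::modifyList(study_config(), config)
  if (any(config$groups < 1)) stop("every group needs at least one subject")
  montage <- make_montage(config$n_channels)
  gt <- config$ground_truth
  if (is.null(gt)) gt <- default_ground_truth(montage)
  groups <- rep(names(config$groups), config$groups)
  nsub <- length(groups)
  subjects <- data.frame(
    subject_id = sprintf("sub-%02d", seq_len(nsub)),
    group = groups, stringsAsFactors = FALSE)
  recordings <- vector("list", nsub)
  names(recordings) <- subjects$subject_id
  fs <- config$fs
  for (i in seq_len(nsub)) {
    set.seed(derive_seed(seed, i))
    art_mult <- exp(rnorm(1, -gt$noise$subject_artifact_sd^2 / 2,
                          gt$noise$subject_artifact_sd))
    recs <- list()
    for (p in seq_along(config$phases)) {
      phase <- config$phases[p]
      sched <- make_test_schedule(config$n_forward, config$n_backward,
                                  config$trial_dur, config$iti_range,
                                  seed = derive_seed(seed, i, p, 1), fs = fs)
      rest <- simulate_resting(montage, config$rest_duration, gt,
                               group = groups[i], phase = phase,
                               seed = derive_seed(seed, i, p, 2), fs = fs,
                               noise = config$noise)
      sess <- simulate_session(montage, sched, gt, groups[i], phase,
                               seed = derive_seed(seed, i, p, 3),
                               noise = config$noise,
                               artifact_mult = art_mult, fs = fs)
      hemo_sess <- if (config$noise) sess$noisy else sess$clean
      hbo <- cbind(rest$hbo, hemo_sess$hbo)
      hb <- cbind(rest$hb, hemo_sess$hb)
      fwd <- forward_mbll(hemo_series(hbo, hb, fs = fs), config$mbll,
                          distance = montage$distance_cm, i0 = config$i0)
      inten <- fwd$intensity
      if (isTRUE(config$clip)) {
        inten[inten < config$dynamic_range[1]] <- config$dynamic_range[1]
        inten[inten > config$dynamic_range[2]] <- config$dynamic_range[2]
      }
      ev <- sched
      ev$onset <- ev$onset + config$rest_duration
      rec <- raw_recording(inten, fs = fs,
                           dynamic_range = config$dynamic_range,
                           subject_id = subjects$subject_id[i],
                           group = groups[i], phase = phase,
                           session_kind = "test", events = ev,
                           rest_duration = config$rest_duration)
      if (isTRUE(config$keep_clean)) {
        clean_hbo <- cbind(matrix(0, nrow(rest$hbo), ncol(rest$hbo)),
                           sess$clean$hbo)
        rec$clean <- hemo_series(clean_hbo,
                                 hb_from_hbo(clean_hbo, gt$hb_ratio,
                                             gt$hb_delay, fs), fs = fs)
      }
      recs[[phase]] <- rec
    }
    recordings[[i]] <- recs
  }
  structure(list(montage = montage, config = config, ground_truth = gt,
                 subjects = subjects, recordings = recordings, seed = seed),
            class = "study")
}

#' Study configuration defaults
#'
#' The default configuration reproduces the study design: three groups of
#' 22/23/21 neonates, three test phases, 52 channels at 10 Hz, 12 forward +
#' 12 backward 6-s trials with 12-16 s ITIs per test, and a 3-min resting
#' window before each test.
#'
#' @param ... overrides for any field
#' @export
study_config <- function(...) {
  base <- list(
    groups = c(experimental = 22L, active = 23L, passive = 21L),
    phases = c("T0", "T1", "T2"),
    n_channels = 52L,
    fs = 10,
    rest_duration = 180,
    n_forward = 12L, n_backward = 12L,
    trial_dur = 6, iti_range = c(12, 16),
    noise = TRUE,
    i0 = 1, dynamic_range = c(0, 2), clip = FALSE,
    distance = 2.3,
    mbll = mbll_params(),
    ground_truth = NULL,
    keep_clean = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(base, over)
}
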