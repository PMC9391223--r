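#' Randomized test-session event schedule
#'
#' Generates the stimulus schedule for one test session: `n_forward` forward
#' and `n_backward` backward trials in random order, each lasting
#' `trial_dur` seconds and followed by a silent inter-trial interval drawn
#' uniformly from `iti_range`. Onsets are snapped to the 10 Hz sample grid.
#' A final ITI is appended after the last trial, so the default session
#' (12 + 12 trials of 6 s, ITI 12-16 s) has an expected duration of 8 min.
#'
#' @param n_forward,n_backward trial counts per stimulus type
#' @param trial_dur trial duration, s
#' @param iti_range length-2 numeric, uniform ITI bounds in s
#' @param seed integer RNG seed (NULL leaves the RNG state alone)
#' @param fs sampling rate used to snap onsets to the sample grid, Hz
#' @return data.frame (onset, duration, trial_type, trial_index) with
#'   attributes `session_kind = "test"` and `total_duration` (s)
#' @export
make_test_schedule <- function(n_forward = 12L, n_backward = 12L,
                               trial_dur = 6, iti_range = c(12, 16),
                               seed = NULL, fs = 10) {
  stopifnot(n_forward >= 0, n_backward >= 0, n_forward + n_backward >= 1,
            trial_dur > 0, length(iti_range) == 2)
  if (iti_range[1] > iti_range[2]) stop("iti_range must be non-decreasing")
  if (!is.null(seed)) set.seed(seed)
  n <- n_forward + n_backward
  types <- sample(rep(c("forward", "backward"), c(n_forward, n_backward)))
  itis <- stats::runif(n, iti_range[1], iti_range[2])
  itis <- round(itis * fs) / fs
  gaps <- trial_dur + itis
  onsets <- cumsum(c(0, gaps[-n]))
  out <- data.frame(
    onset = onsets,
    duration = trial_dur,
    trial_type = types,
    trial_index = seq_len(n),
    stringsAsFactors = FALSE
  )
  attr(out, "session_kind") <- "test"
  attr(out, "total_duration") <- onsets[n] + trial_dur + itis[n]
  class(out) <- c("event_schedule", "data.frame")
  out
}

#' Fixed-ITI training-block schedule
#'
#' One training block presents `n_stimuli` stimuli `n_repetitions` times
#' each with a fixed inter-trial interval (default: 72 trials at 6 s with a
#' 2 s ITI, i.e. one 10-minute exposure block).
#'
#' @inheritParams make_test_schedule
#' @param n_stimuli,n_repetitions block composition
#' @param iti fixed inter-trial interval, s
#' @export
make_training_schedule <- function(n_stimuli = 12L, n_repetitions = 6L,
                                   trial_dur = 6, iti = 2) {
  stopifnot(n_stimuli >= 1, n_repetitions >= 1, trial_dur > 0, iti >= 0)
  n <- n_stimuli * n_repetitions
  onsets <- (seq_len(n) - 1) * (trial_dur + iti)
  out <- data.frame(
    onset = onsets,
    duration = trial_dur,
    trial_type = "forward",
    trial_index = seq_len(n),
    stringsAsFactors = FALSE
  )
  attr(out, "session_kind") <- "training_block"
  attr(out, "total_duration") <- onsets[n] + trial_dur + iti
  class(out) <- c("event_schedule", "data.frame")
  out
}
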