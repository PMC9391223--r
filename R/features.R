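#' Segment a haemoglobin series into trial epochs
#'
#' Cuts one epoch per scheduled event, spanning `window` seconds around the
#' stimulus onset (default -2 to +20 s, i.e. 221 samples at 10 Hz). A
#' channel is valid within an epoch only if none of its samples are masked
#' (all-or-none retention). Events whose window falls outside the recording
#' are dropped and logged.
#'
#' @param series a [hemo_series()]
#' @param schedule event schedule with `onset` and `trial_type`
#' @param window length-2 epoch bounds relative to onset, s
#' @return list of epochs; each has `hbo` (channel x time), `hb`, `time`,
#'   `trial_index`, `stimulus_type`, `valid` (per channel), `baseline_window`
#' @export
epoch_series <- function(series, schedule, window = c(-2, 20)) {
  if (window[1] >= window[2]) stop("epoch window is inverted")
  fs <- series$fs
  n <- ncol(series$hbo)
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  tgrid <- rel / fs
  epochs <- list()
  dropped <- 0L
  for (e in seq_len(nrow(schedule))) {
    i0 <- round(schedule$onset[e] * fs) + 1L
    idx <- i0 + rel
    if (idx[1] < 1L || idx[length(idx)] > n) {
      dropped <- dropped + 1L
      next
    }
    epochs[[length(epochs) + 1L]] <- structure(list(
      hbo = series$hbo[, idx, drop = FALSE],
      hb = series$hb[, idx, drop = FALSE],
      time = tgrid,
      fs = fs,
      trial_index = schedule$trial_index[e],
      stimulus_type = schedule$trial_type[e],
      valid = apply(series$mask[, idx, drop = FALSE], 1, all),
      baseline_window = c(window[1], 0)
    ), class = "nirs_epoch")
  }
  attr(epochs, "dropped") <- dropped
  if (dropped > 0) {
    attr(epochs, "log") <- sprintf("epoch_series: dropped %d edge event(s)",
                                   dropped)
  }
  epochs
}

#' Baseline-correct an epoch
#'
#' Subtracts, per channel, the mean concentration over the pre-stimulus
#' window [-2, 0) s from both the oxy and deoxy traces. Idempotent.
#'
#' @param epoch an epoch from [epoch_series()]
#' @export
baseline_correct <- function(epoch) {
  bl <- epoch$time >= epoch$baseline_window[1] & epoch$time < 0
  if (!any(bl)) stop("empty baseline window")
  epoch$hbo <- epoch$hbo - rowMeans(epoch$hbo[, bl, drop = FALSE])
  epoch$hb <- epoch$hb - rowMeans(epoch$hb[, bl, drop = FALSE])
  epoch$baseline_corrected <- TRUE
  epoch
}

#' Trial mean amplitude
#'
#' Arithmetic mean of the oxyhaemoglobin trace over the post-onset window
#' (default 6-16 s inclusive), per channel. Invalid channels yield NA.
#'
#' @param epoch a baseline-corrected epoch
#' @param window length-2 averaging window, s (inclusive endpoints)
#' @return named numeric vector, umol/l, one value per channel
#' @export
mean_amplitude <- function(epoch, window = c(6, 16)) {
  if (window[1] < epoch$time[1] || window[2] > epoch$time[length(epoch$time)]) {
    stop("amplitude window must lie inside the epoch")
  }
  sel <- epoch$time >= window[1] & epoch$time <= window[2]
  out <- rowMeans(epoch$hbo[, sel, drop = FALSE])
  out[!epoch$valid] <- NA_real_
  out
}

#' Trial peak latency
#'
#' Time of the maximum oxyhaemoglobin sample within the search window
#' (default 0-20 s: the post-onset part of the epoch). Ties are broken to
#' the earliest sample; resolution is one sample (0.1 s at 10 Hz). Invalid
#' channels yield NA.
#'
#' @param epoch a baseline-corrected epoch
#' @param search_window length-2 search bounds, s
#' @return numeric vector of peak times, s, one per channel
#' @export
peak_latency <- function(epoch, search_window = c(0, 20)) {
  sel <- which(epoch$time >= search_window[1] &
                 epoch$time <= search_window[2])
  if (!length(sel)) stop("empty search window")
  tt <- epoch$time[sel]
  out <- apply(epoch$hbo[, sel, drop = FALSE], 1,
               function(x) tt[which.max(x)])  # which.max = earliest tie-break
  out[!epoch$valid] <- NA_real_
  out
}

#' Build the trial feature table
#'
#' Long-format table with one row per retained (valid) trial x channel,
#' carrying the two trial statistics and the design labels. Rows are
#' ordered deterministically by (subject, phase, trial, channel); masked
#' cells produce no rows.
#'
#' @param epochs list of epochs from [epoch_series()] (baseline correction
#'   is applied here if not already done)
#' @param subject_id,group,phase design labels for this session
#' @param montage montage (supplies channel ids and region labels)
#' @param amp_window,search_window feature windows, s
#' @export
build_feature_table <- function(epochs, subject_id, group, phase, montage,
                                amp_window = c(6, 16),
                                search_window = c(0, 20)) {
  rows <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    if (!isTRUE(ep$baseline_corrected)) ep <- baseline_correct(ep)
    amp <- mean_amplitude(ep, amp_window)
    lat <- peak_latency(ep, search_window)
    keep <- ep$valid
    if (!any(keep)) next
    rows[[i]] <- data.frame(
      subject_id = subject_id, group = group, phase = phase,
      channel_id = montage$channel_id[keep],
      region = paste(montage$hemisphere, montage$region)[keep],
      trial_index = ep$trial_index, stimulus_type = ep$stimulus_type,
      mean_amplitude = amp[keep], peak_latency = lat[keep],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0) {
    warning("all epochs masked; empty feature table")
    out <- data.frame(subject_id = character(), group = character(),
                      phase = character(), channel_id = integer(),
                      region = character(), trial_index = integer(),
                      stimulus_type = character(),
                      mean_amplitude = numeric(), peak_latency = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- out[order(out$subject_id, out$phase, out$trial_index,
                   out$channel_id), ]
  rownames(out) <- NULL
  out
}
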