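#' Build a probe montage
#'
#' Constructs the channel table for a symmetric two-hemisphere fNIRS probe
#' layout. The default 52-channel montage mirrors a neonatal whole-head
#' arrangement (20 sources, 16 detectors, mean source-detector separation
#' 2.3 cm) in which specific channels sit over the inferior frontal (IF),
#' superior temporal (ST), supramarginal (SM) and inferior parietal (IP)
#' regions. Channels 1..n/2 are assigned to the left hemisphere and the
#' remainder to the right, so hemisphere counts are always symmetric.
#'
#' @param n_channels even channel count (default 52)
#' @param distance_cm source-detector separation in cm applied to every
#'   channel (default 2.3)
#' @return data.frame with columns `channel_id`, `hemisphere`, `region`,
#'   `distance_cm`; attributes `n_sources` and `n_detectors`
#' @export
make_montage <- function(n_channels = 52L, distance_cm = 2.3) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 2L || n_channels %% 2L != 0L) {
    stop("n_channels must be an even integer >= 2")
  }
  if (!is.numeric(distance_cm) || distance_cm <= 0) {
    stop("distance_cm must be > 0")
  }
  half <- n_channels %/% 2L
  hemisphere <- rep(c("left", "right"), each = half)
  region <- rep("other", n_channels)
  if (n_channels == 52L) {
    # canonical region labels for the neonatal 52-channel layout
    labels <- c(
      "2" = "IF", "6" = "IF", "16" = "IF",        # left inferior frontal
      "7" = "ST", "10" = "ST",                    # left superior temporal
      "19" = "SM",                                # left supramarginal
      "25" = "IP",                                # left inferior parietal
      "26" = "angular",                           # left angular
      "43" = "IF", "44" = "IF",                   # right inferior frontal
      "45" = "ST",                                # right superior temporal
      "37" = "SM",                                # right supramarginal
      "52" = "angular"                            # right angular
    )
    region[as.integer(names(labels))] <- labels
  }
  out <- data.frame(
    channel_id = seq_len(n_channels),
    hemisphere = hemisphere,
    region = region,
    distance_cm = distance_cm,
    stringsAsFactors = FALSE
  )
  attr(out, "n_sources") <- 20L
  attr(out, "n_detectors") <- 16L
  class(out) <- c("nirs_montage", "data.frame")
  out
}

#' Region label for a set of channels
#' @param montage montage from [make_montage()]
#' @param channel_id integer channel ids
#' @return character vector of "<hemisphere> <region>" labels
#' @export
channel_region <- function(montage, channel_id) {
  idx <- match(channel_id, montage$channel_id)
  if (anyNA(idx)) stop("unknown channel id(s): ",
                       paste(channel_id[is.na(idx)], collapse = ", "))
  paste(montage$hemisphere[idx], montage$region[idx])
}
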