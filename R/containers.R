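#' Haemoglobin concentration series
#'
#' Container for channel-by-time oxy- and deoxyhaemoglobin concentration
#' changes (umol/l). `mask` marks valid samples (TRUE = usable); `log`
#' accumulates a provenance record of processing steps.
#'
#' @param hbo,hb channel x time matrices, umol/l
#' @param fs sampling rate, Hz
#' @param mask logical channel x time matrix, TRUE = valid
#' @param log character vector of applied steps
#' @export
hemo_series <- function(hbo, hb, fs = 10, mask = NULL, log = character()) {
  hbo <- as.matrix(hbo); hb <- as.matrix(hb)
  if (!all(dim(hbo) == dim(hb))) stop("hbo and hb must have the same shape")
  if (fs <= 0) stop("fs must be > 0")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(hbo), ncol(hbo))
  if (!all(dim(mask) == dim(hbo))) stop("mask shape mismatch")
  structure(list(hbo = hbo, hb = hb, fs = fs, mask = mask, log = log),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("<hemo_series> %d channels x %d samples @ %g Hz (%.1f s), %.1f%% masked\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, ncol(x$hbo) / x$fs,
              100 * mean(!x$mask)))
  invisible(x)
}

#' Raw two-wavelength intensity recording
#'
#' @param intensity numeric array channel x wavelength x time (device units)
#' @param fs sampling rate, Hz
#' @param wavelengths length-2 numeric, nm; canonical order c(760, 850)
#' @param dynamic_range length-2 numeric device input range
#' @param subject_id,group,phase,session_kind design metadata
#' @param events optional event schedule (test sessions)
#' @param rest_duration seconds of resting recording preceding the first
#'   event (0 if none)
#' @export
raw_recording <- function(intensity, fs = 10, wavelengths = c(760, 850),
                          dynamic_range = c(0, 2), subject_id = NA,
                          group = NA, phase = NA, session_kind = "test",
                          events = NULL, rest_duration = 0) {
  if (length(dim(intensity)) != 3L || dim(intensity)[2] != 2L) {
    stop("intensity must be a channel x 2-wavelength x time array")
  }
  if (!all(is.finite(intensity))) stop("intensity values must be finite")
  if (fs <= 0) stop("fs must be > 0")
  wavelengths <- as.numeric(wavelengths)
  ord <- order(wavelengths)
  if (length(wavelengths) != 2 || any(wavelengths[ord] != c(760, 850))) {
    stop("wavelengths must be {760, 850} nm")
  }
  if (!identical(ord, 1:2)) intensity <- intensity[, ord, , drop = FALSE]
  structure(list(intensity = intensity, fs = fs, wavelengths = c(760, 850),
                 dynamic_range = dynamic_range, subject_id = subject_id,
                 group = group, phase = phase, session_kind = session_kind,
                 events = events, rest_duration = rest_duration,
                 mask = NULL, log = character()),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<raw_recording> subject %s (%s, %s): %d channels x 2 wl x %d samples @ %g Hz\n",
              x$subject_id, x$group, x$phase, d[1], d[3], x$fs))
  invisible(x)
}

n_samples <- function(x) {
  if (inherits(x, "raw_recording")) dim(x$intensity)[3] else ncol(x$hbo)
}
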