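#' Modified Beer-Lambert law constants
#'
#' Extinction coefficients (1/(mM cm)) for {HbO, Hb} at 760 and 850 nm,
#' differential pathlength factors per wavelength, and the optical-density
#' log base. The defaults are standard literature values for the two
#' wavelengths; they are configurable because device constants vary, and
#' only forward/inverse consistency is load-bearing for the pipeline.
#'
#' @param extinction 2x2 matrix, rows = wavelengths (760, 850 nm),
#'   columns = chromophores (HbO, Hb), units 1/(mM cm)
#' @param dpf length-2 differential pathlength factor (760, 850 nm)
#' @param log_base 10 or exp(1); base used for optical density
#' @export
mbll_params <- function(extinction = matrix(c(1.4866, 3.8437,
                                              2.5264, 1.7986),
                                            nrow = 2, byrow = TRUE,
                                            dimnames = list(c("760", "850"),
                                                            c("HbO", "Hb"))),
                        dpf = c(5.0, 5.0), log_base = 10) {
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2))) stop("extinction must be 2x2")
  if (abs(det(extinction)) < 1e-12) stop("extinction matrix is singular")
  if (length(dpf) == 1) dpf <- rep(dpf, 2)
  if (any(dpf <= 0)) stop("dpf must be > 0")
  if (!log_base %in% c(10, exp(1))) stop("log_base must be 10 or e")
  structure(list(extinction = extinction, dpf = dpf, log_base = log_base),
            class = "mbll_params")
}

# channel-wise 2x2 forward matrix M such that OD = M %*% c(hbo, hb)
# (concentrations in umol/l; 1e-3 converts to mM to match extinction units)
mbll_forward_matrix <- function(params, distance) {
  params$dpf * params$extinction * distance * 1e-3
}

#' Forward modified Beer-Lambert model
#'
#' Maps haemoglobin concentration changes to two-wavelength optical density
#' changes and raw intensities:
#' `OD_l(t) = (e_l,HbO dHbO + e_l,Hb dHb) * distance * dpf_l * 1e-3` and
#' `I_l(t) = i0 * base^(-OD_l(t))`. This is the exact inverse of
#' [od_to_hemo()] and is used by the generator to emit device-like raw data.
#'
#' @param hemo a [hemo_series()]
#' @param params [mbll_params()]
#' @param distance source-detector distance(s), cm; scalar or per channel
#' @param i0 reference intensity (device units)
#' @return list with `od` and `intensity`, both channel x wavelength x time
#' @export
forward_mbll <- function(hemo, params = mbll_params(), distance = 2.3,
                         i0 = 1) {
  nch <- nrow(hemo$hbo); nt <- ncol(hemo$hbo)
  if (length(distance) == 1) distance <- rep(distance, nch)
  stopifnot(length(distance) == nch, all(distance > 0))
  od <- array(0, dim = c(nch, 2, nt))
  for (ch in seq_len(nch)) {
    M <- mbll_forward_matrix(params, distance[ch])
    od[ch, , ] <- M %*% rbind(hemo$hbo[ch, ], hemo$hb[ch, ])
  }
  intensity <- i0 * params$log_base^(-od)
  list(od = od, intensity = intensity)
}

#' Convert raw intensities to optical density changes
#'
#' `OD(t) = -log_base(I(t) / mean(I))` per channel and wavelength, with the
#' per-recording mean intensity as the reference level. Non-positive
#' intensity samples are masked and logged rather than propagated as NaN.
#'
#' @param raw a [raw_recording()]
#' @param params [mbll_params()] (supplies the log base)
#' @param reference reference intensity: NULL (default) uses the
#'   per-channel, per-wavelength mean over the recording, yielding
#'   relative (mean-referenced) concentration changes downstream; a known
#'   emitted intensity can be supplied for an exact inversion of the
#'   forward model
#' @return list of class `od_series`: `od` (channel x wavelength x time),
#'   `mask` (channel x time), `fs`, `log`
#' @export
intensity_to_od <- function(raw, params = mbll_params(), reference = NULL) {
  I <- raw$intensity
  d <- dim(I)
  mask <- if (is.null(raw$mask)) matrix(TRUE, d[1], d[3]) else raw$mask
  bad <- apply(I <= 0, c(1, 3), any)
  if (any(bad)) mask <- mask & !bad
  od <- array(0, dim = d)
  for (wl in 1:2) {
    Iw <- matrix(I[, wl, ], nrow = d[1])
    Iw[Iw <= 0] <- NA
    ref <- if (is.null(reference)) rowMeans(Iw, na.rm = TRUE) else reference
    odw <- -log(Iw / ref) / log(params$log_base)
    odw[is.na(odw)] <- 0
    od[, wl, ] <- odw
  }
  structure(list(od = od, mask = mask, fs = raw$fs,
                 log = c(raw$log,
                         sprintf("intensity_to_od: base %s, %d non-positive sample(s) masked",
                                 format(params$log_base), sum(bad)))),
            class = "od_series")
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel and time point, the 2x2 linear system relating the
#' two wavelengths' optical density changes to the haemoglobin
#' concentration changes. Output is in umol/l.
#'
#' @param od an `od_series` (from [intensity_to_od()]) or a raw
#'   channel x wavelength x time array
#' @param params [mbll_params()]
#' @param distance source-detector distance(s), cm
#' @param fs sampling rate (used when `od` is a bare array)
#' @return a [hemo_series()]
#' @export
od_to_hemo <- function(od, params = mbll_params(), distance = 2.3, fs = 10) {
  if (inherits(od, "od_series")) {
    arr <- od$od; mask <- od$mask; fs <- od$fs; log <- od$log
  } else {
    arr <- od; mask <- NULL; log <- character()
  }
  d <- dim(arr)
  nch <- d[1]
  if (length(distance) == 1) distance <- rep(distance, nch)
  hbo <- matrix(0, nch, d[3]); hb <- matrix(0, nch, d[3])
  for (ch in seq_len(nch)) {
    Minv <- solve(mbll_forward_matrix(params, distance[ch]))
    conc <- Minv %*% rbind(arr[ch, 1, ], arr[ch, 2, ])
    hbo[ch, ] <- conc[1, ]
    hb[ch, ] <- conc[2, ]
  }
  hemo_series(hbo, hb, fs = fs, mask = mask,
              log = c(log, "od_to_hemo: MBLL inversion"))
}
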