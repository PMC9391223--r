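#' Extract the pre-test resting window
#'
#' The window of exactly `duration` seconds ending at the test onset (the
#' last included sample is the last sample strictly before the onset).
#'
#' @param series a [hemo_series()]
#' @param test_onset onset of the first test stimulus, s from recording start
#' @param duration window length, s (default 180 s = 1800 samples at 10 Hz)
#' @return a [hemo_series()] restricted to the window
#' @export
resting_window <- function(series, test_onset, duration = 180) {
  fs <- series$fs
  n <- round(duration * fs)
  end <- round(test_onset * fs)  # last sample before onset
  start <- end - n + 1L
  if (start < 1L || end > ncol(series$hbo)) {
    stop("recording does not cover the requested pre-test window")
  }
  idx <- start:end
  hemo_series(series$hbo[, idx, drop = FALSE],
              series$hb[, idx, drop = FALSE], fs = fs,
              mask = series$mask[, idx, drop = FALSE],
              log = c(series$log,
                      sprintf("resting_window: %g s ending at %g s",
                              duration, test_onset)))
}

#' Channel-pair Pearson correlation matrix
#'
#' Pearson correlations between the oxyhaemoglobin time series of every
#' channel pair, dropping masked samples pairwise. Constant channels give
#' undefined correlations, recorded as NA (and excluded from pair tables
#' with a logged count) rather than failing.
#'
#' @param window a [hemo_series()] (typically from [resting_window()])
#' @return symmetric correlation matrix with channel dimnames
#' @export
corr_matrix <- function(window) {
  x <- window$hbo
  x[!window$mask] <- NA
  if (min(rowSums(window$mask)) < 3) {
    warning("channel(s) with fewer than 3 valid samples")
  }
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  dimnames(r) <- list(seq_len(nrow(x)), seq_len(nrow(x)))
  r
}

#' Fisher z-transform
#'
#' `z = artanh(r)`: the variance-stabilizing transform of a Pearson
#' correlation; monotone and odd.
#'
#' @param r correlations with |r| < 1 (|r| = 1 maps to +/-Inf)
#' @export
fisher_z <- function(r) atanh(r)

#' Enumerate seed-channel pairs
#'
#' All unordered channel pairs containing at least one seed, each counted
#' once: s(n-1) - s(s-1)/2 pairs for s seeds among n channels (336 for the
#' canonical 7 seeds among 52 channels).
#'
#' @param seeds integer seed channel ids
#' @param n_channels total channel count
#' @return two-column matrix (chan_a, chan_b) with chan_a < chan_b
#' @export
enumerate_seed_pairs <- function(seeds, n_channels) {
  seeds <- sort(unique(as.integer(seeds)))
  if (!length(seeds)) stop("seed set is empty")
  if (any(seeds < 1L | seeds > n_channels)) stop("seed outside montage")
  all_pairs <- t(utils::combn(n_channels, 2))
  keep <- all_pairs[, 1] %in% seeds | all_pairs[, 2] %in% seeds
  out <- all_pairs[keep, , drop = FALSE]
  colnames(out) <- c("chan_a", "chan_b")
  out
}

#' Build the long connectivity pair table
#'
#' One row per subject x phase x seed pair with the Pearson r and Fisher z
#' of the pre-test resting window. Undefined correlations are dropped with
#' a logged count.
#'
#' @param windows nested list `windows[[subject_id]][[phase]]` of resting
#'   [hemo_series()]
#' @param subjects data.frame (subject_id, group)
#' @param seeds seed channel ids
#' @param n_channels montage size
#' @return data.frame (subject_id, group, phase, chan_a, chan_b, r, z)
#' @export
build_pair_table <- function(windows, subjects, seeds, n_channels) {
  pairs <- enumerate_seed_pairs(seeds, n_channels)
  rows <- list()
  n_undef <- 0L
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    for (phase in names(windows[[sid]])) {
      r_mat <- corr_matrix(windows[[sid]][[phase]])
      r <- r_mat[pairs]
      ok <- is.finite(r) & abs(r) < 1
      n_undef <- n_undef + sum(!ok)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = subjects$group[i], phase = phase,
        chan_a = pairs[ok, 1], chan_b = pairs[ok, 2],
        r = r[ok], z = atanh(r[ok]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$pair_id <- paste(out$chan_a, out$chan_b, sep = "-")
  attr(out, "n_undefined") <- n_undef
  out
}

#' Reduced group-by-phase connectivity model
#'
#' Mixed model of the Fisher z values on the group and phase contrasts and
#' their four products (stimulus terms are necessarily absent at rest),
#' with uncorrelated random effects: by participant, intercept and the
#' within-subject phase terms; by channel pair, intercept and all fixed
#' terms. The coefficient table rows come out in the canonical report
#' order: intercept, the four main contrasts, then the four interactions.
#'
#' @param pair_table from [build_pair_table()] (contrast columns are added
#'   if absent)
#' @param re "maximal" (by-pair intercept + slopes) or "reduced" (by-pair
#'   intercept only)
#' @return an `lmm_fit`
#' @export
fit_connectivity_lmm <- function(pair_table, re = c("maximal", "reduced")) {
  re <- match.arg(re)
  if (!"grp1_c" %in% names(pair_table)) {
    pair_table <- code_contrasts(pair_table)
  }
  if (!all(is.finite(pair_table$z))) stop("non-finite z values")
  fixed <- c("grp1_c", "grp2_c", "phs1_c", "phs2_c",
             "grp1_phs1", "grp1_phs2", "grp2_phs1", "grp2_phs2")
  re_subj <- "(1 + phs1_c + phs2_c || subject_id)"
  re_pair <- switch(re,
    maximal = sprintf("(1 + %s || pair_id)", paste(fixed, collapse = " + ")),
    reduced = "(1 | pair_id)")
  form <- stats::as.formula(paste("z ~", paste(c(fixed, re_subj, re_pair),
                                               collapse = " + ")))
  model <- withCallingHandlers(
    lmerTest::lmer(form, data = pair_table, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) invokeRestart("muffleWarning"))
  new_lmm_fit(model, "z")
}

#' Per-pair interaction tests
#'
#' Refits the reduced connectivity model within each channel pair
#' (participant random effects only) and reports, for the training-by-
#' consolidation interaction (group contrast 1 x phase contrast 2), the
#' per-pair estimate and p-value plus the count of pairs significant at
#' `alpha` split by sign.
#'
#' @param pair_table from [build_pair_table()]
#' @param alpha uncorrected significance threshold (default 0.05)
#' @param term tested interaction term
#' @return list(pairs = per-pair data.frame, n_significant, n_positive,
#'   n_negative)
#' @export
per_pair_tests <- function(pair_table, alpha = 0.05, term = "grp1_phs2") {
  if (nrow(pair_table) == 0) stop("empty pair table")
  if (length(unique(pair_table$phase)) < 2) stop("need >= 2 phases")
  fixed <- c("grp1_c", "grp2_c", "phs1_c", "phs2_c",
             "grp1_phs1", "grp1_phs2", "grp2_phs1", "grp2_phs2")
  form <- stats::as.formula(paste(
    "z ~", paste(fixed, collapse = " + "),
    "+ (1 + phs1_c + phs2_c || subject_id)"))
  ids <- unique(pair_table$pair_id)
  rows <- lapply(ids, function(pid) {
    sub <- pair_table[pair_table$pair_id == pid, ]
    sub <- code_contrasts(sub[, setdiff(names(sub), lmm_fixed_terms())])
    model <- withCallingHandlers(
      lmerTest::lmer(form, data = sub, REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore")),
      warning = function(w) invokeRestart("muffleWarning"))
    cf <- stats::coef(summary(model))
    data.frame(pair_id = pid, chan_a = sub$chan_a[1], chan_b = sub$chan_b[1],
               beta = cf[term, "Estimate"], sem = cf[term, "Std. Error"],
               df = cf[term, "df"], t = cf[term, "t value"],
               p = cf[term, "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  sig <- pairs$p < alpha
  list(pairs = pairs, n_significant = sum(sig),
       n_positive = sum(sig & pairs$beta > 0),
       n_negative = sum(sig & pairs$beta < 0), alpha = alpha, term = term)
}

#' Mean-z edge summary per group and phase
#'
#' @param pair_table from [build_pair_table()]
#' @return data.frame (chan_a, chan_b, group, phase, mean_z)
#' @export
edge_summary <- function(pair_table) {
  agg <- stats::aggregate(z ~ chan_a + chan_b + group + phase,
                          data = pair_table, FUN = mean)
  names(agg)[names(agg) == "z"] <- "mean_z"
  agg[order(agg$group, agg$phase, agg$chan_a, agg$chan_b), ]
}

#' Threshold the connectivity network for display
#'
#' Default rule: the display threshold is the absolute value of the most
#' negative mean z observed in the experimental group's baseline (T0)
#' resting window (zero when no negative edge exists); edges with mean z
#' above the threshold are retained.
#'
#' @param edges from [edge_summary()]
#' @param group,phase cell defining the threshold (defaults: experimental
#'   at T0)
#' @return retained edges, with attributes `threshold` and `rule`
#' @export
threshold_network <- function(edges, group = "experimental", phase = "T0") {
  ref <- edges$mean_z[edges$group == group & edges$phase == phase]
  if (!length(ref)) stop("no edges for the thresholding cell")
  threshold <- abs(min(c(ref, 0)))
  out <- edges[edges$mean_z > threshold, ]
  attr(out, "threshold") <- threshold
  attr(out, "rule") <- sprintf(
    "abs(most negative mean z in %s at %s) = %.3f", group, phase, threshold)
  out
}
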