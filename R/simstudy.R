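#' Simulate a trial feature table directly at the feature level
#'
#' Generates mean-amplitude (or latency) observations straight from the
#' mixed model's generative process — a planted coefficient on one
#' interaction product plus Gaussian subject, channel and trial variation —
#' bypassing the signal-level pipeline. This is the reduced-scale
#' calibration generator used for estimator recovery, type-I-error and
#' coverage studies, where hundreds of model fits are needed. Because the
#' planted coefficient multiplies the raw (uncentred) code product of a
#' balanced design, the true value of the corresponding fixed effect
#' equals `effect` exactly.
#'
#' @param n_per_group subjects per group
#' @param n_channels channels
#' @param n_trials trials per stimulus type per session
#' @param effect planted coefficient (response units, coding scale)
#' @param effect_term interaction receiving the effect (default: the
#'   stimulus x group-2 x phase-2 amplitude term)
#' @param sd_subject,sd_channel random intercept s.d.s
#' @param sd_subject_stim by-subject stimulus slope s.d.
#' @param sd_resid residual (single-trial) s.d.
#' @param response_name name of the generated response column
#' @param seed RNG seed
#' @export
simulate_feature_table <- function(n_per_group = 8, n_channels = 8,
                                   n_trials = 12, effect = 0.3,
                                   effect_term = "stim_grp2_phs2",
                                   sd_subject = 0.2, sd_channel = 0.2,
                                   sd_subject_stim = 0.05, sd_resid = 0.3,
                                   response_name = "mean_amplitude",
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- c("experimental", "active", "passive")
  phases <- c("T0", "T1", "T2")
  nsub <- 3 * n_per_group
  subjects <- data.frame(
    subject_id = sprintf("sub-%02d", seq_len(nsub)),
    group = rep(groups, each = n_per_group), stringsAsFactors = FALSE)
  design <- expand.grid(
    channel_id = seq_len(n_channels),
    trial = seq_len(n_trials),
    stimulus_type = c("forward", "backward"),
    phase = phases,
    subject_id = subjects$subject_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$group <- subjects$group[match(design$subject_id,
                                       subjects$subject_id)]
  design$trial_index <- design$trial +
    n_trials * (design$stimulus_type == "backward")
  design$trial <- NULL
  sch <- contrast_scheme()
  raw_stim <- unname(sch$stimulus[design$stimulus_type])
  raw_grp2 <- unname(sch$group_c2[design$group])
  raw_grp1 <- unname(sch$group_c1[design$group])
  raw_phs1 <- unname(sch$phase_c1[design$phase])
  raw_phs2 <- unname(sch$phase_c2[design$phase])
  x <- switch(effect_term,
    stim_grp2_phs2 = raw_stim * raw_grp2 * raw_phs2,
    stim_grp2_phs1 = raw_stim * raw_grp2 * raw_phs1,
    stim_grp1_phs2 = raw_stim * raw_grp1 * raw_phs2,
    stop("unsupported effect_term: ", effect_term))
  b_subj <- rnorm(nsub, 0, sd_subject)
  b_subj_stim <- rnorm(nsub, 0, sd_subject_stim)
  b_chan <- rnorm(n_channels, 0, sd_channel)
  si <- match(design$subject_id, subjects$subject_id)
  y <- effect * x + b_subj[si] + b_subj_stim[si] * raw_stim +
    b_chan[design$channel_id] + rnorm(nrow(design), 0, sd_resid)
  design[[response_name]] <- y
  attr(design, "true_effect") <- effect
  design
}

#' Simulate a connectivity pair table at the z level
#'
#' Generates Fisher-z observations for seed pairs from the reduced model's
#' generative process: a baseline z, a planted increment for the trained
#' groups (experimental and active) at T2 — whose implied group-1 x
#' phase-2 coefficient equals `delta` exactly under balanced groups — plus
#' subject, pair and residual variation.
#'
#' @param n_per_group subjects per group
#' @param n_channels montage size
#' @param seeds seed channel ids
#' @param delta planted z increment for trained groups at T2
#' @param base baseline mean z
#' @param sd_subject,sd_pair random intercept s.d.s
#' @param sd_subject_phase by-subject phase slope s.d.
#' @param sd_resid residual s.d.
#' @param seed RNG seed
#' @export
simulate_pair_table <- function(n_per_group = 6, n_channels = 10,
                                seeds = 1:3, delta = 0.2, base = 0.2,
                                sd_subject = 0.05, sd_pair = 0.05,
                                sd_subject_phase = 0.03, sd_resid = 0.1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- c("experimental", "active", "passive")
  phases <- c("T0", "T1", "T2")
  nsub <- 3 * n_per_group
  subjects <- data.frame(
    subject_id = sprintf("sub-%02d", seq_len(nsub)),
    group = rep(groups, each = n_per_group), stringsAsFactors = FALSE)
  pairs <- enumerate_seed_pairs(seeds, n_channels)
  design <- expand.grid(
    pair = seq_len(nrow(pairs)),
    phase = phases,
    subject_id = subjects$subject_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$chan_a <- pairs[design$pair, 1]
  design$chan_b <- pairs[design$pair, 2]
  design$pair_id <- paste(design$chan_a, design$chan_b, sep = "-")
  design$pair <- NULL
  design$group <- subjects$group[match(design$subject_id,
                                       subjects$subject_id)]
  si <- match(design$subject_id, subjects$subject_id)
  pi_ <- match(design$pair_id, unique(design$pair_id))
  b_subj <- rnorm(nsub, 0, sd_subject)
  b_subj_ph <- rnorm(nsub, 0, sd_subject_phase)
  b_pair <- rnorm(max(pi_), 0, sd_pair)
  trained_t2 <- design$group %in% c("experimental", "active") &
    design$phase == "T2"
  phs2 <- unname(contrast_scheme()$phase_c2[design$phase])
  design$z <- base + delta * trained_t2 + b_subj[si] +
    b_subj_ph[si] * phs2 + b_pair[pi_] +
    rnorm(nrow(design), 0, sd_resid)
  design$r <- tanh(design$z)
  attr(design, "true_effect") <- delta
  design
}
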