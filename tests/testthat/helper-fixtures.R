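# Shared fixture builders. Everything is generated in code at test time.

# noiseless ground truth with a single planted amplitude/latency structure
quiet_gt <- function(montage, amp_base = 1, amp_effect = 0, lat_base = 8,
                     lat_effect = 0, amp_channels = montage$channel_id,
                     lat_channels = montage$channel_id) {
  cells <- neonirs:::study_cells()
  amp_cells <- cbind(cells, base = amp_base, effect = 0)
  amp_cells$effect[with(amp_cells, group == "experimental" & phase == "T2" &
                          stimulus == "forward")] <- amp_effect
  lat_cells <- cbind(cells, base = lat_base, effect = 0)
  lat_cells$effect[with(lat_cells, group == "experimental" &
                          phase %in% c("T1", "T2") &
                          stimulus == "forward")] <- lat_effect
  ground_truth(amp_cells = amp_cells, amp_channels = amp_channels,
               lat_cells = lat_cells, lat_channels = lat_channels)
}

# balanced, deterministic feature table built from explicit cell means:
# cell_mean(group, phase, stimulus) -> numeric. Optional iid noise.
balanced_feature_table <- function(cell_mean, n_per_group = 2,
                                   n_channels = 2, n_trials = 2,
                                   noise_sd = 0, seed = 1) {
  set.seed(seed)
  groups <- c("experimental", "active", "passive")
  phases <- c("T0", "T1", "T2")
  subjects <- data.frame(
    subject_id = sprintf("sub-%02d", seq_len(3 * n_per_group)),
    group = rep(groups, each = n_per_group), stringsAsFactors = FALSE)
  design <- expand.grid(channel_id = seq_len(n_channels),
                        trial = seq_len(n_trials),
                        stimulus_type = c("forward", "backward"),
                        phase = phases,
                        subject_id = subjects$subject_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$group <- subjects$group[match(design$subject_id,
                                       subjects$subject_id)]
  design$trial_index <- design$trial
  design$trial <- NULL
  mu <- mapply(cell_mean, design$group, design$phase, design$stimulus_type)
  design$mean_amplitude <- mu + rnorm(nrow(design), 0, noise_sd)
  design$peak_latency <- design$mean_amplitude
  design
}

# OLS oracle for a fixed term on a coded table (independent of lme4)
ols_beta <- function(table, response, term) {
  X <- as.matrix(cbind(1, table[, neonirs:::lmm_fixed_terms()]))
  colnames(X)[1] <- "(Intercept)"
  b <- solve(crossprod(X), crossprod(X, table[[response]]))
  unname(b[term, 1])
}

# single-sided FFT amplitude of a real series at the bin nearest f
fft_amplitude <- function(x, f, fs) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  freqs <- (seq_len(n) - 1) * fs / n
  sp[which.min(abs(freqs - f))]
}
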