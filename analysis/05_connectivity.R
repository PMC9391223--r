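#!/usr/bin/env Rscript
# Resting-state functional connectivity: Pearson correlations between the
# seed channels (FDR survivors of the amplitude and latency analyses,
# unioned) and all other channels in the 3-min pre-test windows, Fisher
# z-transformed, then the reduced group x phase mixed model, per-pair
# interaction tests at uncorrected alpha = 0.05, and the thresholded
# network summary.

suppressPackageStartupMessages(library(neonirs))

study <- read_study(file.path("results", "dataset"))
params <- do.call(mbll_params, study$config$mbll[c("extinction", "dpf",
                                                   "log_base")])
amp <- jsonlite::read_json(file.path("results", "amplitude_report.json"),
                           simplifyVector = TRUE)
lat <- jsonlite::read_json(file.path("results", "latency_report.json"),
                           simplifyVector = TRUE)
seeds <- sort(union(amp$seed_channels, lat$seed_channels))
if (!length(seeds)) seeds <- study$montage$channel_id
cat("seed channels:", paste(seeds, collapse = ", "), "\n")

windows <- list()
for (sid in study$subjects$subject_id) {
  windows[[sid]] <- list()
  for (phase in names(study$recordings[[sid]])) {
    raw <- study$recordings[[sid]][[phase]]
    hemo <- run_preprocessing(raw, params,
                              list(distance = study$montage$distance_cm[1]))
    windows[[sid]][[phase]] <- resting_window(hemo, raw$rest_duration, 180)
  }
}

pairs <- build_pair_table(windows, study$subjects, seeds,
                          nrow(study$montage))
pairs <- code_contrasts(pairs)
fit <- fit_connectivity_lmm(pairs, re = "reduced")
key <- fit$coefficients[fit$coefficients$term == "grp1_phs2", ]
cat(sprintf("group-1 x phase-2 interaction on z: beta = %.3f, sem = %.3f, t(%.1f) = %.2f, p = %.3g\n",
            key$beta, key$sem, key$df, key$t, key$p))

pp <- per_pair_tests(pairs)
cat(sprintf("%d of %d pairs significant at alpha = 0.05 (%d positive, %d negative)\n",
            pp$n_significant, nrow(pp$pairs), pp$n_positive, pp$n_negative))
edges <- edge_summary(pairs)
net <- threshold_network(edges)
cat(sprintf("display threshold %.3f retains %d edges\n",
            attr(net, "threshold"), nrow(net)))

write.table(pairs[, c("subject_id", "group", "phase", "chan_a", "chan_b",
                      "r", "z")],
            file.path("results", "pair_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(edges, file.path("results", "edge_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seeds = seeds, coefficients = fit$coefficients,
       n_pairs = nrow(pp$pairs), n_significant = pp$n_significant,
       n_positive = pp$n_positive, n_negative = pp$n_negative,
       network_threshold = attr(net, "threshold")),
  file.path("results", "connectivity_report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("tables -> results/pair_table.tsv, results/edge_summary.tsv\n")
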