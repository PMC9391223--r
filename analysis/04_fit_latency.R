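#!/usr/bin/env Rscript
# Mixed-effects analysis of trial peak latency: same model as the
# amplitude analysis; the critical term is stimulus x group-2 x phase-1
# (training effect at T1/T2 vs baseline). Per-channel refits and BH-FDR
# selection as for amplitude.

suppressPackageStartupMessages(library(neonirs))

features <- read_feature_table(file.path("results", "feature_table.tsv"))
rep <- run_latency_analysis(features, q_star = 0.15, re = "reduced")

cf <- rep$fit$coefficients
key <- cf[cf$term == rep$term, ]
cat(sprintf("latency three-way interaction: beta = %.3f s, sem = %.3f, t(%.1f) = %.2f, p = %.3g\n",
            key$beta, key$sem, key$df, key$t, key$p))
cat("FDR-selected latency channels:",
    paste(rep$seed_channels, collapse = ", "), "\n")

write.table(rep$channel_table, file.path("results", "latency_channels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(term = rep$term, coefficients = cf, seed_channels = rep$seed_channels,
       q_star = rep$q_star),
  file.path("results", "latency_report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("per-channel table -> results/latency_channels.tsv\n")
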