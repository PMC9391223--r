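#' Fit the full-factorial mixed-effects model
#'
#' Fits the trial-level model of a response (mean amplitude or peak
#' latency) on the 17 centred contrast columns (5 mains, 8 two-way and 4
#' three-way between-factor products) with uncorrelated random effects:
#' by participant, the intercept and the within-subject terms (stimulus,
#' the two phase contrasts and their products with stimulus); by channel,
#' the intercept and every fixed term. Estimation is REML via lme4;
#' p-values use the Satterthwaite degrees-of-freedom approximation
#' (lmerTest). Singular fits (variance components estimated at zero) are
#' returned, flagged, rather than failing.
#'
#' @param table coded feature table (see [code_contrasts()]; coding is
#'   applied here if absent)
#' @param response column to model ("mean_amplitude" or "peak_latency")
#' @param re by-channel random-effect structure: "maximal" (intercept +
#'   all fixed terms), "reduced" (intercept only), or "none" (participant
#'   random effects only)
#' @param subject_re by-participant structure: "maximal" (intercept + all
#'   within-subject terms; the default, as in the primary analyses) or
#'   "intercept_stim" (intercept + stimulus slope; the leaner structure
#'   used by the repeated calibration simulations, whose generative
#'   process contains exactly those terms)
#' @param channel_terms optional character vector restricting the
#'   by-channel random slopes to the named fixed terms (intercept always
#'   included); overrides `re` when supplied
#' @return object of class `lmm_fit`: the lmerMod plus a coefficient table
#'   (term, beta, sem, df, t, p), variance components and convergence flags
#' @export
fit_lmm <- function(table, response = "mean_amplitude",
                    re = c("maximal", "reduced", "none"),
                    subject_re = c("maximal", "intercept_stim"),
                    channel_terms = NULL) {
  re <- match.arg(re)
  subject_re <- match.arg(subject_re)
  if (!"stim_c" %in% names(table)) table <- code_contrasts(table)
  if (!response %in% names(table)) stop("response column not found: ", response)
  if (length(unique(table$subject_id)) < 2) stop("need >= 2 participants")
  fixed <- lmm_fixed_terms()
  within <- switch(subject_re,
    maximal = c("stim_c", "phs1_c", "phs2_c", "stim_phs1", "stim_phs2"),
    intercept_stim = "stim_c")
  re_subj <- sprintf("(1 + %s || subject_id)", paste(within, collapse = " + "))
  re_chan <- if (!is.null(channel_terms)) {
    stopifnot(all(channel_terms %in% fixed))
    sprintf("(1 + %s || channel_id)", paste(channel_terms, collapse = " + "))
  } else switch(re,
    maximal = sprintf("(1 + %s || channel_id)", paste(fixed, collapse = " + ")),
    reduced = "(1 | channel_id)",
    none = NULL)
  rhs <- paste(c(fixed, re_subj, re_chan), collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  data <- table[stats::complete.cases(table[, c(response, fixed)]), ]
  X <- as.matrix(data[, fixed])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop <- setdiff(seq_len(ncol(X) + 1), qrX$pivot[seq_len(qrX$rank)]) - 1L
    stop("rank-deficient fixed design; collinear column(s): ",
         paste(fixed[drop], collapse = ", "))
  }
  model <- withCallingHandlers(
    lmerTest::lmer(form, data = data, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) invokeRestart("muffleWarning"))
  new_lmm_fit(model, response)
}

new_lmm_fit <- function(model, response) {
  cf <- stats::coef(summary(model))
  coefficients <- data.frame(
    term = rownames(cf), beta = cf[, "Estimate"],
    sem = cf[, "Std. Error"], df = cf[, "df"], t = cf[, "t value"],
    p = cf[, "Pr(>|t|)"], stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    model = model, response = response, coefficients = coefficients,
    varcor = lme4::VarCorr(model),
    singular = lme4::isSingular(model),
    converged = length(model@optinfo$conv$lme4$messages) == 0
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> response: %s%s\n", x$response,
              if (x$singular) " (singular fit; some variances at 0)" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Satterthwaite denominator degrees of freedom for one term
#'
#' @param fit an `lmm_fit`
#' @param term fixed-term name (as in `fit$coefficients$term`)
#' @return effective df; falls back to Inf (normal approximation) with a
#'   warning when the Satterthwaite computation is unavailable
#' @export
satterthwaite_df <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("unknown term: ", term)
  df <- fit$coefficients$df[i]
  if (!is.finite(df) || df <= 0) {
    warning("Satterthwaite df unavailable for ", term,
            "; using the normal approximation (df = Inf)")
    return(Inf)
  }
  df
}

#' Per-channel BLUPs for a fixed term
#'
#' Channel-level effect estimates formed as the fixed effect plus the
#' conditional mode of the corresponding by-channel random slope. With the
#' channel slope variance estimated at zero the conditional modes vanish
#' and every channel estimate collapses to the fixed effect (complete
#' shrinkage).
#'
#' @param fit an `lmm_fit` with by-channel random effects
#' @param term fixed-term name; "(Intercept)" is allowed
#' @return data.frame (channel_id, blup, cond_mode)
#' @export
extract_blups <- function(fit, term) {
  beta <- fit$coefficients$beta[match(term, fit$coefficients$term)]
  if (is.na(beta)) stop("unknown term: ", term)
  re <- lme4::ranef(fit$model)
  hit <- NULL
  for (i in seq_along(re)) {
    if (names(re)[i] == "channel_id" && term %in% colnames(re[[i]])) {
      hit <- re[[i]][, term]
      ids <- rownames(re[[i]])
      break
    }
  }
  if (is.null(hit)) stop("no by-channel random slope for term: ", term)
  data.frame(channel_id = as.integer(ids), blup = beta + hit,
             cond_mode = hit, row.names = NULL)
}

#' Refit the model within one channel
#'
#' Same fixed structure, by-participant random effects only (a single
#' channel leaves nothing for by-channel terms to group over). Emits the
#' per-channel report row for the requested term: channel, region, beta,
#' sem, df, t, p.
#'
#' @param table coded feature table
#' @param channel_id channel to refit
#' @param response response column
#' @param term fixed term reported in the row
#' @export
per_channel_fit <- function(table, channel_id, response = "mean_amplitude",
                            term = "stim_grp2_phs2") {
  sub <- table[table$channel_id == channel_id, ]
  if (nrow(sub) == 0) stop("channel not present: ", channel_id)
  # re-centre contrasts within the channel subset
  drop <- intersect(names(sub), c(lmm_fixed_terms()))
  sub <- sub[, setdiff(names(sub), drop)]
  sub <- code_contrasts(sub)
  fit <- fit_lmm(sub, response, re = "none")
  i <- match(term, fit$coefficients$term)
  region <- if ("region" %in% names(sub)) sub$region[1] else NA_character_
  row <- data.frame(channel = channel_id, region = region,
                    beta = fit$coefficients$beta[i],
                    sem = fit$coefficients$sem[i],
                    df = fit$coefficients$df[i],
                    t = fit$coefficients$t[i],
                    p = fit$coefficients$p[i],
                    stringsAsFactors = FALSE)
  attr(row, "fit") <- fit
  row
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up false-discovery-rate control: q-values are the BH-adjusted
#' p-values and the selected set is every test with q <= q_star
#' (equivalently, all ranks up to the largest k with p_(k) <= k q*/m).
#'
#' @param pvals p-values in [0, 1]
#' @param q_star FDR threshold (default 0.15)
#' @return data.frame (p, q, selected) in input order
#' @export
bh_fdr <- function(pvals, q_star = 0.15) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, q = q, selected = !is.na(q) & q <= q_star)
}

run_channel_analysis <- function(table, response, term, q_star, re) {
  if (!"stim_c" %in% names(table)) table <- code_contrasts(table)
  fit <- fit_lmm(table, response, re = re)
  blups <- if (re == "maximal") extract_blups(fit, term) else NULL
  channels <- sort(unique(table$channel_id))
  rows <- lapply(channels, function(ch) {
    per_channel_fit(table, ch, response = response, term = term)
  })
  channel_table <- do.call(rbind, rows)
  fdr <- bh_fdr(channel_table$p, q_star)
  list(response = response, term = term, fit = fit, blups = blups,
       channel_table = channel_table, fdr = fdr,
       seed_channels = channel_table$channel[fdr$selected],
       q_star = q_star)
}

#' Amplitude / latency analyses
#'
#' The two trial-level analyses: the full mixed model, per-channel BLUPs
#' for the critical three-way interaction, per-channel refits, and BH-FDR
#' channel selection. For mean amplitude the critical term is stimulus x
#' group contrast 2 (active vs experimental) x phase contrast 2 (T1 vs
#' T2); for peak latency it is stimulus x group contrast 2 x phase
#' contrast 1 (T0 vs mean(T1, T2)).
#'
#' @param table trial feature table
#' @param q_star FDR threshold for seed selection
#' @param re by-channel random structure passed to [fit_lmm()]
#' @return list with the full fit, BLUP map, per-channel table, FDR result
#'   and selected seed channels
#' @export
run_amplitude_analysis <- function(table, q_star = 0.15, re = "maximal") {
  run_channel_analysis(table, "mean_amplitude", "stim_grp2_phs2", q_star, re)
}

#' @rdname run_amplitude_analysis
#' @export
run_latency_analysis <- function(table, q_star = 0.15, re = "maximal") {
  run_channel_analysis(table, "peak_latency", "stim_grp2_phs1", q_star, re)
}

#' Seed-channel union from the two analyses
#'
#' @param amplitude,latency reports from [run_amplitude_analysis()] and
#'   [run_latency_analysis()]
#' @return integer vector of seed channel ids with provenance attributes
#' @export
fdr_seed_union <- function(amplitude, latency) {
  seeds <- sort(union(amplitude$seed_channels, latency$seed_channels))
  attr(seeds, "provenance") <- sprintf(
    "BH-FDR q* = %g: amplitude {%s}, latency {%s}", amplitude$q_star,
    paste(amplitude$seed_channels, collapse = ","),
    paste(latency$seed_channels, collapse = ","))
  seeds
}
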