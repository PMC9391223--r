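test_that("the three-way amplitude beta recovers the coding-implied value", {
  # planting a forward-backward difference d in experimental at T2 only
  # implies a stimulus x group2 x phase2 coefficient of exactly d under
  # the scheme's codes (orthogonal balanced design)
  d <- 0.8
  cell <- function(g, p, s) {
    if (g == "experimental" && p == "T2" && s == "forward") d else 0
  }
  tab <- code_contrasts(balanced_feature_table(cell, n_per_group = 2,
                                               n_channels = 2, n_trials = 2,
                                               noise_sd = 1e-8, seed = 3))
  # independent OLS oracle on the same coded design
  expect_equal(ols_beta(tab, "mean_amplitude", "stim_grp2_phs2"), d,
               tolerance = 1e-6)
  fit <- fit_lmm(tab, "mean_amplitude", re = "reduced")
  beta <- fit$coefficients$beta[fit$coefficients$term == "stim_grp2_phs2"]
  expect_equal(beta, d, tolerance = 1e-6)
})

test_that("with negligible random variance the fit matches OLS", {
  set.seed(21)
  cell <- function(g, p, s) 0.3 * (s == "forward")
  tab <- code_contrasts(balanced_feature_table(cell, n_per_group = 2,
                                               n_channels = 2, n_trials = 3,
                                               noise_sd = 0.5, seed = 21))
  fit <- fit_lmm(tab, "mean_amplitude", re = "reduced")
  for (term in c("stim_c", "grp2_c", "stim_grp2_phs2")) {
    expect_equal(fit$coefficients$beta[fit$coefficients$term == term],
                 ols_beta(tab, "mean_amplitude", term), tolerance = 1e-6)
  }
  # iid data: variance components collapse and the fit reports singularity
  expect_true(fit$singular)
})

test_that("Satterthwaite df matches the balanced between-subject oracle", {
  # 2 groups x g subjects, m replicates, subject random intercept:
  # classical between-subject df = 2g - 2
  set.seed(5)
  g <- 6; m <- 4
  dat <- expand.grid(rep = 1:m, subject = 1:(2 * g))
  dat$grp <- ifelse(dat$subject <= g, -0.5, 0.5)
  b <- rnorm(2 * g, 0, 1)
  dat$y <- 0.4 * dat$grp + b[dat$subject] + rnorm(nrow(dat), 0, 1)
  fit <- lmerTest::lmer(y ~ grp + (1 | subject), data = dat)
  df <- coef(summary(fit))["grp", "df"]
  expect_lt(abs(df - (2 * g - 2)), 0.5)
})

test_that("zero random variance drives Satterthwaite df to the residual df", {
  set.seed(6)
  tab <- code_contrasts(balanced_feature_table(function(g, p, s) 0,
                                               n_per_group = 2,
                                               n_channels = 2, n_trials = 2,
                                               noise_sd = 1, seed = 6))
  fit <- fit_lmm(tab, "mean_amplitude", re = "reduced")
  expect_true(fit$singular)
  df <- satterthwaite_df(fit, "stim_c")
  expect_gt(df, 0)
  resid_df <- nrow(tab) - 18
  expect_gt(df / resid_df, 0.8)
  expect_error(satterthwaite_df(fit, "nope"), "unknown term")
})

test_that("BLUP shrinkage behaves across the channel-variance range", {
  # no channel heterogeneity: every channel estimate equals the fixed beta
  set.seed(31)
  tab <- code_contrasts(simulate_feature_table(
    n_per_group = 4, n_channels = 6, n_trials = 4, effect = 0.4,
    sd_channel = 0, sd_resid = 0.2, seed = 31))
  fit <- fit_lmm(tab, subject_re = "intercept_stim",
                 channel_terms = "stim_grp2_phs2")
  bl <- extract_blups(fit, "stim_grp2_phs2")
  expect_equal(nrow(bl), 6L)
  beta <- fit$coefficients$beta[fit$coefficients$term == "stim_grp2_phs2"]
  expect_lt(max(abs(bl$blup - beta)), 0.05)
  # conditional modes centre near zero
  expect_lt(abs(mean(bl$cond_mode)), 0.05)
  expect_error(extract_blups(fit, "made_up"), "unknown term")
})

test_that("a channel-specific effect surfaces as the largest BLUP", {
  set.seed(41)
  tab <- simulate_feature_table(n_per_group = 6, n_channels = 6,
                                n_trials = 8, effect = 0, sd_channel = 0.1,
                                sd_resid = 0.2, seed = 41)
  # add a strong three-way effect at channel 3 only
  sch <- contrast_scheme()
  x3 <- unname(sch$stimulus[tab$stimulus_type]) *
    unname(sch$group_c2[tab$group]) * unname(sch$phase_c2[tab$phase])
  tab$mean_amplitude <- tab$mean_amplitude + 2 * x3 * (tab$channel_id == 3)
  fit <- fit_lmm(code_contrasts(tab), subject_re = "intercept_stim",
                 channel_terms = "stim_grp2_phs2")
  bl <- extract_blups(fit, "stim_grp2_phs2")
  expect_equal(bl$channel_id[which.max(bl$blup)], 3L)
})

test_that("per-channel refits recover planted effects and report the row", {
  d <- 0.6
  cell <- function(g, p, s) {
    if (g == "experimental" && p == "T2" && s == "forward") d else 0
  }
  tab <- balanced_feature_table(cell, n_per_group = 2, n_channels = 3,
                                n_trials = 2, noise_sd = 1e-8, seed = 51)
  tab$region <- paste("left", c("IF", "ST", "other"))[tab$channel_id]
  row <- per_channel_fit(code_contrasts(tab), 2)
  expect_named(row, c("channel", "region", "beta", "sem", "df", "t", "p"))
  expect_equal(row$beta, d, tolerance = 1e-6)
  expect_equal(row$channel, 2)
  expect_equal(row$region, "left ST")
  expect_error(per_channel_fit(code_contrasts(tab), 99), "not present")
})

test_that("analysis reports name the critical terms and select channels", {
  set.seed(61)
  tab <- simulate_feature_table(n_per_group = 5, n_channels = 4,
                                n_trials = 6, effect = 1.2,
                                sd_resid = 0.25, seed = 61)
  tab$peak_latency <- tab$mean_amplitude
  amp <- run_amplitude_analysis(tab, re = "reduced")
  expect_equal(amp$term, "stim_grp2_phs2")
  expect_equal(nrow(amp$channel_table), 4L)
  lat <- run_latency_analysis(tab, re = "reduced")
  expect_equal(lat$term, "stim_grp2_phs1")
  seeds <- fdr_seed_union(amp, lat)
  expect_true(all(seeds %in% 1:4))
  # an effect this large is picked up on every channel
  expect_true(all(amp$fdr$selected))
})

test_that("the maximal random structures fit and expose every channel slope", {
  tab <- code_contrasts(simulate_feature_table(
    n_per_group = 2, n_channels = 3, n_trials = 3, effect = 0.5, seed = 8))
  fit <- fit_lmm(tab, re = "maximal")
  expect_equal(nrow(fit$coefficients), 18L)
  bl <- extract_blups(fit, "stim_grp2_phs2")
  expect_equal(bl$channel_id, 1:3)
  # intercept BLUPs are available too
  expect_equal(nrow(extract_blups(fit, "(Intercept)")), 3L)
  pt <- code_contrasts(simulate_pair_table(
    n_per_group = 3, n_channels = 6, seeds = 1:2, delta = 0.3, seed = 9))
  fc <- fit_connectivity_lmm(pt, re = "maximal")
  expect_equal(nrow(fc$coefficients), 9L)
})

test_that("small planted effects are recovered without bias and with calibrated CIs", {
  # same reduced-scale design as the main calibration study, at the
  # weaker effect size
  delta <- 0.1
  rec <- t(vapply(1:100, function(i) {
    tab <- simulate_feature_table(n_per_group = 8, n_channels = 8,
                                  n_trials = 12, effect = delta,
                                  seed = 9000 + i)
    fit <- fit_lmm(code_contrasts(tab), re = "reduced",
                   subject_re = "intercept_stim")
    row <- fit$coefficients[fit$coefficients$term == "stim_grp2_phs2", ]
    c(row$beta, row$sem, row$df)
  }, numeric(3)))
  expect_lt(abs(mean(rec[, 1]) - delta) / delta, 0.10)
  cover <- mean(abs(rec[, 1] - delta) <= qt(0.975, rec[, 3]) * rec[, 2])
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})
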