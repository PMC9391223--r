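test_that("noise-free sessions superimpose kernels with planted parameters", {
  m <- make_montage(4)
  gt <- quiet_gt(m, amp_base = 0)
  sch <- make_test_schedule(2, 2, seed = 3)
  out <- simulate_session(m, sch, gt, "experimental", "T0", noise = FALSE)
  expect_true(all(out$clean$hbo == 0))          # zero amplitude, zero signal

  gt1 <- quiet_gt(m, amp_base = 1)
  one <- data.frame(onset = 10, duration = 6, trial_type = "forward",
                    trial_index = 1L)
  attr(one, "total_duration") <- 60
  out1 <- simulate_session(m, one, gt1, "active", "T1", noise = FALSE)
  # epoch mean over the kernel support equals the brute-force kernel mean
  fs <- 10
  tg <- (seq_len(600) - 1) / fs - 10
  kern <- hrf_kernel(tg, peak_time = 8, dispersion = 1, amplitude = 1)
  kern[tg <= 0 | tg >= 30] <- 0  # the generator's kernel support
  expect_equal(mean(out1$clean$hbo[1, ]), mean(kern), tolerance = 1e-9)
  # maximum lands at the planted peak time
  expect_equal(tg[which.max(out1$clean$hbo[2, ])], 8)
})

test_that("evoked amplitude is linear in the planted amplitude", {
  m <- make_montage(2)
  sch <- make_test_schedule(3, 3, seed = 5)
  base <- simulate_session(m, sch, quiet_gt(m, amp_base = 1), "passive",
                           "T0", noise = FALSE)$clean$hbo
  for (a in c(0.25, 2, 7.5)) {
    scaled <- simulate_session(m, sch, quiet_gt(m, amp_base = a), "passive",
                               "T0", noise = FALSE)$clean$hbo
    expect_equal(scaled, a * base, tolerance = 1e-6)
  }
})

test_that("session simulation is deterministic and validates its schedule", {
  m <- make_montage(2)
  gt <- default_ground_truth(m)
  sch <- make_test_schedule(2, 2, seed = 9)
  a <- simulate_session(m, sch, gt, "experimental", "T2", seed = 21)
  b <- simulate_session(m, sch, gt, "experimental", "T2", seed = 21)
  expect_identical(a$noisy$hbo, b$noisy$hbo)
  expect_error(simulate_session(m, sch, gt, "experimental", "T2",
                                duration = 10), "beyond")
  expect_error(neonirs:::gt_cell(gt$amp_cells, "experimental", "T9",
                                 "forward"), "cell")
})

test_that("deoxy trace is a scaled delayed copy of the oxy trace", {
  m <- make_montage(2)
  gt <- quiet_gt(m, amp_base = 1)
  sch <- make_test_schedule(2, 2, seed = 2)
  out <- simulate_session(m, sch, gt, "active", "T0", noise = FALSE)
  n <- ncol(out$clean$hbo)
  d <- 10  # 1 s at 10 Hz
  expect_equal(out$clean$hb[, (d + 1):n], -0.3 * out$clean$hbo[, 1:(n - d)],
               tolerance = 1e-12)
})

test_that("resting windows hit their planted correlation targets", {
  m <- make_montage(8)
  gt <- default_ground_truth(m)
  gt$conn_base <- 0
  gt$conn_cells <- data.frame(group = "experimental", phase = "T0",
                              increment = 0.6)
  gt$conn_pairs <- cbind(6L, 7L)
  w <- simulate_resting(m, 180, gt, "experimental", "T0", seed = 31,
                        noise = TRUE)
  expect_equal(ncol(w$hbo), 1800L)      # 3 min at 10 Hz
  r <- cor(w$hbo[6, ], w$hbo[7, ])
  expect_lt(abs(r - 0.6), 0.15)
  # independent channels decorrelate
  r_off <- cor(w$hbo[1, ], w$hbo[3, ])
  expect_lt(abs(r_off), 0.2)
  expect_error(simulate_resting(m, 5, gt), ">= 10")
})

test_that("resting correlation targeting is unbiased across seeds", {
  m <- make_montage(4)
  gt <- default_ground_truth(m)
  gt$conn_base <- 0
  gt$conn_cells <- data.frame(group = "active", phase = "T1",
                              increment = 0.6)
  gt$conn_pairs <- cbind(1L, 2L)
  # the target is the correlation of the band-limited process itself
  rs <- vapply(1:60, function(s) {
    w <- simulate_resting(m, 120, gt, "active", "T1", seed = 1000 + s,
                          noise = FALSE)
    cor(w$hbo[1, ], w$hbo[2, ])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.02)
})

test_that("study simulation is reproducible and respects the group design", {
  cfg <- study_config(groups = c(experimental = 2L, active = 1L,
                                 passive = 1L),
                      n_channels = 4L, n_forward = 2L, n_backward = 2L,
                      rest_duration = 30)
  s1 <- simulate_study(cfg, seed = 5)
  s2 <- simulate_study(cfg, seed = 5)
  expect_equal(nrow(s1$subjects), 4L)
  expect_equal(sum(s1$subjects$group == "experimental"), 2L)
  expect_named(s1$recordings[["sub-01"]], c("T0", "T1", "T2"))
  expect_identical(s1$recordings[["sub-03"]][["T1"]]$intensity,
                   s2$recordings[["sub-03"]][["T1"]]$intensity)
  expect_error(simulate_study(study_config(groups = c(experimental = 0L,
                                                      active = 1L,
                                                      passive = 1L))),
               "at least one")
  expect_error(study_config(bogus = 1), "unknown")
})
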