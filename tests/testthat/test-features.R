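toy_series <- function(nch = 2, n = 6000, fill = 0) {
  hemo_series(matrix(fill, nch, n), matrix(fill, nch, n))
}

toy_epoch <- function(values, valid = NULL) {
  nch <- nrow(values)
  structure(list(hbo = values, hb = -0.3 * values,
                 time = seq(-2, 20, by = 0.1), fs = 10,
                 trial_index = 1L, stimulus_type = "forward",
                 valid = if (is.null(valid)) rep(TRUE, nch) else valid,
                 baseline_window = c(-2, 0)),
            class = "nirs_epoch")
}

test_that("epoching yields 221-sample windows and drops edge events", {
  sch <- make_test_schedule(12, 12, seed = 17)
  sch$onset <- sch$onset + 30     # room for the baseline and final window
  dur <- attr(sch, "total_duration") + 40
  ser <- toy_series(3, round(dur * 10))
  eps <- epoch_series(ser, sch)
  expect_equal(length(eps), 24L)
  expect_true(all(vapply(eps, function(e) ncol(e$hbo), 1L) == 221L))
  # event too close to the recording end is dropped and logged
  short <- toy_series(3, round((sch$onset[24] + 1) * 10))
  eps2 <- epoch_series(short, sch)
  expect_lt(length(eps2), 24L)
  expect_gt(attr(eps2, "dropped"), 0L)
  expect_error(epoch_series(ser, sch, window = c(20, -2)), "inverted")
})

test_that("masked samples invalidate only the affected channels", {
  sch <- data.frame(onset = 10, duration = 6, trial_type = "forward",
                    trial_index = 1L)
  ser <- toy_series(3, 600)
  ser$mask[2, 130:140] <- FALSE   # inside the epoch of channel 2 only
  eps <- epoch_series(ser, sch)
  expect_equal(eps[[1]]$valid, c(TRUE, FALSE, TRUE))
})

test_that("baseline correction is exact and idempotent", {
  ep <- toy_epoch(matrix(3.7, 2, 221))
  bc <- baseline_correct(ep)
  expect_true(all(bc$hbo == 0))
  expect_equal(baseline_correct(bc)$hbo, bc$hbo)
  # ramp 0.1 t: baseline mean is removed exactly
  ramp <- matrix(rep(0.1 * seq(-2, 20, by = 0.1), each = 1), 1, 221,
                 byrow = FALSE)
  bc2 <- baseline_correct(toy_epoch(ramp))
  bl <- bc2$time >= -2 & bc2$time < 0
  expect_equal(mean(bc2$hbo[1, bl]), 0, tolerance = 1e-12)
})

test_that("mean amplitude equals brute-force averaging over 6-16 s", {
  ep <- baseline_correct(toy_epoch(matrix(1, 2, 221)))
  ep$hbo[] <- 1  # constant 1 after baseline by construction
  expect_equal(unname(mean_amplitude(ep)), c(1, 1))
  # kernel epoch: amplitude equals the hand-computed sample average
  tg <- seq(-2, 20, by = 0.1)
  kern <- hrf_kernel(tg, 8, 1, 1.4)
  ep2 <- toy_epoch(matrix(kern, 1, 221, byrow = TRUE))
  expect_equal(unname(mean_amplitude(ep2))[1],
               mean(kern[tg >= 6 & tg <= 16]), tolerance = 1e-12)
  # antisymmetric signal about t = 11 s averages to zero
  anti <- sin(2 * pi * (tg - 11) / 10)
  ep3 <- toy_epoch(matrix(anti, 1, 221, byrow = TRUE))
  expect_equal(unname(mean_amplitude(ep3))[1], 0, tolerance = 1e-12)
  expect_error(mean_amplitude(ep2, window = c(6, 30)), "inside")
  ep4 <- toy_epoch(matrix(1, 2, 221), valid = c(TRUE, FALSE))
  expect_true(is.na(mean_amplitude(ep4)[2]))
})

test_that("peak latency is the earliest-tie argmax on the sample grid", {
  tg <- seq(-2, 20, by = 0.1)
  kern <- hrf_kernel(tg, 8, 1, 1)
  ep <- toy_epoch(matrix(kern, 1, 221, byrow = TRUE))
  expect_equal(unname(peak_latency(ep))[1], 8)
  # two equal maxima: earliest wins
  twin <- numeric(221)
  twin[tg == 7] <- 5; twin[tg == 9] <- 5
  expect_equal(unname(peak_latency(toy_epoch(matrix(twin, 1))))[1], 7)
  # scaling invariance
  expect_equal(peak_latency(toy_epoch(matrix(3.3 * kern, 1))),
               peak_latency(ep))
  # brute-force scan oracle on random epochs
  set.seed(99)
  for (i in 1:200) {
    x <- rnorm(221)
    ep_r <- toy_epoch(matrix(x, 1))
    sel <- tg >= 0 & tg <= 20
    expect_equal(unname(peak_latency(ep_r))[1], tg[sel][which.max(x[sel])])
  }
  # search excludes the pre-stimulus baseline by default
  pre <- numeric(221); pre[tg == -1] <- 10; pre[tg == 5] <- 3
  expect_equal(unname(peak_latency(toy_epoch(matrix(pre, 1))))[1], 5)
})

test_that("feature table row counts follow the mask bookkeeping", {
  m <- make_montage(4)
  sch <- make_test_schedule(12, 12, seed = 23)
  sch$onset <- sch$onset + 30
  ser <- toy_series(4, round((attr(sch, "total_duration") + 40) * 10),
                    fill = 0)
  set.seed(1); ser$hbo[] <- rnorm(length(ser$hbo))
  eps <- epoch_series(ser, sch)
  tab <- build_feature_table(eps, "sub-01", "experimental", "T0", m)
  expect_equal(nrow(tab), 24 * 4)
  expect_equal(tab$trial_index, rep(1:24, each = 4))
  # masking trials removes exactly the invalidated trial x channel cells
  ser2 <- ser
  for (e in 1:12) {
    i0 <- round(sch$onset[e] * 10) + 1
    ser2$mask[, (i0 - 20):(i0 + 200)] <- FALSE
  }
  eps2 <- epoch_series(ser2, sch)
  tab2 <- build_feature_table(eps2, "sub-01", "experimental", "T0", m)
  n_valid <- sum(vapply(eps2, function(e) sum(e$valid), 1L))
  expect_equal(nrow(tab2), n_valid)
  expect_lte(nrow(tab2), 12 * 4)     # at least the 12 masked trials gone
  expect_lt(nrow(tab2), nrow(tab))
  # everything masked gives an empty table with a warning
  ser3 <- ser; ser3$mask[] <- FALSE
  expect_warning(
    tab3 <- build_feature_table(epoch_series(ser3, sch), "s", "g", "T0", m),
    "empty")
  expect_equal(nrow(tab3), 0L)
})
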