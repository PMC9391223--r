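make_quiet_raw <- function(nch = 2, n = 600, value = 1) {
  raw_recording(array(value, dim = c(nch, 2, n)))
}

test_that("saturation screen flags only sustained clipped runs", {
  raw <- make_quiet_raw(3)
  raw$intensity[2, 1, ] <- 2                     # pinned at range max
  raw$intensity[3, 2, 100] <- 2                  # single-sample touch
  flags <- screen_saturation(raw, run_length = 10)
  expect_equal(flags, c(FALSE, TRUE, FALSE))
  expect_equal(sum(screen_saturation(make_quiet_raw(4))), 0L)
})

test_that("artifact-epoch masking applies the dynamic-range rule per cell", {
  n <- 600
  raw <- make_quiet_raw(2, n)
  ev <- data.frame(onset = c(5, 30), duration = 6,
                   trial_type = c("forward", "backward"),
                   trial_index = 1:2)
  raw$events <- ev
  # epoch 1, channel 1: peak-to-peak 0.25 x range width (= 0.5) -> masked
  raw$intensity[1, 1, 60:70] <- 1 + 0.25 * 2
  out <- remove_artifact_epochs(raw, fraction = 0.2)
  i0 <- round(5 * 10) + 1
  expect_false(any(out$mask[1, (i0 - 20):(i0 + 200)]))
  expect_true(all(out$mask[2, ]))                # other channel untouched
  expect_equal(out$removed_fraction, 1 / 4)      # 1 of 2 epochs x 2 channels
  # all-quiet data removes nothing
  quiet <- make_quiet_raw(2, n); quiet$events <- ev
  expect_equal(remove_artifact_epochs(quiet)$removed_fraction, 0)
})

test_that("lowering the artifact threshold never unmasks data", {
  set.seed(8)
  n <- 600
  raw <- make_quiet_raw(3, n)
  raw$intensity <- raw$intensity +
    array(rnorm(length(raw$intensity), 0, 0.08), dim = dim(raw$intensity))
  raw$events <- data.frame(onset = seq(2, 50, by = 8), duration = 6,
                           trial_type = "forward",
                           trial_index = seq_along(seq(2, 50, by = 8)))
  masks <- lapply(c(0.3, 0.2, 0.1, 0.05), function(f) {
    remove_artifact_epochs(raw, fraction = f)$mask
  })
  for (i in 2:length(masks)) {
    expect_true(all(masks[[i]] <= masks[[i - 1]]))  # monotone masking
  }
})

test_that("spike correction repairs inserted jumps and nothing else", {
  fs <- 10
  t <- (0:999) / fs
  base <- 1 + 0.05 * sin(2 * pi * 0.05 * t)
  raw <- make_quiet_raw(1, 1000)
  raw$intensity[1, 1, ] <- base
  raw$intensity[1, 2, ] <- base
  # clean sinusoid passes through unchanged
  out <- correct_spikes(raw)
  expect_equal(out$intensity, raw$intensity, tolerance = 1e-12)
  # an inserted jump of ~10 robust s.d. over 3 samples is repaired
  spiked <- raw
  jump <- 10 * mad(base)
  spiked$intensity[1, 1, 500:502] <- base[500:502] + jump
  fixed <- correct_spikes(spiked)
  err <- abs(fixed$intensity[1, 1, ] - base)
  slope_bound <- max(abs(diff(base)))
  expect_lt(max(err), 2 * slope_bound * 10)  # repaired span near the truth
  expect_lt(max(err), jump / 5)              # far below the inserted jump
  # samples outside the flagged neighbourhood are untouched
  expect_equal(fixed$intensity[1, 1, 1:480], base[1:480], tolerance = 1e-12)
  expect_equal(fixed$intensity[1, 1, 522:1000], base[522:1000],
               tolerance = 1e-12)
  # infinite threshold is the identity
  ident <- correct_spikes(spiked, sd_threshold = Inf)
  expect_identical(ident$intensity, spiked$intensity)
})

test_that("band-pass meets its frequency-response specification", {
  fs <- 10
  n <- 20000
  t <- (0:(n - 1)) / fs
  for (f in c(0.02, 0.05, 0.10, 0.15)) {
    x <- sin(2 * pi * f * t)
    y <- bandpass(matrix(x, 1), 0.01, 0.2, fs)[1, ]
    ratio <- fft_amplitude(y, f, fs) / fft_amplitude(x, f, fs)
    expect_gt(ratio, 10^(-1 / 20))             # < 1 dB passband loss
  }
  for (f in c(1, 2.5)) {
    x <- sin(2 * pi * f * t)
    y <- bandpass(matrix(x, 1), 0.01, 0.2, fs)[1, ]
    expect_lt(fft_amplitude(y, f, fs) / fft_amplitude(x, f, fs),
              10^(-20 / 20))                   # > 20 dB stopband loss
  }
  x <- sin(2 * pi * 0.001 * t)
  y <- bandpass(matrix(x, 1), 0.01, 0.2, fs)[1, ]
  expect_lt(fft_amplitude(y, 0.001, fs) / fft_amplitude(x, 0.001, fs),
            10^(-20 / 20))
  # zero in, zero out; too-short series rejected
  expect_equal(bandpass(matrix(0, 1, 1000)), matrix(0, 1, 1000))
  expect_error(bandpass(matrix(1, 1, 10)), "short")
  expect_error(bandpass(matrix(1, 1, 100), high = 6), "sampling rate")
})

test_that("filtering is linear and zero-phase", {
  fs <- 10
  n <- 6000
  t <- (0:(n - 1)) / fs
  x1 <- sin(2 * pi * 0.05 * t)
  x2 <- 0.5 * sin(2 * pi * 0.11 * t + 1)
  y1 <- bandpass(matrix(x1, 1))[1, ]
  y2 <- bandpass(matrix(x2, 1))[1, ]
  y12 <- bandpass(matrix(x1 + x2, 1))[1, ]
  expect_lt(max(abs(y12 - (y1 + y2))), 1e-6)
  # passband peaks keep their sample positions (+- 1 sample), mid-series
  mid <- 2000:4000
  peaks_in <- mid[which(diff(sign(diff(x1[mid]))) == -2) + 1]
  peaks_out <- mid[which(diff(sign(diff(y1[mid]))) == -2) + 1]
  expect_equal(length(peaks_in), length(peaks_out))
  expect_true(all(abs(peaks_in - peaks_out) <= 1))
})

test_that("the full chain runs in order and recovers the clean signal", {
  m <- make_montage(4)
  gt <- quiet_gt(m, amp_base = 1.2)
  sch <- make_test_schedule(6, 6, seed = 13)
  sess <- simulate_session(m, sch, gt, "experimental", "T0", noise = FALSE)
  fw <- forward_mbll(sess$clean, distance = m$distance_cm)
  raw <- raw_recording(fw$intensity, events = sch, subject_id = "s1",
                       group = "experimental", phase = "T0")
  hemo <- run_preprocessing(raw, config = list(distance = 2.3))
  steps <- c("screen_saturation", "remove_artifact_epochs", "correct_spikes",
             "intensity_to_od", "bandpass", "od_to_hemo")
  expect_equal(length(hemo$log), 6L)
  expect_equal(vapply(strsplit(hemo$log, ":"), `[`, "", 1), steps)
  # output matches the band-passed clean ground truth away from the edges
  oracle <- bandpass(sess$clean$hbo)
  core <- 301:(ncol(oracle) - 300)
  err <- max(abs(hemo$hbo[, core] - oracle[, core]))
  expect_lt(err, 0.01 * max(abs(sess$clean$hbo)))
  # with the filter disabled the chain is the MBLL inverse up to channel means
  hemo2 <- run_preprocessing(raw, config = list(distance = 2.3, band = NULL))
  ctr <- function(x) sweep(x, 1, rowMeans(x))
  expect_lt(max(abs(ctr(hemo2$hbo) - ctr(sess$clean$hbo))), 5e-3)
  expect_error(run_preprocessing(raw, config = list(bogus = 1)), "unknown")
  sat <- raw
  sat$intensity[] <- sat$dynamic_range[2]
  expect_error(run_preprocessing(sat, config = list(distance = 2.3)),
               "saturated")
})
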