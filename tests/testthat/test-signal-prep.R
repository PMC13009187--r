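test_that("the periodized wavelet banks reconstruct perfectly", {
  withr::with_seed(2, x <- rnorm(200))
  for (wv in c("bior4.4", "db3")) {
    dec <- adwear:::dwt_periodic(x, wv, 5L)
    expect_lt(max(abs(x - adwear:::idwt_periodic(dec))), 1e-9)
  }
})

test_that("wavelet denoising attenuates noise but keeps the waveform", {
  tpl <- template_ecg(n_beats = 20)
  clean <- tpl$channel$value
  withr::with_seed(5, noisy <- clean + rnorm(length(clean), 0, 0.1))
  dn <- wavelet_denoise(noisy)
  expect_lt(sqrt(mean((dn - clean)^2)), sqrt(mean((noisy - clean)^2)))
})

test_that("PPG band-pass keeps cardiac frequencies and removes drift", {
  fs <- 128
  t <- seq(0, 30, by = 1 / fs)
  # pure 1 Hz tone (in the passband); generator convention: raw PPG is inverted
  tone <- tibble::tibble(t_s = t, value = -sin(2 * pi * 1 * t))
  out <- ppg_preprocess(tone, rate = fs)
  mid <- out$clean$value[(5 * fs):(25 * fs)]
  amp <- diff(range(mid)) / 2   # baseline correction may shift the DC level
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)

  # 0.05 Hz drift attenuated by > 90 %
  drift <- tibble::tibble(t_s = t, value = -sin(2 * pi * 0.05 * t))
  outd <- suppressWarnings(ppg_preprocess(drift, rate = fs))  # no true beats
  expect_lt(max(abs(outd$clean$value[(5 * fs):(25 * fs)])), 0.1)
})

test_that("a constant PPG yields no beats without crashing", {
  fs <- 128
  flat <- tibble::tibble(t_s = seq(0, 10, by = 1 / fs), value = rep(1, 10 * fs + 1))
  out <- ppg_preprocess(flat, rate = fs)
  expect_equal(nrow(out$beats), 0)
})

test_that("R peaks of a clean template train are recovered within 20 ms", {
  tpl <- template_ecg(n_beats = 10, noise = 0.01)
  out <- ecg_preprocess(tpl$channel, rate = tpl$fs)
  expect_equal(length(out$rpeaks), 10)
  matched <- vapply(tpl$beat_times, function(bt) min(abs(out$rpeaks - bt)), 0)
  expect_lt(max(matched), 0.020)
})

test_that("R-peak detection is invariant to a slow baseline ramp", {
  tpl <- template_ecg(n_beats = 10, noise = 0.01)
  out0 <- ecg_preprocess(tpl$channel, rate = tpl$fs)
  ramped <- dplyr::mutate(tpl$channel, value = value + seq(0, 1, length.out = dplyr::n()))
  out1 <- ecg_preprocess(ramped, rate = tpl$fs)
  expect_equal(length(out1$rpeaks), length(out0$rpeaks))
  expect_lt(max(abs(out1$rpeaks - out0$rpeaks)), 2 / tpl$fs)  # zero-phase filters
})

test_that("a flat ECG yields zero peaks", {
  fs <- 128
  flat <- tibble::tibble(t_s = seq(0, 5, by = 1 / fs), value = rep(0, 5 * fs + 1))
  out <- ecg_preprocess(flat, rate = fs)
  expect_equal(length(out$rpeaks), 0)
})

test_that("EDA decomposition reconstructs exactly and isolates SCRs", {
  fs <- 32
  t <- seq(0, 60, by = 1 / fs)
  flat <- tibble::tibble(t_s = t, value = rep(5, length(t)))
  d0 <- eda_split(flat, rate = fs)
  expect_true(all(d0$tonic == 5))
  expect_true(all(d0$phasic == 0))

  bump <- 1 * exp(-((t - 30) / 0.25)^2)  # 0.5 s wide SCR
  sig <- tibble::tibble(t_s = t, value = 5 + bump)
  d1 <- eda_split(sig, rate = fs)
  expect_equal(d1$tonic + d1$phasic, sig$value)  # identity to machine precision
  expect_gt(max(d1$phasic), 0.9)                 # bump survives within 10 %
})

test_that("resting normalization rescales, interpolates gaps, ignores scale", {
  hr <- tibble::tibble(t_s = 0:299, value = c(rep(60, 200), rep(90, 100)))
  out <- normalize_to_resting(hr, rate = 1, resting_window_s = 180)
  expect_equal(out$value[1], 1)
  expect_equal(out$value[300], 1.5)

  const <- tibble::tibble(t_s = 0:199, value = rep(70, 200))
  expect_true(all(normalize_to_resting(const, rate = 1)$value == 1))

  gap <- tibble::tibble(t_s = c(0, 1, 3), value = c(60, 60, 70))
  og <- normalize_to_resting(gap, rate = 1, resting_window_s = 2)
  expect_equal(og$value[og$t_s == 2] * 60, 65)

  doubled <- dplyr::mutate(hr, value = value * 3)
  expect_equal(normalize_to_resting(doubled, rate = 1)$value, out$value)
})

test_that("SQI bounds are subject-specific and degenerate configs disable them", {
  metrics <- tibble::tibble(skewness = rep(0.5, 50), kurtosis = rep(3, 50),
                            snr = c(rep(20, 49), -10))
  b <- sqi_thresholds(metrics, multiplier = 3)
  flags <- adwear:::sqi_flag(metrics, b)
  expect_equal(which(flags), 50)   # only the corrupted beat

  clean <- tibble::tibble(a = rep(1, 20))
  expect_false(any(adwear:::sqi_flag(clean, sqi_thresholds(clean))))

  binf <- sqi_thresholds(metrics, multiplier = Inf)
  expect_false(any(adwear:::sqi_flag(metrics, binf)))

  few <- tibble::tibble(a = rnorm(3))
  bf <- sqi_thresholds(few)
  expect_equal(bf$lo, -Inf)
})

test_that("a grossly corrupted beat is rejected by the PPG quality filter", {
  fs <- 128
  t <- seq(0, 40, by = 1 / fs)
  v <- numeric(length(t))
  feet <- seq(0.5, 39, by = 0.8)
  for (ft in feet) {
    dt <- t - ft
    v <- v + exp(-((dt - 0.15) / 0.07)^2) * (dt > -0.1 & dt < 0.7)
  }
  withr::with_seed(8, {
    bad <- t > 20 & t < 20.8
    v[bad] <- v[bad] + rnorm(sum(bad), 0, 2)  # 10x amplitude noise on one beat
  })
  out <- ppg_preprocess(tibble::tibble(t_s = t, value = -v), rate = fs)
  expect_gt(nrow(out$beats), 30)
  rej <- out$beats$foot_time[!out$beats$accepted]
  expect_true(any(rej > 19 & rej < 21.5))
})
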