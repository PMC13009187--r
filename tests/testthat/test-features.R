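# Independent brute-force HRV definitions used as the oracle.
brute_hrv <- function(nn_ms) {
  d <- diff(nn_ms)
  list(
    sdnn = sqrt(sum((nn_ms - mean(nn_ms))^2) / (length(nn_ms) - 1)),
    rmssd = sqrt(sum(d^2) / length(d)),
    pnn50 = 100 * sum(abs(d) > 50) / length(d),
    sd1 = sqrt(0.5 * sum((d - mean(d))^2) / (length(d) - 1))
  )
}

test_that("window tiling drops incomplete windows", {
  expect_equal(nrow(make_windows(120, 60, 10)), 7)
  expect_equal(make_windows(120, 60, 10)$window_start_s, seq(0, 60, 10))
  expect_equal(nrow(make_windows(20, 5, 5)), 4)
  expect_equal(nrow(make_windows(30, 60, 10)), 0)
})

test_that("HRV features match brute-force definitions on random NN lists", {
  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      nn <- runif(n, 400, 1400)                       # ms
      bt <- cumsum(c(0.1, nn / 1000))                 # beat times, s
      got <- hrv_features(bt, 0, max(bt) + 1)
      want <- brute_hrv(nn)
      expect_equal(got$sdnn, want$sdnn, tolerance = 1e-9)
      expect_equal(got$rmssd, want$rmssd, tolerance = 1e-9)
      expect_equal(got$pnn50, want$pnn50, tolerance = 1e-9)
      expect_equal(got$sd1, want$sd1, tolerance = 1e-9)
      expect_equal(got$sd2, sqrt(max(2 * want$sdnn^2 - want$sd1^2, 0)),
                   tolerance = 1e-9)
    }
  })
})

test_that("the worked HRV example reproduces by hand", {
  bt <- cumsum(c(0, 0.800, 0.860, 0.805, 0.900))
  f <- hrv_features(bt, 0, 10)
  expect_equal(f$rmssd, sqrt((60^2 + 55^2 + 95^2) / 3), tolerance = 1e-6)
  expect_equal(round(f$rmssd, 2), 72.23)
  expect_equal(f$pnn50, 100)

  const <- cumsum(c(0, rep(0.8, 10)))
  fc <- hrv_features(const, 0, 10)
  expect_equal(fc$sdnn, 0)
  expect_equal(fc$rmssd, 0)
  expect_equal(fc$sd1, 0)
  expect_equal(fc$hr_mean, 75)
  expect_true(is.na(hrv_features(c(0.1, 0.9), 0, 10)$sdnn))  # < 3 beats
})

test_that("ECG morphology recovers constructed fiducial geometry", {
  fs <- 128
  n <- round(0.65 * fs) + 1
  r0 <- round(0.25 * fs) + 1
  tt <- (seq_len(n) - r0) / fs
  # symmetric triangle of half-width 40 ms
  tri <- pmax(0, 1 - abs(tt) / 0.040)
  f <- adwear:::ecg_beat_morphology(tri, fs, r0)
  expect_lt(abs(f[["qrsw"]] - 80), 1000 / fs + 1e-9)

  beats <- tibble::tibble(
    fiducial_time = c(10, 11, 12),
    amplitude = 1, template_cor = 1,
    waveform = list(tri, tri, tri),
    accepted = TRUE
  )
  m <- ecg_morph_features(beats, fs)
  vals <- as.matrix(m[, -1])
  expect_equal(max(apply(vals, 2, sd), na.rm = TRUE), 0)  # identical beats
})

test_that("local binary patterns of a monotone ramp concentrate on one code", {
  h <- adwear:::ulbp_hist(seq(0, 1, length.out = 40))
  expect_equal(sum(h), 1)
  expect_equal(max(h), 1)       # every window yields the same uniform code
  expect_equal(h[10], 0)        # nothing non-uniform on a ramp
})

test_that("PPG spectral and index features behave on constructed pulses", {
  fs <- 128
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t)
  f <- adwear:::ppg_window_features(x, x, fs)
  expect_lt(abs(f$f1 - 1.2), fs / length(t) + 0.01)

  const <- rep(2, 600)
  fc <- adwear:::ppg_window_features(const, const, fs)
  expect_equal(fc$perfusion, 0)
  expect_equal(fc$entropy, 0)

  # reflection index is invariant to beat scaling
  foot0 <- round(0.05 * fs) + 1
  tt <- seq(0, 1.05, by = 1 / fs) - 0.05
  beat <- exp(-((tt - 0.15) / 0.06)^2) + 0.5 * exp(-((tt - 0.45) / 0.09)^2)
  i1 <- adwear:::ppg_beat_indices(beat, fs, foot0)
  i2 <- adwear:::ppg_beat_indices(2 * beat, fs, foot0)
  expect_equal(i1[["ri"]], i2[["ri"]], tolerance = 1e-9)
  expect_gt(i1[["ri"]], 0.3)
})

test_that("EDA features count constructed SCRs and flat inputs", {
  fs <- 32
  t <- seq(0, 60, by = 1 / fs)
  flat <- list(t_s = t, tonic = rep(3, length(t)), phasic = rep(0, length(t)))
  f0 <- eda_features(tibble::as_tibble(flat), 0, 60, fs)
  expect_equal(f0$scr_count, 0)
  expect_equal(f0$scr_auc, 0)
  expect_equal(f0$scl_mean, 3)
  expect_equal(f0$scl_max, 3)

  # one triangular SCR: rise 1 s, amplitude 0.5
  ph <- numeric(length(t))
  up <- t >= 20 & t <= 21
  dn <- t > 21 & t <= 23
  ph[up] <- 0.5 * (t[up] - 20)
  ph[dn] <- 0.5 * (1 - (t[dn] - 21) / 2)
  f1 <- eda_features(tibble::tibble(t_s = t, tonic = 3, phasic = ph), 0, 60, fs)
  expect_equal(f1$scr_count, 1)
  expect_equal(f1$scr_amp_mean, 0.5, tolerance = 1e-6)
  expect_lt(abs(f1$scr_rise_mean - 1), 1 / fs + 1e-9)
})

test_that("temperature trend features are lookback differences", {
  t <- seq(0, 600, by = 60)
  lin <- 36 + 0.01 * t
  f <- trend_features(t, lin, 540, 600)
  expect_equal(f$d1_1min, 0.6, tolerance = 1e-9)
  expect_equal(f$d1_3min, 1.8, tolerance = 1e-9)
  expect_equal(f$d2_1min, 0, tolerance = 1e-9)
  fconst <- trend_features(t, rep(36.5, length(t)), 540, 600)
  for (d in 1:3) for (m in 1:3) {
    expect_equal(fconst[[paste0("d", d, "_", m, "min")]], 0)
  }
})

test_that("scope tables pool modalities across devices correctly", {
  ft <- small_features()
  tabs <- assemble_tables(ft)
  expect_setequal(names(tabs), learner_scopes())
  hr_cols <- setdiff(names(tabs[["modality:hr"]]),
                     c("subject_id", "window_start_s", "window_end_s",
                       "label", "gate_flag", "ad_fraction"))
  expect_true(any(grepl("wristband", hr_cols)))
  expect_true(any(grepl("ecg_patch", hr_cols)))
  tp_cols <- setdiff(names(tabs[["device:temp_patch"]]),
                     c("subject_id", "window_start_s", "window_end_s",
                       "label", "gate_flag", "ad_fraction"))
  expect_true(all(grepl("^temp\\.", tp_cols)))  # temp patch records only Temp
})

test_that("feature extraction is deterministic and translation-invariant", {
  co <- small_cohort()
  sig <- dplyr::filter(co$signals, subject_id == "S01")
  a <- build_feature_table(sig, 60, 10)
  b <- build_feature_table(sig, 60, 10)
  expect_identical(a, b)

  shifted <- dplyr::mutate(sig, t_s = t_s + 10)
  s <- build_feature_table(shifted, 60, 10, span_s = max(shifted$t_s))
  # windows shift; values of corresponding windows agree
  joined <- dplyr::inner_join(
    a, dplyr::mutate(s, window_start_s = window_start_s - 10,
                     window_end_s = window_end_s - 10),
    by = c("subject_id", "window_start_s", "window_end_s"),
    suffix = c("_a", "_s")
  )
  expect_gt(nrow(joined), 10)
  # compare a stable subset of features (cumulative/trend features depend on
  # the session origin by construction)
  for (cl in c("ecg.ecg_patch.sdnn", "hr.wristband.hr_mean",
               "bioz.wristband.scl_mean", "ppg.wristband.rms")) {
    expect_equal(joined[[paste0(cl, "_a")]], joined[[paste0(cl, "_s")]],
                 tolerance = 1e-6)
  }
})

test_that("a failed device leaves other scopes intact and flags missing data", {
  co <- small_cohort()
  sig <- dplyr::filter(co$signals,
                       !(subject_id == "S01" & modality == "BioZ"))
  ft <- build_feature_table(dplyr::filter(sig, subject_id %in% c("S01", "S02")),
                            60, 10)
  bioz_cols <- grep("^bioz\\.", names(ft), value = TRUE)
  expect_gt(length(bioz_cols), 0)   # S02 still has EDA features
  s1 <- dplyr::filter(ft, subject_id == "S01")
  expect_true(all(is.na(as.matrix(s1[, bioz_cols]))))
})
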