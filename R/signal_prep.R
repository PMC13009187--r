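# Modality-specific signal conditioning. All filters are zero-phase so beat
# fiducial times are preserved. Single-channel functions take a tibble with
# columns t_s, value (one subject, one channel); the sampling rate is read
# from a nominal_rate column or passed explicitly.

channel_rate <- function(channel, rate = NULL) {
  r <- rate %||% channel$nominal_rate[1]
  if (is.null(r) || !is.finite(r)) rlang::abort("sampling rate unknown; pass rate =")
  r
}

# Asymmetric least squares (Whittaker) baseline: iteratively reweighted fit of
# a smooth curve lying under/through the signal. Weights p for points above
# the baseline, 1 - p below.
asls_baseline <- function(y, lambda = 1e7, p = 0.01, iters = 10L) {
  n <- length(y)
  if (n < 10) return(rep(mean(y), n))
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iters)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

# Zero-phase Butterworth band-pass.
butter_bandpass <- function(x, fs, low, high, order = 4L) {
  ny <- fs / 2
  b <- signal::butter(order, c(low, high) / ny, type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

# Sequential adaptive-threshold peak picking on a non-negative detection
# function (Christov-style steep-slope criterion with a refractory period and
# threshold decay during long beat gaps).
adaptive_peaks <- function(y, fs, refractory_s = 0.25, init_s = 3,
                           gain = 0.6, decay = 0.97) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  m0 <- max(y[seq_len(min(n, round(init_s * fs)))])
  if (m0 <= 0) return(integer(0))
  M <- gain * m0
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    gap <- (i - last) / fs
    if (gap < refractory_s) next
    if (y[i] > M) {
      peaks <- c(peaks, i)
      last <- i
      M <- 0.7 * M + 0.3 * gain * y[i]
    } else if (gap > 1.5) {
      M <- M * decay   # lower the bar when no beat arrives
    }
  }
  peaks
}

# Extract fixed-length waveform templates around fiducial sample indices.
extract_templates <- function(x, idx, fs, before_s, after_s) {
  nb <- round(before_s * fs); na <- round(after_s * fs)
  keep <- idx - nb >= 1 & idx + na <= length(x)
  idx <- idx[keep]
  if (!length(idx)) return(list(idx = integer(0), wave = matrix(0, 0, nb + na + 1)))
  wave <- t(vapply(idx, function(i) x[(i - nb):(i + na)], numeric(nb + na + 1)))
  list(idx = idx, wave = wave)
}

#' Subject-specific signal-quality bounds
#'
#' For each beat-quality metric (columns of `metrics`), bounds are the subject
#' median plus/minus `multiplier` times the MAD. With fewer than `min_beats`
#' beats, wide universal default bounds are returned instead.
#'
#' @param metrics Tibble of per-beat quality metrics (numeric columns).
#' @param multiplier MAD multiplier (default 3; `Inf` disables flagging).
#' @param min_beats Minimum beats for subject-specific bounds.
#' @return Tibble `metric`, `lo`, `hi`.
#' @export
sqi_thresholds <- function(metrics, multiplier = 3, min_beats = 10L) {
  cols <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  if (nrow(metrics) < min_beats) {
    return(tibble(metric = cols, lo = -Inf, hi = Inf))
  }
  if (!is.finite(multiplier)) {
    return(tibble(metric = cols, lo = -Inf, hi = Inf))
  }
  purrr::map(cols, function(cl) {
    v <- metrics[[cl]][is.finite(metrics[[cl]])]
    m <- median(v); s <- mad(v)
    if (!is.finite(s)) s <- 0
    tibble(metric = cl, lo = m - multiplier * s, hi = m + multiplier * s)
  }) |> bind_rows()
}

sqi_flag <- function(metrics, bounds) {
  bad <- rep(FALSE, nrow(metrics))
  for (r in seq_len(nrow(bounds))) {
    v <- metrics[[bounds$metric[r]]]
    bad <- bad | (is.finite(v) & (v < bounds$lo[r] | v > bounds$hi[r]))
  }
  bad
}

#' PPG conditioning and beat segmentation
#'
#' Pipeline: sign inversion (reflective sensor), zero-phase 4th-order
#' Butterworth band-pass 0.25-10 Hz, baseline removal by asymmetric
#' least-squares (iteratively reweighted Whittaker fit), beat segmentation by
#' adaptive thresholding of the first derivative (pulse feet at the local
#' minimum preceding the steepest upslope), per-beat systolic amplitude
#' normalization, and SQI filtering: beats whose skewness, kurtosis or SNR
#' fall outside subject-specific bounds are excluded.
#'
#' @param channel Single PPG channel tibble (`t_s`, `value`).
#' @param rate Sampling rate in Hz (default from `nominal_rate`).
#' @param band Band-pass corner frequencies, Hz.
#' @param sqi_multiplier MAD multiplier for the quality bounds.
#' @param asls_lambda,asls_p Baseline-fit smoothness and asymmetry.
#' @return List: `clean` (tibble `t_s`, `value`), `beats` (tibble with
#'   `foot_time`, `peak_time`, `amplitude`, normalized `waveform` list-column,
#'   `accepted`), `rate`.
#' @export
ppg_preprocess <- function(channel, rate = NULL, band = c(0.25, 10),
                           sqi_multiplier = 3, asls_lambda = 1e7, asls_p = 0.01) {
  fs <- channel_rate(channel, rate)
  x <- -channel$value                      # sensor reflection correction
  if (length(x) < fs * 2 || diff(range(x)) < 1e-10) {
    return(list(clean = tibble(t_s = channel$t_s, value = x - mean(x)),
                beats = empty_ppg_beats(), rate = fs))
  }
  x <- butter_bandpass(x, fs, band[1], band[2])
  x <- x - asls_baseline(x, lambda = asls_lambda, p = asls_p)
  clean <- tibble(t_s = channel$t_s, value = x)

  dx <- c(0, diff(x)) * fs
  up <- adaptive_peaks(pmax(dx, 0), fs, refractory_s = 0.3)
  if (!length(up)) {
    return(list(clean = clean, beats = empty_ppg_beats(), rate = fs))
  }
  # pulse foot: local minimum in the 0.3 s before the upslope;
  # systolic peak: local maximum in the 0.5 s after it
  foot <- vapply(up, function(i) {
    a <- max(1L, i - as.integer(round(0.3 * fs)))
    a + which.min(x[a:i]) - 1L
  }, integer(1))
  peak <- vapply(up, function(i) {
    b <- min(length(x), i + as.integer(round(0.5 * fs)))
    as.integer(i + which.max(x[i:b]) - 1L)
  }, integer(1))
  amp <- x[peak] - x[foot]
  ok <- amp > 0
  foot <- foot[ok]; peak <- peak[ok]; amp <- amp[ok]
  if (!length(foot)) {
    return(list(clean = clean, beats = empty_ppg_beats(), rate = fs))
  }

  tpl <- extract_templates(x, foot, fs, before_s = 0.05, after_s = 1.0)
  keep <- foot %in% tpl$idx
  foot <- foot[keep]; peak <- peak[keep]; amp <- amp[keep]
  wave <- sweep(tpl$wave - x[foot], 1, amp, "/")   # systolic amplitude -> 1

  metrics <- tibble(
    skewness = apply(wave, 1, moment_skewness),
    kurtosis = apply(wave, 1, moment_kurtosis),
    snr = beat_snr(wave),
    amplitude = amp
  )
  bad <- sqi_flag(metrics, sqi_thresholds(metrics, sqi_multiplier))
  beats <- tibble(
    foot_time = channel$t_s[foot],
    peak_time = channel$t_s[peak],
    amplitude = amp,
    waveform = unname(split(wave, row(wave))),
    skewness = metrics$skewness,
    kurtosis = metrics$kurtosis,
    snr = metrics$snr,
    accepted = !bad
  )
  if (!any(beats$accepted)) rlang::warn("all PPG beats rejected by SQI filtering")
  list(clean = clean, beats = beats, rate = fs)
}

empty_ppg_beats <- function() {
  tibble(foot_time = numeric(), peak_time = numeric(), amplitude = numeric(),
         waveform = list(), skewness = numeric(), kurtosis = numeric(),
         snr = numeric(), accepted = logical())
}

# SNR of each beat against the ensemble-mean template, dB.
beat_snr <- function(wave) {
  if (nrow(wave) < 2) return(rep(Inf, nrow(wave)))
  tmpl <- colMeans(wave)
  res <- sweep(wave, 2, tmpl)
  sig <- sum(tmpl^2)
  10 * log10(sig / pmax(rowSums(res^2) / nrow(res), 1e-12))
}

#' ECG conditioning, R-peak detection and beat templates
#'
#' Pipeline: wavelet shrinkage denoising (biorthogonal 4.4 basis, soft
#' universal threshold), baseline estimation by sequential median filtering —
#' a 600 ms median filter applied to the 200 ms median-filtered signal — which
#' is subtracted; R-peak detection by an adaptive steep-slope threshold with a
#' refractory period (Christov's criterion class); outlier beats removed when
#' their correlation with the running mean template falls below
#' `min_template_cor` or their R amplitude lies outside median +/- 3 MAD.
#'
#' @param channel Single ECG channel tibble (`t_s`, `value`).
#' @param rate Sampling rate, Hz.
#' @param min_template_cor Morphology acceptance threshold.
#' @param amp_multiplier MAD multiplier for the amplitude bound.
#' @return List: `clean` tibble, `rpeaks` (times, s) of accepted beats,
#'   `beats` tibble (`fiducial_time`, `waveform` list-column, `accepted`),
#'   `rate`.
#' @export
ecg_preprocess <- function(channel, rate = NULL, min_template_cor = 0.8,
                           amp_multiplier = 3) {
  fs <- channel_rate(channel, rate)
  x <- wavelet_denoise(channel$value, "bior4.4", levels = 5L)
  base <- running_median(running_median(x, round(0.2 * fs)), round(0.6 * fs))
  x <- x - base
  clean <- tibble(t_s = channel$t_s, value = x)
  if (length(x) < fs || diff(range(x)) < 1e-8) {
    return(list(clean = clean, rpeaks = numeric(0), beats = empty_ecg_beats(), rate = fs))
  }

  dx <- c(0, diff(x)) * fs
  det <- abs(butter_lowpass(abs(dx), fs, 16))
  cand <- adaptive_peaks(det, fs, refractory_s = 0.25)
  if (!length(cand)) {
    return(list(clean = clean, rpeaks = numeric(0), beats = empty_ecg_beats(), rate = fs))
  }
  # snap to the true R peak: extremum of the cleaned ECG within +/- 80 ms
  w <- as.integer(round(0.08 * fs))
  r_idx <- vapply(cand, function(i) {
    a <- max(1L, i - w); b <- min(length(x), i + w)
    as.integer(a + which.max(abs(x[a:b])) - 1L)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # enforce refractory after snapping
  if (length(r_idx) > 1) {
    keep <- c(TRUE, diff(r_idx) > 0.2 * fs)
    r_idx <- r_idx[keep]
  }

  tpl <- extract_templates(x, r_idx, fs, before_s = 0.25, after_s = 0.4)
  r_idx <- tpl$idx
  if (!length(r_idx)) {
    return(list(clean = clean, rpeaks = numeric(0), beats = empty_ecg_beats(), rate = fs))
  }
  wave <- tpl$wave
  amp <- x[r_idx]
  # morphology: correlation with the running mean template
  cors <- rep(1, nrow(wave))
  if (nrow(wave) >= 3) {
    run_tmpl <- colMeans(wave)
    for (pass in 1:2) {
      cors <- apply(wave, 1, function(b) {
        if (sd(b) == 0) return(0)
        stats::cor(b, run_tmpl)
      })
      run_tmpl <- colMeans(wave[cors >= min_template_cor, , drop = FALSE])
      if (!is.matrix(wave[cors >= min_template_cor, , drop = FALSE]) ||
          !nrow(wave[cors >= min_template_cor, , drop = FALSE])) break
    }
  }
  med_a <- median(amp)
  # MAD floor at 5 % of the median amplitude: near-identical beats otherwise
  # produce a razor-thin band that rejects on numerical noise
  mad_a <- max(mad(amp), 0.05 * abs(med_a))
  amp_ok <- if (mad_a > 0) abs(amp - med_a) <= amp_multiplier * mad_a else rep(TRUE, length(amp))
  accepted <- cors >= min_template_cor & amp_ok
  beats <- tibble(
    fiducial_time = channel$t_s[r_idx],
    amplitude = amp,
    template_cor = cors,
    waveform = unname(split(wave, row(wave))),
    accepted = accepted
  )
  if (sum(accepted) < 2) {
    rlang::warn("fewer than 2 accepted R-peaks; HRV downstream will be missing")
  }
  list(clean = clean, rpeaks = channel$t_s[r_idx[accepted]], beats = beats, rate = fs)
}

empty_ecg_beats <- function() {
  tibble(fiducial_time = numeric(), amplitude = numeric(),
         template_cor = numeric(), waveform = list(), accepted = logical())
}

butter_lowpass <- function(x, fs, cutoff, order = 2L) {
  b <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(b, x))
}

#' Tonic/phasic decomposition of electrodermal activity
#'
#' The tonic skin-conductance level (SCL) is a centered 4 s running median of
#' the bioimpedance EDA signal; the phasic skin-conductance response (SCR)
#' component is the residual, so `tonic + phasic` reconstructs the input
#' exactly.
#'
#' @param channel Single BioZ/EDA channel tibble (`t_s`, `value`).
#' @param rate Sampling rate, Hz.
#' @param width_s Median filter width, seconds.
#' @return Tibble `t_s`, `value`, `tonic`, `phasic`.
#' @export
eda_split <- function(channel, rate = NULL, width_s = 4) {
  fs <- channel_rate(channel, rate)
  tonic <- running_median(channel$value, round(width_s * fs))
  tibble(t_s = channel$t_s, value = channel$value,
         tonic = tonic, phasic = channel$value - tonic)
}

#' Normalize a 1 Hz channel to its resting level
#'
#' The resting reference is the median over the first `resting_window_s`
#' seconds (the pre-provocation phase of a UDS session); the series is divided
#' by it. The channel is regularized onto its nominal grid; interior gaps are
#' linearly interpolated, while leading/trailing gaps stay missing.
#'
#' @param channel Single HR or RR channel tibble (`t_s`, `value`).
#' @param rate Sampling rate, Hz.
#' @param resting_window_s Length of the resting reference window, seconds.
#' @return Tibble `t_s`, `value` (normalized, unitless).
#' @export
normalize_to_resting <- function(channel, rate = NULL, resting_window_s = 180) {
  fs <- channel_rate(channel, rate)
  grid <- seq(min(channel$t_s), max(channel$t_s), by = 1 / fs)
  v <- rep(NA_real_, length(grid))
  v[match(round(channel$t_s * fs), round(grid * fs))] <- channel$value
  v <- fill_interior_na(grid, v)
  rest <- v[grid < min(channel$t_s) + resting_window_s]
  rest <- rest[is.finite(rest)]
  if (!length(rest) || median(rest) == 0) {
    rlang::warn("empty or degenerate resting window; normalization skipped")
    return(tibble(t_s = grid, value = v))
  }
  tibble(t_s = grid, value = v / median(rest))
}
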