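# Beat-template morphology descriptors: ECG fiducial geometry, wavelet and
# Hermite expansions, local binary patterns; PPG pulse-wave indices.
# Per-beat features are computed once per session and aggregated per window
# by the median (robust to residual artifact beats).

# --- ECG beat morphology -----------------------------------------------------

# Hermite functions h_0..h_{k-1} evaluated at u, orthonormalized numerically.
hermite_basis <- function(u, k = 6L) {
  H <- matrix(0, length(u), k)
  H[, 1] <- 1
  if (k >= 2) H[, 2] <- 2 * u
  if (k >= 3) for (j in 3:k) H[, j] <- 2 * u * H[, j - 1] - 2 * (j - 2) * H[, j - 2]
  B <- H * exp(-u^2 / 2)
  qr.Q(qr(B))
}

# Project a beat on the first k Hermite functions; the time scale sigma is
# chosen from a small candidate grid by residual energy.
hermite_coefs <- function(beat, fs, k = 6L, sigmas = c(0.03, 0.06, 0.12)) {
  n <- length(beat)
  tt <- (seq_len(n) - which.max(abs(beat))) / fs
  best <- NULL; best_res <- Inf
  for (s in sigmas) {
    B <- hermite_basis(tt / s, k)
    cf <- crossprod(B, beat)
    res <- sum((beat - B %*% cf)^2)
    if (res < best_res) { best_res <- res; best <- as.numeric(cf) }
  }
  best
}

# Rotation-invariant uniform 1-D local binary patterns (8 neighbors: 4 left,
# 4 right). Uniform codes (<= 2 circular transitions) are binned by their
# number of set bits (0..8); all non-uniform codes share one bin.
ulbp_hist <- function(x, radius = 4L) {
  n <- length(x)
  if (n < 2 * radius + 1) return(rep(NA_real_, 10))
  counts <- numeric(10)
  offs <- c(-(radius:1), 1:radius)
  for (i in (radius + 1):(n - radius)) {
    bits <- as.integer(x[i + offs] >= x[i])
    trans <- sum(bits != c(bits[-1], bits[1]))
    bin <- if (trans <= 2) sum(bits) + 1L else 10L
    counts[bin] <- counts[bin] + 1
  }
  counts / sum(counts)
}

# Per-beat ECG morphology. `beat` is the template (R peak at sample r0).
ecg_beat_morphology <- function(beat, fs, r0) {
  n <- length(beat)
  win <- function(a_s, b_s) {
    idx <- (r0 + round(a_s * fs)):(r0 + round(b_s * fs))
    idx[idx >= 1 & idx <= n]
  }
  r_amp <- beat[r0]
  iq <- win(-0.06, -0.008); is_ <- win(0.008, 0.06)
  ip <- win(-0.25, -0.08); it <- win(0.08, 0.39)
  if (!length(iq) || !length(is_) || !length(ip) || !length(it)) return(NULL)
  q_i <- iq[which.min(beat[iq])]; s_i <- is_[which.min(beat[is_])]
  p_i <- ip[which.max(beat[ip])]; t_i <- it[which.max(beat[it])]
  # QRS width: contiguous region around R above 2% of the R amplitude
  above <- beat > 0.02 * r_amp
  lo <- r0; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- r0; while (hi < n && above[hi + 1]) hi <- hi + 1
  qrsw <- (hi - lo) / fs
  qsd <- (s_i - q_i) / fs
  pqa <- beat[p_i] - beat[q_i]
  qra <- r_amp - beat[q_i]
  rsa <- r_amp - beat[s_i]
  feats <- c(
    qrsw = qrsw * 1000, qsd = qsd * 1000,
    pqa = pqa, qra = qra, rsa = rsa,
    pq_qr = if (qra != 0) pqa / qra else NA_real_,
    rs_qr = if (qra != 0) rsa / qra else NA_real_
  )
  # resample the template to 64 samples for the wavelet descriptor
  b64 <- approx(seq_len(n), beat, xout = seq(1, n, length.out = 64))$y
  wav <- dwt_approx_coefs(b64, "db3", level = 3L, k = 8L)
  names(wav) <- paste0("dwt_a", seq_len(8))
  hc <- hermite_coefs(beat, fs, k = 6L)
  names(hc) <- paste0("hermite", seq_len(6))
  qrs_seg <- beat[max(1, r0 - round(0.06 * fs)):min(n, r0 + round(0.06 * fs))]
  lb <- ulbp_hist(qrs_seg)
  names(lb) <- paste0("ulbp", 0:9)
  c(feats, wav, hc, lb)
}

#' ECG morphology features per beat
#'
#' Computes the per-beat morphology descriptor set (fiducial durations QRSw
#' and QSd; P-Q/Q-R/R-S amplitude differences and their ratios; the first 8
#' Daubechies-3 approximation coefficients of the resampled template; 6
#' Hermite-function projection coefficients with fitted width; and the
#' rotation-invariant uniform local-binary-pattern histogram of the QRS
#' segment) for every accepted beat. Aggregate per window with
#' [aggregate_beat_features()].
#'
#' @param beats Beat tibble from [ecg_preprocess()] (accepted beats are used).
#' @param rate Sampling rate, Hz.
#' @return Tibble: `fiducial_time` plus one column per morphology feature.
#' @export
ecg_morph_features <- function(beats, rate) {
  beats <- beats[beats$accepted, ]
  if (!nrow(beats)) return(tibble(fiducial_time = numeric()))
  rows <- purrr::map(seq_len(nrow(beats)), function(i) {
    w <- beats$waveform[[i]]
    r0 <- round(0.25 * rate) + 1L
    f <- ecg_beat_morphology(w, rate, r0)
    if (is.null(f)) return(NULL)
    c(fiducial_time = beats$fiducial_time[i], f)
  })
  rows <- compact(rows)
  if (!length(rows)) return(tibble(fiducial_time = numeric()))
  as_tibble(do.call(rbind, rows))
}

# --- PPG pulse-wave indices --------------------------------------------------

# Width of the pulse at a fraction of the systolic amplitude, split at the
# systolic peak into systolic (rising) and diastolic (falling) parts.
pulse_widths <- function(beat, fs, peak_i, frac) {
  h <- frac * beat[peak_i]
  lo <- peak_i; while (lo > 1 && beat[lo - 1] >= h) lo <- lo - 1
  hi <- peak_i; while (hi < length(beat) && beat[hi + 1] >= h) hi <- hi + 1
  c(sw = (peak_i - lo) / fs * 1000, dw = (hi - peak_i) / fs * 1000)
}

ppg_beat_indices <- function(beat, fs, foot0, dc = NA_real_) {
  n <- length(beat)
  sys_lim <- min(n, foot0 + round(0.45 * fs))
  peak_i <- foot0 + which.max(beat[foot0:sys_lim]) - 1L
  sys_amp <- beat[peak_i]
  if (sys_amp <= 0) return(NULL)
  ct <- (peak_i - foot0) / fs
  # dicrotic notch: minimum between systolic peak and the diastolic bump
  a <- min(n, peak_i + round(0.08 * fs)); b <- min(n, peak_i + round(0.45 * fs))
  notch_i <- if (b > a) a + which.min(beat[a:b]) - 1L else NA_integer_
  dia_i <- NA_integer_
  if (!is.na(notch_i) && notch_i < n - 2) {
    c2 <- min(n, notch_i + round(0.3 * fs))
    if (c2 > notch_i) dia_i <- notch_i + which.max(beat[notch_i:c2]) - 1L
  }
  has_notch <- !is.na(notch_i) && !is.na(dia_i) && dia_i > notch_i &&
    beat[dia_i] > beat[notch_i]
  ri <- if (has_notch) beat[dia_i] / sys_amp else NA_real_
  ai <- if (has_notch) (sys_amp - beat[dia_i]) / sys_amp else NA_real_
  lasi <- if (has_notch && dia_i > peak_i) 1 / ((dia_i - peak_i) / fs) else NA_real_
  w25 <- pulse_widths(beat, fs, peak_i, 0.25)
  w50 <- pulse_widths(beat, fs, peak_i, 0.50)
  w75 <- pulse_widths(beat, fs, peak_i, 0.75)
  c(ct = ct * 1000, ri = ri, ai = ai, lasi = lasi,
    npv = if (is.finite(dc) && dc != 0) 1 / abs(dc) else NA_real_,
    sw25 = w25["sw"], dw25 = w25["dw"], dwsw25 = w25["dw"] / max(w25["sw"], 1e-9),
    sw50 = w50["sw"], dw50 = w50["dw"], dwsw50 = w50["dw"] / max(w50["sw"], 1e-9),
    sw75 = w75["sw"], dw75 = w75["dw"], dwsw75 = w75["dw"] / max(w75["sw"], 1e-9))
}

#' PPG per-beat pulse-wave indices
#'
#' Crest time, reflection and augmentation indices, large-artery stiffness
#' index, normalized pulse volume and multi-height systolic/diastolic widths
#' for every accepted beat (notch-dependent indices are missing when no
#' dicrotic notch is found).
#'
#' @param ppg Output of [ppg_preprocess()].
#' @param raw_dc Raw-signal DC level used for NPV (per-beat amplitude is
#'   normalized away; NPV falls back to 1/|DC|).
#' @return Tibble: `foot_time` plus one column per index.
#' @export
ppg_beat_features <- function(ppg, raw_dc = NA_real_) {
  beats <- ppg$beats[ppg$beats$accepted, ]
  if (!nrow(beats)) return(tibble(foot_time = numeric()))
  fs <- ppg$rate
  foot0 <- round(0.05 * fs) + 1L
  rows <- purrr::map(seq_len(nrow(beats)), function(i) {
    f <- ppg_beat_indices(beats$waveform[[i]], fs, foot0, dc = raw_dc)
    if (is.null(f)) return(NULL)
    names(f) <- sub("\\.sw$|\\.dw$", "", names(f))
    c(foot_time = beats$foot_time[i], f, amplitude = beats$amplitude[i])
  })
  rows <- compact(rows)
  if (!length(rows)) return(tibble(foot_time = numeric()))
  as_tibble(do.call(rbind, rows))
}

# Median-aggregate a per-beat feature tibble over a window keyed by its time
# column (first column).
aggregate_beat_features <- function(beat_feats, window_start, window_end) {
  if (!nrow(beat_feats)) return(NULL)
  tcol <- beat_feats[[1]]
  sel <- tcol >= window_start & tcol < window_end
  if (!any(sel)) return(NULL)
  vals <- beat_feats[sel, -1, drop = FALSE]
  as.list(vapply(vals, function(v) median(v, na.rm = TRUE), 0))
}

# Window-level PPG statistics and spectral descriptors on the cleaned signal.
ppg_window_features <- function(clean_v, raw_v, fs) {
  x <- clean_v[is.finite(clean_v)]
  if (length(x) < 8) return(NULL)
  dc <- mean(abs(raw_v), na.rm = TRUE)
  ac <- diff(range(x))
  out <- list(
    mean = mean(x), variance = var(x), mad = mad(x),
    rms = sqrt(mean(x^2)), skewness = moment_skewness(x),
    kurtosis = moment_kurtosis(x), entropy = shannon_entropy(x),
    perfusion = if (dc > 0) ac / dc else 0
  )
  if (sd(x) == 0) {
    out$perfusion <- 0
    return(c(out, list(f1 = NA_real_, h1 = NA_real_, h2 = NA_real_, h3 = NA_real_,
                       spec_skew = NA_real_, spec_energy = 0, wav_entropy = 0)))
  }
  n <- length(x)
  mag <- abs(fft(x - mean(x)))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * fs / n
  band <- freq >= 0.5 & freq <= 3
  if (any(band)) {
    f1 <- freq[band][which.max(mag[band])]
    harm <- function(k) {
      i <- which.min(abs(freq - k * f1))
      mag[i]
    }
    out$f1 <- f1; out$h1 <- harm(1); out$h2 <- harm(2); out$h3 <- harm(3)
  } else {
    out$f1 <- NA_real_; out$h1 <- NA_real_; out$h2 <- NA_real_; out$h3 <- NA_real_
  }
  out$spec_skew <- moment_skewness(mag)
  out$spec_energy <- sum(mag^2) / n
  out$wav_entropy <- wavelet_entropy(x, "db3", 4L)
  out
}
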