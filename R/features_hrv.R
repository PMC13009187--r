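# Heart-rate-variability features from beat fiducial times, and their
# analogues computed from a 1 Hz HR channel.

#' HRV features for one window
#'
#' Computes time-domain, frequency-domain and Poincare descriptors from the
#' beat fiducial times falling in `[window_start, window_end)`. NN intervals
#' are the successive differences in ms. Frequency-domain power (LF 0.04-0.15
#' Hz, HF 0.15-0.4 Hz, their ratio and total power) is estimated with a Welch
#' periodogram of the NN series cubic-interpolated at 4 Hz, and only for
#' windows of at least `min_freq_span_s` seconds. `hr_mean_cum` is the
#' cumulative mean HR from session start (t = 0) to the window end.
#'
#' @param beat_times Fiducial times of accepted beats for the whole session, s.
#' @param window_start,window_end Window bounds, s (half-open).
#' @param min_beats Minimum beats in the window for time-domain features.
#' @param min_freq_span_s Minimum window span for frequency-domain features.
#' @return Named list of features (NA when not computable).
#' @export
#' @examples
#' bt <- cumsum(c(0, 0.800, 0.860, 0.805, 0.900))
#' hrv_features(bt, 0, 10)$rmssd   # 72.23 ms
hrv_features <- function(beat_times, window_start, window_end,
                         min_beats = 3L, min_freq_span_s = 30) {
  out <- list(
    hr_mean = NA_real_, hr_min = NA_real_, sdnn = NA_real_, rmssd = NA_real_,
    pnn50 = NA_real_, nn_p80 = NA_real_, nn_max = NA_real_,
    sd1 = NA_real_, sd2 = NA_real_,
    lf = NA_real_, hf = NA_real_, lf_hf = NA_real_, total_power = NA_real_,
    hr_mean_cum = NA_real_
  )
  bt_cum <- beat_times[beat_times < window_end]
  if (length(bt_cum) >= 2) {
    nn_cum <- diff(bt_cum)
    out$hr_mean_cum <- 60 / mean(nn_cum)
  }
  bt <- beat_times[beat_times >= window_start & beat_times < window_end]
  if (length(bt) < min_beats) return(out)
  nn <- diff(bt) * 1000          # ms
  dnn <- diff(nn)
  out$hr_mean <- 60000 / mean(nn)
  out$hr_min <- 60000 / max(nn)
  out$sdnn <- if (length(nn) > 1) sd(nn) else 0
  out$rmssd <- if (length(dnn)) sqrt(mean(dnn^2)) else 0
  out$pnn50 <- if (length(dnn)) 100 * mean(abs(dnn) > 50) else 0
  out$nn_p80 <- as.numeric(quantile(nn, 0.8))
  out$nn_max <- max(nn)
  out$sd1 <- if (length(dnn)) sqrt(0.5) * sd(dnn) else 0
  if (length(dnn) < 1) out$sd1 <- 0
  out$sd2 <- sqrt(max(2 * out$sdnn^2 - out$sd1^2, 0))
  if ((window_end - window_start) >= min_freq_span_s && length(bt) >= 8) {
    fs_i <- 4
    grid <- seq(bt[1], bt[length(bt)], by = 1 / fs_i)
    if (length(grid) >= 32) {
      nn_t <- stats::spline(bt[-1], nn, xout = grid, method = "natural")$y
      ps <- welch_psd(nn_t - mean(nn_t), fs_i, nperseg = min(length(nn_t), 256L))
      out$lf <- bandpower(ps$freq, ps$psd, 0.04, 0.15)
      out$hf <- bandpower(ps$freq, ps$psd, 0.15, 0.4)
      out$lf_hf <- if (out$hf > 0) out$lf / out$hf else NA_real_
      out$total_power <- bandpower(ps$freq, ps$psd, 0.0033, 0.4)
    }
  }
  out
}

# HRV-style features from a (resting-normalized) 1 Hz HR channel: the series
# 60/HR plays the role of the NN tachogram. Values are in normalized units.
hr_channel_features <- function(t, v, window_start, window_end,
                                min_freq_span_s = 30) {
  out <- list(
    hr_mean = NA_real_, rr_mean = NA_real_, sdnn = NA_real_, rmssd = NA_real_,
    pnn50 = NA_real_, nn_p80 = NA_real_,
    sd1 = NA_real_, sd2 = NA_real_,
    lf = NA_real_, hf = NA_real_, lf_hf = NA_real_, total_power = NA_real_,
    hr_mean_cum = NA_real_
  )
  cum <- v[t < window_end & is.finite(v)]
  if (length(cum)) out$hr_mean_cum <- mean(cum)
  sel <- t >= window_start & t < window_end & is.finite(v)
  if (sum(sel) < 3) return(out)
  hr <- v[sel]
  nn <- 1000 / hr                # pseudo-NN, ms-scaled in normalized units
  dnn <- diff(nn)
  out$hr_mean <- mean(hr)
  out$rr_mean <- mean(nn)
  out$sdnn <- sd(nn)
  out$rmssd <- sqrt(mean(dnn^2))
  out$pnn50 <- 100 * mean(abs(dnn) > 50)
  out$nn_p80 <- as.numeric(quantile(nn, 0.8))
  out$sd1 <- sqrt(0.5) * sd(dnn)
  out$sd2 <- sqrt(max(2 * out$sdnn^2 - out$sd1^2, 0))
  if ((window_end - window_start) >= min_freq_span_s && sum(sel) >= 16) {
    fs_i <- 4
    grid <- seq(t[sel][1], t[sel][sum(sel)], by = 1 / fs_i)
    nn_t <- stats::spline(t[sel], nn, xout = grid, method = "natural")$y
    ps <- welch_psd(nn_t - mean(nn_t), fs_i, nperseg = min(length(nn_t), 256L))
    out$lf <- bandpower(ps$freq, ps$psd, 0.04, 0.15)
    out$hf <- bandpower(ps$freq, ps$psd, 0.15, 0.4)
    out$lf_hf <- if (out$hf > 0) out$lf / out$hf else NA_real_
    out$total_power <- bandpower(ps$freq, ps$psd, 0.0033, 0.4)
  }
  out
}
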