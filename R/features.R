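# Sliding-window segmentation, EDA and temperature descriptors, and the
# orchestrator that turns a cohort's raw signals into the per-(subject,
# window) feature table. Feature columns are named
# `<modality>.<device>.<feature>` so every column carries its scope tags.

.window_presets <- list(c(5, 5), c(10, 5), c(10, 10), c(30, 10), c(60, 5), c(60, 10))

#' Sliding windows over a session
#'
#' Half-open windows `[start, start + duration)` with starts at 0, step,
#' 2 step, ...; windows extending past the span are dropped, so only complete
#' windows are produced.
#'
#' @param span_s Session span, seconds.
#' @param duration_s,step_s Window duration and step, seconds
#'   (`duration_s >= step_s > 0`).
#' @return Tibble `window_start_s`, `window_end_s`.
#' @export
#' @examples
#' make_windows(120, 60, 10)  # 7 windows
make_windows <- function(span_s, duration_s = 60, step_s = 10) {
  stopifnot(duration_s >= step_s, step_s > 0)
  if (span_s < duration_s) {
    return(tibble(window_start_s = numeric(0), window_end_s = numeric(0)))
  }
  starts <- seq(0, span_s - duration_s, by = step_s)
  tibble(window_start_s = starts, window_end_s = starts + duration_s)
}

# --- EDA features ------------------------------------------------------------

# Detect SCR peaks in a phasic series: local maxima with prominence above
# `prominence` uS; onset = preceding local minimum, rise time onset-to-peak.
scr_events <- function(t, phasic, prominence = 0.01) {
  empty <- list(peak_t = numeric(), amplitude = numeric(), rise_time = numeric())
  n <- length(phasic)
  if (n < 5) return(empty)
  is_max <- which(phasic[2:(n - 1)] > phasic[1:(n - 2)] & phasic[2:(n - 1)] >= phasic[3:n]) + 1L
  if (!length(is_max)) return(empty)
  # onset of each SCR = preceding local minimum (start of the rising limb)
  rising <- c(FALSE, diff(phasic) > 0)
  onset <- vapply(is_max, function(i) {
    j <- i
    while (j > 1 && rising[j]) j <- j - 1L
    j
  }, integer(1))
  amp <- phasic[is_max] - phasic[onset]
  keep <- amp >= prominence
  list(peak_t = t[is_max[keep]], amplitude = amp[keep],
       rise_time = t[is_max[keep]] - t[onset[keep]])
}

#' Electrodermal features for one window
#'
#' Tonic (SCL) statistics and derivative means, phasic SCR descriptors (peak
#' count, mean amplitude, mean rise time, area under the positive phasic
#' curve), band powers over 0-0.5 Hz in 0.1 Hz bands, and magnitude-spectrum
#' shape statistics.
#'
#' @param decomp Output of [eda_split()].
#' @param window_start,window_end Window bounds, s.
#' @param rate Sampling rate, Hz.
#' @param scr_prominence Minimum SCR prominence, uS.
#' @return Named list of features.
#' @export
eda_features <- function(decomp, window_start, window_end, rate,
                         scr_prominence = 0.01) {
  sel <- decomp$t_s >= window_start & decomp$t_s < window_end
  if (sum(sel) < 4) return(NULL)
  t <- decomp$t_s[sel]; ton <- decomp$tonic[sel]; ph <- decomp$phasic[sel]
  d1 <- diff(ton) * rate; d2 <- diff(d1) * rate
  ev <- scr_events(t, ph, scr_prominence)
  n_ev <- length(ev$peak_t)
  out <- list(
    scl_mean = mean(ton), scl_std = sd(ton), scl_min = min(ton), scl_max = max(ton),
    scl_d1_mean = mean(d1), scl_d2_mean = if (length(d2)) mean(d2) else 0,
    scr_count = n_ev,
    scr_amp_mean = if (n_ev) mean(ev$amplitude) else 0,
    scr_rise_mean = if (n_ev) mean(ev$rise_time) else 0,
    scr_auc = sum(pmax(ph, 0)) / rate,
    energy = sum(ph^2) / rate, variance = var(ph)
  )
  x <- ph - mean(ph)
  ps <- welch_psd(x, rate, nperseg = min(length(x), 128L))
  bands <- seq(0, 0.5, by = 0.1)
  for (b in seq_len(length(bands) - 1)) {
    out[[paste0("bp_", bands[b] * 10, "_", bands[b + 1] * 10)]] <-
      bandpower(ps$freq, ps$psd, bands[b], bands[b + 1])
  }
  n <- length(x)
  mag <- abs(fft(x))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * rate / n
  wsum <- sum(mag)
  out$spec_area <- wsum
  if (wsum > 0) {
    fm <- sum(freq * mag) / wsum
    out$spec_fmean <- fm
    out$spec_fstd <- sqrt(sum((freq - fm)^2 * mag) / wsum)
  } else {
    out$spec_fmean <- 0; out$spec_fstd <- 0
  }
  out$spec_frange <- if (any(mag > max(mag) * 0.05)) diff(range(freq[mag > max(mag) * 0.05])) else 0
  out$spec_skew <- moment_skewness(mag)
  out$spec_kurt <- moment_kurtosis(mag)
  out
}

# --- slow-trend features (Temp, and the RR channel) --------------------------

#' Slow-trend features for one window
#'
#' Mean absolute value over the window plus first, second and third finite
#' differences over 1-, 2- and 3-minute lookbacks ending at the window end
#' (values at lookback times by linear interpolation of the sparse series).
#' Designed for the 1/60 Hz temperature channels and reused for the
#' respiratory-rate channel. Units: value change per lookback interval.
#'
#' @param t,v Channel times (s) and values.
#' @param window_start,window_end Window bounds, s.
#' @return Named list: `mav`, `d{1,2,3}_{1,2,3}min`.
#' @export
trend_features <- function(t, v, window_start, window_end) {
  ok <- is.finite(v)
  t <- t[ok]; v <- v[ok]
  out <- list(mav = NA_real_)
  for (d in 1:3) for (m in 1:3) out[[paste0("d", d, "_", m, "min")]] <- NA_real_
  if (length(t) < 2) return(out)
  inw <- t >= window_start & t < window_end
  at <- function(tt) {
    if (tt < min(t) || tt > max(t)) return(NA_real_)
    approx(t, v, xout = tt)$y
  }
  out$mav <- if (any(inw)) mean(abs(v[inw])) else abs(at(window_end))
  for (m in 1:3) {
    lag <- m * 60
    g <- function(tt) at(tt)
    d1 <- function(tt) g(tt) - g(tt - lag)
    d2 <- function(tt) d1(tt) - d1(tt - lag)
    d3 <- function(tt) d2(tt) - d2(tt - lag)
    out[[paste0("d1_", m, "min")]] <- d1(window_end)
    out[[paste0("d2_", m, "min")]] <- d2(window_end)
    out[[paste0("d3_", m, "min")]] <- d3(window_end)
  }
  out
}

# --- orchestration -----------------------------------------------------------

prefix_names <- function(x, modality, device) {
  if (is.null(x) || !length(x)) return(NULL)
  setNames(as.list(x), paste(tolower(modality), device, names(x), sep = "."))
}

# Preprocess every channel of one subject once; returns the cached artifacts
# the per-window extractors need.
prep_subject <- function(signals, subject, resting_window_s = 180) {
  ch <- function(device, modality) get_channel(signals, subject, device, modality)
  arts <- list()
  ecg <- ch("ecg_patch", "ECG")
  if (!is.null(ecg) && length(ecg$v) > 256) {
    pe <- ecg_preprocess(tibble(t_s = ecg$t, value = ecg$v), rate = ecg$rate)
    arts$ecg_rpeaks <- pe$rpeaks
    arts$ecg_morph <- ecg_morph_features(pe$beats, ecg$rate)
  }
  ppg <- ch("wristband", "PPG")
  if (!is.null(ppg) && length(ppg$v) > 256) {
    pp <- ppg_preprocess(tibble(t_s = ppg$t, value = ppg$v), rate = ppg$rate)
    arts$ppg <- pp
    arts$ppg_raw <- tibble(t_s = ppg$t, value = ppg$v)
    arts$ppg_beat_feats <- ppg_beat_features(pp, raw_dc = mean(abs(ppg$v)))
  }
  eda <- ch("wristband", "BioZ")
  if (!is.null(eda) && length(eda$v) > 16) {
    arts$eda <- eda_split(tibble(t_s = eda$t, value = eda$v), rate = eda$rate)
    arts$eda_rate <- eda$rate
  }
  for (dev in c("wristband", "temp_patch")) {
    tp <- ch(dev, "Temp")
    if (!is.null(tp)) arts[[paste0("temp_", dev)]] <- tp
  }
  for (dev in c("wristband", "ecg_patch")) {
    hr <- ch(dev, "HR")
    if (!is.null(hr) && length(hr$v) > 3) {
      nh <- normalize_to_resting(tibble(t_s = hr$t, value = hr$v), rate = hr$rate,
                                 resting_window_s = resting_window_s)
      arts[[paste0("hr_", dev)]] <- nh
    }
    rr <- ch(dev, "RR")
    if (!is.null(rr) && length(rr$v) > 3) {
      nr <- normalize_to_resting(tibble(t_s = rr$t, value = rr$v), rate = rr$rate,
                                 resting_window_s = resting_window_s)
      arts[[paste0("rr_", dev)]] <- nr
    }
  }
  arts
}

subject_window_features <- function(arts, ws, we) {
  row <- list()
  if (!is.null(arts$ecg_rpeaks)) {
    row <- c(row, prefix_names(hrv_features(arts$ecg_rpeaks, ws, we), "ECG", "ecg_patch"))
  }
  if (!is.null(arts$ecg_morph) && nrow(arts$ecg_morph)) {
    row <- c(row, prefix_names(aggregate_beat_features(arts$ecg_morph, ws, we),
                               "ECG", "ecg_patch"))
  }
  if (!is.null(arts$ppg)) {
    selc <- arts$ppg$clean$t_s >= ws & arts$ppg$clean$t_s < we
    wf <- ppg_window_features(arts$ppg$clean$value[selc],
                              arts$ppg_raw$value[selc], arts$ppg$rate)
    row <- c(row, prefix_names(wf, "PPG", "wristband"))
    if (nrow(arts$ppg_beat_feats)) {
      row <- c(row, prefix_names(aggregate_beat_features(arts$ppg_beat_feats, ws, we),
                                 "PPG", "wristband"))
    }
  }
  if (!is.null(arts$eda)) {
    row <- c(row, prefix_names(eda_features(arts$eda, ws, we, arts$eda_rate),
                               "BioZ", "wristband"))
  }
  for (dev in c("wristband", "temp_patch")) {
    tp <- arts[[paste0("temp_", dev)]]
    if (!is.null(tp)) {
      row <- c(row, prefix_names(trend_features(tp$t, tp$v, ws, we), "Temp", dev))
    }
  }
  for (dev in c("wristband", "ecg_patch")) {
    hr <- arts[[paste0("hr_", dev)]]
    if (!is.null(hr)) {
      row <- c(row, prefix_names(hr_channel_features(hr$t_s, hr$value, ws, we),
                                 "HR", dev))
    }
    rr <- arts[[paste0("rr_", dev)]]
    if (!is.null(rr)) {
      sel <- is.finite(rr$value)
      row <- c(row, prefix_names(trend_features(rr$t_s[sel], rr$value[sel], ws, we),
                                 "RR", dev))
    }
  }
  row
}

#' Build the windowed feature table for a cohort
#'
#' Preprocesses every channel of every subject once (beat detection and
#' per-beat morphology are session-level), then extracts all per-modality
#' features for each sliding window. Temperature and RR trend features of
#' windows with no usable data are forward-filled from the last valid window
#' of the same subject; other missing features stay missing.
#'
#' @param signals Long signal tibble (e.g. `cohort$signals`).
#' @param duration_s,step_s Window configuration, seconds.
#' @param resting_window_s Resting reference span for HR/RR normalization.
#' @param span_s Session span; default last signal timestamp per subject.
#' @return Tibble: `subject_id`, `window_start_s`, `window_end_s`, one column
#'   per feature (named `<modality>.<device>.<feature>`).
#' @export
build_feature_table <- function(signals, duration_s = 60, step_s = 10,
                                resting_window_s = 180, span_s = NULL) {
  subjects <- unique(signals$subject_id)
  purrr::map(subjects, function(sub) {
    sig <- signals[signals$subject_id == sub, ]
    span <- span_s %||% max(sig$t_s)
    win <- make_windows(span, duration_s, step_s)
    if (!nrow(win)) return(NULL)
    arts <- prep_subject(sig, sub, resting_window_s)
    rows <- purrr::map(seq_len(nrow(win)), function(i) {
      r <- subject_window_features(arts, win$window_start_s[i], win$window_end_s[i])
      r <- r[lengths(r) == 1]
      vapply(r, as.numeric, 0)
    })
    feat_names <- unique(unlist(purrr::map(rows, names)))
    mat <- matrix(NA_real_, nrow(win), length(feat_names),
                  dimnames = list(NULL, feat_names))
    for (i in seq_along(rows)) mat[i, names(rows[[i]])] <- rows[[i]]
    out <- bind_cols(
      tibble(subject_id = sub,
             window_start_s = win$window_start_s,
             window_end_s = win$window_end_s),
      as_tibble(mat)
    )
    forward_fill_trend(out)
  }) |> bind_rows()
}

# Forward-fill Temp/RR trend feature columns within a subject (the channels
# are too sparse for every window to see fresh data).
forward_fill_trend <- function(df) {
  cols <- grep("^(temp|rr)\\.", names(df), value = TRUE)
  for (cl in cols) {
    v <- df[[cl]]
    for (i in seq_along(v)) if (is.na(v[i]) && i > 1) v[i] <- v[i - 1]
    df[[cl]] <- v
  }
  df
}

#' Cohort signals to a labeled, gated feature table
#'
#' Convenience wrapper running the standard pipeline: windowed feature
#' extraction, AD labeling from the cuff BP references (baseline of the first
#' three readings, PCHIP interpolation, the +20 mmHg rule, majority-occupancy
#' window labels) and the BP-proximity gate. Windows without a valid label
#' (outside the BP reference span) are dropped.
#'
#' @param cohort An `ad_cohort` (or any list with `signals` and `bp` tibbles).
#' @param duration_s,step_s Window configuration.
#' @param resting_window_s HR/RR resting normalization span.
#' @param max_gap_s BP-proximity gate width.
#' @param delta_mmHg AD threshold above baseline.
#' @return Feature table with `label`, `ad_fraction` and `gate_flag` columns.
#' @export
prepare_features <- function(cohort, duration_s = 60, step_s = 10,
                             resting_window_s = 180, max_gap_s = 120,
                             delta_mmHg = 20) {
  ft <- build_feature_table(cohort$signals, duration_s, step_s,
                            resting_window_s = resting_window_s)
  lab <- ad_labels(cohort$bp, delta_mmHg = delta_mmHg)
  ids <- c("subject_id", "window_start_s", "window_end_s")
  ft <- suppressWarnings(
    left_join(ft, assign_window_labels(ft[, ids], lab), by = ids)
  )
  ft <- left_join(ft, gate_by_bp_proximity(ft[, ids], cohort$bp, max_gap_s), by = ids)
  filter(ft, !is.na(.data$label))
}

#' Feature manifest: scope tags per column
#'
#' Parses the `<modality>.<device>.<feature>` column naming of a feature
#' table into a manifest tibble, the basis for modality- and device-scoped
#' weak learners.
#'
#' @param features Feature table from [build_feature_table()].
#' @return Tibble `feature`, `modality`, `device`.
#' @export
feature_manifest <- function(features) {
  pat <- "^(ecg|ppg|bioz|temp|hr|rr)\\.(wristband|ecg_patch|temp_patch)\\.(.+)$"
  cols <- grep(pat, names(features), value = TRUE)
  tibble(
    feature = cols,
    modality = sub(pat, "\\1", cols),
    device = sub(pat, "\\2", cols)
  )
}

#' Scope-specific feature tables
#'
#' Splits a feature table into the nine learner scopes: one table per modality
#' (features of that modality pooled across devices) and one per device (all
#' modalities recorded by that device). Scopes with no feature columns are
#' omitted with a warning.
#'
#' @param features Feature table (id columns plus any label/gate columns are
#'   carried through).
#' @param manifest Optional manifest; derived from the names by default.
#' @return Named list of tibbles, names `modality:<m>` and `device:<d>`.
#' @export
assemble_tables <- function(features, manifest = NULL) {
  manifest <- manifest %||% feature_manifest(features)
  id_cols <- intersect(c("subject_id", "window_start_s", "window_end_s",
                         "label", "gate_flag", "ad_fraction"), names(features))
  out <- list()
  for (m in unique(manifest$modality)) {
    cols <- manifest$feature[manifest$modality == m]
    out[[paste0("modality:", m)]] <- features[, c(id_cols, cols)]
  }
  for (d in unique(manifest$device)) {
    cols <- manifest$feature[manifest$device == d]
    out[[paste0("device:", d)]] <- features[, c(id_cols, cols)]
  }
  empty <- names(out)[vapply(out, function(x) ncol(x) == length(id_cols), TRUE)]
  if (length(empty)) {
    rlang::warn(paste("scope(s) with zero features omitted:", paste(empty, collapse = ", ")))
    out <- out[setdiff(names(out), empty)]
  }
  out
}

#' The nine learner scopes
#'
#' @return Character vector of scope names (6 modalities, 3 devices).
#' @export
learner_scopes <- function() {
  c(paste0("modality:", c("ecg", "ppg", "bioz", "temp", "hr", "rr")),
    paste0("device:", c("wristband", "ecg_patch", "temp_patch")))
}
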