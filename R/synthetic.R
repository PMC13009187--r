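# Synthetic urodynamic-study (UDS) sessions with controllable autonomic
# dysreflexia (AD) episodes. The generator emulates the *structure* of a
# clinical session — nine wearable channels at their native rates plus sparse
# cuff BP readings — not biophysical waveform realism: templates are rich
# enough for the beat detectors and feature extractors to operate on.

#' Cohort specification for the synthetic UDS generator
#'
#' Defaults emulate the session-level scales of a UDS AD cohort: 17 subjects
#' of whom 7 exhibit AD episodes, ~21-minute sessions, cuff BP readings every
#' 2-3 minutes with cuff-grade measurement noise (sd 2 mmHg), and episodes
#' defined by an SBP rise of >= 20 mmHg above baseline with coupled HR, EDA
#' and (earlier-onset) temperature responses.
#'
#' @param n_subjects Number of subjects.
#' @param ad_subject_fraction Fraction of subjects given AD episodes.
#' @param session_minutes Session length in minutes.
#' @param bp_interval_s Mean spacing of cuff BP references, seconds.
#' @param bp_jitter_s Uniform jitter (+/-) on BP spacing, seconds.
#' @param bp_noise_sd Cuff measurement noise sd, mmHg.
#' @param episode Named list of episode parameters: `rise_duration_s`,
#'   `plateau_s`, `sbp_delta` (mmHg, > 20 for true episodes; length-2 vector =
#'   uniform range), `hr_delta` (bpm, signed; AD can present with tachy- or
#'   bradycardia), `eda_tonic_delta` (uS), `temp_delta` (degC),
#'   `temp_lead_s` (temperature drift starts this many seconds before onset).
#' @param channel_failure Named numeric vector `modality -> missing fraction`,
#'   applied as block dropout after generation.
#' @param noise_scale Named numeric vector `modality -> multiplier` on the
#'   additive sensor noise sd.
#' @param seed Integer seed; the same spec generates a bit-identical cohort.
#' @return An object of class `cohort_spec` (a list).
#' @export
cohort_spec <- function(n_subjects = 17,
                        ad_subject_fraction = 7 / 17,
                        session_minutes = 21,
                        bp_interval_s = 150,
                        bp_jitter_s = 30,
                        bp_noise_sd = 2,
                        episode = list(),
                        channel_failure = NULL,
                        noise_scale = NULL,
                        seed = 1L) {
  stopifnot(n_subjects >= 0, ad_subject_fraction >= 0, ad_subject_fraction <= 1,
            session_minutes > 0, bp_interval_s > 0, bp_noise_sd >= 0)
  ep <- utils::modifyList(list(
    rise_duration_s = 60,
    plateau_s = 60,
    sbp_delta = c(25, 40),
    hr_delta = 15,
    eda_tonic_delta = 1.5,
    temp_delta = 0.3,
    temp_lead_s = 60
  ), episode)
  structure(list(
    n_subjects = as.integer(n_subjects),
    ad_subject_fraction = ad_subject_fraction,
    session_minutes = session_minutes,
    bp_interval_s = bp_interval_s,
    bp_jitter_s = bp_jitter_s,
    bp_noise_sd = bp_noise_sd,
    episode = ep,
    channel_failure = channel_failure,
    noise_scale = noise_scale,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Smooth random wander: natural spline through N(0, sd) control points spaced
# corr_s apart, evaluated on the grid.
smooth_wander <- function(t, sd, corr_s) {
  if (sd == 0) return(numeric(length(t)))
  knots <- seq(min(t) - corr_s, max(t) + corr_s, by = corr_s)
  stats::spline(knots, rnorm(length(knots), 0, sd), xout = t)$y
}

# Smooth 0..1 episode bump: logistic rise over rise_s, hold plateau_s, fall.
episode_bump <- function(t, onset, rise_s, plateau_s) {
  up <- stats::plogis((t - onset - rise_s / 2) * 8 / rise_s)
  dn <- stats::plogis((t - onset - rise_s * 1.5 - plateau_s) * 8 / rise_s)
  up * (1 - dn)
}

noise_mult <- function(spec, modality) {
  ns <- spec$noise_scale
  if (is.null(ns) || is.null(ns[[modality]]) || is.na(ns[[modality]])) 1 else ns[[modality]]
}

# One ECG beat evaluated at offsets dt (s) from the R peak: Gaussian P/Q/R/S/T.
ecg_beat_template <- function(dt) {
  0.12 * exp(-((dt + 0.20) / 0.025)^2) -
    0.12 * exp(-((dt + 0.025) / 0.010)^2) +
    1.00 * exp(-(dt / 0.012)^2) -
    0.18 * exp(-((dt - 0.025) / 0.010)^2) +
    0.28 * exp(-((dt - 0.25) / 0.055)^2)
}

# One PPG pulse at offsets dt from the pulse foot: systolic + diastolic lobes.
ppg_pulse_template <- function(dt, rr) {
  sys <- exp(-((dt - 0.17) / 0.075)^2)
  dia <- 0.45 * exp(-((dt - 0.17 - 0.28) / 0.11)^2)
  (sys + dia) * (dt >= -0.05 & dt < rr)
}

place_templates <- function(n, fs, event_times, template_fun, half_width_s) {
  out <- numeric(n)
  hw <- round(half_width_s * fs)
  for (et in event_times) {
    c0 <- round(et * fs) + 1L
    idx <- max(1L, c0 - hw):min(n, c0 + hw)
    if (!length(idx)) next
    dt <- (idx - 1L) / fs - et
    out[idx] <- out[idx] + template_fun(dt)
  }
  out
}

generate_subject <- function(spec, subject_id, is_ad, seed) {
  withr::with_seed(seed, {
    T_s <- spec$session_minutes * 60
    ep <- spec$episode
    grid1 <- seq(0, T_s, by = 1)

    episodes <- tibble(subject_id = character(), onset_s = numeric(),
                       rise_duration_s = numeric(), plateau_s = numeric(),
                       sbp_delta = numeric(), hr_delta = numeric())
    bump1 <- numeric(length(grid1))
    bump_of <- function(t) numeric(length(t))
    if (is_ad) {
      # onset after the baseline cuff readings (first ~3 references)
      onset <- runif(1, 0.45 * T_s, 0.60 * T_s)
      delta <- if (length(ep$sbp_delta) == 2) runif(1, ep$sbp_delta[1], ep$sbp_delta[2]) else ep$sbp_delta
      episodes <- tibble(subject_id = subject_id, onset_s = onset,
                         rise_duration_s = ep$rise_duration_s, plateau_s = ep$plateau_s,
                         sbp_delta = delta, hr_delta = ep$hr_delta)
      bump_of <- function(t) episode_bump(t, onset, ep$rise_duration_s, ep$plateau_s)
      bump1 <- bump_of(grid1)
    }

    # continuous SBP truth (1 Hz) --------------------------------------------
    sbp_base <- runif(1, 112, 128)
    sbp_delta_tot <- if (is_ad) episodes$sbp_delta[1] else 0
    sbp_cont <- sbp_base + smooth_wander(grid1, 2, 180) + sbp_delta_tot * bump1
    sbp_truth <- tibble(subject_id = subject_id, t_s = grid1, sbp = sbp_cont)

    # continuous HR (1 Hz) ---------------------------------------------------
    hr_base <- runif(1, 65, 85)
    hr_delta <- if (is_ad) episodes$hr_delta[1] else 0
    hr_cont <- hr_base + smooth_wander(grid1, 1.5, 120) + hr_delta * bump1
    hr_cont <- pmax(hr_cont, 40)

    # beat times: mean RR from HR(t), AR(1) HRV around it ---------------------
    rr_phi <- 0.9; rr_sd <- 0.025
    beat_times <- numeric(0)
    tt <- runif(1, 0, 0.8); x <- rnorm(1, 0, rr_sd / sqrt(1 - rr_phi^2))
    while (tt < T_s) {
      beat_times <- c(beat_times, tt)
      mean_rr <- 60 / approx(grid1, hr_cont, tt, rule = 2)$y
      rr <- min(max(mean_rr + x, 0.4), 1.5)
      x <- rr_phi * x + rnorm(1, 0, rr_sd)
      tt <- tt + rr
    }

    fs_ecg <- 128
    n_ecg <- floor(T_s * fs_ecg)
    t_ecg <- (seq_len(n_ecg) - 1) / fs_ecg
    ecg <- place_templates(n_ecg, fs_ecg, beat_times, ecg_beat_template, 0.45) +
      rnorm(n_ecg, 0, 0.02 * noise_mult(spec, "ECG")) +
      0.05 * sin(2 * pi * 0.15 * t_ecg)   # respiration-band baseline sway

    # PPG shares beat times, shifted by pulse transit time; raw sensor is
    # reflective (inverted) and rides a slow drift the preprocessor removes.
    ptt <- 0.22
    rr_seq <- c(diff(beat_times), median(diff(beat_times)))
    amp <- pmax(0.6, 1 + rnorm(length(beat_times), 0, 0.08))
    ppg_clean <- numeric(n_ecg)
    for (b in seq_along(beat_times)) {
      et <- beat_times[b] + ptt
      hw <- round(1.2 * fs_ecg)
      c0 <- round(et * fs_ecg) + 1L
      idx <- max(1L, c0 - hw):min(n_ecg, c0 + hw)
      if (!length(idx)) next
      dt <- (idx - 1L) / fs_ecg - et
      ppg_clean[idx] <- ppg_clean[idx] + amp[b] * ppg_pulse_template(dt, rr_seq[b])
    }
    drift <- smooth_wander(t_ecg, 0.4, 20) + 0.3 * sin(2 * pi * 0.04 * t_ecg)
    ppg_raw <- -(ppg_clean + drift + rnorm(n_ecg, 0, 0.02 * noise_mult(spec, "PPG")))

    # BioZ / EDA at 32 Hz: tonic level + Gaussian-bump SCRs ------------------
    fs_eda <- 32
    n_eda <- floor(T_s * fs_eda)
    t_eda <- (seq_len(n_eda) - 1) / fs_eda
    eda_delta <- if (is_ad) ep$eda_tonic_delta else 0
    tonic <- runif(1, 2, 6) + smooth_wander(t_eda, 0.15, 120) + eda_delta * bump_of(t_eda)
    base_rate <- 3 / 60; ad_rate <- 12 / 60
    rate_of <- function(t) base_rate + (ad_rate - base_rate) * bump_of(t)
    scr_t <- numeric(0); tt <- stats::rexp(1, base_rate)
    while (tt < T_s) {          # thinning for the inhomogeneous Poisson SCRs
      if (runif(1) < rate_of(tt) / ad_rate) scr_t <- c(scr_t, tt)
      tt <- tt + stats::rexp(1, ad_rate)
    }
    phasic <- numeric(n_eda)
    for (st in scr_t) {
      a <- runif(1, 0.1, 0.5)
      idx <- which(t_eda > st - 4 & t_eda < st + 6)
      if (length(idx)) phasic[idx] <- phasic[idx] + a * exp(-((t_eda[idx] - st - 1.2) / 0.9)^2)
    }
    eda <- tonic + phasic + rnorm(n_eda, 0, 0.01 * noise_mult(spec, "BioZ"))

    # temperature at 1/60 Hz; episode drift starts temp_lead_s early ---------
    t_temp <- seq(0, T_s, by = 60)
    temp_delta <- if (is_ad) ep$temp_delta else 0
    temp_bump <- if (is_ad) {
      episode_bump(t_temp, episodes$onset_s[1] - ep$temp_lead_s,
                   ep$rise_duration_s * 2, ep$plateau_s + ep$temp_lead_s)
    } else numeric(length(t_temp))
    temp_base <- runif(1, 36.4, 37.0)
    make_temp <- function() temp_base + smooth_wander(t_temp, 0.05, 300) +
      temp_delta * temp_bump + rnorm(length(t_temp), 0, 0.02 * noise_mult(spec, "Temp"))

    # 1 Hz HR and respiratory-rate channels per device -----------------------
    make_hr <- function() hr_cont + rnorm(length(grid1), 0, 1.5 * noise_mult(spec, "HR"))
    rr_base <- runif(1, 12, 16)
    resp_cont <- rr_base + smooth_wander(grid1, 0.5, 120) + 1.5 * bump1
    make_resp <- function() resp_cont + rnorm(length(grid1), 0, 0.5 * noise_mult(spec, "RR"))

    chan <- function(device, modality, t, v, rate) {
      tibble(subject_id = subject_id, device = device, modality = modality,
             t_s = t, value = v, nominal_rate = rate)
    }
    signals <- bind_rows(
      chan("ecg_patch", "ECG", t_ecg, ecg, fs_ecg),
      chan("wristband", "PPG", t_ecg, ppg_raw, fs_ecg),
      chan("wristband", "BioZ", t_eda, eda, fs_eda),
      chan("wristband", "Temp", t_temp, make_temp(), 1 / 60),
      chan("temp_patch", "Temp", t_temp, make_temp(), 1 / 60),
      chan("wristband", "HR", grid1, make_hr(), 1),
      chan("ecg_patch", "HR", grid1, make_hr(), 1),
      chan("wristband", "RR", grid1, make_resp(), 1),
      chan("ecg_patch", "RR", grid1, make_resp(), 1)
    )

    # sparse cuff BP references; t = 0 at the first reading ------------------
    bp_t <- 0
    while (tail(bp_t, 1) < T_s - spec$bp_interval_s / 2) {
      bp_t <- c(bp_t, tail(bp_t, 1) + spec$bp_interval_s +
                  runif(1, -spec$bp_jitter_s, spec$bp_jitter_s))
    }
    bp_t <- bp_t[bp_t <= T_s]
    sbp_at <- approx(grid1, sbp_cont, bp_t, rule = 2)$y
    bp <- tibble(
      subject_id = subject_id,
      t_s = bp_t,
      sbp = sbp_at + rnorm(length(bp_t), 0, spec$bp_noise_sd),
      dbp = 0.62 * sbp_at + rnorm(length(bp_t), 0, spec$bp_noise_sd),
      hr = approx(grid1, hr_cont, bp_t, rule = 2)$y + rnorm(length(bp_t), 0, 2)
    )

    list(signals = signals, bp = bp, episodes = episodes, sbp_truth = sbp_truth)
  })
}

#' Generate a synthetic UDS cohort
#'
#' Builds one session per subject: ECG at 128 Hz as a beat-template train whose
#' RR intervals follow an AR(1) HRV process (phi = 0.9, sd 25 ms, clipped to
#' 0.4-1.5 s around the instantaneous 60/HR mean), PPG at 128 Hz sharing the
#' beat times, bioimpedance EDA at 32 Hz (tonic level + Gaussian-bump skin
#' conductance responses from an inhomogeneous Poisson process), temperature
#' at 1/60 Hz, and HR/RR at 1 Hz. During AD episodes the continuous SBP rides
#' a smooth logistic ramp of the specified height, HR shifts by `hr_delta`,
#' the SCR rate and tonic EDA level increase, and temperature drifts starting
#' `temp_lead_s` before onset. Cuff BP references sample the continuous SBP at
#' 2-3 minute spacing with measurement noise.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `ad_cohort`: list of tibbles `signals`, `bp`,
#'   `episodes` (ground-truth annotations), `sbp_truth` (noise-free continuous
#'   SBP at 1 Hz, for validation), and the `spec`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 2, session_minutes = 3, seed = 7))
#' dplyr::count(co$signals, device, modality)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects == 0) {
    return(structure(list(signals = tibble(), bp = tibble(), episodes = tibble(),
                          sbp_truth = tibble(), spec = spec), class = "ad_cohort"))
  }
  n_ad <- round(spec$n_subjects * spec$ad_subject_fraction)
  ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  is_ad <- withr::with_seed(child_seed(spec$seed, "assign"), {
    sample(c(rep(TRUE, n_ad), rep(FALSE, spec$n_subjects - n_ad)))
  })
  subs <- purrr::map(seq_len(spec$n_subjects), function(i) {
    generate_subject(spec, ids[i], is_ad[i], child_seed(spec$seed, "subject", ids[i]))
  })
  out <- list(
    signals = bind_rows(purrr::map(subs, "signals")),
    bp = bind_rows(purrr::map(subs, "bp")),
    episodes = bind_rows(purrr::map(subs, "episodes")),
    sbp_truth = bind_rows(purrr::map(subs, "sbp_truth")),
    spec = spec
  )
  if (!is.null(spec$channel_failure)) {
    for (m in names(spec$channel_failure)) {
      out$signals <- inject_channel_failure(out$signals, m, spec$channel_failure[[m]],
                                            seed = child_seed(spec$seed, "fail", m))
    }
  }
  structure(out, class = "ad_cohort")
}

#' @export
#' @method print ad_cohort
print.ad_cohort <- function(x, ...) {
  cat("<ad_cohort> ", length(unique(x$signals$subject_id)), " subjects, ",
      nrow(x$episodes), " AD episodes, ", nrow(x$bp), " BP references\n", sep = "")
  invisible(x)
}

#' Simulate sensor failure on one modality
#'
#' Degrades every channel of the given modality, either by removing contiguous
#' dropout blocks totaling `missing_fraction` of the samples, or by adding
#' Gaussian noise with sd = `missing_fraction` times the channel's
#' interquartile range. Other channels are untouched.
#'
#' @param signals Long signal tibble.
#' @param modality One of ECG, PPG, BioZ, Temp, HR, RR.
#' @param missing_fraction In `[0, 1]`.
#' @param mode `"dropout_blocks"` or `"gaussian_noise"`.
#' @param n_blocks Number of dropout spans (dropout mode).
#' @param seed Integer seed.
#' @return The modified signal tibble.
#' @export
inject_channel_failure <- function(signals, modality, missing_fraction,
                                   mode = c("dropout_blocks", "gaussian_noise"),
                                   n_blocks = 3L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(missing_fraction >= 0, missing_fraction <= 1)
  if (!any(signals$modality == modality)) {
    rlang::warn(paste("modality", modality, "absent; nothing to degrade"))
    return(signals)
  }
  if (missing_fraction == 0) return(signals)
  hit <- signals$modality == modality
  keys <- distinct(signals[hit, ], .data$subject_id, .data$device)
  withr::with_seed(seed, {
    if (mode == "gaussian_noise") {
      iqr <- stats::IQR(signals$value[hit], na.rm = TRUE)
      signals$value[hit] <- signals$value[hit] +
        rnorm(sum(hit), 0, missing_fraction * iqr)
      return(signals)
    }
    drop_idx <- integer(0)
    for (r in seq_len(nrow(keys))) {
      idx <- which(hit & signals$subject_id == keys$subject_id[r] &
                     signals$device == keys$device[r])
      n <- length(idx)
      n_drop <- round(missing_fraction * n)
      if (n_drop >= n) { drop_idx <- c(drop_idx, idx); next }
      if (n_drop == 0) next
      nb <- min(n_blocks, n_drop)
      block <- ceiling(n_drop / nb)
      taken <- logical(n)
      guard <- 0L
      while (sum(taken) < n_drop && guard < 100L) {
        guard <- guard + 1L
        free <- which(!taken)
        st <- free[sample.int(length(free), 1)]
        span <- st:min(n, st + min(block, n_drop - sum(taken)) - 1L)
        taken[span] <- TRUE
      }
      over <- sum(taken) - n_drop
      if (over > 0) taken[tail(which(taken), over)] <- FALSE
      drop_idx <- c(drop_idx, idx[taken])
    }
    if (length(drop_idx)) signals <- signals[-drop_idx, ]
    signals
  })
}

#' Dense noise-free BP references from the simulator truth
#'
#' Resamples the cohort's continuous SBP truth as if a cuff reading were taken
#' every `interval_s` seconds with no measurement noise. Used to validate that
#' the labeling pipeline reproduces the simulator's ground truth when the BP
#' information is complete.
#'
#' @param cohort An `ad_cohort`.
#' @param interval_s Sampling interval of the pseudo-cuff, seconds.
#' @return A BP reference tibble (`subject_id`, `t_s`, `sbp`, `dbp`, `hr`).
#' @export
dense_bp <- function(cohort, interval_s = 1) {
  cohort$sbp_truth |>
    group_by(.data$subject_id) |>
    filter((.data$t_s %% interval_s) == 0) |>
    ungroup() |>
    mutate(dbp = 0.62 * .data$sbp, hr = NA_real_) |>
    select("subject_id", "t_s", "sbp", "dbp", "hr")
}
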