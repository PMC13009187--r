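# Shared fixtures, built once per test run and cached in this environment.
# Sizes are deliberately small; the acceptance tests build their own cohort
# at the study scale.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 4 subjects (2 AD), 5-minute sessions, dense-ish cuff readings.
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(cohort_spec(
      n_subjects = 4, ad_subject_fraction = 0.5, session_minutes = 5,
      bp_interval_s = 45, bp_jitter_s = 10, seed = 202
    ))
  })
}

small_features <- function() {
  fixture("small_features", function() {
    co <- small_cohort()
    ft <- build_feature_table(co$signals, duration_s = 60, step_s = 10)
    lab <- ad_labels(co$bp)
    ft <- suppressWarnings(
      dplyr::left_join(ft, assign_window_labels(ft[, 1:3], lab),
                       by = c("subject_id", "window_start_s", "window_end_s"))
    )
    dplyr::left_join(ft, gate_by_bp_proximity(ft[, 1:3], co$bp),
                     by = c("subject_id", "window_start_s", "window_end_s"))
  })
}

# Study-scale cohort for the acceptance properties: 17 subjects, 7 with AD
# episodes (~2 min: 60 s rise, 60 s plateau), 7-minute sessions with cuff
# readings every ~55 s (the per-session reference count of a full-length UDS
# session at reduced duration).
study_spec <- function(seed = 1L) {
  cohort_spec(n_subjects = 17, ad_subject_fraction = 7 / 17,
              session_minutes = 7, bp_interval_s = 55, bp_jitter_s = 15,
              seed = seed)
}

study_features <- function() {
  fixture("study_features", function() {
    prepare_features(generate_cohort(study_spec(1L)), 60, 10)
  })
}

# Single clean ECG channel: beats at exactly 1 Hz.
template_ecg <- function(n_beats = 10, fs = 128, rr = 1.0, noise = 0) {
  t <- seq(0, n_beats * rr + 1, by = 1 / fs)
  beat_times <- (seq_len(n_beats) - 1) * rr + 0.5
  v <- numeric(length(t))
  for (bt in beat_times) {
    dt <- t - bt
    v <- v + 1.0 * exp(-(dt / 0.012)^2) -
      0.12 * exp(-((dt + 0.025) / 0.010)^2) -
      0.18 * exp(-((dt - 0.025) / 0.010)^2) +
      0.12 * exp(-((dt + 0.20) / 0.025)^2) +
      0.28 * exp(-((dt - 0.25) / 0.055)^2)
  }
  if (noise > 0) v <- v + withr::with_seed(42, rnorm(length(v), 0, noise))
  list(channel = tibble::tibble(t_s = t, value = v), beat_times = beat_times, fs = fs)
}

# Feature tibble for selection tests: n_inf informative + n_noise pure noise.
selection_sim <- function(seed, n = 500, n_inf = 5, n_noise = 50,
                          informative = TRUE) {
  withr::with_seed(seed, {
    xi <- matrix(rnorm(n * n_inf), n)
    xn <- matrix(rnorm(n * n_noise), n)
    eta <- if (informative) rowSums(xi) else rep(0, n)
    y <- as.integer(eta + rnorm(n) > 0)
    if (!informative) y <- sample(y)
    colnames(xi) <- paste0("inf", seq_len(n_inf))
    colnames(xn) <- paste0("noise", seq_len(n_noise))
    list(x = tibble::as_tibble(cbind(xi, xn)), y = y)
  })
}
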