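# Data model for multichannel wearable recordings and cross-device clock alignment.
#
# A session is kept in two long tibbles:
#   signals: subject_id, device, modality, t_s, value, nominal_rate
#   bp:      subject_id, t_s, sbp, dbp, hr
# Time t_s is seconds from session start, with t = 0 at the first cuff BP reading
# (labels derive from BP, so all channels are expressed on that axis).

.adwear_devices <- c("wristband", "ecg_patch", "temp_patch")
.adwear_modalities <- c("ECG", "PPG", "BioZ", "Temp", "HR", "RR")

#' Sensor channel table
#'
#' The nine (device, modality) channels of the wearable setup: a multimodal
#' wristband (PPG, bioimpedance EDA, skin temperature, HR, RR), a chest ECG
#' patch (ECG, HR, RR) and a temperature patch (core/skin temperature), with
#' their nominal sampling rates in Hz.
#'
#' @return A tibble with columns `device`, `modality`, `nominal_rate`.
#' @export
#' @examples
#' sensor_channels()
sensor_channels <- function() {
  tibble(
    device = c("wristband", "wristband", "wristband", "wristband", "wristband",
               "ecg_patch", "ecg_patch", "ecg_patch", "temp_patch"),
    modality = c("PPG", "BioZ", "Temp", "HR", "RR", "ECG", "HR", "RR", "Temp"),
    nominal_rate = c(128, 32, 1 / 60, 1, 1, 128, 1, 1, 1 / 60)
  )
}

#' Validate a long signal table
#'
#' Checks the invariants of the signal data model: required columns, known
#' (device, modality) channel pairs, strictly increasing timestamps within each
#' channel, and positive nominal sampling rates.
#'
#' @param signals Long tibble with columns `subject_id`, `device`, `modality`,
#'   `t_s`, `value`, `nominal_rate`.
#' @return `signals`, invisibly; aborts with an informative message otherwise.
#' @export
validate_signals <- function(signals) {
  needed <- c("subject_id", "device", "modality", "t_s", "value", "nominal_rate")
  missing_cols <- setdiff(needed, names(signals))
  if (length(missing_cols)) {
    rlang::abort(paste("signal table is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  known <- sensor_channels()
  pairs <- distinct(signals, .data$device, .data$modality)
  bad <- dplyr::anti_join(pairs, known, by = c("device", "modality"))
  if (nrow(bad)) {
    rlang::abort(paste0(
      "unknown (device, modality) channel(s): ",
      paste(paste(bad$device, bad$modality, sep = "/"), collapse = ", ")
    ))
  }
  if (any(!is.finite(signals$nominal_rate)) || any(signals$nominal_rate <= 0)) {
    rlang::abort("nominal_rate must be positive and finite")
  }
  ok <- signals |>
    group_by(.data$subject_id, .data$device, .data$modality) |>
    summarise(mono = all(diff(.data$t_s) > 0) || n() < 2, .groups = "drop")
  if (!all(ok$mono)) {
    rlang::abort("timestamps must be strictly increasing within each channel")
  }
  invisible(signals)
}

#' Align device clocks to the reference timeline
#'
#' Wearable clocks drift relative to the reference (BP cuff) timeline. Given at
#' least two synchronization anchor pairs per (subject, device) — device time
#' vs reference time of a shared event at the start and end of the session —
#' each device's timestamps are linearly stretched/compressed onto the
#' reference axis. With exactly two anchors this is the affine map through
#' them; with more, the least-squares affine fit.
#'
#' @param signals Long signal tibble (see [validate_signals()]).
#' @param anchors Tibble with columns `subject_id`, `device`, `device_t_s`,
#'   `reference_t_s`; at least two rows with distinct `device_t_s` per
#'   (subject, device) present in `signals`.
#' @return `signals` with `t_s` mapped onto the reference timeline.
#' @export
align_clocks <- function(signals, anchors) {
  needed <- c("subject_id", "device", "device_t_s", "reference_t_s")
  if (!all(needed %in% names(anchors))) {
    rlang::abort("anchors must have columns subject_id, device, device_t_s, reference_t_s")
  }
  keys <- distinct(signals, .data$subject_id, .data$device)
  maps <- purrr::pmap(keys, function(subject_id, device) {
    a <- anchors[anchors$subject_id == subject_id & anchors$device == device, ]
    if (nrow(a) < 2) {
      rlang::abort(paste0("need >= 2 sync anchors for subject ", subject_id, ", device ", device))
    }
    if (anyDuplicated(a$device_t_s)) {
      rlang::abort(paste0("duplicate device anchor times for subject ", subject_id, ", device ", device))
    }
    fit <- stats::lm.fit(cbind(1, a$device_t_s), a$reference_t_s)
    tibble(subject_id = subject_id, device = device,
           .intercept = unname(fit$coefficients[1]),
           .slope = unname(fit$coefficients[2]))
  }) |> bind_rows()
  if (any(maps$.slope <= 0)) {
    rlang::abort("anchor pairs imply a non-increasing clock map")
  }
  signals |>
    left_join(maps, by = c("subject_id", "device")) |>
    mutate(t_s = .data$.intercept + .data$.slope * .data$t_s) |>
    select(-".intercept", -".slope")
}

#' Read a recorded session from disk
#'
#' Reads the long-format signal table and the sparse cuff BP reference table
#' written by [write_session()] (or exported from an acquisition pipeline).
#' Rows with non-finite values are dropped with a message. CSV is always
#' supported; Parquet requires the arrow package.
#'
#' @param dir Directory containing `signals.csv`/`signals.parquet` and
#'   `bp.csv`/`bp.parquet`, optionally `episodes.csv` (simulator annotations)
#'   and `anchors.csv` (sync anchors; when present, [align_clocks()] is
#'   applied on load).
#' @return A list with tibbles `signals`, `bp`, `episodes` and `anchors`
#'   (NULL when absent).
#' @export
load_session <- function(dir) {
  read_any <- function(stem) {
    csv <- file.path(dir, paste0(stem, ".csv"))
    pq <- file.path(dir, paste0(stem, ".parquet"))
    if (file.exists(csv)) {
      readr::read_csv(csv, show_col_types = FALSE)
    } else if (file.exists(pq)) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        rlang::abort("reading parquet requires the arrow package")
      }
      as_tibble(arrow::read_parquet(pq))
    } else {
      NULL
    }
  }
  signals <- read_any("signals")
  if (is.null(signals)) rlang::abort(paste("no signals file found in", dir))
  bp <- read_any("bp")
  episodes <- read_any("episodes")
  anchors <- read_any("anchors")
  if (!"nominal_rate" %in% names(signals)) {
    signals <- left_join(signals, sensor_channels(), by = c("device", "modality")) |>
      rename(nominal_rate = "nominal_rate")
  }
  n0 <- nrow(signals)
  signals <- filter(signals, is.finite(.data$value), is.finite(.data$t_s))
  if (nrow(signals) < n0) {
    rlang::inform(paste("dropped", n0 - nrow(signals), "non-finite signal rows"))
  }
  if (nrow(signals)) validate_signals(signals)
  if (!is.null(anchors)) signals <- align_clocks(signals, anchors)
  list(signals = signals, bp = bp, episodes = episodes, anchors = anchors)
}

#' Write a session to disk
#'
#' @param session List with tibbles `signals`, `bp` and optionally `episodes`
#'   (as returned by [generate_cohort()] or [load_session()]).
#' @param dir Output directory, created if needed.
#' @param format `"csv"` (default) or `"parquet"` (requires arrow).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(df, stem) {
    if (is.null(df)) return(invisible(NULL))
    if (format == "csv") {
      readr::write_csv(df, file.path(dir, paste0(stem, ".csv")))
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        rlang::abort("writing parquet requires the arrow package")
      }
      arrow::write_parquet(df, file.path(dir, paste0(stem, ".parquet")))
    }
  }
  write_one(session$signals, "signals")
  write_one(session$bp, "bp")
  write_one(session$episodes, "episodes")
  invisible(dir)
}

# Pull one channel (t_s, value, rate) for a subject; NULL when absent.
get_channel <- function(signals, subject, device = NULL, modality = NULL) {
  x <- signals[signals$subject_id == subject, ]
  if (!is.null(device)) x <- x[x$device == device, ]
  if (!is.null(modality)) x <- x[x$modality == modality, ]
  if (!nrow(x)) return(NULL)
  list(t = x$t_s, v = x$value, rate = x$nominal_rate[1])
}
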