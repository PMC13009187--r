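# Objective AD labeling from sparse cuff BP: shape-preserving interpolation of
# SBP, a baseline from the first readings, the >= 20 mmHg threshold rule,
# window labels, and the BP-proximity gate used to limit label noise.

# PCHIP knot derivatives (Fritsch-Carlson/Butland rule): weighted harmonic
# mean of adjacent secant slopes, zero where slopes change sign or vanish;
# shape-preserving one-sided rule at the ends. Matches the convention used by
# scipy.interpolate.PchipInterpolator.
pchip_derivs <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  s <- diff(y) / h
  d <- numeric(n)
  if (n == 2) return(rep(s, 2))
  for (k in 2:(n - 1)) {
    if (s[k - 1] * s[k] <= 0) {
      d[k] <- 0
    } else {
      w1 <- 2 * h[k] + h[k - 1]
      w2 <- h[k] + 2 * h[k - 1]
      d[k] <- (w1 + w2) / (w1 / s[k - 1] + w2 / s[k])
    }
  }
  edge <- function(h0, h1, s0, s1) {
    dd <- ((2 * h0 + h1) * s0 - h0 * s1) / (h0 + h1)
    if (sign(dd) != sign(s0)) dd <- 0
    else if (sign(s0) != sign(s1) && abs(dd) > 3 * abs(s0)) dd <- 3 * s0
    dd
  }
  d[1] <- edge(h[1], h[2], s[1], s[2])
  d[n] <- edge(h[n - 1], h[n - 2], s[n - 1], s[n - 2])
  d
}

pchip_fun <- function(x, y) {
  if (length(x) < 2) rlang::abort("PCHIP needs >= 2 knots")
  splinefunH(x, y, m = pchip_derivs(x, y))
}

#' Resting SBP baseline from the first cuff readings
#'
#' The baseline is the arithmetic mean of the first `n_first` (default three)
#' SBP measurements of the session; subjects with fewer readings cannot be
#' labeled and raise an error, mirroring their exclusion from analysis.
#'
#' @param bp BP reference tibble (`subject_id`, `t_s`, `sbp`, ...).
#' @param n_first Number of initial readings averaged.
#' @return Tibble with one row per subject: `subject_id`, `baseline`.
#' @export
#' @examples
#' bp <- tibble::tibble(subject_id = "S01", t_s = c(0, 150, 300, 450),
#'                      sbp = c(120, 124, 122, 150))
#' compute_baseline(bp)  # 122
compute_baseline <- function(bp, n_first = 3L) {
  out <- bp |>
    group_by(.data$subject_id) |>
    arrange(.data$t_s, .by_group = TRUE) |>
    summarise(n_refs = n(),
              baseline = mean(head(.data$sbp, n_first)),
              .groups = "drop")
  short <- out$subject_id[out$n_refs < n_first]
  if (length(short)) {
    rlang::abort(paste0("insufficient BP references (< ", n_first, ") for subject(s): ",
                        paste(short, collapse = ", ")))
  }
  select(out, "subject_id", "baseline")
}

#' Continuous SBP by shape-preserving cubic interpolation
#'
#' Fits a monotone piecewise-cubic Hermite interpolant (PCHIP) through the
#' sparse cuff SBP readings of each subject and evaluates it on a uniform grid
#' clipped to the observed reference span. PCHIP is exact at the knots and
#' creates no new extrema between them, so a flat pair of readings stays flat
#' and a rise never overshoots.
#'
#' @param bp BP reference tibble.
#' @param grid_rate Grid rate in Hz (default 1).
#' @return Tibble `subject_id`, `t_s`, `sbp_interp`.
#' @export
interpolate_sbp <- function(bp, grid_rate = 1) {
  bp |>
    group_by(.data$subject_id) |>
    arrange(.data$t_s, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      if (any(diff(d$t_s) <= 0)) rlang::abort("BP reference times must be strictly increasing")
      if (any(d$sbp < 50 | d$sbp > 300)) {
        rlang::warn(paste("SBP outside the 50-300 mmHg sanity range for", key$subject_id))
      }
      grid <- seq(ceiling(min(d$t_s) * grid_rate), floor(max(d$t_s) * grid_rate)) / grid_rate
      grid <- grid[grid >= min(d$t_s) & grid <= max(d$t_s)]
      if (nrow(d) == 1) {
        rlang::warn(paste("single BP reading for", key$subject_id, "- constant series"))
        return(tibble(t_s = d$t_s, sbp_interp = d$sbp))
      }
      tibble(t_s = grid, sbp_interp = pchip_fun(d$t_s, d$sbp)(grid))
    }) |>
    ungroup()
}

#' Binary AD indicator from continuous SBP
#'
#' A grid point is labeled AD when the interpolated SBP is at least
#' `delta_mmHg` above the subject's baseline (boundary inclusive). A
#' minimum-duration filter (`min_duration_s`) optionally removes positive runs
#' shorter than the given length, as a stricter reading of "sustained".
#'
#' @param sbp_cont Output of [interpolate_sbp()].
#' @param baseline Output of [compute_baseline()] (or a tibble
#'   `subject_id`, `baseline`).
#' @param delta_mmHg AD threshold above baseline, mmHg.
#' @param min_duration_s Minimum positive-run duration, seconds (0 disables).
#' @return `sbp_cont` with columns `baseline`, `threshold`, `label`.
#' @export
label_ad <- function(sbp_cont, baseline, delta_mmHg = 20, min_duration_s = 0) {
  out <- sbp_cont |>
    left_join(baseline, by = "subject_id") |>
    mutate(threshold = .data$baseline + delta_mmHg,
           label = as.integer(.data$sbp_interp >= .data$threshold))
  if (min_duration_s > 0) {
    out <- out |>
      group_by(.data$subject_id) |>
      arrange(.data$t_s, .by_group = TRUE) |>
      dplyr::group_modify(function(d, key) {
        r <- rle(d$label)
        dur <- r$lengths * ifelse(length(d$t_s) > 1, median(diff(d$t_s)), 1)
        r$values[r$values == 1 & dur < min_duration_s] <- 0L
        d$label <- inverse.rle(r)
        d
      }) |>
      ungroup()
  }
  out
}

#' Full labeling pipeline
#'
#' Convenience wrapper: baseline, PCHIP interpolation and thresholding in one
#' call.
#'
#' @inheritParams label_ad
#' @inheritParams interpolate_sbp
#' @inheritParams compute_baseline
#' @return Label tibble as from [label_ad()].
#' @export
ad_labels <- function(bp, grid_rate = 1, delta_mmHg = 20, n_first = 3L,
                      min_duration_s = 0) {
  label_ad(interpolate_sbp(bp, grid_rate), compute_baseline(bp, n_first),
           delta_mmHg = delta_mmHg, min_duration_s = min_duration_s)
}

#' Window labels by majority occupancy
#'
#' A window `[start, end)` is labeled AD when more than `positive_fraction`
#' (default one half) of the label-grid points inside it are positive. Windows
#' that fall partly outside the labeled span are dropped with a warning.
#'
#' @param windows Tibble `subject_id`, `window_start_s`, `window_end_s`.
#' @param labels Output of [label_ad()] / [ad_labels()].
#' @param positive_fraction Occupancy needed for a positive window label
#'   (strict `>`).
#' @return `windows` with columns `label` and `ad_fraction`.
#' @export
assign_window_labels <- function(windows, labels, positive_fraction = 0.5) {
  res <- windows |>
    group_by(.data$subject_id) |>
    dplyr::group_modify(function(w, key) {
      lab <- labels[labels$subject_id == key$subject_id, ]
      if (!nrow(lab)) {
        w$ad_fraction <- NA_real_
        w$label <- NA_integer_
        return(w)
      }
      lo <- min(lab$t_s); hi <- max(lab$t_s)
      step <- if (nrow(lab) > 1) median(diff(sort(lab$t_s))) else 1
      w$ad_fraction <- purrr::map2_dbl(w$window_start_s, w$window_end_s, function(a, b) {
        inside <- lab$t_s >= a & lab$t_s < b
        if (!any(inside)) return(NA_real_)
        mean(lab$label[inside])
      })
      outside <- w$window_start_s < lo - 1e-9 | w$window_end_s > hi + step + 1e-9
      w$ad_fraction[outside] <- NA_real_
      w$label <- ifelse(is.na(w$ad_fraction), NA_integer_,
                        as.integer(w$ad_fraction > positive_fraction))
      w
    }) |>
    ungroup()
  n_bad <- sum(is.na(res$label))
  if (n_bad) {
    rlang::warn(paste(n_bad, "window(s) outside the labeled span were excluded (label NA)"))
  }
  res
}

#' Gate windows by proximity to a cuff BP reading
#'
#' The interpolated label is most trustworthy near an actual cuff measurement.
#' A window passes the gate when its midpoint lies within `max_gap_s`
#' (default 120 s) of some reference reading (boundary inclusive).
#'
#' @param windows Tibble `subject_id`, `window_start_s`, `window_end_s`.
#' @param bp BP reference tibble.
#' @param max_gap_s Maximum midpoint-to-reference distance, seconds.
#' @return `windows` with logical column `gate_flag`.
#' @export
gate_by_bp_proximity <- function(windows, bp, max_gap_s = 120) {
  windows |>
    group_by(.data$subject_id) |>
    dplyr::group_modify(function(w, key) {
      rt <- bp$t_s[bp$subject_id == key$subject_id]
      mid <- (w$window_start_s + w$window_end_s) / 2
      w$gate_flag <- if (!length(rt)) FALSE else
        purrr::map_lgl(mid, function(m) min(abs(rt - m)) <= max_gap_s)
      w
    }) |>
    ungroup()
}
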