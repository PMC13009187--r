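test_that("baseline is the mean of the first three SBP readings", {
  bp <- tibble::tibble(subject_id = "S01", t_s = c(0, 150, 300, 450),
                       sbp = c(120, 124, 122, 150))
  expect_equal(compute_baseline(bp)$baseline, 122)
  bp2 <- tibble::tibble(subject_id = "S01", t_s = c(0, 150, 300),
                        sbp = c(100, 100, 100))
  expect_equal(compute_baseline(bp2)$baseline, 100)
  short <- tibble::tibble(subject_id = "S01", t_s = c(0, 150), sbp = c(118, 121))
  expect_error(compute_baseline(short), "insufficient")
})

test_that("PCHIP interpolation is exact at knots and preserves shape", {
  # flat pair of readings stays flat
  flat <- tibble::tibble(subject_id = "A", t_s = c(0, 150), sbp = c(120, 120))
  out <- interpolate_sbp(flat, grid_rate = 1)
  expect_lt(max(abs(out$sbp_interp - 120)), 1e-9)

  # knot fidelity
  two <- tibble::tibble(subject_id = "A", t_s = c(0, 60), sbp = c(100, 140))
  o2 <- interpolate_sbp(two, grid_rate = 1)
  expect_equal(o2$sbp_interp[o2$t_s == 0], 100)
  expect_equal(o2$sbp_interp[o2$t_s == 60], 140)

  # no overshoot beyond the knot range on a rise-then-fall profile
  three <- tibble::tibble(subject_id = "A", t_s = c(0, 60, 120),
                          sbp = c(100, 140, 110))
  o3 <- interpolate_sbp(three, grid_rate = 100)
  expect_lte(max(o3$sbp_interp), 140 + 1e-9)
  expect_gte(min(o3$sbp_interp), 100 - 1e-9)

  # monotone knot runs produce monotone interpolants (dense grid)
  mono <- tibble::tibble(subject_id = "A", t_s = c(0, 40, 90, 150),
                         sbp = c(100, 112, 130, 151))
  om <- interpolate_sbp(mono, grid_rate = 50)
  expect_true(all(diff(om$sbp_interp) >= -1e-12))
})

test_that("PCHIP matches the reference shape-preserving interpolant", {
  # oracle: scipy.interpolate.PchipInterpolator on the same knots
  bp <- tibble::tibble(subject_id = "A",
                       t_s = c(0, 30, 60, 150, 200, 260),
                       sbp = c(118, 120, 131, 152, 149, 121))
  f <- adwear:::pchip_fun(bp$t_s, bp$sbp)
  got <- f(c(10, 45, 100, 175, 230, 259))
  expect_equal(got,
               c(118.26780627, 124.8125, 143.41342197,
                 151.14936282, 139.38440098, 121.6870979),
               tolerance = 1e-7)
  expect_equal(max(f(seq(0, 260, by = 0.01))), 152.0, tolerance = 1e-9)
})

test_that("the AD threshold is boundary-inclusive at baseline + 20", {
  base <- tibble::tibble(subject_id = "A", baseline = 122)
  cont <- tibble::tibble(subject_id = "A", t_s = 1:3,
                         sbp_interp = c(142.0, 141.9, 150))
  lab <- label_ad(cont, base)
  expect_equal(lab$label, c(1L, 0L, 1L))
  expect_equal(lab$threshold, rep(142, 3))
})

test_that("a ramped episode yields one contiguous positive run", {
  t <- 0:600
  sbp <- 120 + 25 * exp(-((t - 300) / 80)^2)  # 120 -> 145 -> 120
  cont <- tibble::tibble(subject_id = "A", t_s = t, sbp_interp = sbp)
  lab <- label_ad(cont, tibble::tibble(subject_id = "A", baseline = 122))
  runs <- rle(lab$label)
  expect_equal(sum(runs$values == 1), 1)
})

test_that("window labels follow the majority-occupancy rule", {
  lab <- tibble::tibble(subject_id = "A", t_s = 0:119,
                        label = c(rep(0L, 29), rep(1L, 31), rep(0L, 60)))
  win <- tibble::tibble(subject_id = "A", window_start_s = 0, window_end_s = 60)
  expect_equal(assign_window_labels(win, lab)$label, 1L)  # 31/60
  lab30 <- dplyr::mutate(lab, label = c(rep(0L, 30), rep(1L, 30), rep(0L, 60)))
  expect_equal(assign_window_labels(win, lab30)$label, 0L)  # 30/60 not a majority

  inside <- tibble::tibble(subject_id = "A", window_start_s = 30, window_end_s = 55)
  expect_equal(assign_window_labels(inside, lab)$label, 1L)
  outside <- tibble::tibble(subject_id = "A", window_start_s = 80, window_end_s = 110)
  expect_equal(assign_window_labels(outside, lab)$label, 0L)
  past <- tibble::tibble(subject_id = "A", window_start_s = 100, window_end_s = 160)
  expect_warning(out <- assign_window_labels(past, lab), "excluded")
  expect_true(is.na(out$label))
})

test_that("the BP proximity gate uses window midpoints inclusively", {
  bp <- tibble::tibble(subject_id = "A", t_s = c(0, 180), sbp = c(120, 121))
  win <- tibble::tibble(subject_id = "A",
                        window_start_s = c(60, 270, 150),
                        window_end_s = c(120, 330, 330))
  g <- gate_by_bp_proximity(win, bp, max_gap_s = 120)
  # midpoints 90 (gap 90), 300 (gap 120, inclusive), 240 (gap 60)
  expect_equal(g$gate_flag, c(TRUE, TRUE, TRUE))
  far <- tibble::tibble(subject_id = "A", window_start_s = 290, window_end_s = 312)
  expect_false(gate_by_bp_proximity(far, dplyr::slice(bp, 1))$gate_flag)
})

test_that("labels from dense noise-free BP match simulator ground truth", {
  co <- small_cohort()
  lab <- ad_labels(dense_bp(co, interval_s = 1))
  win <- dplyr::bind_rows(purrr::map(unique(co$signals$subject_id), function(s) {
    w <- make_windows(300, 60, 10)
    w$subject_id <- s
    w[, c("subject_id", "window_start_s", "window_end_s")]
  }))
  got <- assign_window_labels(win, lab)

  # ground truth occupancy from the simulator's continuous SBP + baseline rule
  truth_lab <- co$sbp_truth |>
    dplyr::group_by(subject_id) |>
    dplyr::mutate(baseline = mean(sbp[1:3]),
                  label = as.integer(sbp >= baseline + 20)) |>
    dplyr::ungroup() |>
    dplyr::select(subject_id, t_s, label)
  want <- assign_window_labels(win, truth_lab)
  expect_equal(got$label, want$label)
  expect_gt(sum(got$label), 0)  # the comparison is not vacuous
})

test_that("minimum-duration filtering removes short positive runs", {
  cont <- tibble::tibble(subject_id = "A", t_s = 0:99,
                         sbp_interp = c(rep(120, 40), rep(150, 5), rep(120, 55)))
  base <- tibble::tibble(subject_id = "A", baseline = 120)
  lab0 <- label_ad(cont, base)
  expect_equal(sum(lab0$label), 5)
  lab1 <- label_ad(cont, base, min_duration_s = 10)
  expect_equal(sum(lab1$label), 0)
})
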