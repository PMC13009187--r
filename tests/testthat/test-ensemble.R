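scope_fixture <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = rep(c("A", "B", "C"), length.out = n),
      window_start_s = seq_len(n) * 10,
      window_end_s = seq_len(n) * 10 + 60,
      label = rep(c(1, rep(0, 9)), length.out = n),
      hr.wristband.hr_mean = rnorm(n) + 2 * rep(c(1, rep(0, 9)), length.out = n),
      hr.wristband.sdnn = rnorm(n),
      hr.ecg_patch.hr_mean = rnorm(n)
    )
  })
}

test_that("undersampling balances classes exactly and is seeded", {
  y <- c(rep(0, 100), rep(1, 10))
  idx <- adwear:::undersample_idx(y, seed = 5)
  expect_equal(sum(y[idx] == 0), 10)
  expect_equal(sum(y[idx] == 1), 10)
  expect_identical(idx, adwear:::undersample_idx(y, seed = 5))
  expect_false(identical(idx, adwear:::undersample_idx(y, seed = 6)))
})

test_that("weak learner training scales robustly and drops degenerate columns", {
  tab <- scope_fixture()
  tab$hr.wristband.constant <- 5
  expect_warning(
    wl <- train_weak_learner(tab, "modality:hr", n_trees = 50, seed = 2),
    "constant|degenerate"
  )
  expect_true(wl$available)
  expect_false("hr.wristband.constant" %in% wl$features)
  p <- predict_weak_learner(wl, tab)
  expect_true(all(p >= 0 & p <= 1))

  # rows with every scope feature missing make the learner abstain
  tab2 <- tab
  tab2[1, c("hr.wristband.hr_mean", "hr.wristband.sdnn",
            "hr.ecg_patch.hr_mean", "hr.wristband.constant")] <- NA
  expect_true(is.na(suppressWarnings(predict_weak_learner(wl, tab2))[1]))
})

test_that("learners with too few minority samples become unavailable", {
  tab <- scope_fixture()
  tab$label <- c(1, rep(0, nrow(tab) - 1))
  expect_warning(wl <- train_weak_learner(tab, "modality:hr", seed = 1),
                 "unavailable")
  expect_false(wl$available)
  expect_true(all(is.na(predict_weak_learner(wl, tab))))
})

test_that("k-threshold voting counts concurring learners", {
  v <- c(1, 1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(k_vote(v, 3), 1L)
  expect_equal(k_vote(v, 4), 0L)
  expect_equal(k_vote(v, 0), 1L)
  expect_equal(k_vote(rep(0, 9), 0), 1L)  # k = 0 is always positive
  # unavailable learners shrink the vote without crashing
  expect_equal(k_vote(c(1, 1, NA, NA, 0), 2), 1L)
  # decisions are non-increasing in k
  decs <- vapply(0:9, function(k) k_vote(v, k), 0L)
  expect_true(all(diff(decs) <= 0))
})

test_that("the full ensemble trains nine scoped learners and degrades gracefully", {
  ft <- small_features()
  ens <- suppressWarnings(train_ensemble(ft, n_trees = 30, seed = 3))
  td <- tidy(ens)
  expect_equal(nrow(td), 9)
  expect_setequal(td$scope, learner_scopes())

  pred <- suppressWarnings(predict(ens, ft))
  expect_true(all(pred$vote_count <= pred$n_available))

  # zeroing one modality at prediction time still yields decisions
  broken <- ft
  broken[, grep("^hr\\.", names(ft))] <- NA
  pb <- suppressWarnings(predict(ens, broken))
  expect_true(all(is.na(pb[["proba.modality:hr"]])))
  expect_true(all(pb$n_available > 0))
  expect_true(all(pb$vote_count >= 0))
})

test_that("stacked meta-learner separates separable meta-features", {
  withr::with_seed(7, {
    y <- rep(c(0, 1), each = 60)
    x <- matrix(0.1, 120, 9) + outer(y, rep(0.8, 9)) +
      matrix(rnorm(120 * 9, 0, 0.02), 120)
    colnames(x) <- paste0("proba.", learner_scopes())
    groups <- rep(c("A", "B", "C"), length.out = 120)
  })
  meta <- train_stacked_meta(x, y, groups, choose = "nearest_centroid", seed = 1)
  expect_equal(as.integer(predict(meta, x) >= 0.5), y)

  expect_gte(length(meta_candidates()), 7)

  # uninformative meta features stay at chance
  flat <- matrix(0.5, 120, 9, dimnames = list(NULL, colnames(x)))
  mf <- train_stacked_meta(flat, y, groups, choose = "nearest_centroid", seed = 1)
  p <- predict(mf, flat)
  expect_true(all(abs(p - 0.5) < 1e-9))
})

test_that("candidate meta-learners all fit and predict probabilities", {
  withr::with_seed(8, {
    y <- rep(c(0, 1), each = 40)
    x <- matrix(rnorm(80 * 9, 0.5, 0.1), 80, 9) + outer(y, rep(0.3, 9))
    colnames(x) <- paste0("proba.", learner_scopes())
  })
  for (nm in names(meta_candidates())) {
    cand <- meta_candidates()[[nm]]
    m <- cand$fit(x, y, seed = 1)
    p <- cand$prob(m, x)
    expect_true(all(is.finite(p)), info = nm)
    expect_true(all(p >= -1e-9 & p <= 1 + 1e-9), info = nm)
    expect_gt(suppressWarnings(roc_auc(y, p)), 0.8)
  }
})
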