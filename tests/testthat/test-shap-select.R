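test_that("SHAP standardization has exact column mean 0 and sd 1", {
  phi <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = rnorm(3))
  st <- standardize_shap(phi)
  expect_equal(unname(st$z[, "a"]), c(-1, 0, 1))
  expect_true(st$degenerate[["b"]])
  expect_true(all(is.na(st$z[, "b"])))
  expect_equal(mean(st$z[, "c"]), 0, tolerance = 1e-12)
  expect_equal(sd(st$z[, "c"]), 1, tolerance = 1e-12)
  expect_error(standardize_shap(phi[1, , drop = FALSE]), "N >= 2")
})

test_that("TreeSHAP values satisfy local additivity", {
  s <- selection_sim(1, n = 300, n_noise = 10)
  imp <- tree_shap_importances(s$x, s$y, seed = 1)
  expect_lt(glance(imp)$max_additivity_residual, 1e-4)  # float32 contributions
  expect_equal(nrow(tidy(imp)), 15)
  # the informative block dominates the ranking
  top5 <- tidy(imp) |> dplyr::arrange(dplyr::desc(mean_abs_phi)) |>
    head(5) |> dplyr::pull(feature)
  expect_setequal(top5, paste0("inf", 1:5))
})

test_that("the gate restricts the samples entering selection", {
  s <- selection_sim(2, n = 300, n_noise = 5)
  gate <- rep(c(TRUE, FALSE), length.out = 300)
  imp <- tree_shap_importances(s$x, s$y, gate = gate, seed = 1)
  expect_equal(imp$n, sum(gate))
  expect_error(tree_shap_importances(s$x, rep(1, 300), seed = 1), "single-class")
})

test_that("shadow selection separates signal from noise at small scale", {
  s <- selection_sim(3, n = 500, n_inf = 3, n_noise = 10)
  b <- boruta_select(s$x, s$y, max_iter = 80, seed = 3)
  d <- tidy(b)
  expect_gte(sum(d$decision[1:3] == "accepted"), 2)
  expect_lte(sum(d$decision[4:13] == "accepted"), 1)
  # determinism
  b2 <- boruta_select(s$x, s$y, max_iter = 80, seed = 3)
  expect_identical(tidy(b), tidy(b2))
})

test_that("a duplicated informative feature is never fully rejected", {
  for (sd in 1:3) {
    withr::with_seed(sd, {
      f <- rnorm(400)
      y <- as.integer(f + rnorm(400, 0, 0.5) > 0)
      x <- tibble::tibble(a = f, b = f)
    })
    d <- tidy(boruta_select(x, y, max_iter = 60, seed = sd))
    expect_gte(sum(d$decision == "accepted"), 1)
  }
})

test_that("selection strength is monotone in effect size", {
  accept_rate <- function(beta) {
    hits <- 0
    for (sd in 1:3) {
      withr::with_seed(100 + sd, {
        f <- rnorm(300)
        y <- as.integer(beta * f + rnorm(300) > 0)
        x <- tibble::as_tibble(matrix(rnorm(300 * 6), 300,
                                      dimnames = list(NULL, paste0("n", 1:6))))
        x$sig <- f
      })
      d <- tidy(boruta_select(x, y, max_iter = 60, seed = sd))
      hits <- hits + (d$decision[d$feature == "sig"] == "accepted")
    }
    hits
  }
  expect_gte(accept_rate(2), accept_rate(0.05))
})

# an ad_shap restricted to a single-feature scope
local_one <- function(s) {
  imp <- tree_shap_importances(s$x[, c("inf1", "noise1")], s$y, seed = 9)
  imp$records <- imp$records[1, ]
  imp
}

test_that("importance quadrants combine global and scope-local rankings", {
  s <- selection_sim(5, n = 300, n_inf = 2, n_noise = 4)
  glob <- tree_shap_importances(s$x, s$y, seed = 1)
  locals <- list(
    "scope:a" = tree_shap_importances(s$x[, c("inf1", "inf2", "noise1")], s$y, seed = 2),
    "scope:b" = tree_shap_importances(s$x[, c("noise2", "noise3", "noise4")], s$y, seed = 3)
  )
  q <- importance_quadrants(glob, locals)
  expect_equal(nrow(q), 6)
  i1 <- q[q$feature == "inf1", ]
  expect_gt(i1$global_z, 0)
  expect_gt(i1$local_z, 0)

  # a single-feature scope cannot be z-scored; flagged with local_z 0
  qs <- importance_quadrants(glob, list("scope:one" = local_one(s)))
  expect_equal(qs$local_z[qs$scope == "scope:one"], 0)
  expect_true(qs$single_feature_scope[qs$scope == "scope:one"])
})
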