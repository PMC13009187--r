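# The weak-learner ensemble: nine random forests, each scoped to a single
# modality or device, trained on robust-scaled, class-balanced data; k-
# threshold voting and a stacked meta-learner aggregate their probabilities.

# --- robust scaling ----------------------------------------------------------

fit_robust_scaler <- function(x) {
  qs <- apply(x, 2, function(v) {
    quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  })
  center <- qs[2, ]
  scale <- qs[3, ] - qs[1, ]
  names(center) <- names(scale) <- colnames(x)
  ok <- is.finite(scale) & scale > 0 & is.finite(center)
  if (any(!ok)) {
    rlang::warn(paste("dropping", sum(!ok), "constant/degenerate feature(s):",
                      paste(head(colnames(x)[!ok], 5), collapse = ", ")))
  }
  list(center = center[ok], scale = scale[ok], features = colnames(x)[ok])
}

apply_robust_scaler <- function(scaler, x) {
  x <- x[, scaler$features, drop = FALSE]
  x <- sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
  x[!is.finite(x)] <- 0   # missing features at the (scaled) training median
  x
}

# Balanced 1:1 undersample of the majority class; returns row indices.
undersample_idx <- function(y, seed) {
  i0 <- which(y == 0); i1 <- which(y == 1)
  if (!length(i0) || !length(i1)) return(seq_along(y))
  withr::with_seed(seed, {
    if (length(i0) > length(i1)) i0 <- sample(i0, length(i1))
    else if (length(i1) > length(i0)) i1 <- sample(i1, length(i0))
  })
  sort(c(i0, i1))
}

# --- weak learners -----------------------------------------------------------

#' Train one scope-specific weak learner
#'
#' Restricts the feature table to the learner's scope columns (optionally the
#' selection's accepted set), drops rows whose scope features are entirely
#' missing (absent sensor), robust-scales by training median/IQR, balances
#' classes 1:1 by random undersampling of the majority, and fits a random
#' forest. Learners with fewer than `min_minority` minority rows are marked
#' unavailable and excluded from voting.
#'
#' @param scope_table Scope feature tibble (from [assemble_tables()]) with a
#'   `label` column.
#' @param scope Scope name (e.g. `"modality:hr"`).
#' @param selected Optional character vector of selected feature names; NULL
#'   uses all scope features. If none of the selected names are in scope, the
#'   full scope set is used with a warning.
#' @param n_trees Random forest size.
#' @param min_minority Minimum minority-class rows.
#' @param seed Integer seed (undersampling and forest).
#' @return Object of class `ad_weak_learner`.
#' @export
train_weak_learner <- function(scope_table, scope, selected = NULL,
                               n_trees = 100L, min_minority = 2L, seed = 1L) {
  feat_cols <- setdiff(names(scope_table)[vapply(scope_table, is.numeric, TRUE)],
                       c("window_start_s", "window_end_s", "label", "ad_fraction"))
  if (!is.null(selected)) {
    sel <- intersect(feat_cols, selected)
    if (!length(sel)) {
      rlang::warn(paste0(scope, ": no selected features in scope; using all ",
                         length(feat_cols), " features"))
    } else feat_cols <- sel
  }
  out <- structure(list(scope = scope, features = feat_cols, available = FALSE,
                        scaler = NULL, rf = NULL, seed = seed), class = "ad_weak_learner")
  y <- scope_table$label
  x <- as.matrix(scope_table[, feat_cols, drop = FALSE])
  usable <- !is.na(y) & rowSums(is.finite(x)) > 0
  x <- x[usable, , drop = FALSE]; y <- y[usable]
  if (sum(y == 1) < min_minority || sum(y == 0) < min_minority) {
    rlang::warn(paste0(scope, ": too few minority samples; learner unavailable"))
    return(out)
  }
  scaler <- fit_robust_scaler(x)
  if (!length(scaler$features)) {
    rlang::warn(paste0(scope, ": all features degenerate; learner unavailable"))
    return(out)
  }
  xs <- apply_robust_scaler(scaler, x)
  idx <- undersample_idx(y, child_seed(seed, "under", scope))
  rf <- withr::with_seed(child_seed(seed, "rf", scope), {
    randomForest::randomForest(xs[idx, , drop = FALSE], factor(y[idx], levels = c(0, 1)),
                               ntree = n_trees)
  })
  out$available <- TRUE
  out$scaler <- scaler
  out$rf <- rf
  out$features <- scaler$features
  out$n_train <- length(idx)
  out
}

#' Predict AD probability with one weak learner
#'
#' Rows whose scope features are entirely missing get `NA` (the learner
#' abstains, modeling sensor absence).
#'
#' @param learner An `ad_weak_learner`.
#' @param scope_table New data with the learner's feature columns.
#' @return Numeric vector of probabilities (NA where the learner abstains).
#' @export
predict_weak_learner <- function(learner, scope_table) {
  n <- nrow(scope_table)
  if (!learner$available) return(rep(NA_real_, n))
  x <- as.matrix(scope_table[, learner$features, drop = FALSE])
  absent <- rowSums(is.finite(x)) == 0
  xs <- apply_robust_scaler(learner$scaler, x)
  p <- predict(learner$rf, xs, type = "prob")[, "1"]
  p[absent] <- NA_real_
  unname(p)
}

#' k-threshold vote
#'
#' Predicts AD when at least `k` available weak learners vote positive.
#' Unavailable learners (NA votes) contribute nothing. `k = 0` always
#' predicts AD.
#'
#' @param votes Binary (0/1/NA) vector or matrix (rows = samples).
#' @param k Concurrence threshold.
#' @return Binary decision(s).
#' @export
#' @examples
#' k_vote(c(1, 1, 1, 0, 0, 0, 0, 0, 0), k = 3)  # 1
#' k_vote(c(1, 1, 1, 0, 0, 0, 0, 0, 0), k = 4)  # 0
k_vote <- function(votes, k) {
  stopifnot(k >= 0)
  if (is.matrix(votes)) {
    as.integer(rowSums(votes == 1, na.rm = TRUE) >= k)
  } else {
    as.integer(sum(votes == 1, na.rm = TRUE) >= k)
  }
}

# --- full ensemble -----------------------------------------------------------

#' Train the nine-learner ensemble
#'
#' Builds the scope tables (6 modalities + 3 devices), trains one weak
#' learner per scope, and stores everything needed for prediction.
#'
#' @param features Feature table with a `label` column.
#' @param manifest Optional manifest (derived from names by default).
#' @param selected Named list `scope -> character vector` of selected
#'   features (e.g. from [boruta_select()] per scope), or NULL for all.
#' @param scopes Scopes to train (default all nine).
#' @param n_trees,seed Forwarded to [train_weak_learner()].
#' @return Object of class `ad_ensemble`.
#' @export
train_ensemble <- function(features, manifest = NULL, selected = NULL,
                           scopes = learner_scopes(), n_trees = 100L, seed = 1L) {
  manifest <- manifest %||% feature_manifest(features)
  tables <- assemble_tables(features, manifest)
  scopes <- intersect(scopes, names(tables))
  learners <- purrr::map(scopes, function(sc) {
    train_weak_learner(tables[[sc]], sc, selected = selected[[sc]],
                       n_trees = n_trees, seed = child_seed(seed, sc))
  })
  names(learners) <- scopes
  structure(list(learners = learners, scopes = scopes, manifest = manifest,
                 n_trees = n_trees, seed = seed), class = "ad_ensemble")
}

#' @export
#' @method print ad_ensemble
print.ad_ensemble <- function(x, ...) {
  av <- vapply(x$learners, function(l) l$available, TRUE)
  cat("<ad_ensemble> ", sum(av), "/", length(av), " learners available: ",
      paste(x$scopes[av], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-learner ensemble probabilities
#'
#' @param object An `ad_ensemble`.
#' @param features New feature table (same column naming).
#' @param vote_threshold Per-learner probability binarization threshold.
#' @param ... Unused.
#' @return Tibble: id columns, one probability column per scope
#'   (`proba.<scope>`), `vote_count`, and `n_available`.
#' @export
predict.ad_ensemble <- function(object, features, vote_threshold = 0.5, ...) {
  tables <- assemble_tables(features, object$manifest)
  id_cols <- intersect(c("subject_id", "window_start_s", "window_end_s", "label"),
                       names(features))
  out <- features[, id_cols]
  probs <- purrr::map(object$scopes, function(sc) {
    if (!sc %in% names(tables)) return(rep(NA_real_, nrow(features)))
    predict_weak_learner(object$learners[[sc]], tables[[sc]])
  })
  names(probs) <- paste0("proba.", object$scopes)
  out <- bind_cols(out, as_tibble(probs))
  pm <- as.matrix(out[, paste0("proba.", object$scopes)])
  votes <- (pm >= vote_threshold) * 1L
  out$vote_count <- rowSums(votes == 1, na.rm = TRUE)
  out$n_available <- rowSums(!is.na(pm))
  out
}

# --- stacked meta-learning ---------------------------------------------------

# Candidate bank of meta-classifiers on the 9 learner probabilities. Each
# candidate is fit(x, y) -> model and prob(model, x) -> P(AD). Meta features
# are imputed at 0.5 (an abstaining learner is uninformative).
meta_candidates <- function() {
  list(
    nearest_centroid = list(
      fit = function(x, y, seed) {
        list(c0 = colMeans(x[y == 0, , drop = FALSE]),
             c1 = colMeans(x[y == 1, , drop = FALSE]))
      },
      prob = function(m, x) {
        d0 <- sqrt(rowSums(sweep(x, 2, m$c0)^2))
        d1 <- sqrt(rowSums(sweep(x, 2, m$c1)^2))
        ifelse(d0 + d1 < 1e-12, 0.5, d0 / (d0 + d1))
      }
    ),
    logistic = list(
      fit = function(x, y, seed) {
        suppressWarnings(glm.fit(cbind(1, x), y, family = binomial()))$coefficients
      },
      prob = function(m, x) {
        m[!is.finite(m)] <- 0
        as.numeric(stats::plogis(cbind(1, x) %*% m))
      }
    ),
    random_forest = list(
      fit = function(x, y, seed) {
        withr::with_seed(seed, randomForest::randomForest(
          x, factor(y, levels = c(0, 1)), ntree = 100L))
      },
      prob = function(m, x) unname(predict(m, x, type = "prob")[, "1"])
    ),
    gradient_boosting = list(
      fit = function(x, y, seed) {
        fit_booster(x, y, utils::modifyList(default_booster_params(),
                                            list(nrounds = 60L, max_depth = 3L)),
                    seed = seed)
      },
      prob = function(m, x) {
        storage.mode(x) <- "double"
        predict(m, xgboost::xgb.DMatrix(x, nthread = 1))
      }
    ),
    knn = list(
      fit = function(x, y, seed) list(x = x, y = factor(y, levels = c(0, 1)),
                                      k = min(5L, nrow(x))),
      prob = function(m, x) {
        pr <- class::knn(m$x, x, m$y, k = m$k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      }
    ),
    naive_bayes = list(
      fit = function(x, y, seed) {
        e1071::naiveBayes(as.data.frame(x), factor(y, levels = c(0, 1)))
      },
      prob = function(m, x) unname(predict(m, as.data.frame(x), type = "raw")[, "1"])
    ),
    lda = list(
      fit = function(x, y, seed) {
        keep <- apply(x, 2, sd) > 0
        if (!any(keep)) keep[1] <- TRUE
        list(fit = MASS::lda(x[, keep, drop = FALSE], grouping = factor(y, levels = c(0, 1))),
             keep = keep)
      },
      prob = function(m, x) {
        unname(predict(m$fit, x[, m$keep, drop = FALSE])$posterior[, "1"])
      }
    )
  )
}

impute_meta <- function(x) {
  x[!is.finite(x)] <- 0.5
  x
}

# Grouped k-fold macro-F1 of one candidate on the meta-training data.
meta_cv_f1 <- function(cand, x, y, groups, k = 3L, seed = 1L) {
  ug <- unique(groups)
  if (length(ug) < 2) return(NA_real_)
  k <- min(k, length(ug))
  fold_of <- withr::with_seed(seed, setNames(sample(rep_len(seq_len(k), length(ug))), ug))
  preds <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- !(groups %in% ug[fold_of[ug] == f])
    if (length(unique(y[tr])) < 2) next
    m <- try(cand$fit(x[tr, , drop = FALSE], y[tr], seed), silent = TRUE)
    if (inherits(m, "try-error")) next
    p <- try(cand$prob(m, x[!tr, , drop = FALSE]), silent = TRUE)
    if (inherits(p, "try-error")) next
    preds[!tr] <- p
  }
  ok <- !is.na(preds)
  if (!any(ok)) return(NA_real_)
  macro_f1(y[ok], as.integer(preds[ok] >= 0.5))
}

#' Train the stacked meta-learner
#'
#' Fits every candidate meta-classifier on the weak-learner probability
#' matrix, scores each by grouped cross-validated macro F1 (folds split by
#' subject so no subject straddles folds), and keeps the best. Meta features
#' from abstaining learners are imputed at 0.5.
#'
#' @param meta_x Matrix/tibble of weak-learner probabilities (one column per
#'   scope).
#' @param y Binary labels.
#' @param groups Subject ids used for grouped model-selection CV.
#' @param candidates Candidate bank; default [meta_candidates()] (7 families).
#' @param choose `"cv"` selects by grouped CV; a candidate name forces it.
#' @param seed Integer seed.
#' @return Object of class `ad_meta`.
#' @export
train_stacked_meta <- function(meta_x, y, groups, candidates = meta_candidates(),
                               choose = "cv", seed = 1L) {
  if (length(candidates) < 7 && identical(choose, "cv")) {
    rlang::warn("candidate bank smaller than the 7 required families")
  }
  x <- impute_meta(as.matrix(meta_x))
  if (choose != "cv") {
    stopifnot(choose %in% names(candidates))
    name <- choose
  } else {
    scores <- vapply(candidates, meta_cv_f1, 0, x = x, y = y, groups = groups,
                     seed = seed)
    name <- names(candidates)[which.max(scores)]
  }
  cand <- candidates[[name]]
  model <- cand$fit(x, y, seed)
  structure(list(name = name, model = model, prob = cand$prob,
                 features = colnames(x)), class = "ad_meta")
}

#' @export
predict.ad_meta <- function(object, meta_x, ...) {
  x <- impute_meta(as.matrix(meta_x))
  x <- x[, object$features, drop = FALSE]
  as.numeric(object$prob(object$model, x))
}
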