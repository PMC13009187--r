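# Leave-one-subject-out evaluation with repeats, imbalance-aware metrics,
# the window-configuration sweep, the constant-predictor baseline, and the
# learner-subset robustness analysis.

#' Leave-one-subject-out splits
#'
#' @param subjects Vector of subject ids (duplicates collapsed).
#' @return List of `list(train, test)` with `test` a single subject; one
#'   split per subject.
#' @export
loso_splits <- function(subjects) {
  subjects <- unique(subjects)
  if (length(subjects) < 2) rlang::abort("LOSO needs >= 2 subjects")
  purrr::map(subjects, function(s) list(train = setdiff(subjects, s), test = s))
}

#' Macro F1 score
#'
#' Unweighted mean of the two class F1 scores. A class with zero true and
#' zero predicted members contributes F1 = 0 (explicit convention, so a
#' degenerate constant predictor is penalized on the absent class).
#'
#' @param labels,predictions Binary vectors.
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(labels, predictions) {
  f1_of <- function(cls) {
    tp <- sum(labels == cls & predictions == cls)
    fp <- sum(labels != cls & predictions == cls)
    fn <- sum(labels == cls & predictions != cls)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  (f1_of(0) + f1_of(1)) / 2
}

classification_metrics <- function(labels, predictions) {
  pr <- function(cls) {
    tp <- sum(labels == cls & predictions == cls)
    fp <- sum(labels != cls & predictions == cls)
    fn <- sum(labels == cls & predictions != cls)
    c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = if (tp + fn > 0) tp / (tp + fn) else 0,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
  }
  p0 <- pr(0); p1 <- pr(1)
  tibble(
    accuracy = mean(labels == predictions),
    precision_neg = p0[["precision"]], recall_neg = p0[["recall"]], f1_neg = p0[["f1"]],
    precision_pos = p1[["precision"]], recall_pos = p1[["recall"]], f1_pos = p1[["f1"]],
    macro_precision = (p0[["precision"]] + p1[["precision"]]) / 2,
    macro_recall = (p0[["recall"]] + p1[["recall"]]) / 2,
    macro_f1 = (p0[["f1"]] + p1[["f1"]]) / 2
  )
}

#' Macro F1 of a constant majority-class predictor
#'
#' Closed form: with majority prevalence `p = n_maj / n_total`, the majority
#' class has F1 `2p / (1 + p)` and the minority class F1 0, so macro
#' F1 = `p / (1 + p)`. With a single-class population the convention above
#' yields 0.5.
#'
#' @param n_pos,n_neg Class counts (AD, normal).
#' @return Macro F1 of always predicting the majority class.
#' @export
#' @examples
#' dummy_baseline(105, 2040)  # 0.4875
dummy_baseline <- function(n_pos, n_neg) {
  total <- n_pos + n_neg
  if (total <= 0) rlang::abort("class counts must sum to a positive total")
  if (n_pos == 0 || n_neg == 0) return(0.5)
  p <- max(n_pos, n_neg) / total
  (2 * p / (1 + p)) / 2
}

#' Rank-based ROC-AUC
#'
#' Mann-Whitney statistic with midranks for ties: the probability that a
#' random positive outranks a random negative.
#'
#' @param labels Binary labels.
#' @param probabilities Scores.
#' @return AUC, or NA with a warning if a class is absent.
#' @export
roc_auc <- function(labels, probabilities) {
  ok <- !is.na(labels) & !is.na(probabilities)
  labels <- labels[ok]; probabilities <- probabilities[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::warn("single-class labels: AUC undefined")
    return(NA_real_)
  }
  r <- rank(probabilities)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- full LOSO evaluation ----------------------------------------------------

select_per_scope <- function(features, manifest, gate, boruta_args, seed) {
  tables <- assemble_tables(features, manifest)
  sel <- purrr::imap(tables, function(tab, sc) {
    res <- try(rlang::exec(boruta_select, features = tab, labels = features$label,
                           gate = gate, seed = child_seed(seed, "sel", sc),
                           !!!boruta_args), silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    acc <- accepted_features(res)
    if (!length(acc)) NULL else acc
  })
  compact(sel)
}

ensemble_probs_matrix <- function(pred, scopes) {
  as.matrix(pred[, paste0("proba.", scopes), drop = FALSE])
}

#' Leave-one-subject-out evaluation of the full ensemble
#'
#' For each repeat and each held-out subject: trains the nine weak learners
#' on the remaining subjects, aggregates with a stacked meta-learner (meta
#' training features built by inner leave-one-subject-out within the training
#' fold, so no training subject's meta-features come from learners that saw
#' it) and/or k-threshold voting, and predicts the held-out subject's windows
#' at the original class imbalance.
#'
#' @param features Feature table with `label` (and optionally `gate_flag`).
#' @param manifest Optional manifest.
#' @param repeats Number of repeats with different random seeds.
#' @param seed Base seed.
#' @param selection `"pooled"` (one shadow-feature selection per scope on all
#'   gated samples, reused across folds), `"per_fold"` (refit inside every
#'   training fold; leakage-safe but far more expensive) or `"none"`.
#' @param aggregator `"stacked"`, `"kvote"`, or both (default).
#' @param k Voting threshold for the reported k-vote metrics.
#' @param stacking `"inner_cv"` (inner LOSO meta-features) or `"in_sample"`.
#' @param n_trees Weak-learner forest size.
#' @param boruta_args List of arguments for [boruta_select()].
#' @param meta_choose `"cv"` or a candidate name (e.g. `"nearest_centroid"`).
#' @param vote_threshold Per-learner probability binarization threshold.
#' @return Object of class `ad_eval`: `predictions` (per repeat/window),
#'   `metrics`, `fold_art` (stacking artifacts for subset analysis), config.
#' @export
evaluate_loso <- function(features, manifest = NULL, repeats = 10L, seed = 1L,
                          selection = c("pooled", "per_fold", "none"),
                          aggregator = c("stacked", "kvote"), k = 5L,
                          stacking = c("inner_cv", "in_sample"),
                          n_trees = 100L, boruta_args = list(),
                          meta_choose = "cv", vote_threshold = 0.5) {
  selection <- match.arg(selection)
  stacking <- match.arg(stacking)
  aggregator <- match.arg(aggregator, several.ok = TRUE)
  manifest <- manifest %||% feature_manifest(features)
  features <- filter(features, !is.na(.data$label))
  gate <- if ("gate_flag" %in% names(features)) features$gate_flag else NULL
  subjects <- unique(features$subject_id)
  scopes <- learner_scopes()

  sel_pooled <- NULL
  if (selection == "pooled") {
    sel_pooled <- select_per_scope(features, manifest, gate, boruta_args,
                                   child_seed(seed, "selection"))
  }

  all_pred <- list(); all_art <- list()
  for (r in seq_len(repeats)) {
    rs <- child_seed(seed, "repeat", r)
    fold_pred <- list(); fold_art <- list()
    for (sp in loso_splits(subjects)) {
      s <- sp$test
      tr_rows <- features$subject_id %in% sp$train
      train_feat <- features[tr_rows, ]
      test_feat <- features[!tr_rows, ]
      sel <- sel_pooled
      if (selection == "per_fold") {
        g <- if (is.null(gate)) NULL else gate[tr_rows]
        sel <- select_per_scope(train_feat, manifest, g, boruta_args,
                                child_seed(rs, "fold", s, "sel"))
      }
      ens <- suppressWarnings(
        train_ensemble(train_feat, manifest, selected = sel, n_trees = n_trees,
                       seed = child_seed(rs, "fold", s))
      )
      pred <- suppressWarnings(predict(ens, test_feat, vote_threshold))
      pred$fold_subject <- s

      meta_x <- NULL; meta_y <- NULL; meta_g <- NULL
      if ("stacked" %in% aggregator) {
        if (stacking == "inner_cv" && length(sp$train) >= 3) {
          inner <- purrr::map(sp$train, function(j) {
            in_rows <- train_feat$subject_id != j
            ens_in <- suppressWarnings(
              train_ensemble(train_feat[in_rows, ], manifest, selected = sel,
                             n_trees = n_trees,
                             seed = child_seed(rs, "fold", s, "inner", j))
            )
            pj <- suppressWarnings(predict(ens_in, train_feat[!in_rows, ], vote_threshold))
            list(x = ensemble_probs_matrix(pj, scopes),
                 y = train_feat$label[!in_rows],
                 g = train_feat$subject_id[!in_rows])
          })
          meta_x <- do.call(rbind, purrr::map(inner, "x"))
          meta_y <- unlist(purrr::map(inner, "y"))
          meta_g <- unlist(purrr::map(inner, "g"))
        } else {
          if (stacking == "inner_cv") {
            rlang::warn("fewer than 3 training subjects: falling back to in-sample meta-features")
          }
          pin <- suppressWarnings(predict(ens, train_feat, vote_threshold))
          meta_x <- ensemble_probs_matrix(pin, scopes)
          meta_y <- train_feat$label
          meta_g <- train_feat$subject_id
        }
        colnames(meta_x) <- paste0("proba.", scopes)
        meta <- suppressWarnings(
          train_stacked_meta(meta_x, meta_y, meta_g, choose = meta_choose,
                             seed = child_seed(rs, "fold", s, "meta"))
        )
        pred$meta_proba <- predict(meta, ensemble_probs_matrix(pred, scopes))
        pred$meta_decision <- as.integer(pred$meta_proba >= 0.5)
        pred$meta_name <- meta$name
      }
      fold_pred[[s]] <- pred
      fold_art[[s]] <- list(meta_x = meta_x, meta_y = meta_y, meta_g = meta_g,
                            test_x = ensemble_probs_matrix(pred, scopes),
                            test_y = pred$label, seed = child_seed(rs, "fold", s, "meta"))
    }
    rp <- bind_rows(fold_pred)
    rp$.repeat <- r
    all_pred[[r]] <- rp
    all_art[[r]] <- fold_art
  }
  predictions <- bind_rows(all_pred)
  structure(list(
    predictions = predictions,
    metrics = eval_metrics(predictions, scopes, k = k,
                           vote_threshold = vote_threshold),
    fold_art = all_art,
    config = list(repeats = repeats, seed = seed, selection = selection,
                  aggregator = aggregator, k = k, stacking = stacking,
                  n_trees = n_trees, meta_choose = meta_choose,
                  vote_threshold = vote_threshold),
    scopes = scopes, subjects = subjects
  ), class = "ad_eval")
}

# Pooled-over-windows metrics per repeat, then mean +/- sd across repeats.
eval_metrics <- function(predictions, scopes, k = 5L, vote_threshold = 0.5) {
  per_rep <- predictions |>
    group_by(.data$.repeat) |>
    dplyr::group_modify(function(d, key) {
      y <- d$label
      rows <- list()
      for (sc in scopes) {
        p <- d[[paste0("proba.", sc)]]
        ok <- !is.na(p)
        if (!any(ok)) next
        rows[[sc]] <- bind_cols(
          tibble(component = sc,
                 auc = suppressWarnings(roc_auc(y[ok], p[ok]))),
          classification_metrics(y[ok], as.integer(p[ok] >= vote_threshold))
        )
      }
      for (kk in 0:length(scopes)) {
        dec <- as.integer(d$vote_count >= kk)
        rows[[paste0("kvote_", kk)]] <- bind_cols(
          tibble(component = paste0("kvote_", kk), auc = NA_real_),
          classification_metrics(y, dec)
        )
      }
      if ("meta_proba" %in% names(d)) {
        rows[["meta"]] <- bind_cols(
          tibble(component = "stacked_meta",
                 auc = suppressWarnings(roc_auc(y, d$meta_proba))),
          classification_metrics(y, d$meta_decision)
        )
      }
      bind_rows(rows)
    }) |>
    ungroup()
  per_rep |>
    group_by(.data$component) |>
    summarise(across(dplyr::where(is.numeric) & !dplyr::any_of(".repeat"),
                     list(mean = ~ mean(.x, na.rm = TRUE),
                          sd = ~ sd(.x, na.rm = TRUE))),
              n_repeats = dplyr::n(), .groups = "drop")
}

#' @export
#' @method print ad_eval
print.ad_eval <- function(x, ...) {
  m <- x$metrics
  hl <- m[m$component %in% c("stacked_meta", paste0("kvote_", x$config$k)), ]
  cat("<ad_eval> ", length(x$subjects), " subjects, ", x$config$repeats, " repeats\n", sep = "")
  for (i in seq_len(nrow(hl))) {
    cat(sprintf("  %s: macro F1 %.3f +/- %.3f\n", hl$component[i],
                hl$macro_f1_mean[i], hl$macro_f1_sd[i]))
  }
  invisible(x)
}

# --- per-learner LOSO (used by the window sweep) -----------------------------

loso_learner_f1 <- function(features, manifest = NULL, repeats = 10L, seed = 1L,
                            n_trees = 100L, vote_threshold = 0.5) {
  manifest <- manifest %||% feature_manifest(features)
  features <- filter(features, !is.na(.data$label))
  subjects <- unique(features$subject_id)
  purrr::map(seq_len(repeats), function(r) {
    rs <- child_seed(seed, "repeat", r)
    preds <- purrr::map(loso_splits(subjects), function(sp) {
      tr <- features$subject_id %in% sp$train
      ens <- suppressWarnings(
        train_ensemble(features[tr, ], manifest, n_trees = n_trees,
                       seed = child_seed(rs, "fold", sp$test))
      )
      suppressWarnings(predict(ens, features[!tr, ], vote_threshold))
    }) |> bind_rows()
    purrr::map(learner_scopes(), function(sc) {
      p <- preds[[paste0("proba.", sc)]]
      ok <- !is.na(p)
      tibble(scope = sc, .repeat = r,
             f1 = if (any(ok)) macro_f1(preds$label[ok], as.integer(p[ok] >= vote_threshold)) else NA_real_)
    }) |> bind_rows()
  }) |> bind_rows()
}

#' Window-configuration sweep
#'
#' Re-extracts features for each (duration, step) configuration, re-labels
#' the windows, and evaluates every weak learner leave-one-subject-out over
#' repeats. Consecutive configurations are compared per learner with a paired
#' two-sided t-test over the repeat F1 values.
#'
#' @param signals Long signal tibble.
#' @param bp BP reference tibble.
#' @param configs List of `c(duration_s, step_s)` pairs (default the six
#'   studied configurations).
#' @param repeats,seed,n_trees Evaluation settings.
#' @param resting_window_s Forwarded to [build_feature_table()].
#' @return List: `f1` (config x learner x repeat), `tests` (paired t-tests
#'   between consecutive configs), `grand` (mean +/- sd per config).
#' @export
window_sweep <- function(signals, bp, configs = .window_presets, repeats = 10L,
                         seed = 1L, n_trees = 100L, resting_window_s = 180) {
  labels <- ad_labels(bp)
  res <- purrr::map(configs, function(cf) {
    ft <- build_feature_table(signals, cf[1], cf[2],
                              resting_window_s = resting_window_s)
    ft <- suppressWarnings(
      left_join(ft, assign_window_labels(ft[, 1:3], labels),
                by = c("subject_id", "window_start_s", "window_end_s"))
    )
    f1 <- loso_learner_f1(ft, repeats = repeats, seed = seed, n_trees = n_trees)
    f1$duration_s <- cf[1]; f1$step_s <- cf[2]
    f1
  }) |> bind_rows()
  cfg_lab <- function(d, s) paste0("(", d, ",", s, ")")
  res$config <- cfg_lab(res$duration_s, res$step_s)
  cfgs <- unique(res$config)
  tests <- list()
  if (length(cfgs) > 1) {
    for (i in seq_len(length(cfgs) - 1)) {
      for (sc in unique(res$scope)) {
        a <- res$f1[res$config == cfgs[i] & res$scope == sc]
        b <- res$f1[res$config == cfgs[i + 1] & res$scope == sc]
        pv <- if (length(a) > 1 && length(b) > 1 && sd(c(a - b)) > 0) {
          t.test(a, b, paired = TRUE)$p.value
        } else NA_real_
        tests[[paste(cfgs[i], cfgs[i + 1], sc)]] <-
          tibble(config_a = cfgs[i], config_b = cfgs[i + 1], scope = sc,
                 mean_a = mean(a), mean_b = mean(b), p_value = pv)
      }
    }
  }
  grand <- res |>
    group_by(.data$config) |>
    summarise(f1_mean = mean(.data$f1, na.rm = TRUE),
              f1_sd = sd(.data$f1, na.rm = TRUE), .groups = "drop")
  list(f1 = res, tests = bind_rows(tests), grand = grand)
}

# --- learner-subset robustness ----------------------------------------------

#' Robustness over weak-learner subsets
#'
#' Re-aggregates a completed LOSO evaluation over subsets of the nine weak
#' learners: for every subset, the stacked meta-learner is refit per fold on
#' the stored inner meta-features restricted to the subset's probability
#' columns, and the held-out windows are re-scored. Learner training is
#' unchanged (weak learners are scope-independent), so this reproduces the
#' full-ensemble result exactly for the complete subset.
#'
#' @param eval_result An `ad_eval` run with the stacked aggregator.
#' @param min_size,max_size Subset size limits (default 4..9; 511 subsets at
#'   1..9).
#' @param meta_choose Candidate selection, as in [evaluate_loso()].
#' @return Tibble `weak_learners`, `size`, `accuracy`, `precision`, `recall`,
#'   `f1` (macro, mean over repeats), sorted by F1.
#' @export
subset_robustness <- function(eval_result, min_size = 4L, max_size = NULL,
                              meta_choose = NULL) {
  scopes <- eval_result$scopes
  max_size <- max_size %||% length(scopes)
  meta_choose <- meta_choose %||% eval_result$config$meta_choose
  subsets <- list()
  for (sz in seq(min_size, max_size)) {
    cmb <- combn(length(scopes), sz)
    for (j in seq_len(ncol(cmb))) subsets[[length(subsets) + 1]] <- cmb[, j]
  }
  rows <- purrr::map(subsets, function(ss) {
    cols <- paste0("proba.", scopes[ss])
    per_rep <- purrr::map(eval_result$fold_art, function(folds) {
      y_all <- integer(0); d_all <- integer(0)
      for (fa in folds) {
        if (is.null(fa$meta_x)) next
        meta <- suppressWarnings(
          train_stacked_meta(fa$meta_x[, cols, drop = FALSE], fa$meta_y, fa$meta_g,
                             choose = meta_choose, seed = fa$seed)
        )
        p <- predict(meta, fa$test_x[, cols, drop = FALSE])
        y_all <- c(y_all, fa$test_y)
        d_all <- c(d_all, as.integer(p >= 0.5))
      }
      classification_metrics(y_all, d_all)
    }) |> bind_rows()
    tibble(weak_learners = paste(scopes[ss], collapse = "+"), size = length(ss),
           accuracy = mean(per_rep$accuracy),
           precision = mean(per_rep$macro_precision),
           recall = mean(per_rep$macro_recall),
           f1 = mean(per_rep$macro_f1))
  })
  arrange(bind_rows(rows), dplyr::desc(.data$f1))
}

#' Prediction timeline matrix
#'
#' Matrix view of one repeat's held-out predictions: one column per window
#' (ordered by subject, then time), rows for each learner's probability, each
#' k-vote decision (k = 0..9), the stacked meta probability, and the ground
#' truth.
#'
#' @param eval_result An `ad_eval`.
#' @param which_repeat Repeat to export.
#' @return Numeric matrix with named rows; column order attribute
#'   `subject_id`.
#' @export
prediction_timeline <- function(eval_result, which_repeat = 1L) {
  d <- eval_result$predictions |>
    filter(.data$.repeat == which_repeat) |>
    arrange(.data$subject_id, .data$window_start_s)
  scopes <- eval_result$scopes
  rows <- list()
  for (sc in scopes) rows[[paste0("proba ", sc)]] <- d[[paste0("proba.", sc)]]
  for (kk in 0:length(scopes)) rows[[paste0("k=", kk)]] <- as.integer(d$vote_count >= kk)
  if ("meta_proba" %in% names(d)) rows[["stacked meta"]] <- d$meta_proba
  rows[["truth"]] <- d$label
  m <- do.call(rbind, rows)
  colnames(m) <- NULL
  attr(m, "subject_id") <- d$subject_id
  attr(m, "window_start_s") <- d$window_start_s
  m
}
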