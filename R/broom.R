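# Broom-style tidiers for the fitted objects.

#' Tidy a shadow-feature selection
#'
#' @param x An `ad_boruta`.
#' @param ... Unused.
#' @return The per-feature decision tibble.
#' @export
tidy.ad_boruta <- function(x, ...) x$decisions

#' @export
glance.ad_boruta <- function(x, ...) {
  tibble(n_features = nrow(x$decisions),
         n_accepted = sum(x$decisions$decision == "accepted"),
         n_rejected = sum(x$decisions$decision == "rejected"),
         n_iter = x$n_iter, alpha = x$alpha)
}

#' Tidy TreeSHAP importances
#'
#' @param x An `ad_shap`.
#' @param ... Unused.
#' @return The per-feature importance record tibble.
#' @export
tidy.ad_shap <- function(x, ...) x$records

#' @export
glance.ad_shap <- function(x, ...) {
  tibble(n_features = nrow(x$records), n_samples = x$n,
         n_degenerate = sum(x$records$degenerate),
         max_additivity_residual = x$additivity_residual)
}

#' Tidy the weak learners of an ensemble
#'
#' @param x An `ad_ensemble`.
#' @param ... Unused.
#' @return One row per learner: scope, availability, feature/training counts.
#' @export
tidy.ad_ensemble <- function(x, ...) {
  purrr::map(x$learners, function(l) {
    tibble(scope = l$scope, available = l$available,
           n_features = length(l$features),
           n_train = l$n_train %||% NA_integer_)
  }) |> bind_rows()
}

#' @export
glance.ad_ensemble <- function(x, ...) {
  av <- vapply(x$learners, function(l) l$available, TRUE)
  tibble(n_learners = length(x$learners), n_available = sum(av),
         n_trees = x$n_trees)
}

#' Tidy an evaluation
#'
#' @param x An `ad_eval`.
#' @param ... Unused.
#' @return Per-component metric summary (mean +/- sd over repeats).
#' @export
tidy.ad_eval <- function(x, ...) x$metrics

#' @export
glance.ad_eval <- function(x, ...) {
  m <- x$metrics
  meta <- m[m$component == "stacked_meta", ]
  kv <- m[m$component == paste0("kvote_", x$config$k), ]
  y <- x$predictions[x$predictions$.repeat == 1, ]
  tibble(
    n_subjects = length(x$subjects),
    n_windows = nrow(y),
    n_ad_windows = sum(y$label == 1),
    repeats = x$config$repeats,
    macro_f1_stacked = if (nrow(meta)) meta$macro_f1_mean else NA_real_,
    macro_f1_stacked_sd = if (nrow(meta)) meta$macro_f1_sd else NA_real_,
    macro_f1_kvote = if (nrow(kv)) kv$macro_f1_mean else NA_real_,
    dummy_macro_f1 = dummy_baseline(sum(y$label == 1), sum(y$label == 0))
  )
}
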