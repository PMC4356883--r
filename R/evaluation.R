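#' Mean absolute error in log10 units
#'
#' @param predicted,observed Equal-length numeric vectors; observed values
#'   must be complete.
#' @return Mean of `|predicted - observed|`.
#' @export
mae <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have equal length.")
  }
  if (!length(predicted)) abort("Cannot compute MAE of zero pairs.")
  if (anyNA(observed)) abort("`observed` must not contain missing values.")
  mean(abs(predicted - observed))
}

#' Geometric mean fold error from a log10 MAE
#'
#' `GMFE = 10^MAE`: a model with GMFE 2 makes Vss predictions that are on
#' average twofold off (100% above or 50% below the true value).
#'
#' @param mae_value A non-negative MAE in log10 units.
#' @return The fold error `10^mae_value`.
#' @export
gmfe <- function(mae_value) {
  if (any(mae_value < 0)) abort("MAE must be non-negative.")
  10^mae_value
}

#' The eight-method roster
#'
#' Named method specifications compared throughout: M5P model trees with
#' minimum leaf sizes 4, 6, 8 and 10; the M5P regression-tree variant; a
#' reduced-error-pruned tree; M5-Rules; and a bagging ensemble of 10 M5P
#' model trees. Each spec maps to tree/rule parameters; fit a spec with
#' [fit_method()].
#'
#' @return A named list of method specs.
#' @export
method_roster <- function() {
  mk <- function(kind, min_instances, learner = "tree", n_trees = NULL) {
    list(kind = kind, min_instances = min_instances, learner = learner,
         n_trees = n_trees)
  }
  list(
    "M5P-4"       = mk("model", 4L),
    "M5P-6"       = mk("model", 6L),
    "M5P-8"       = mk("model", 8L),
    "M5P-10"      = mk("model", 10L),
    "M5P-RegTree" = mk("regression", 4L),
    "REP-Tree"    = mk("rep", 4L),
    "M5-Rules"    = mk("regression", 4L, learner = "rules"),
    "Bagging-M5P" = mk("model", 4L, learner = "bagging", n_trees = 10L)
  )
}

#' Fit one roster method
#'
#' @param spec One element of [method_roster()].
#' @param data A [compound_table()] (or data frame).
#' @param target Name of the target column.
#' @param seed Seed for the method's stochastic parts (rep holdout,
#'   bootstrap).
#' @return A fitted model (`vss_tree`, `vss_ensemble` or `rule_set`).
#' @export
fit_method <- function(spec, data, target, seed = 1L) {
  params <- tree_params(spec$kind, min_instances = spec$min_instances,
                        seed = seed)
  switch(spec$learner,
         tree = fit_tree(data, target, params),
         rules = fit_m5rules(data, target, params),
         bagging = fit_bagging(data, target, params,
                               n_trees = spec$n_trees, seed = seed),
         abort("Unknown learner in method spec."))
}

#' k-fold cross-validation of a method
#'
#' Labeled compounds are shuffled under the seed and chunked into `n_folds`
#' near-equal contiguous folds (no stratification); each fold is scored by a
#' model fit on the other folds, and the per-fold MAEs are averaged. Rows
#' with a missing target never participate.
#'
#' @param data A [compound_table()] (or data frame).
#' @param target Name of the target column.
#' @param method A roster spec (see [method_roster()]) or a function
#'   `function(data, target, seed)` returning a model with a `predict`
#'   method.
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for fold assignment and per-fold fits.
#' @return A list with `fold_mae`, `mean_mae` and the fold assignment.
#' @export
cross_validate <- function(data, target, method, n_folds = 10L, seed = 1L) {
  labeled_idx <- which(!is.na(data[[target]]))
  n <- length(labeled_idx)
  if (n < n_folds) {
    abort(sprintf("Only %d labeled compounds for %d folds.", n, n_folds))
  }
  fold_of <- with_local_seed(seed, {
    shuffled <- sample(labeled_idx)
    sizes <- rep(n %/% n_folds, n_folds) +
      (seq_len(n_folds) <= n %% n_folds)
    setNames(rep(seq_len(n_folds), times = sizes), shuffled)
  })
  fit_fun <- if (is.function(method)) method else {
    function(d, t, s) fit_method(method, d, t, s)
  }
  fold_mae <- vapply(seq_len(n_folds), function(f) {
    test_rows <- as.integer(names(fold_of)[fold_of == f])
    train_rows <- setdiff(labeled_idx, test_rows)
    model <- fit_fun(data[train_rows, , drop = FALSE], target, seed + f)
    pred <- predict(model, data[test_rows, , drop = FALSE])
    mae(pred, data[[target]][test_rows])
  }, numeric(1))
  list(fold_mae = fold_mae, mean_mae = mean(fold_mae), folds = fold_of)
}

#' Pick the method with the lowest MAE
#'
#' Ties are resolved by position: the earlier entry (roster order) wins.
#'
#' @param results Named numeric vector of mean MAEs.
#' @return The winning method name.
#' @export
select_best <- function(results) {
  if (!length(results)) abort("No methods to select from.")
  names(results)[which.min(results)]
}

#' Cross-validate every roster method on one target
#'
#' @inheritParams cross_validate
#' @param roster A [method_roster()]-style named list.
#' @return A tibble with columns `method` and `cv_mae` in roster order.
#' @export
evaluate_roster <- function(data, target, roster = method_roster(),
                            n_folds = 10L, seed = 1L) {
  cv_mae <- vapply(roster, function(spec) {
    cross_validate(data, target, spec, n_folds = n_folds, seed = seed)$mean_mae
  }, numeric(1))
  tibble::tibble(method = names(roster), cv_mae = unname(cv_mae))
}

#' Paired comparison of two external prediction-error vectors
#'
#' A paired t-test on per-compound absolute errors of two models evaluated on
#' the same external compounds — a reporting utility, never part of model
#' selection.
#'
#' @param pred_a,pred_b Predictions (log10) from the two models.
#' @param observed Observed values (log10) for the same compounds.
#' @return A one-row tibble with the mean difference, confidence interval and
#'   p-value.
#' @export
compare_external_errors <- function(pred_a, pred_b, observed) {
  err_a <- abs(pred_a - observed)
  err_b <- abs(pred_b - observed)
  tt <- t.test(err_a, err_b, paired = TRUE)
  tibble::tibble(mean_difference = unname(tt$estimate),
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                 p_value = tt$p.value)
}
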