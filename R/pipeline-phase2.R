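#' Phase 2: log Vss models on three descriptor-set configurations
#'
#' Splits the Vss-target table into a model-selection set and an external
#' validation set, builds the configured descriptor set, cross-validates the
#' method roster on the model-selection set, selects the lowest-MAE method,
#' refits it on the full model-selection set and scores it on the external
#' set. The three modes are the pipeline's three descriptor-set
#' configurations:
#'
#' * `"with_ktp"` — molecular descriptors plus every usable tissue's
#'   predicted log Kt:p;
#' * `"descriptors_only"` — molecular descriptors only (the baseline);
#' * `"cfs_selected"` — genetic-search CFS run once on the model-selection
#'   set over descriptors plus predicted Kt:p, then the roster restricted to
#'   the selected subset.
#'
#' External compounds never touch fitting, feature selection or model
#' selection. The result also carries the external MAE of a global-mean
#' (intercept-only) predictor as a floor baseline.
#'
#' @param vss_table A [compound_table()] with a `logVss` target.
#' @param registry A `tissue_registry` from [run_phase1()] (required unless
#'   `mode = "descriptors_only"`).
#' @param mode Descriptor-set configuration (see above).
#' @param target Target column name (default `"logVss"`).
#' @param n_model_selection,n_external Holdout split sizes (defaults 402 and
#'   202; scaled automatically when the table is smaller, preserving the
#'   402:202 ratio).
#' @param split_seed Seed of the holdout partition.
#' @param n_folds,cv_seed Cross-validation setup on the model-selection set.
#' @param cfs A [cfs_config()] (mode `"cfs_selected"` only).
#' @param roster A [method_roster()]-style named list.
#' @return A `vss_phase2` object: CV report, selected model, external MAE and
#'   GMFE, per-compound external predictions and the selected descriptors.
#' @export
run_phase2 <- function(vss_table, registry = NULL,
                       mode = c("with_ktp", "descriptors_only", "cfs_selected"),
                       target = "logVss",
                       n_model_selection = NULL, n_external = NULL,
                       split_seed = 1L, n_folds = 10L, cv_seed = 1L,
                       cfs = cfs_config(), roster = method_roster()) {
  mode <- match.arg(mode)
  n <- nrow(vss_table)
  if (is.null(n_model_selection)) {
    n_model_selection <- if (n == 604L) 402L else round(n * 402 / 604)
  }
  if (is.null(n_external)) n_external <- n - n_model_selection

  merged <- if (mode == "descriptors_only") {
    vss_table
  } else {
    if (is.null(registry)) {
      abort("`registry` is required unless mode = 'descriptors_only'.")
    }
    merge_predicted_ktp(vss_table, predict_ktp(registry, vss_table))
  }

  parts <- split_holdout(merged, n_model_selection, n_external, split_seed)
  model_sel <- parts$model_selection
  external <- parts$external

  selected <- NULL
  if (mode == "cfs_selected") {
    search <- ga_search(model_sel, target, cfs)
    selected <- search$names
    if (!length(selected)) abort("CFS selected an empty descriptor subset.")
    keep <- c("compound_id", selected, target)
    model_sel <- model_sel[, intersect(names(model_sel), keep), drop = FALSE]
    external <- external[, intersect(names(external), keep), drop = FALSE]
  }

  report <- evaluate_roster(model_sel, target, roster, n_folds, cv_seed)
  best <- select_best(setNames(report$cv_mae, report$method))
  model <- fit_method(roster[[best]], model_sel, target, cv_seed)

  pred_ext <- predict(model, external)
  obs_ext <- external[[target]]
  external_mae <- mae(pred_ext, obs_ext)
  baseline_mae <- mae(rep(mean(model_sel[[target]], na.rm = TRUE),
                          length(obs_ext)), obs_ext)

  structure(list(
    mode = mode, target = target,
    report = report, best_method = best, model = model,
    external_mae = external_mae, external_gmfe = gmfe(external_mae),
    baseline_external_mae = baseline_mae,
    selected_descriptors = selected,
    external_predictions = tibble::tibble(
      compound_id = external$compound_id,
      observed = obs_ext, predicted = pred_ext),
    n_model_selection = nrow(model_sel), n_external = nrow(external),
    split_seed = split_seed, cv_seed = cv_seed,
    model_selection_ids = model_sel$compound_id),
    class = "vss_phase2")
}

#' @export
print.vss_phase2 <- function(x, ...) {
  cat(sprintf("<vss_phase2: mode '%s', best method %s>\n", x$mode, x$best_method))
  cat(sprintf("  external MAE %.4f (log10), GMFE %.2f over %d compounds\n",
              x$external_mae, x$external_gmfe, x$n_external))
  invisible(x)
}
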