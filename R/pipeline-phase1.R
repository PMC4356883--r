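#' Phase 1: per-tissue log Kt:p models
#'
#' For every tissue target with enough labeled compounds, cross-validates the
#' whole method roster (molecular descriptors only — no other tissue's Kt:p
#' is ever a descriptor), selects the method with the lowest mean CV MAE, and
#' refits the winner on all labeled compounds. Tissues with fewer than
#' `min_labeled` labeled compounds are excluded with reason
#' `"too_few_labeled"` (the pancreas-style case); tissues whose refit winner
#' is a degenerate single-leaf model are excluded with reason
#' `"degenerate_model"` (the intestine-style case).
#'
#' @param ktp_table A [compound_table()] with `logKtp_*` target columns.
#' @param roster A [method_roster()]-style named list.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Seed for fold assignment and fits.
#' @param min_labeled Minimum labeled compounds to attempt a model
#'   (default 10).
#' @return A `tissue_registry`: per-tissue winner, CV MAE, fitted model and
#'   exclusion status, plus the full tissue-by-method CV grid.
#' @export
run_phase1 <- function(ktp_table, roster = method_roster(), n_folds = 10L,
                       seed = 1L, min_labeled = 10L) {
  targets <- target_names(ktp_table)
  if (!length(targets)) abort("The table has no target columns.")
  rows <- list()
  models <- list()
  grid <- list()
  for (target in targets) {
    tissue <- sub("^logKtp_", "", target)
    n_labeled <- sum(!is.na(ktp_table[[target]]))
    if (n_labeled < max(min_labeled, n_folds)) {
      rows[[tissue]] <- tibble::tibble(
        tissue = tissue, target = target, n_labeled = n_labeled,
        best_method = NA_character_, cv_mae = NA_real_,
        excluded = TRUE, reason = "too_few_labeled")
      next
    }
    report <- evaluate_roster(ktp_table, target, roster, n_folds, seed)
    best <- select_best(setNames(report$cv_mae, report$method))
    model <- fit_method(roster[[best]], ktp_table, target, seed)
    degenerate <- is_degenerate(model)
    rows[[tissue]] <- tibble::tibble(
      tissue = tissue, target = target, n_labeled = n_labeled,
      best_method = best,
      cv_mae = report$cv_mae[report$method == best],
      excluded = degenerate,
      reason = if (degenerate) "degenerate_model" else NA_character_)
    if (!degenerate) models[[tissue]] <- model
    grid[[tissue]] <- dplyr::mutate(report, tissue = tissue, .before = 1)
  }
  tissues <- dplyr::bind_rows(rows)
  if (!any(!tissues$excluded)) {
    abort("No tissue could be modeled (all excluded).")
  }
  structure(list(tissues = tissues, models = models,
                 cv_grid = dplyr::bind_rows(grid),
                 roster_names = names(roster)),
            class = "tissue_registry")
}

#' Usable tissues of a registry
#'
#' @param registry A `tissue_registry`.
#' @return Character vector of non-excluded tissue names.
#' @export
usable_tissues <- function(registry) {
  registry$tissues$tissue[!registry$tissues$excluded]
}

#' Predict log Kt:p descriptors for new compounds
#'
#' Applies every usable tissue model of a phase-1 registry to a compound
#' table, returning one `pred_logKtp_<tissue>` column per usable tissue,
#' ready for [merge_predicted_ktp()].
#'
#' @param registry A `tissue_registry` from [run_phase1()].
#' @param table A [compound_table()] with the molecular descriptor columns.
#' @return A tibble of predicted log Kt:p columns.
#' @export
predict_ktp <- function(registry, table) {
  tissues <- usable_tissues(registry)
  if (!length(tissues)) abort("The registry has no usable tissue models.")
  cols <- lapply(tissues, function(tissue) {
    predict(registry$models[[tissue]], table)
  })
  names(cols) <- paste0("pred_logKtp_", tissues)
  tibble::as_tibble(cols)
}

#' @export
print.tissue_registry <- function(x, ...) {
  n_usable <- sum(!x$tissues$excluded)
  cat(sprintf("<tissue_registry: %d usable tissue models of %d targets>\n",
              n_usable, nrow(x$tissues)))
  print(x$tissues)
  invisible(x)
}
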