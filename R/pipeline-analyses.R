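#' Sensitivity of Vss prediction to noise on a predicted Kt:p descriptor
#'
#' For each repeat, every compound's value of `target_descriptor` in the
#' entire merged Vss-target table (model-selection and external compounds
#' alike) is replaced by `v * (1 +/- noise_fraction)`, the sign chosen at
#' random per compound; the bagging model-tree learner is then refit on the
#' model-selection set and its external GMFE measured, along with the
#' perturbed descriptor's root frequency in the ensemble. The unperturbed
#' run is computed once as the reference.
#'
#' @param vss_table A [compound_table()] with a `logVss` target.
#' @param registry A `tissue_registry` supplying the predicted Kt:p columns.
#' @param target_descriptor Name of the perturbed descriptor (default: the
#'   predicted adipose log Kt:p).
#' @param noise_fraction Relative perturbation (default 0.10).
#' @param seeds One seed per repeat (default `1:5`).
#' @param target Target column name.
#' @param n_model_selection,n_external,split_seed Holdout split (see
#'   [run_phase2()]).
#' @param params A [tree_params()] for the bagged members.
#' @param n_trees Ensemble size (default 10).
#' @param features Optional restriction of the feature columns (e.g. a
#'   CFS-selected subset); the perturbed descriptor must be included.
#' @return A `sensitivity_result`: per-repeat tibble (external MAE, GMFE,
#'   root frequency), the mean GMFE over repeats and the unperturbed
#'   reference.
#' @export
sensitivity_analysis <- function(vss_table, registry,
                                 target_descriptor = "pred_logKtp_adipose",
                                 noise_fraction = 0.10, seeds = 1:5,
                                 target = "logVss",
                                 n_model_selection = NULL, n_external = NULL,
                                 split_seed = 1L,
                                 params = tree_params("model"),
                                 n_trees = 10L, features = NULL) {
  if (noise_fraction < 0) abort("`noise_fraction` must be non-negative.")
  merged <- merge_predicted_ktp(vss_table, predict_ktp(registry, vss_table))
  if (!target_descriptor %in% names(merged)) {
    abort(sprintf("Descriptor '%s' not found in the merged table.",
                  target_descriptor))
  }
  if (!is.null(features)) {
    keep <- c("compound_id", union(features, target_descriptor), target)
    merged <- merged[, intersect(names(merged), keep), drop = FALSE]
  }
  n <- nrow(merged)
  if (is.null(n_model_selection)) {
    n_model_selection <- if (n == 604L) 402L else round(n * 402 / 604)
  }
  if (is.null(n_external)) n_external <- n - n_model_selection

  # the ensemble seed is held fixed across repeats: only the perturbation
  # varies, as in the repeated-noise design this implements
  run_once <- function(table) {
    parts <- split_holdout(table, n_model_selection, n_external, split_seed)
    ens <- fit_bagging(parts$model_selection, target, params,
                       n_trees = n_trees, seed = split_seed)
    pred <- predict(ens, parts$external)
    m <- mae(pred, parts$external[[target]])
    freq <- count_root_frequency(ens, target_descriptor)
    tibble::tibble(external_mae = m, external_gmfe = gmfe(m),
                   root_count = freq$root_count,
                   child_of_root_count = freq$child_of_root_count)
  }

  reference <- run_once(merged)
  repeats <- purrr::map_dfr(seeds, function(s) {
    perturbed <- merged
    perturbed[[target_descriptor]] <-
      perturb_descriptor(perturbed[[target_descriptor]], noise_fraction, s)
    dplyr::mutate(run_once(perturbed), seed = s, .before = 1)
  })

  structure(list(repeats = repeats,
                 mean_gmfe = mean(repeats$external_gmfe),
                 mean_root_count = mean(repeats$root_count),
                 unperturbed = reference,
                 target_descriptor = target_descriptor,
                 noise_fraction = noise_fraction),
            class = "sensitivity_result")
}

#' Apply the +/- fractional perturbation to a descriptor column
#'
#' Each value `v` becomes `v * (1 + noise_fraction)` or
#' `v * (1 - noise_fraction)`, the sign drawn independently per compound
#' under the seed; a positive value keeps its sign for any fraction < 1.
#'
#' @param values Numeric descriptor column.
#' @param noise_fraction Relative perturbation (e.g. 0.10).
#' @param seed Seed for the sign draws.
#' @return The perturbed column.
#' @export
perturb_descriptor <- function(values, noise_fraction, seed) {
  signs <- with_local_seed(seed, sample(c(-1, 1), length(values),
                                        replace = TRUE))
  values * (1 + signs * noise_fraction)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_result: %s +/- %.0f%% noise, %d repeats>\n",
    x$target_descriptor, 100 * x$noise_fraction, nrow(x$repeats)))
  cat(sprintf("  mean perturbed GMFE %.3f vs unperturbed %.3f; mean root frequency %.1f/%d\n",
              x$mean_gmfe, x$unperturbed$external_gmfe, x$mean_root_count,
              max(x$repeats$root_count, x$unperturbed$root_count)))
  invisible(x)
}

#' Descriptor-range applicability domain
#'
#' A test compound is outside the applicability domain when at least one of
#' the named descriptors falls below the training minimum or above the
#' training maximum; missing values never trigger. This is the range-based
#' check used on the Vss external set against the Kt:p training data, over
#' the descriptor set of the adipose Kt:p model.
#'
#' @param train_table Training [compound_table()] defining the ranges.
#' @param test_table Test [compound_table()] to classify.
#' @param descriptors Descriptor names present in both tables.
#' @return An `ad_report`: per-compound inside flag with offending
#'   descriptors, and the outside count and fraction.
#' @export
applicability_domain <- function(train_table, test_table, descriptors) {
  if (!length(descriptors)) abort("`descriptors` must be non-empty.")
  for (tab in list(train = train_table, test = test_table)) {
    absent <- setdiff(descriptors, names(tab))
    if (length(absent)) {
      abort(paste0("Descriptors absent from a table: ",
                   paste(absent, collapse = ", ")))
    }
  }
  ranges <- purrr::map_dfr(descriptors, function(d) {
    v <- train_table[[d]]
    tibble::tibble(descriptor = d,
                   train_min = min(v, na.rm = TRUE),
                   train_max = max(v, na.rm = TRUE))
  })
  offending <- lapply(seq_len(nrow(test_table)), function(i) {
    vals <- vapply(descriptors, function(d) test_table[[d]][i], numeric(1))
    out <- !is.na(vals) &
      (vals < ranges$train_min | vals > ranges$train_max)
    descriptors[out]
  })
  compounds <- tibble::tibble(
    compound_id = test_table$compound_id,
    inside = lengths(offending) == 0L,
    offending = offending)
  n_outside <- sum(!compounds$inside)
  structure(list(compounds = compounds, ranges = ranges,
                 n_outside = n_outside, n_total = nrow(compounds),
                 fraction_outside = n_outside / nrow(compounds)),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report: %d of %d compounds (%.1f%%) outside the descriptor ranges>\n",
              x$n_outside, x$n_total, 100 * x$fraction_outside))
  invisible(x)
}

#' Descriptor importance in a bagged ensemble
#'
#' For every descriptor splitting any member, counts the members where it is
#' the root split and the members where it splits a direct child of the
#' root; descriptors with a combined count below 2 are dropped (a single
#' occurrence may be a stochastic effect of the bootstrap), and rows are
#' sorted by root count then child count, descending.
#'
#' @param ensemble A fitted `vss_ensemble`.
#' @return A tibble with `descriptor`, `root_count`, `child_of_root_count`.
#' @export
descriptor_importance <- function(ensemble) {
  descriptors <- unique(unlist(lapply(ensemble$members, function(m) {
    tree_split_descriptors(m$root)
  })))
  rows <- purrr::map_dfr(descriptors, function(d) {
    freq <- count_root_frequency(ensemble, d)
    tibble::tibble(descriptor = d, root_count = freq$root_count,
                   child_of_root_count = freq$child_of_root_count)
  })
  if (!nrow(rows)) {
    return(tibble::tibble(descriptor = character(), root_count = integer(),
                          child_of_root_count = integer()))
  }
  rows <- rows[rows$root_count + rows$child_of_root_count >= 2L, , drop = FALSE]
  dplyr::arrange(rows, dplyr::desc(.data$root_count),
                 dplyr::desc(.data$child_of_root_count))
}
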