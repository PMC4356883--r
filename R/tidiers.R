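#' Tidy a fitted tree into a node table
#'
#' @param x A `vss_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: depth, type, split descriptor and
#'   threshold (splits), prediction and linear-model term count (leaves), and
#'   training size.
#' @method tidy vss_tree
#' @export
tidy.vss_tree <- function(x, ...) {
  rows <- list()
  walk <- function(node, depth) {
    if (node$type == "leaf") {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        depth = depth, type = "leaf", descriptor = NA_character_,
        threshold = NA_real_, prediction = node$prediction,
        n_terms = length(node$model$coefficients), n_train = node$n_train)
    } else {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        depth = depth, type = "split", descriptor = node$descriptor,
        threshold = node$threshold, prediction = NA_real_,
        n_terms = 0L, n_train = node$n_train)
      walk(node$left, depth + 1L)
      walk(node$right, depth + 1L)
    }
  }
  walk(x$root, 0L)
  dplyr::bind_rows(rows)
}

#' @method glance vss_tree
#' @export
glance.vss_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble::tibble(kind = x$kind, n_nodes = nrow(nodes),
                 n_leaves = sum(nodes$type == "leaf"),
                 depth = max(nodes$depth), n_train = x$n_train,
                 target = x$target)
}

#' @method tidy vss_ensemble
#' @export
tidy.vss_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(b) {
    dplyr::mutate(glance(x$members[[b]]), member = b, .before = 1)
  })
}

#' @method glance vss_ensemble
#' @export
glance.vss_ensemble <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, kind = x$params$tree_kind,
                 target = x$target,
                 mean_leaves = mean(tidy(x)$n_leaves))
}

#' Tidy a rule set into one row per rule
#'
#' @param x A `rule_set`.
#' @param ... Unused.
#' @return A tibble with the rule index, a readable antecedent, the log10
#'   prediction, the linear-scale Vss (L/kg) and the coverage.
#' @method tidy rule_set
#' @export
tidy.rule_set <- function(x, ...) {
  purrr::map_dfr(seq_along(x$rules), function(i) {
    r <- x$rules[[i]]
    antecedent <- if (nrow(r$conditions) == 0) "TRUE" else {
      paste(sprintf("%s %s %.4g", r$conditions$descriptor,
                    r$conditions$relation, r$conditions$threshold),
            collapse = " and ")
    }
    tibble::tibble(rule = i, antecedent = antecedent,
                   prediction_log = r$prediction_log,
                   vss = rule_vss(r$prediction_log),
                   coverage = as.integer(r$coverage))
  })
}

#' @method glance rule_set
#' @export
glance.rule_set <- function(x, ...) {
  tibble::tibble(n_rules = length(x$rules), mode = x$mode,
                 has_default = !is.null(x$default_prediction))
}

#' @method tidy tissue_registry
#' @export
tidy.tissue_registry <- function(x, ...) {
  x$tissues
}

#' @method glance tissue_registry
#' @export
glance.tissue_registry <- function(x, ...) {
  tibble::tibble(n_targets = nrow(x$tissues),
                 n_usable = sum(!x$tissues$excluded),
                 n_excluded = sum(x$tissues$excluded))
}

#' @method tidy vss_phase2
#' @export
tidy.vss_phase2 <- function(x, ...) {
  x$report
}

#' @method glance vss_phase2
#' @export
glance.vss_phase2 <- function(x, ...) {
  tibble::tibble(mode = x$mode, best_method = x$best_method,
                 external_mae = x$external_mae,
                 external_gmfe = x$external_gmfe,
                 baseline_external_mae = x$baseline_external_mae,
                 n_model_selection = x$n_model_selection,
                 n_external = x$n_external)
}

#' @method tidy ad_report
#' @export
tidy.ad_report <- function(x, ...) {
  dplyr::mutate(x$compounds,
                offending = vapply(.data$offending, paste,
                                   character(1), collapse = ";"))
}

#' @method glance ad_report
#' @export
glance.ad_report <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_outside = x$n_outside,
                 fraction_outside = x$fraction_outside)
}

#' @method tidy sensitivity_result
#' @export
tidy.sensitivity_result <- function(x, ...) {
  x$repeats
}

#' @method glance sensitivity_result
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::tibble(target_descriptor = x$target_descriptor,
                 noise_fraction = x$noise_fraction,
                 n_repeats = nrow(x$repeats),
                 mean_gmfe = x$mean_gmfe,
                 unperturbed_gmfe = x$unperturbed$external_gmfe,
                 mean_root_count = x$mean_root_count)
}
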