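#' Fit a bagging ensemble of trees
#'
#' Draws `n_trees` bootstrap resamples (with replacement, same size as the
#' labeled training set) and fits one tree per resample; the ensemble
#' prediction is the arithmetic mean of the member predictions. With
#' `resample = FALSE` every member is fit on the full training set (the
#' identity-resample switch, mainly for testing the averaging contract).
#'
#' @param data A [compound_table()] (or data frame).
#' @param target Name of the target column.
#' @param params A [tree_params()] shared by all members (the default mirrors
#'   the bagged M5 model trees of the method roster).
#' @param n_trees Number of members (default 10).
#' @param seed Seed for the bootstrap draws.
#' @param resample Draw bootstrap samples (`TRUE`) or reuse the full training
#'   set for every member (`FALSE`).
#' @return A fitted `vss_ensemble`.
#' @export
fit_bagging <- function(data, target, params = tree_params("model"),
                        n_trees = 10L, seed = params$seed, resample = TRUE) {
  if (!target %in% names(data)) {
    abort(sprintf("Target column '%s' not found.", target))
  }
  labeled <- data[!is.na(data[[target]]), , drop = FALSE]
  if (inherits(data, "compound_table")) {
    labeled <- new_compound_table(labeled, col_roles(data))
  }
  n <- nrow(labeled)
  if (n == 0L) abort(sprintf("No labeled compounds for target '%s'.", target))
  members <- with_local_seed(seed, {
    lapply(seq_len(n_trees), function(b) {
      idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
      member_params <- params
      member_params$seed <- params$seed + b  # rep-kind internal holdouts differ
      fit_tree(labeled[idx, , drop = FALSE], target, member_params)
    })
  })
  structure(list(members = members, n_trees = as.integer(n_trees),
                 seed = as.integer(seed), params = params, target = target),
            class = "vss_ensemble")
}

#' @export
predict.vss_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  if (nrow(newdata) == 1L) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Root and child-of-root frequency of a descriptor in an ensemble
#'
#' Counts the members whose root split uses `descriptor`, and the members in
#' which a direct child of the root splits on it — the importance summary
#' used for bagged model trees, where the root carries the most relevant
#' descriptor. Single-leaf members contribute to neither count.
#'
#' @param ensemble A fitted `vss_ensemble`.
#' @param descriptor Descriptor name.
#' @return A list with integer `root_count` and `child_of_root_count`.
#' @export
count_root_frequency <- function(ensemble, descriptor) {
  root_count <- 0L
  child_count <- 0L
  for (m in ensemble$members) {
    root <- m$root
    if (root$type != "split") next
    if (root$descriptor == descriptor) root_count <- root_count + 1L
    kids <- list(root$left, root$right)
    if (any(vapply(kids, function(k) {
      k$type == "split" && k$descriptor == descriptor
    }, logical(1)))) {
      child_count <- child_count + 1L
    }
  }
  list(root_count = root_count, child_of_root_count = child_count)
}

#' @export
print.vss_ensemble <- function(x, ...) {
  cat(sprintf("<vss_ensemble: %d bagged %s trees, target '%s'>\n",
              x$n_trees, x$params$tree_kind, x$target))
  invisible(x)
}
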