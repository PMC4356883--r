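#' Tree learner parameters
#'
#' @param tree_kind `"model"` (M5-style model tree with multivariate linear
#'   leaf models), `"regression"` (constant leaves, the mean of the leaf's
#'   training targets) or `"rep"` (regression tree grown on 2/3 of the data
#'   and reduced-error-pruned on the remaining 1/3).
#' @param min_instances Minimum number of compounds allowed at a leaf (the
#'   M5 `minNumInstances` parameter; 4, 6, 8 and 10 are the roster values).
#' @param variance_stop_fraction Stop splitting a node whose target standard
#'   deviation falls below this fraction of the root standard deviation.
#' @param use_smoothing Blend leaf predictions with ancestor node means using
#'   the standard `(n * p + k * q) / (n + k)` form with `k = 15`. Off by
#'   default; predictions never depend on it unless switched on.
#' @param prune Reduced-error pruning switch (only the `"rep"` kind prunes).
#' @param seed Seed for the rep-pruning internal holdout.
#' @return A `tree_params` list.
#' @export
tree_params <- function(tree_kind = c("model", "regression", "rep"),
                        min_instances = 4L, variance_stop_fraction = 0.05,
                        use_smoothing = FALSE, prune = TRUE, seed = 1L) {
  tree_kind <- match.arg(tree_kind)
  stopifnot(min_instances >= 2,
            variance_stop_fraction > 0, variance_stop_fraction < 1)
  structure(list(tree_kind = tree_kind,
                 min_instances = as.integer(min_instances),
                 variance_stop_fraction = variance_stop_fraction,
                 use_smoothing = isTRUE(use_smoothing),
                 prune = isTRUE(prune),
                 seed = as.integer(seed)),
            class = "tree_params")
}

#' Best single-descriptor split by standard-deviation reduction
#'
#' Scans the midpoints between consecutive distinct sorted values of
#' `values`; the score of a candidate threshold is the parent (population)
#' standard deviation minus the size-weighted mean of the child standard
#' deviations. Both children must hold at least `min_instances` rows. Missing
#' descriptor values are imputed with the mean of the non-missing values.
#'
#' @param values Numeric descriptor column.
#' @param targets Numeric target column of the same length.
#' @param min_instances Minimum rows on each side of the split.
#' @return A list with `threshold` and `score`, or `NULL` when no admissible
#'   split improves on the parent (e.g. constant targets).
#' @export
best_split <- function(values, targets, min_instances = 4L) {
  if (length(values) != length(targets)) {
    abort("`values` and `targets` must have equal length.")
  }
  if (all(is.na(targets))) abort("All target values are missing.")
  res <- scan_best_split_cpp(matrix(values, ncol = 1), as.numeric(targets),
                             as.integer(min_instances))
  if (res$col == 0L) return(NULL)
  list(threshold = res$threshold, score = res$score)
}

#' Fit a regression, model or reduced-error-pruned tree
#'
#' Recursively partitions the labeled compounds, at each node choosing the
#' (descriptor, threshold) pair with the largest standard-deviation reduction
#' over all feature columns. Growth stops when a node holds fewer than
#' `2 * min_instances` compounds, when its target standard deviation falls
#' below `variance_stop_fraction` of the root standard deviation, or when no
#' split has positive score. Rows with a missing target are dropped before
#' fitting; missing descriptor cells are imputed with the current node's
#' column mean at fit time and with the stored training column means at
#' predict time. Degenerate data (e.g. a constant target) yields a
#' single-leaf tree.
#'
#' Model trees fit a multivariate linear model at each leaf over the
#' descriptors used by splits on the root-to-leaf path or in the subtree
#' containing the leaf, then greedily drop
#' terms while the estimated error `MAE * (n + v) / (n - v)` (v = number of
#' terms) improves; the linear model is kept only when it beats the constant
#' leaf on that estimate. With `prune = TRUE` (the default) model trees are
#' additionally pruned bottom-up, collapsing any subtree whose node-level
#' model has an estimated error no worse than the size-weighted estimate of
#' its children. The `"rep"` kind grows a regression tree on a
#' seeded 2/3 subset and collapses any subtree whose held-out 1/3 absolute
#' error does not beat the collapsed leaf.
#'
#' @param data A [compound_table()] (or plain data frame whose non-target
#'   numeric columns are all treated as features).
#' @param target Name of the target column.
#' @param params A [tree_params()].
#' @return A fitted `vss_tree`.
#' @export
fit_tree <- function(data, target, params = tree_params()) {
  prep <- prepare_training(data, target)
  if (params$tree_kind == "rep") {
    fit_rep_tree(prep, params)
  } else {
    root <- grow_node(prep$X, prep$y, seq_len(nrow(prep$X)), integer(0),
                      params, pop_sd(prep$y))
    if (params$tree_kind == "model" && params$prune) {
      root <- prune_model_tree(root, prep$X, prep$y)
    }
    root <- strip_grow_state(root)
    new_vss_tree(root, prep, params)
  }
}

prepare_training <- function(data, target) {
  if (!target %in% names(data)) {
    abort(sprintf("Target column '%s' not found.", target))
  }
  feats <- if (inherits(data, "compound_table")) {
    feature_names(data)
  } else {
    setdiff(names(data)[vapply(data, is.numeric, logical(1))], target)
  }
  keep <- !is.na(data[[target]])
  if (!any(keep)) abort(sprintf("No labeled compounds for target '%s'.", target))
  X <- as.matrix(as.data.frame(data[keep, feats, drop = FALSE],
                               check.names = FALSE))
  list(X = X, y = as.numeric(data[[target]][keep]), target = target,
       features = feats,
       column_means = colMeans(X, na.rm = TRUE))
}

new_vss_tree <- function(root, prep, params) {
  structure(list(root = root, kind = params$tree_kind, params = params,
                 target = prep$target, features = prep$features,
                 column_means = prep$column_means,
                 n_train = length(prep$y), root_sd = pop_sd(prep$y),
                 y_range = range(prep$y)),
            class = "vss_tree")
}

grow_node <- function(X, y, idx, path_cols, params, root_sd) {
  yy <- y[idx]
  nd <- length(idx)
  if (nd < 2 * params$min_instances ||
      pop_sd(yy) < params$variance_stop_fraction * root_sd) {
    return(make_leaf(X, yy, idx, path_cols, params))
  }
  sp <- scan_best_split_cpp(X[idx, , drop = FALSE], yy, params$min_instances)
  if (sp$col == 0L) {
    return(make_leaf(X, yy, idx, path_cols, params))
  }
  xval <- X[idx, sp$col]
  if (anyNA(xval)) xval[is.na(xval)] <- mean(xval, na.rm = TRUE)
  go_left <- xval <= sp$threshold
  list(type = "split",
       descriptor = colnames(X)[sp$col],
       threshold = sp$threshold,
       n_train = nd,
       mean = mean(yy),
       .idx = idx, .path = path_cols, .col = sp$col,
       left = grow_node(X, y, idx[go_left], c(path_cols, sp$col), params, root_sd),
       right = grow_node(X, y, idx[!go_left], c(path_cols, sp$col), params, root_sd))
}

make_leaf <- function(X, yy, idx, path_cols, params) {
  leaf <- list(type = "leaf", prediction = mean(yy), n_train = length(yy),
               model = NULL, .est = mean(abs(yy - mean(yy))))
  if (params$tree_kind == "model" && length(path_cols)) {
    fit <- fit_leaf_model(X[idx, , drop = FALSE], yy, unique(path_cols))
    leaf$model <- fit$model
    leaf$.est <- fit$est
  }
  leaf
}

# Structural pruning of model trees (canonical M5): bottom-up, a subtree is
# collapsed to a leaf carrying the node's own linear model whenever the
# node-level estimated error mae * (n + v) / (n - v) does not exceed the
# size-weighted estimated error of its children. This is what keeps small
# leaf models from extrapolating wildly on new compounds.
prune_model_tree <- function(node, X, y) {
  if (node$type == "leaf") return(node)
  node$left <- prune_model_tree(node$left, X, y)
  node$right <- prune_model_tree(node$right, X, y)
  nl <- node$left$n_train
  nr <- node$right$n_train
  subtree_est <- (nl * node$left$.est + nr * node$right$.est) / (nl + nr)
  yy <- y[node$.idx]
  allowed <- unique(c(node$.path, subtree_cols(node)))
  cand <- fit_leaf_model(X[node$.idx, , drop = FALSE], yy, allowed)
  if (cand$est <= subtree_est) {
    return(list(type = "leaf", prediction = mean(yy), n_train = node$n_train,
                model = cand$model, .est = cand$est))
  }
  node$.est <- subtree_est
  node
}

# Split-column indices tested anywhere in the subtree rooted at `node`
# (the descriptors an interior-node linear model may use, per the M5
# convention, together with the path descriptors).
subtree_cols <- function(node) {
  if (node$type == "leaf") return(integer(0))
  c(node$.col, subtree_cols(node$left), subtree_cols(node$right))
}

strip_grow_state <- function(node) {
  node$.idx <- NULL
  node$.path <- NULL
  node$.est <- NULL
  node$.col <- NULL
  if (node$type == "split") {
    node$left <- strip_grow_state(node$left)
    node$right <- strip_grow_state(node$right)
  }
  node
}

# Leaf linear model with greedy backward elimination under the M5 error
# estimate mae * (n + v) / (n - v); `model` is NULL when the constant leaf
# wins, and `est` is the estimated error of whichever candidate won.
fit_leaf_model <- function(Xn, yy, cols) {
  n <- length(yy)
  const_err <- mean(abs(yy - mean(yy)))  # v = 0 candidate
  constant <- list(model = NULL, est = const_err)
  Xs <- Xn[, cols, drop = FALSE]
  for (j in seq_len(ncol(Xs))) {
    cj <- Xs[, j]
    if (anyNA(cj)) {
      m <- mean(cj, na.rm = TRUE)
      Xs[is.na(cj), j] <- if (is.nan(m)) 0 else m
    }
  }
  usable <- apply(Xs, 2, function(v) stats::var(v) > 0)
  Xs <- Xs[, usable, drop = FALSE]
  if (ncol(Xs) == 0L) return(constant)

  est <- function(active) {
    v <- length(active)
    if (v == 0L) return(list(err = const_err, fit = NULL))
    if (n - v <= 1L) return(list(err = Inf, fit = NULL))
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs[, active, drop = FALSE]), yy)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    mae_tr <- mean(abs(fit$residuals))
    list(err = mae_tr * (n + v) / (n - v), fit = cf)
  }

  active <- colnames(Xs)
  # numerical stability: never let a node model approach interpolation —
  # at most one term per three training compounds before refinement
  max_terms <- max(1L, n %/% 3L)
  while (length(active) > max_terms) {
    trials <- lapply(seq_along(active), function(i) est(active[-i]))
    errs <- vapply(trials, `[[`, numeric(1), "err")
    best_i <- which.min(errs)
    active <- active[-best_i]
  }
  cur <- est(active)
  repeat {
    if (!length(active)) break
    trials <- lapply(seq_along(active), function(i) est(active[-i]))
    errs <- vapply(trials, `[[`, numeric(1), "err")
    best_i <- which.min(errs)
    if (errs[best_i] < cur$err) {
      active <- active[-best_i]
      cur <- trials[[best_i]]
    } else break
  }
  if (!length(active) || is.null(cur$fit) || cur$err >= const_err) {
    return(constant)
  }
  list(model = list(intercept = unname(cur$fit["(Intercept)"]),
                    coefficients = as.list(cur$fit[setdiff(names(cur$fit),
                                                           "(Intercept)")])),
       est = cur$err)
}

fit_rep_tree <- function(prep, params) {
  n <- nrow(prep$X)
  grow_idx <- with_local_seed(params$seed, {
    prune_n <- max(1L, floor(n / 3))
    sort(sample.int(n, n - prune_n))
  })
  prune_idx <- setdiff(seq_len(n), grow_idx)
  grow_params <- params
  grow_params$tree_kind <- "regression"
  root <- grow_node(prep$X, prep$y, grow_idx, integer(0), grow_params,
                    pop_sd(prep$y[grow_idx]))
  if (params$prune && length(prune_idx)) {
    root <- rep_prune(root, prep$X, prep$y, prune_idx, prep$column_means)
  }
  root <- strip_grow_state(root)
  tree <- new_vss_tree(root, prep, params)
  tree$kind <- "rep"
  tree
}

# Reduced-error pruning: bottom-up, collapse a subtree to a leaf (predicting
# the grow-set node mean) whenever the pruning-set absolute error does not get
# worse; nodes reached by no pruning rows are collapsed.
rep_prune <- function(node, X, y, idx, column_means) {
  if (node$type == "leaf") return(node)
  xval <- X[idx, node$descriptor]
  xval[is.na(xval)] <- column_means[[node$descriptor]]
  left_idx <- idx[xval <= node$threshold]
  right_idx <- idx[xval > node$threshold]
  node$left <- rep_prune(node$left, X, y, left_idx, column_means)
  node$right <- rep_prune(node$right, X, y, right_idx, column_means)
  as_leaf <- list(type = "leaf", prediction = node$mean,
                  n_train = node$n_train, model = NULL)
  if (!length(idx)) return(as_leaf)
  subtree_pred <- route_matrix(node, X[idx, , drop = FALSE], column_means,
                               smoothing = FALSE)
  err_subtree <- sum(abs(y[idx] - subtree_pred))
  err_leaf <- sum(abs(y[idx] - node$mean))
  if (err_leaf <= err_subtree) as_leaf else node
}

#' Predict from a fitted tree
#'
#' Routes each compound by the split conditions (`descriptor <= threshold`
#' goes left); missing split-descriptor values are imputed with the stored
#' training column means. Model-tree leaves evaluate their linear model,
#' other leaves return the leaf constant. With `use_smoothing` the leaf value
#' is blended with the ancestor node means on the way back to the root.
#'
#' @param object A fitted `vss_tree`.
#' @param newdata Data frame of descriptor columns (one row per compound).
#' @param ... Unused.
#' @return Numeric predictions in target (log10) units.
#' @export
predict.vss_tree <- function(object, newdata, ...) {
  used <- tree_split_descriptors(object$root)
  model_vars <- unlist(lapply(collect_leaves(object$root), function(l) {
    names(l$model$coefficients)
  }))
  needed <- unique(c(used, model_vars))
  missing_cols <- setdiff(needed, names(newdata))
  if (length(missing_cols)) {
    abort(paste0("Missing descriptor columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!length(needed)) {
    return(rep(leaf_value(object$root, NULL), nrow(newdata)))
  }
  M <- as.matrix(as.data.frame(newdata[needed], check.names = FALSE))
  pred <- route_matrix(object$root, M, object$column_means,
                       smoothing = object$params$use_smoothing)
  clamp_to_range(pred, object$y_range)
}

# Linear leaf models may extrapolate; predictions of a fitted tree are
# clamped to the training target range widened by 5% on each side. Constant
# leaves are always within range, so this only acts on model-tree
# extrapolation. Hand-built trees without a stored range are left alone.
clamp_to_range <- function(pred, y_range) {
  if (is.null(y_range)) return(pred)
  margin <- 0.05 * (y_range[2] - y_range[1])
  pmin(pmax(pred, y_range[1] - margin), y_range[2] + margin)
}

# Vectorized routing of a descriptor matrix through a node.
route_matrix <- function(node, M, column_means, smoothing = FALSE, k = 15) {
  out <- numeric(nrow(M))
  recurse <- function(node, rows) {
    if (!length(rows)) return(invisible())
    if (node$type == "leaf") {
      out[rows] <<- eval_leaf(node, M, rows)
      return(invisible())
    }
    xval <- M[rows, node$descriptor]
    na <- is.na(xval)
    if (any(na)) xval[na] <- column_means[[node$descriptor]]
    go_left <- xval <= node$threshold
    recurse(node$left, rows[go_left])
    recurse(node$right, rows[!go_left])
    if (smoothing) {
      n_child <- ifelse(go_left, node$left$n_train, node$right$n_train)
      out[rows] <<- (n_child * out[rows] + k * node$mean) / (n_child + k)
    }
    invisible()
  }
  recurse(node, seq_len(nrow(M)))
  out
}

eval_leaf <- function(leaf, M, rows) {
  if (is.null(leaf$model)) return(rep(leaf$prediction, length(rows)))
  cf <- leaf$model$coefficients
  pred <- rep(leaf$model$intercept, length(rows))
  for (nm in names(cf)) {
    v <- M[rows, nm]
    if (anyNA(v)) v[is.na(v)] <- 0
    pred <- pred + cf[[nm]] * v
  }
  pred
}

leaf_value <- function(node, M) node$prediction

collect_leaves <- function(node) {
  if (node$type == "leaf") return(list(node))
  c(collect_leaves(node$left), collect_leaves(node$right))
}

tree_split_descriptors <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$descriptor,
           tree_split_descriptors(node$left),
           tree_split_descriptors(node$right)))
}

#' Is a fitted model degenerate?
#'
#' A tree is degenerate when it is a single leaf with no linear-model terms —
#' it predicts the same value for every compound, making it useless as a
#' source of predicted Kt:p descriptors (the intestine-style exclusion).
#'
#' @param model A `vss_tree` (or ensemble/rule set; an ensemble is degenerate
#'   when all members are, a rule set when it predicts a single constant).
#' @return `TRUE` or `FALSE`.
#' @export
is_degenerate <- function(model) {
  UseMethod("is_degenerate")
}

#' @export
is_degenerate.vss_tree <- function(model) {
  node <- model$root
  node$type == "leaf" &&
    (is.null(node$model) || length(node$model$coefficients) == 0L)
}

#' @export
is_degenerate.vss_ensemble <- function(model) {
  all(vapply(model$members, is_degenerate, logical(1)))
}

#' @export
is_degenerate.rule_set <- function(model) {
  preds <- vapply(model$rules, `[[`, numeric(1), "prediction_log")
  preds <- c(preds, model$default_prediction)
  n_cond <- vapply(model$rules, function(r) nrow(r$conditions), integer(1))
  length(unique(preds)) <= 1L && all(n_cond == 0L)
}

#' Descriptors used anywhere in a fitted model
#'
#' The union of the descriptors in split nodes and in leaf linear models; for
#' ensembles, the union over members; for rule sets, the descriptors in rule
#' conditions. This is the descriptor set whose training ranges define the
#' applicability domain of the model.
#'
#' @param model A fitted `vss_tree`, `vss_ensemble` or `rule_set`.
#' @return Character vector of descriptor names.
#' @export
model_descriptor_set <- function(model) {
  UseMethod("model_descriptor_set")
}

#' @export
model_descriptor_set.vss_tree <- function(model) {
  leaves <- collect_leaves(model$root)
  unique(c(tree_split_descriptors(model$root),
           unlist(lapply(leaves, function(l) names(l$model$coefficients)))))
}

#' @export
model_descriptor_set.vss_ensemble <- function(model) {
  unique(unlist(lapply(model$members, model_descriptor_set)))
}

#' @export
model_descriptor_set.rule_set <- function(model) {
  unique(unlist(lapply(model$rules, function(r) r$conditions$descriptor)))
}

#' @export
print.vss_tree <- function(x, ...) {
  leaves <- collect_leaves(x$root)
  cat(sprintf("<vss_tree: %s tree, %d leaves, %d training compounds, target '%s'>\n",
              x$kind, length(leaves), x$n_train, x$target))
  invisible(x)
}
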