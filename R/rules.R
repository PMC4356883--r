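#' If-Then regression rule sets
#'
#' A rule is a conjunction of threshold conditions on descriptors
#' (`descriptor <= t` or `descriptor > t`) with a constant predicted log10
#' target and a training coverage count. A rule set is either
#' `"tree_extracted"` (one rule per leaf of a tree: mutually exclusive and
#' exhaustive) or an `"ordered_list"` (first match wins, with an optional
#' default rule).
#'
#' @param rules List of rules; each rule is a list with a `conditions` tibble
#'   (`descriptor`, `relation`, `threshold`), `prediction_log` and `coverage`.
#' @param mode `"tree_extracted"` or `"ordered_list"`.
#' @param default_prediction Optional default (log10) prediction for
#'   ordered-list sets.
#' @return A `rule_set`.
#' @export
rule_set <- function(rules, mode = c("ordered_list", "tree_extracted"),
                     default_prediction = NULL) {
  mode <- match.arg(mode)
  new_rule_set(rules, mode, default_prediction)
}

new_rule_set <- function(rules, mode, default_prediction = NULL) {
  structure(list(rules = rules, mode = mode,
                 default_prediction = default_prediction),
            class = "rule_set")
}

empty_conditions <- function() {
  tibble::tibble(descriptor = character(), relation = character(),
                 threshold = numeric())
}

new_rule <- function(conditions, prediction_log, coverage = NA_integer_) {
  stopifnot(all(conditions$relation %in% c("<=", ">")))
  list(conditions = conditions, prediction_log = prediction_log,
       coverage = coverage)
}

#' Extract If-Then rules from a regression tree
#'
#' Each root-to-leaf path becomes one rule whose conditions are the edge
#' conditions on the path and whose prediction is the leaf constant; the
#' resulting set is mutually exclusive and exhaustive and reproduces the
#' tree's predictions exactly. Coverage is counted on `data` (descriptor
#' missings imputed with the tree's training means, as in tree routing).
#'
#' @param tree A fitted `vss_tree` with constant leaves (model-tree leaves
#'   with linear terms cannot be expressed as constant-consequent rules and
#'   raise an error).
#' @param data Optional [compound_table()] on which to count coverage.
#' @return A `rule_set` with mode `"tree_extracted"`.
#' @export
extract_rules <- function(tree, data = NULL) {
  leaves <- collect_leaves(tree$root)
  if (any(vapply(leaves, function(l) {
    !is.null(l$model) && length(l$model$coefficients) > 0
  }, logical(1)))) {
    abort("Rules require constant leaves; refit with tree_kind = 'regression'.")
  }
  rules <- list()
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      rules[[length(rules) + 1L]] <<- new_rule(conds, node$prediction)
      return(invisible())
    }
    walk(node$left, dplyr::bind_rows(conds, tibble::tibble(
      descriptor = node$descriptor, relation = "<=", threshold = node$threshold)))
    walk(node$right, dplyr::bind_rows(conds, tibble::tibble(
      descriptor = node$descriptor, relation = ">", threshold = node$threshold)))
  }
  walk(tree$root, empty_conditions())
  rs <- new_rule_set(rules, "tree_extracted")
  if (!is.null(data)) {
    sat <- satisfies_matrix(rs, data, column_means = tree$column_means)
    for (i in seq_along(rs$rules)) rs$rules[[i]]$coverage <- sum(sat[, i])
  }
  rs
}

# Logical matrix (compound x rule) of full-antecedent satisfaction. Missing
# descriptor values are imputed with `column_means` when given; otherwise a
# condition on a missing value is unsatisfied.
satisfies_matrix <- function(ruleset, data, column_means = NULL) {
  n <- nrow(data)
  out <- matrix(TRUE, n, length(ruleset$rules))
  for (i in seq_along(ruleset$rules)) {
    conds <- ruleset$rules[[i]]$conditions
    ok <- rep(TRUE, n)
    for (j in seq_len(nrow(conds))) {
      d <- conds$descriptor[j]
      if (!d %in% names(data)) {
        ok <- rep(FALSE, n)
        break
      }
      v <- data[[d]]
      if (!is.null(column_means) && d %in% names(column_means)) {
        v[is.na(v)] <- column_means[[d]]
      }
      cmp <- if (conds$relation[j] == "<=") v <= conds$threshold[j]
             else v > conds$threshold[j]
      cmp[is.na(cmp)] <- FALSE
      ok <- ok & cmp
    }
    out[, i] <- ok
  }
  out
}

#' Keep only rules with sufficient training coverage
#'
#' Retains, in order, the rules covering at least `min_coverage` compounds —
#' the reliability filter used when reporting interpretable rules. The result
#' is generally non-exhaustive, so its mode becomes `"ordered_list"` without
#' a default: applying it can return no match.
#'
#' @param ruleset A `rule_set` with populated coverages.
#' @param min_coverage Minimum coverage to keep a rule.
#' @return A filtered `rule_set`.
#' @export
filter_by_coverage <- function(ruleset, min_coverage) {
  cov <- vapply(ruleset$rules, `[[`, numeric(1), "coverage")
  if (anyNA(cov)) abort("Rule coverages are not populated.")
  new_rule_set(ruleset$rules[cov >= min_coverage], "ordered_list",
               default_prediction = NULL)
}

#' Apply a rule set to compounds
#'
#' Tree-extracted sets return the unique matching rule's prediction (and
#' raise an error if the exclusivity invariant is violated); ordered lists
#' return the first matching rule, the default prediction if none matches, or
#' `NA` when there is no default. A condition on a missing descriptor value
#' is unsatisfied.
#'
#' @param ruleset A `rule_set`.
#' @param newdata Data frame of descriptor columns.
#' @return Predicted log10 target values (`NA` = no match).
#' @export
apply_rules <- function(ruleset, newdata) {
  sat <- satisfies_matrix(ruleset, newdata)
  preds <- vapply(ruleset$rules, `[[`, numeric(1), "prediction_log")
  n <- nrow(newdata)
  out <- rep(NA_real_, n)
  if (ruleset$mode == "tree_extracted") {
    n_match <- rowSums(sat)
    if (any(n_match > 1)) {
      abort("Ambiguous match: tree-extracted rules must be mutually exclusive.")
    }
    hit <- n_match == 1
    out[hit] <- preds[apply(sat[hit, , drop = FALSE], 1, which.max)]
  } else {
    for (i in seq_len(n)) {
      m <- which(sat[i, ])
      out[i] <- if (length(m)) preds[m[1]]
                else ruleset$default_prediction %||% NA_real_
    }
  }
  out
}

#' @export
predict.rule_set <- function(object, newdata, ...) {
  apply_rules(object, newdata)
}

#' Convert rule predictions from log10 to linear L/kg
#'
#' Rule predictions are stored in log10 space; reports print Vss in L/kg.
#'
#' @param prediction_log Predicted log10 value(s).
#' @return `10^prediction_log`.
#' @export
rule_vss <- function(prediction_log) 10^prediction_log

#' Learn an ordered list of regression rules (M5-Rules style)
#'
#' Iteratively fits a constant-leaf regression tree on the remaining
#' compounds, turns the best leaf — lowest training MAE adjusted by
#' `(n + v) / (n - v)` with `v` the number of path conditions; ties broken by
#' larger coverage, then shallower leaf — into a rule, removes the covered
#' compounds, and repeats. When the remaining compounds yield a degenerate
#' (single-leaf) tree or fall below `2 * min_instances`, a default rule
#' predicting their mean closes the list, guaranteeing totality.
#'
#' @param data A [compound_table()] (or data frame).
#' @param target Name of the target column.
#' @param params A [tree_params()]; the intermediate trees are always grown
#'   with constant leaves so consequents stay constant.
#' @return A `rule_set` with mode `"ordered_list"` and a default rule.
#' @export
fit_m5rules <- function(data, target, params = tree_params()) {
  inner <- params
  inner$tree_kind <- "regression"
  labeled <- data[!is.na(data[[target]]), , drop = FALSE]
  if (inherits(data, "compound_table")) {
    labeled <- new_compound_table(labeled, col_roles(data))
  }
  if (!nrow(labeled)) abort(sprintf("No labeled compounds for target '%s'.", target))
  overall_mean <- mean(labeled[[target]])
  rules <- list()
  remaining <- labeled
  repeat {
    if (nrow(remaining) < 2 * inner$min_instances) {
      default <- if (nrow(remaining)) mean(remaining[[target]]) else overall_mean
      return(new_rule_set(rules, "ordered_list", default))
    }
    tree <- fit_tree(remaining, target, inner)
    if (tree$root$type == "leaf") {
      return(new_rule_set(rules, "ordered_list", tree$root$prediction))
    }
    best <- best_leaf_rule(tree, remaining, target)
    rules[[length(rules) + 1L]] <- best
    sat <- satisfies_matrix(new_rule_set(list(best), "ordered_list"),
                            remaining, column_means = tree$column_means)
    remaining <- remaining[!sat[, 1], , drop = FALSE]
  }
}

best_leaf_rule <- function(tree, data, target) {
  candidates <- list()
  walk <- function(node, conds, depth) {
    if (node$type == "leaf") {
      candidates[[length(candidates) + 1L]] <<-
        list(conds = conds, prediction = node$prediction, depth = depth)
      return(invisible())
    }
    walk(node$left, dplyr::bind_rows(conds, tibble::tibble(
      descriptor = node$descriptor, relation = "<=",
      threshold = node$threshold)), depth + 1L)
    walk(node$right, dplyr::bind_rows(conds, tibble::tibble(
      descriptor = node$descriptor, relation = ">",
      threshold = node$threshold)), depth + 1L)
  }
  walk(tree$root, empty_conditions(), 0L)

  y <- data[[target]]
  scored <- lapply(candidates, function(cand) {
    rs <- new_rule_set(list(new_rule(cand$conds, cand$prediction)), "ordered_list")
    sat <- satisfies_matrix(rs, data, column_means = tree$column_means)[, 1]
    n <- sum(sat)
    v <- nrow(cand$conds)
    adj <- if (n - v <= 0 || n == 0) Inf
           else mean(abs(y[sat] - cand$prediction)) * (n + v) / (n - v)
    list(cand = cand, n = n, adj = adj, depth = cand$depth)
  })
  adj <- vapply(scored, `[[`, numeric(1), "adj")
  cov <- vapply(scored, `[[`, numeric(1), "n")
  depth <- vapply(scored, `[[`, numeric(1), "depth")
  ord <- order(adj, -cov, depth)
  pick <- scored[[ord[1]]]
  new_rule(pick$cand$conds, pick$cand$prediction, as.integer(pick$n))
}

#' Read and write plain-text rule files
#'
#' One rule per line in the format
#' `IF desc1 <= 0.04 AND desc2 > 1.5 THEN 1.10 ; coverage = 100`
#' (`IF TRUE THEN v` encodes a condition-free default-style rule; `#` lines
#' are comments). With `units = "linear"` the THEN values are Vss in L/kg and
#' are log10-transformed on read (and back-transformed on write).
#'
#' @param path Rule file path.
#' @param units `"log10"` or `"linear"` for the THEN values.
#' @param mode Rule-set mode for the parsed set.
#' @return `read_rules()` returns a `rule_set`; `write_rules()` returns
#'   `path` invisibly.
#' @export
read_rules <- function(path, units = c("log10", "linear"),
                       mode = c("ordered_list", "tree_extracted")) {
  units <- match.arg(units)
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- lapply(lines, function(line) parse_rule_line(line, units))
  new_rule_set(rules, mode)
}

parse_rule_line <- function(line, units) {
  m <- regmatches(line, regexec("^IF\\s+(.*)\\s+THEN\\s+(.*)$", line))[[1]]
  if (length(m) != 3) abort(paste0("Cannot parse rule line: ", line))
  then_part <- m[3]
  coverage <- NA_integer_
  if (grepl(";", then_part, fixed = TRUE)) {
    bits <- strsplit(then_part, ";", fixed = TRUE)[[1]]
    then_part <- trimws(bits[1])
    cov_m <- regmatches(bits[2], regexec("coverage\\s*=\\s*([0-9]+)", bits[2]))[[1]]
    if (length(cov_m) == 2) coverage <- as.integer(cov_m[2])
  }
  value <- as.numeric(then_part)
  if (is.na(value)) abort(paste0("Cannot parse THEN value in: ", line))
  if (units == "linear") value <- log10(value)
  cond_str <- trimws(m[2])
  conds <- empty_conditions()
  if (!identical(toupper(cond_str), "TRUE")) {
    for (piece in strsplit(cond_str, "\\s+AND\\s+")[[1]]) {
      cm <- regmatches(piece,
                       regexec("^(.*\\S)\\s*(<=|>)\\s*(-?[0-9.eE+-]+)$", piece))[[1]]
      if (length(cm) != 4) abort(paste0("Cannot parse condition: ", piece))
      conds <- dplyr::bind_rows(conds, tibble::tibble(
        descriptor = trimws(cm[2]), relation = cm[3],
        threshold = as.numeric(cm[4])))
    }
  }
  new_rule(conds, value, coverage)
}

#' @rdname read_rules
#' @param ruleset A `rule_set` to write.
#' @export
write_rules <- function(ruleset, path, units = c("log10", "linear")) {
  units <- match.arg(units)
  fmt_val <- function(v) {
    format(if (units == "linear") 10^v else v, digits = 15)
  }
  lines <- vapply(ruleset$rules, function(r) {
    lhs <- if (nrow(r$conditions) == 0) "TRUE" else {
      paste(sprintf("%s %s %s", r$conditions$descriptor, r$conditions$relation,
                    format(r$conditions$threshold, digits = 15)),
            collapse = " AND ")
    }
    cov <- if (is.na(r$coverage)) "" else sprintf(" ; coverage = %d", r$coverage)
    sprintf("IF %s THEN %s%s", lhs, fmt_val(r$prediction_log), cov)
  }, character(1))
  if (!is.null(ruleset$default_prediction)) {
    lines <- c(lines, sprintf("IF TRUE THEN %s",
                              fmt_val(ruleset$default_prediction)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set: %d rules, mode %s%s>\n", length(x$rules), x$mode,
              if (is.null(x$default_prediction)) "" else ", with default"))
  invisible(x)
}
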