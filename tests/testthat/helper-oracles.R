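# Shared helpers: independent oracles and small in-code fixtures.

# Brute-force standard-deviation-reduction split oracle: scans every midpoint
# between consecutive distinct sorted values, population sds, both children
# at least `min_instances` rows. Independent of the C++ scan it checks.
brute_force_split <- function(x, y, min_instances = 4L) {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  o <- order(x)
  xs <- x[o]
  ys <- y[o]
  n <- length(x)
  sd_p <- pop_sd(y)
  best <- NULL
  for (i in seq_len(n - 1)) {
    if (xs[i + 1] <= xs[i]) next
    nl <- i
    nr <- n - i
    if (nl < min_instances || nr < min_instances) next
    score <- sd_p - nl / n * pop_sd(ys[1:i]) - nr / n * pop_sd(ys[(i + 1):n])
    if (is.null(best) || score > best$score) {
      best <- list(threshold = (xs[i] + xs[i + 1]) / 2, score = score)
    }
  }
  if (!is.null(best) && best$score <= 1e-12) best <- NULL
  best
}

# A tiny labeled table: one informative descriptor plus noise columns.
make_small_table <- function(n = 40, seed = 1, target = "y") {
  withr::with_seed(seed, {
    x <- runif(n, -2, 2)
    df <- tibble::tibble(
      compound_id = sprintf("C%03d", seq_len(n)),
      x = x,
      z1 = rnorm(n),
      z2 = rnorm(n))
    df[[target]] <- ifelse(x <= 0, 1, -1) + 0.5 * x + rnorm(n, 0, 0.05)
    compound_table(df, targets = target)
  })
}

# Perfect two-level step: target depends only on whether x <= 10.5.
make_step_table <- function() {
  compound_table(tibble::tibble(
    compound_id = sprintf("S%02d", 1:20),
    x = as.numeric(1:20),
    y = rep(c(0, 10), each = 10)), targets = "y")
}

# Hand-built depth-1 tree with a linear model leaf (prediction = 2 * x on the
# left branch); bypasses fitting so predict() can be checked in isolation.
hand_built_model_tree <- function() {
  structure(list(
    root = list(
      type = "split", descriptor = "a", threshold = 0, n_train = 20, mean = 1,
      left = list(type = "leaf", prediction = 0, n_train = 10,
                  model = list(intercept = 0, coefficients = list(x = 2))),
      right = list(type = "leaf", prediction = 5, n_train = 10, model = NULL)),
    kind = "model",
    params = tree_params("model"),
    target = "y", features = c("a", "x"),
    column_means = c(a = 0, x = 0),
    n_train = 20, root_sd = 1, y_range = NULL),
    class = "vss_tree")
}

single_leaf_tree <- function(prediction = 1.5, model = NULL) {
  structure(list(
    root = list(type = "leaf", prediction = prediction, n_train = 5,
                model = model),
    kind = "regression", params = tree_params("regression"),
    target = "y", features = character(0),
    column_means = numeric(0), n_train = 5, root_sd = 0, y_range = NULL),
    class = "vss_tree")
}

# Minimal split-only tree for importance/root-frequency checks.
stub_tree <- function(root_desc, left_desc = NULL, right_desc = NULL) {
  leaf <- function(p) list(type = "leaf", prediction = p, n_train = 4,
                           model = NULL)
  child <- function(desc, p) {
    if (is.null(desc)) leaf(p)
    else list(type = "split", descriptor = desc, threshold = 0, n_train = 8,
              mean = p, left = leaf(p - 1), right = leaf(p + 1))
  }
  structure(list(
    root = list(type = "split", descriptor = root_desc, threshold = 0,
                n_train = 16, mean = 0,
                left = child(left_desc, -1), right = child(right_desc, 1)),
    kind = "regression", params = tree_params("regression"),
    target = "y", features = unique(c(root_desc, left_desc, right_desc)),
    column_means = setNames(
      rep(0, length(unique(c(root_desc, left_desc, right_desc)))),
      unique(c(root_desc, left_desc, right_desc))),
    n_train = 16, root_sd = 1, y_range = NULL),
    class = "vss_tree")
}

stub_ensemble <- function(trees) {
  structure(list(members = trees, n_trees = length(trees), seed = 1L,
                 params = tree_params("regression"), target = "y"),
            class = "vss_ensemble")
}

# Reduced roster for small-scale pipeline tests (keeps one method of each
# learner family).
small_roster <- function() {
  method_roster()[c("M5P-4", "M5P-RegTree", "Bagging-M5P")]
}
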