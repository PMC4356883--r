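test_that("best_split finds the obvious separator and refuses constants", {
  sp <- best_split(c(1, 2, 3, 4), c(0, 0, 10, 10), min_instances = 2)
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$score, 5)  # parent sd 5, both children pure

  expect_null(best_split(c(1, 2, 3, 4), c(7, 7, 7, 7), min_instances = 2))
  expect_null(best_split(rep(1, 10), rnorm(10), min_instances = 2))
  expect_error(best_split(1:4, rep(NA_real_, 4)), "missing")
})

test_that("a constant target yields a degenerate single-leaf tree", {
  tab <- compound_table(tibble::tibble(
    compound_id = sprintf("C%02d", 1:12), x = rnorm(12), y = rep(1.5, 12)),
    targets = "y")
  tr <- fit_tree(tab, "y")
  expect_identical(tr$root$type, "leaf")
  expect_true(is_degenerate(tr))
  expect_equal(predict(tr, tibble::tibble(x = c(-10, 0, 10))), rep(1.5, 3))
})

test_that("a step function is reproduced exactly by a depth-1 tree", {
  tab <- make_step_table()
  tr <- fit_tree(tab, "y", tree_params("regression", min_instances = 2))
  expect_identical(tr$root$type, "split")
  expect_equal(tr$root$threshold, 10.5)
  pred <- predict(tr, tab)
  expect_equal(pred, tab$y)
})

test_that("every regression-tree leaf predicts the mean of its training rows", {
  tab <- make_small_table(n = 40, seed = 2)
  tr <- fit_tree(tab, "y", tree_params("regression"))
  pred <- predict(tr, tab)
  for (p in unique(pred)) {
    expect_equal(p, mean(tab$y[pred == p]))
  }
})

test_that("accepted splits never increase the weighted child deviation", {
  tab <- make_small_table(n = 60, seed = 3)
  tr <- fit_tree(tab, "y", tree_params("regression"))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  check <- function(node, rows) {
    if (node$type == "leaf") return(invisible())
    x <- tab[[node$descriptor]][rows]
    left <- rows[x <= node$threshold]
    right <- rows[x > node$threshold]
    parent_sd <- pop_sd(tab$y[rows])
    child_sd <- (length(left) * pop_sd(tab$y[left]) +
                   length(right) * pop_sd(tab$y[right])) / length(rows)
    expect_gte(parent_sd, child_sd - 1e-12)
    check(node$left, left)
    check(node$right, right)
  }
  check(tr$root, seq_len(nrow(tab)))
})

test_that("hand-built model-tree leaves evaluate their linear model", {
  tr <- hand_built_model_tree()
  probe <- tibble::tibble(a = c(-1, 1), x = c(3, 3))
  expect_equal(predict(tr, probe), c(6, 5))  # left: y = 2x; right: constant
})

test_that("missing split values route by the stored training column mean", {
  tab <- make_step_table()
  tr <- fit_tree(tab, "y", tree_params("regression", min_instances = 2))
  # training mean of x is 10.5, equal to the threshold: routes left
  expect_equal(predict(tr, tibble::tibble(x = NA_real_)), 0)
})

test_that("fitted trees serialize deterministically and round-trip bit-exactly", {
  tab <- make_small_table(n = 50, seed = 4)
  tr1 <- fit_tree(tab, "y", tree_params("model"))
  tr2 <- fit_tree(tab, "y", tree_params("model"))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(tr1, f1)
  write_model(tr2, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_model(f1)
  probes <- make_small_table(n = 30, seed = 5)
  expect_identical(predict(back, probes), predict(tr1, probes))
})

test_that("bagging with the identity resample equals the single tree", {
  tab <- make_small_table(n = 40, seed = 6)
  ens <- fit_bagging(tab, "y", tree_params("regression"), n_trees = 1L,
                     seed = 1, resample = FALSE)
  tr <- fit_tree(tab, "y", tree_params("regression"))
  probes <- make_small_table(n = 25, seed = 7)
  expect_equal(predict(ens, probes), predict(tr, probes))
})

test_that("ensemble predictions are the exact mean of member predictions", {
  tab <- make_small_table(n = 50, seed = 8)
  ens <- fit_bagging(tab, "y", tree_params("model"), n_trees = 10L, seed = 2)
  probes <- make_small_table(n = 50, seed = 9)
  members <- sapply(ens$members, predict, newdata = probes)
  expect_equal(predict(ens, probes), rowMeans(members))

  const <- compound_table(tibble::tibble(
    compound_id = sprintf("K%02d", 1:12), x = rnorm(12), y = rep(2, 12)),
    targets = "y")
  cens <- fit_bagging(const, "y", tree_params("regression"), n_trees = 5L,
                      seed = 1)
  expect_true(is_degenerate(cens))
  expect_equal(predict(cens, tibble::tibble(x = 0)), 2)
})

test_that("ensembles reproduce bit-identically under the same seed", {
  tab <- make_small_table(n = 40, seed = 10)
  e1 <- fit_bagging(tab, "y", tree_params("model"), n_trees = 3L, seed = 7)
  e2 <- fit_bagging(tab, "y", tree_params("model"), n_trees = 3L, seed = 7)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_model(e1, f1)
  write_model(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("root and child-of-root frequencies count members, not nodes", {
  ens <- stub_ensemble(list(
    stub_tree("A"), stub_tree("A"),
    stub_tree("B", left_desc = "C"),
    stub_tree("A", left_desc = "B", right_desc = "B")))
  expect_equal(count_root_frequency(ens, "A"),
               list(root_count = 3L, child_of_root_count = 0L))
  expect_equal(count_root_frequency(ens, "B"),
               list(root_count = 1L, child_of_root_count = 1L))
  expect_equal(count_root_frequency(ens, "absent"),
               list(root_count = 0L, child_of_root_count = 0L))

  leafy <- stub_ensemble(list(single_leaf_tree(1)))
  expect_equal(count_root_frequency(leafy, "A"),
               list(root_count = 0L, child_of_root_count = 0L))
})

test_that("degeneracy distinguishes constant leaves from linear-model leaves", {
  expect_true(is_degenerate(single_leaf_tree(1)))
  expect_false(is_degenerate(stub_tree("A")))
  with_model <- single_leaf_tree(
    1, model = list(intercept = 0, coefficients = list(x = 2)))
  expect_false(is_degenerate(with_model))
})

test_that("the REP tree prunes on its internal holdout and stays seeded", {
  tab <- make_small_table(n = 60, seed = 11)
  t1 <- fit_tree(tab, "y", tree_params("rep", seed = 3))
  t2 <- fit_tree(tab, "y", tree_params("rep", seed = 3))
  probes <- make_small_table(n = 20, seed = 12)
  expect_identical(predict(t1, probes), predict(t2, probes))

  unpruned <- fit_tree(tab, "y", tree_params("rep", seed = 3, prune = FALSE))
  expect_lte(nrow(tidy(t1)), nrow(tidy(unpruned)))
})

test_that("model_descriptor_set unions splits and leaf-model terms", {
  expect_length(model_descriptor_set(single_leaf_tree(1)), 0L)
  expect_setequal(model_descriptor_set(stub_tree("x")), "x")
  expect_setequal(model_descriptor_set(hand_built_model_tree()), c("a", "x"))
  ens <- stub_ensemble(list(stub_tree("A"), stub_tree("B", left_desc = "C")))
  expect_setequal(model_descriptor_set(ens), c("A", "B", "C"))
})
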