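test_that("mae and gmfe follow their definitions and contracts", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1.3, 2.3), c(1, 2)), 0.3)
  expect_equal(mae(c(1, 0), c(0, 2)), 1.5)
  expect_error(mae(numeric(0), numeric(0)), "zero")
  expect_error(mae(1:2, 1:3), "length")
  expect_error(mae(c(1, 2), c(1, NA)), "missing")

  expect_equal(gmfe(0), 1)
  expect_equal(gmfe(log10(2)), 2)
  expect_error(gmfe(-0.1), "non-negative")
})

test_that("gmfe is strictly increasing and exactly multiplicative", {
  withr::with_seed(1, {
    a <- runif(20, 0, 1)
    b <- runif(20, 0, 1)
    expect_equal(gmfe(a + b), gmfe(a) * gmfe(b))
    ord <- order(a)
    expect_true(all(diff(gmfe(a[ord])) > 0))
  })
})

test_that("cross-validation partitions labeled rows and is reproducible", {
  tab <- make_small_table(n = 45, seed = 1)
  tab$y[1:5] <- NA  # unlabeled rows must never participate
  mean_method <- function(data, target, seed) {
    single_leaf_tree(mean(data[[target]], na.rm = TRUE))
  }
  cv <- cross_validate(tab, "y", mean_method, n_folds = 10, seed = 3)
  cv2 <- cross_validate(tab, "y", mean_method, n_folds = 10, seed = 3)
  expect_identical(cv, cv2)

  folds <- cv$folds
  expect_setequal(as.integer(names(folds)), which(!is.na(tab$y)))
  expect_true(max(table(folds)) - min(table(folds)) <= 1)
  expect_equal(cv$mean_mae, mean(cv$fold_mae))
})

test_that("two-fold CV of the mean predictor matches hand arithmetic", {
  tab <- compound_table(tibble::tibble(
    compound_id = c("a", "b", "c", "d"), x = c(1, 2, 3, 4),
    y = c(0, 1, 10, 11)), targets = "y")
  mean_method <- function(data, target, seed) {
    single_leaf_tree(mean(data[[target]]))
  }
  cv <- cross_validate(tab, "y", mean_method, n_folds = 2, seed = 5)
  for (f in 1:2) {
    test_rows <- as.integer(names(cv$folds)[cv$folds == f])
    train_rows <- setdiff(1:4, test_rows)
    expected <- mean(abs(tab$y[test_rows] - mean(tab$y[train_rows])))
    expect_equal(cv$fold_mae[f], expected)
  }

  const <- compound_table(tibble::tibble(
    compound_id = sprintf("c%02d", 1:10), x = rnorm(10), y = rep(0, 10)),
    targets = "y")
  expect_equal(cross_validate(const, "y", mean_method, 5, 1)$mean_mae, 0)

  expect_error(cross_validate(tab, "y", mean_method, n_folds = 5), "folds")
})

test_that("model selection takes the lowest MAE with roster-order ties", {
  expect_equal(select_best(c(A = 0.3, B = 0.2)), "B")
  expect_equal(select_best(c(A = 0.25, B = 0.25)), "A")
  muscle_row <- c("M5P-4" = 0.3029, "M5P-6" = 0.3040, "M5P-8" = 0.3164,
                  "M5P-10" = 0.2950, "M5P-RegTree" = 0.3384,
                  "REP-Tree" = 0.3857, "M5-Rules" = 0.3172,
                  "Bagging-M5P" = 0.3228)
  expect_equal(select_best(muscle_row), "M5P-10")
  expect_error(select_best(numeric(0)), "No methods")
})

test_that("the roster has the eight named methods and they all fit", {
  roster <- method_roster()
  expect_named(roster, c("M5P-4", "M5P-6", "M5P-8", "M5P-10", "M5P-RegTree",
                         "REP-Tree", "M5-Rules", "Bagging-M5P"))
  tab <- make_small_table(n = 40, seed = 2)
  probes <- make_small_table(n = 10, seed = 3)
  for (nm in names(roster)) {
    model <- fit_method(roster[[nm]], tab, "y", seed = 1)
    expect_true(all(is.finite(predict(model, probes))), info = nm)
  }
})

test_that("paired error comparison reports a confidence interval and p-value", {
  withr::with_seed(4, {
    obs <- rnorm(50)
    res <- compare_external_errors(obs + rnorm(50, 0, 0.2),
                                   obs + rnorm(50, 0, 0.2), obs)
  })
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_lt(res$conf_low, res$conf_high)
})
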