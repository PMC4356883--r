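test_that("rule extraction mirrors the tree structure", {
  leafy <- single_leaf_tree(2.5)
  tab <- make_small_table(n = 10, seed = 1)
  rs <- extract_rules(leafy, tab)
  expect_length(rs$rules, 1L)
  expect_equal(nrow(rs$rules[[1]]$conditions), 0L)
  expect_equal(rs$rules[[1]]$coverage, 10L)

  step <- fit_tree(make_step_table(), "y",
                   tree_params("regression", min_instances = 2))
  rs2 <- extract_rules(step, make_step_table())
  expect_length(rs2$rules, 2L)
  expect_setequal(
    vapply(rs2$rules, function(r) r$conditions$relation, character(1)),
    c("<=", ">"))

  expect_error(extract_rules(hand_built_model_tree()), "constant")
})

test_that("tree-extracted rules reproduce tree predictions on 1000 probes", {
  tab <- make_small_table(n = 80, seed = 2)
  tr <- fit_tree(tab, "y", tree_params("regression"))
  rs <- extract_rules(tr, tab)
  probes <- withr::with_seed(3, tibble::tibble(
    x = runif(1000, -3, 3), z1 = rnorm(1000), z2 = rnorm(1000)))
  expect_equal(apply_rules(rs, probes), predict(tr, probes))

  # mutual exclusivity and exhaustiveness: exactly one rule fires per probe
  sat <- vapply(rs$rules, function(r) {
    ok <- rep(TRUE, nrow(probes))
    for (j in seq_len(nrow(r$conditions))) {
      v <- probes[[r$conditions$descriptor[j]]]
      ok <- ok & if (r$conditions$relation[j] == "<=") {
        v <= r$conditions$threshold[j]
      } else v > r$conditions$threshold[j]
    }
    ok
  }, logical(nrow(probes)))
  expect_true(all(rowSums(sat) == 1))
})

test_that("coverage is conserved across the extracted rule set", {
  tab <- make_small_table(n = 60, seed = 4)
  tr <- fit_tree(tab, "y", tree_params("regression"))
  rs <- extract_rules(tr, tab)
  expect_equal(sum(vapply(rs$rules, `[[`, numeric(1), "coverage")), nrow(tab))
})

test_that("coverage filtering keeps order and may lose exhaustiveness", {
  coverages <- c(80, 30, 60, 13, 26, 20, 19, 100, rep(5, 10))
  rules <- lapply(seq_along(coverages), function(i) {
    list(conditions = tibble::tibble(descriptor = "x", relation = "<=",
                                     threshold = i),
         prediction_log = i / 10, coverage = coverages[i])
  })
  rs <- rule_set(rules, "ordered_list")
  kept <- filter_by_coverage(rs, 10)
  expect_length(kept$rules, 8L)
  expect_equal(vapply(kept$rules, `[[`, numeric(1), "coverage"),
               c(80, 30, 60, 13, 26, 20, 19, 100))

  expect_length(filter_by_coverage(rs, 0)$rules, length(coverages))
  expect_length(filter_by_coverage(rs, 1000)$rules, 0L)

  # non-exhaustive ordered list without default: no match gives NA
  expect_true(is.na(apply_rules(kept, tibble::tibble(x = 100))))
})

test_that("ambiguous matches violate the tree-extracted invariant loudly", {
  overlap <- rule_set(list(
    list(conditions = tibble::tibble(descriptor = "x", relation = "<=",
                                     threshold = 5), prediction_log = 1,
         coverage = 1L),
    list(conditions = tibble::tibble(descriptor = "x", relation = "<=",
                                     threshold = 10), prediction_log = 2,
         coverage = 1L)), "tree_extracted")
  expect_error(apply_rules(overlap, tibble::tibble(x = 1)), "exclusive")
})

test_that("the plain-text rule format round-trips", {
  tab <- make_small_table(n = 60, seed = 5)
  tr <- fit_tree(tab, "y", tree_params("regression"))
  rs <- extract_rules(tr, tab)
  path <- withr::local_tempfile(fileext = ".txt")
  write_rules(rs, path)
  back <- read_rules(path, mode = "tree_extracted")
  probes <- make_small_table(n = 40, seed = 6)
  expect_equal(apply_rules(back, probes), apply_rules(rs, probes))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("nonsense line", bad)
  expect_error(read_rules(bad), "Cannot parse")
})

test_that("the packaged Vss rule set encodes the printed thresholds", {
  rs <- read_rules(system.file("extdata", "vss_rules.txt",
                               package = "tidyvss"), units = "linear")
  expect_length(rs$rules, 8L)
  td <- tidy(rs)
  expect_equal(td$coverage, c(80L, 30L, 60L, 13L, 26L, 20L, 19L, 100L))
  expect_equal(round(td$vss, 2), c(0.57, 0.37, 0.27, 1.66, 1.96, 3.14, 2.15, 1.10))
  # all antecedents start at the skin partition coefficient (the tree root)
  expect_true(all(vapply(rs$rules, function(r) {
    r$conditions$descriptor[1] == "logK_skin:plasma"
  }, logical(1))))
})

test_that("iterative rule learning is total and handles degenerate input", {
  const <- compound_table(tibble::tibble(
    compound_id = sprintf("C%02d", 1:12), x = rnorm(12), y = rep(3, 12)),
    targets = "y")
  rs <- fit_m5rules(const, "y")
  expect_length(rs$rules, 0L)
  expect_equal(rs$default_prediction, 3)

  step <- make_step_table()
  rs2 <- fit_m5rules(step, "y", tree_params(min_instances = 2))
  expect_equal(apply_rules(rs2, step), step$y)

  tab <- make_small_table(n = 60, seed = 7)
  rs3 <- fit_m5rules(tab, "y")
  pred <- apply_rules(rs3, tab)
  expect_false(anyNA(pred))  # ordered list with default: every compound matched
})
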