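# Independent merit oracle: the CFS formula evaluated directly from cor().
merit_oracle <- function(data, target, subset) {
  X <- as.matrix(as.data.frame(data[subset], check.names = FALSE))
  y <- data[[target]]
  k <- length(subset)
  rcf <- mean(abs(suppressWarnings(cor(X, y))))
  rff <- if (k == 1) 0 else {
    cm <- abs(suppressWarnings(cor(X)))
    mean(cm[upper.tri(cm)])
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

make_cfs_table <- function(n = 120, seed = 1, p_noise = 4) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    df <- tibble::tibble(
      compound_id = sprintf("C%03d", seq_len(n)),
      good1 = f + rnorm(n, 0, 0.4),
      good2 = f + rnorm(n, 0, 0.6),
      dup1 = 0, dup2 = 0)
    for (j in seq_len(p_noise)) df[[paste0("noise", j)]] <- rnorm(n)
    df$dup1 <- df$good1          # exact duplicates: pure redundancy
    df$dup2 <- df$good2
    df$y <- f + rnorm(n, 0, 0.3)
    compound_table(df, targets = "y")
  })
}

test_that("merit matches the closed formula and collapses for k = 1", {
  tab <- make_cfs_table()
  expect_equal(cfs_merit(tab, "y", "good1"),
               abs(cor(tab$good1, tab$y)))
  for (subset in list(c("good1", "good2"), c("good1", "noise1", "noise2"),
                      c("good1", "good2", "dup1", "noise3"))) {
    expect_equal(cfs_merit(tab, "y", subset), merit_oracle(tab, "y", subset))
  }
  expect_equal(cfs_merit(tab, "y", character(0)), 0)
  # permutation invariance
  expect_equal(cfs_merit(tab, "y", c("good2", "good1")),
               cfs_merit(tab, "y", c("good1", "good2")))
})

test_that("constant columns contribute zero correlation, not an error", {
  tab <- compound_table(tibble::tibble(
    compound_id = c("a", "b", "c", "d"),
    flat = rep(1, 4), x = c(1, 2, 3, 4), y = c(1, 2, 3, 4)),
    targets = "y")
  expect_equal(cfs_merit(tab, "y", "flat"), 0)
  expect_gt(cfs_merit(tab, "y", c("x", "flat")), 0)
})

test_that("pure duplication cannot beat the single feature", {
  # k exact copies of one feature have pairwise correlation 1, so the merit
  # k * r / sqrt(k + k * (k - 1)) collapses to r, the singleton merit.
  tab <- make_cfs_table(seed = 2)
  single <- cfs_merit(tab, "y", "good1")
  expect_equal(cfs_merit(tab, "y", c("good1", "dup1")), single)
  expect_equal(cfs_merit(tab, "y", c("good2", "dup2")),
               cfs_merit(tab, "y", "good2"))
})

test_that("exhaustive search maximizes merit and enforces its size limit", {
  tab <- make_cfs_table(seed = 3)
  res <- exhaustive_search(tab, "y")
  # no subset among a random sample beats the enumerated optimum
  feats <- feature_names(tab)
  withr::with_seed(4, {
    for (i in 1:50) {
      subset <- sample(feats, sample(length(feats), 1))
      expect_lte(cfs_merit(tab, "y", subset), res$merit + 1e-12)
    }
  })

  single <- compound_table(tibble::tibble(
    compound_id = c("a", "b", "c"), x = c(1, 2, 3), y = c(1, 2, 3)),
    targets = "y")
  expect_equal(exhaustive_search(single, "y")$names, "x")

  wide <- compound_table(tibble::tibble(
    compound_id = "a", !!!setNames(as.list(rnorm(16)), paste0("d", 1:16)),
    y = 1), targets = "y")
  expect_error(exhaustive_search(wide, "y"), "15")
})

test_that("genetic search is seeded and bounded by the exhaustive oracle", {
  tab <- make_cfs_table(seed = 5)
  opt <- exhaustive_search(tab, "y")
  hits <- 0L
  for (s in 1:20) {
    res <- ga_search(tab, "y", cfs_config(seed = s))
    expect_lte(res$merit, opt$merit + 1e-12)
    if (abs(res$merit - opt$merit) < 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 15L)      # finds the optimum in most seeds

  r1 <- ga_search(tab, "y", cfs_config(seed = 9))
  r2 <- ga_search(tab, "y", cfs_config(seed = 9))
  expect_identical(r1, r2)

  one <- compound_table(tibble::tibble(
    compound_id = sprintf("C%02d", 1:20), x = rnorm(20), y = rnorm(20)),
    targets = "y")
  expect_equal(ga_search(one, "y")$names, "x")
})

test_that("pure-noise subsets have vanishing merit at large n", {
  withr::with_seed(6, {
    tab <- compound_table(tibble::tibble(
      compound_id = sprintf("C%03d", 1:500),
      !!!setNames(replicate(5, rnorm(500), simplify = FALSE), paste0("n", 1:5)),
      y = rnorm(500)), targets = "y")
  })
  expect_lt(cfs_merit(tab, "y", paste0("n", 1:5)), 0.2)
})
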