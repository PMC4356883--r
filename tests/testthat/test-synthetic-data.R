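small_cfg <- function(...) {
  synthetic_config(n_compounds = 60L, n_descriptors = 40L, ...)
}

test_that("seeded generation is bit-reproducible and phases share no ids", {
  a <- generate_phase1_dataset(small_cfg(seed = 3))
  b <- generate_phase1_dataset(small_cfg(seed = 3))
  expect_identical(as.data.frame(a), as.data.frame(b))

  p2 <- generate_phase2_dataset(small_cfg(seed = 3))
  expect_length(intersect(a$compound_id, p2$compound_id), 0L)
})

test_that("the tissue-composition equation evaluates exactly", {
  one_tissue <- physiology_params(
    V_p = 0.04, V_e = 0.03, EtoP = 1,
    V_t = setNames(c(0.5, rep(0, 12)), c("muscle", setdiff(vss_tissues, "muscle"))))
  ktp <- setNames(c(2, rep(0, 12)), c("muscle", setdiff(vss_tissues, "muscle")))
  expect_equal(compute_vss(one_tissue, ktp), 0.04 + 0.03 + 1.0)

  phys <- physiology_params()
  zero <- setNames(rep(0, 13), vss_tissues)
  no_rbc <- physiology_params(EtoP = 0)
  expect_equal(compute_vss(no_rbc, zero), phys$V_p)
  ones <- setNames(rep(1, 13), vss_tissues)
  expect_equal(compute_vss(phys, ones),
               phys$V_p + phys$V_e + sum(phys$V_t))

  expect_error(compute_vss(phys, setNames(c(-1, rep(1, 12)), vss_tissues)),
               "non-negative")
})

test_that("Vss is monotone in every single Kt:p", {
  phys <- physiology_params()
  withr::with_seed(5, {
    for (i in 1:25) {
      base <- setNames(runif(13, 0, 5), vss_tissues)
      tissue <- sample(vss_tissues, 1)
      bumped <- base
      bumped[tissue] <- bumped[tissue] + runif(1, 0, 3)
      expect_gte(compute_vss(phys, bumped), compute_vss(phys, base))
    }
  })
})

test_that("missingness masks the rounded fraction per tissue", {
  cfg <- synthetic_config(n_compounds = 110L, n_descriptors = 20L, seed = 2)
  Z <- generate_compounds(cfg)$latents
  ktp <- generate_ktp(Z, cfg)

  cfg0 <- cfg
  cfg0$missingness[] <- 0
  expect_identical(apply_missingness(ktp, cfg0), ktp)

  cfg1 <- cfg
  cfg1$missingness[] <- 1
  expect_true(all(is.na(apply_missingness(ktp, cfg1))))

  cfg_sparse <- cfg
  cfg_sparse$missingness["thymus"] <- 0.97  # the 3-labeled-compound analog
  masked <- apply_missingness(ktp, cfg_sparse)
  expect_equal(sum(!is.na(masked$logKtp_thymus)), 3L)
})

test_that("planted tissue structure: degenerate intestine, adipose on factor 1", {
  cfg <- synthetic_config(n_compounds = 200L, n_descriptors = 20L, seed = 4)
  Z <- generate_compounds(cfg)$latents
  ktp <- generate_ktp(Z, cfg)

  expect_equal(sd(ktp$logKtp_intestine), 0)
  expect_gt(cor(ktp$logKtp_adipose, Z[, 1]), 0.99)
  expect_gt(abs(cor(ktp$logKtp_adipose, Z[, 1])),
            abs(cor(ktp$logKtp_spleen, Z[, 1])))
})

test_that("informative descriptors are more intercorrelated than noise", {
  cmp <- generate_compounds(synthetic_config(n_compounds = 200L,
                                             n_descriptors = 50L, seed = 6))
  X <- as.matrix(as.data.frame(cmp$table[descriptor_names(cmp$table)]))
  informative <- 1:40  # 80% of columns, by construction
  noise <- 41:50
  mean_abs_cor <- function(cols) {
    cm <- abs(cor(X[, cols]))
    mean(cm[upper.tri(cm)])
  }
  expect_gt(mean_abs_cor(informative), mean_abs_cor(noise))
})

test_that("noiseless log Vss is an exact function of the generated Kt:p", {
  cfg <- small_cfg(seed = 9)
  cfg$target_noise_sd <- 0
  phys <- physiology_params()
  p2 <- generate_phase2_dataset(cfg, phys)
  truth <- attr(p2, "truth")

  ktp_lin <- as.data.frame(10^as.matrix(truth$ktp_log))
  names(ktp_lin) <- sub("^logKtp_", "", names(truth$ktp_log))
  expect_equal(p2$logVss, log10(compute_vss(phys, ktp_lin)))
  expect_true(all(10^p2$logVss >= phys$V_p))
})

test_that("linear-scale Vss is right-skewed under defaults", {
  p2 <- generate_phase2_dataset(small_cfg(seed = 10))
  vss <- 10^p2$logVss
  skew <- mean((vss - mean(vss))^3) / sd(vss)^3
  expect_gt(skew, 0)
})
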