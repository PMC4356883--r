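#' The thirteen modeled tissues
#'
#' Tissue names used throughout: each has a tissue volume in the physiology
#' parameters and a `logKtp_<tissue>` target column in phase-1 tables.
#'
#' @export
vss_tissues <- c("muscle", "brain", "intestine", "lung", "spleen", "heart",
                 "skin", "bone", "adipose", "kidneys", "liver", "gut", "thymus")

#' Human-like physiology parameters
#'
#' Plasma volume `V_p`, erythrocyte volume `V_e`, the erythrocyte:plasma
#' partition coefficient `EtoP` and per-tissue volumes `V_t` (all volumes in
#' L/kg body weight) for the tissue-composition equation
#' `Vss = V_p + V_e * EtoP + sum_t V_t * Ktp_t`. The defaults are rounded
#' human reference values; they shape the synthetic marginal distribution of
#' Vss and are fully overridable.
#'
#' @param V_p,V_e Plasma and erythrocyte volumes (L/kg).
#' @param EtoP Erythrocyte-to-plasma partition coefficient (dimensionless).
#' @param V_t Named vector of tissue volumes (L/kg) over [vss_tissues].
#' @return A `physiology_params` list.
#' @export
physiology_params <- function(V_p = 0.0436, V_e = 0.0245, EtoP = 1.0,
                              V_t = c(muscle = 0.4000, brain = 0.0200,
                                      intestine = 0.0088, lung = 0.0076,
                                      spleen = 0.0026, heart = 0.0047,
                                      skin = 0.0371, bone = 0.0656,
                                      adipose = 0.1430, kidneys = 0.0044,
                                      liver = 0.0257, gut = 0.0171,
                                      thymus = 0.0007)) {
  if (V_p < 0 || V_e < 0 || EtoP < 0 || any(V_t < 0)) {
    abort("Volumes and the E:P coefficient must be non-negative.")
  }
  if (!setequal(names(V_t), vss_tissues)) {
    abort("`V_t` must be named over exactly the 13 modeled tissues.")
  }
  structure(list(V_p = V_p, V_e = V_e, EtoP = EtoP, V_t = V_t[vss_tissues]),
            class = "physiology_params")
}

#' Configuration of the synthetic compound generator
#'
#' @param n_compounds Number of compounds (110 for a phase-1-like Kt:p table,
#'   604 for a phase-2-like Vss table).
#' @param n_descriptors Number of molecular descriptor columns.
#' @param n_latent Number of latent compound factors (lipophilicity, acidity
#'   and molecular size under the default loadings).
#' @param missingness Named vector over [vss_tissues]: fraction of compounds
#'   whose log Kt:p is missing for that tissue. Extreme values are allowed so
#'   a tissue can end up with only a handful of labeled compounds.
#' @param target_noise_sd Standard deviation of the additive log10-scale noise
#'   on the Vss target.
#' @param seed Integer seed; the same seed reproduces the dataset bit for bit.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 110L, n_descriptors = 300L,
                             n_latent = 3L,
                             missingness = default_missingness(),
                             target_noise_sd = 0.1, seed = 1L) {
  stopifnot(n_compounds >= 1, n_descriptors >= 1, n_latent >= 1,
            target_noise_sd >= 0)
  missingness <- missingness[vss_tissues]
  if (anyNA(missingness) || any(missingness < 0) || any(missingness > 1)) {
    abort("`missingness` must give a fraction in [0, 1] for every tissue.")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 n_latent = as.integer(n_latent),
                 missingness = missingness,
                 target_noise_sd = target_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_missingness <- function() {
  c(muscle = 0.25, brain = 0.50, intestine = 0.45, lung = 0.50,
    spleen = 0.60, heart = 0.55, skin = 0.45, bone = 0.60,
    adipose = 0.00, kidneys = 0.50, liver = 0.40, gut = 0.55,
    thymus = 0.60)
}

#' Planted tissue loadings on the latent factors
#'
#' Packaged constants defining how each tissue's log10 Kt:p depends on the
#' latent compound factors. The planted signal: adipose (and, less so, skin)
#' load most heavily on factor 1, the lipophilicity analog, and adipose has
#' the smallest target noise and full label coverage — so importance analyses
#' have a known ground truth. Intestine has zero loadings and zero noise: its
#' log Kt:p is exactly constant, the planted degenerate tissue. All other
#' tissues have deliberately small loadings and noise, so that lipophilicity
#' reaches Vss almost entirely through the adipose (and skin) partition terms.
#'
#' @param n_latent Number of latent factors (extra factors beyond the first
#'   four get zero loadings; the default configuration uses the first three).
#' @return A tibble with columns `tissue`, `intercept`, `noise_sd` and one
#'   loading column per factor.
#' @export
tissue_loadings <- function(n_latent = 4L) {
  base <- tibble::tribble(
    ~tissue,     ~intercept, ~f1,    ~f2,    ~f3,   ~f4,   ~noise_sd,
    "muscle",     0.00,       0.075,  0.175,  0.150, 0.00,  0.15,
    "brain",      0.10,       0.075,  0.000,  0.100, -0.175, 0.15,
    "intestine",  0.15,       0.000,  0.000,  0.000, 0.00,  0.00,
    "lung",       0.05,       0.050,  0.100,  0.000, 0.15,  0.15,
    "spleen",     0.00,       0.050,  0.150,  0.000, 0.10,  0.15,
    "heart",      0.05,       0.050,  0.000,  0.175, 0.05,  0.15,
    "skin",       0.00,       0.350,  0.000,  0.100, 0.10,  0.15,
    "bone",      -0.10,       0.025, -0.150,  0.100, 0.00,  0.15,
    "adipose",    0.20,       1.400, -0.100,  0.100, 0.00,  0.05,
    "kidneys",    0.10,       0.050,  0.150,  0.000, 0.10,  0.15,
    "liver",      0.15,       0.075,  0.150,  0.100, 0.00,  0.15,
    "gut",        0.10,       0.050,  0.000,  0.150, 0.10,  0.15,
    "thymus",     0.00,       0.050,  0.000,  0.050, 0.15,  0.15
  )
  load_cols <- paste0("f", seq_len(n_latent))
  for (col in setdiff(load_cols, names(base))) base[[col]] <- 0
  base[, c("tissue", "intercept", load_cols, "noise_sd")]
}

# Descriptor mixing weights: packaged constants derived from a fixed internal
# seed so the same descriptor-generating process applies to every table
# (phase-1 models must transfer to phase-2 compounds). 80% of descriptors are
# informative: each mixes every latent factor with a weight drawn from
# [0.3, 0.5] and a random sign, plus noise with sd 0.4; 20% of the
# informative ones pass their linear mix through tanh (mild monotone
# nonlinearity); the rest are pure noise. Spreading each descriptor's signal
# over all factors caps any single raw descriptor's correlation with the
# lipophilicity factor well below what a model aggregating many descriptors
# reaches — the identifiability argument behind the planted adipose truth.
descriptor_loadings <- function(n_descriptors, n_latent = 3L) {
  with_local_seed(20150226L, {
    p <- n_descriptors
    n_inf <- round(0.8 * p)
    W <- matrix(0, nrow = p, ncol = n_latent)
    nonlinear <- logical(p)
    for (j in seq_len(n_inf)) {
      W[j, ] <- runif(n_latent, 0.3, 0.5) * sample(c(-1, 1), n_latent,
                                                   replace = TRUE)
    }
    nonlinear[seq_len(n_inf)] <- runif(n_inf) < 0.2
    list(W = W,
         noise_sd = ifelse(seq_len(p) <= n_inf, 0.4, 1.0),
         informative = seq_len(p) <= n_inf,
         nonlinear = nonlinear)
  })
}

#' Generate latent factors and a descriptor table
#'
#' Latent compound factors are standard normal; descriptors are noisy linear
#' (or tanh-transformed) mixtures of the factors plus pure-noise columns, so
#' descriptor redundancy exists (exercising correlation-based feature
#' selection) and a known informative subset exists.
#'
#' @param config A [synthetic_config()].
#' @param id_prefix Prefix for the generated compound ids.
#' @return A list with `latents` (n x k matrix) and `table` (a
#'   [compound_table()] of descriptors only).
#' @export
generate_compounds <- function(config = synthetic_config(), id_prefix = "CMP") {
  n <- config$n_compounds; p <- config$n_descriptors; k <- config$n_latent
  mix <- descriptor_loadings(p, k)
  with_local_seed(config$seed, {
    Z <- matrix(rnorm(n * k), nrow = n, ncol = k,
                dimnames = list(NULL, paste0("f", seq_len(k))))
    lin <- Z %*% t(mix$W)
    lin[, mix$nonlinear] <- tanh(lin[, mix$nonlinear, drop = FALSE])
    X <- lin + matrix(rnorm(n * p), n, p) * rep(mix$noise_sd, each = n)
    colnames(X) <- sprintf("desc_%03d", seq_len(p))
    tab <- compound_table(tibble::tibble(
      compound_id = sprintf("%s%04d", id_prefix, seq_len(n)),
      tibble::as_tibble(X)))
    list(latents = Z, table = tab)
  })
}

#' Generate complete per-tissue log Kt:p columns
#'
#' Each tissue's log10 Kt:p is its planted intercept plus a tissue-specific
#' linear combination of the latent factors plus Gaussian noise (see
#' [tissue_loadings()]); no missingness is applied here.
#'
#' @param latents Latent factor matrix from [generate_compounds()].
#' @param config A [synthetic_config()].
#' @param loadings A loadings table as returned by [tissue_loadings()].
#' @return A tibble with one `logKtp_<tissue>` column per tissue.
#' @export
generate_ktp <- function(latents, config = synthetic_config(),
                         loadings = tissue_loadings(config$n_latent)) {
  n <- nrow(latents)
  load_cols <- paste0("f", seq_len(config$n_latent))
  with_local_seed(config$seed + 1L, {
    cols <- lapply(seq_len(nrow(loadings)), function(i) {
      row <- loadings[i, ]
      drop(latents %*% as.numeric(row[load_cols])) + row$intercept +
        rnorm(n, 0, row$noise_sd)
    })
    names(cols) <- paste0("logKtp_", loadings$tissue)
    tibble::as_tibble(cols)
  })
}

#' Steady-state volume of distribution from tissue composition
#'
#' Evaluates `Vss = V_p + V_e * EtoP + sum_t V_t * Ktp_t` exactly, with the
#' partition coefficients on the linear (not log) scale.
#'
#' @param physiology A [physiology_params()].
#' @param ktp A named vector (one compound) or data frame (one row per
#'   compound) of linear-scale Kt:p values covering all tissues in `V_t`.
#' @return Vss in L/kg, one value per compound.
#' @export
compute_vss <- function(physiology, ktp) {
  tissues <- names(physiology$V_t)
  if (is.null(dim(ktp))) {
    ktp <- as.data.frame(as.list(ktp), check.names = FALSE)
  }
  missing_t <- setdiff(tissues, names(ktp))
  if (length(missing_t)) {
    abort(paste0("Missing Kt:p for tissues: ", paste(missing_t, collapse = ", ")))
  }
  K <- as.matrix(ktp[tissues])
  if (any(K < 0, na.rm = TRUE)) {
    abort("Kt:p values must be non-negative on the linear scale.")
  }
  drop(physiology$V_p + physiology$V_e * physiology$EtoP +
         K %*% physiology$V_t[tissues])
}

#' Mask tissue Kt:p values at the configured rates
#'
#' Per tissue, `round(fraction * n)` entries (round-half-to-even, the base R
#' convention) are set missing uniformly at random under the configured seed —
#' emulating the sparse literature coverage of measured partition
#' coefficients, down to a pancreas-like tissue with only 3 labeled compounds.
#'
#' @param ktp Tibble of complete `logKtp_*` columns from [generate_ktp()].
#' @param config A [synthetic_config()] with the per-tissue `missingness` map.
#' @return The tibble with missing entries inserted.
#' @export
apply_missingness <- function(ktp, config = synthetic_config()) {
  n <- nrow(ktp)
  with_local_seed(config$seed + 2L, {
    for (tissue in names(config$missingness)) {
      col <- paste0("logKtp_", tissue)
      if (!col %in% names(ktp)) next
      n_missing <- round(config$missingness[[tissue]] * n)
      if (n_missing > 0) {
        ktp[[col]][sample.int(n, n_missing)] <- NA_real_
      }
    }
    ktp
  })
}

#' Generate a phase-1 (Kt:p-target) dataset
#'
#' Descriptors plus 13 partially missing `logKtp_<tissue>` target columns.
#' The `"truth"` attribute records the latent factors and the complete
#' (pre-masking) Kt:p columns for oracle checks.
#'
#' @param config A [synthetic_config()] (default: 110 compounds).
#' @param physiology A [physiology_params()] (unused here beyond naming, kept
#'   for interface symmetry with [generate_phase2_dataset()]).
#' @return A [compound_table()] with descriptor and target columns.
#' @export
generate_phase1_dataset <- function(config = synthetic_config(),
                                    physiology = physiology_params()) {
  cmp <- generate_compounds(config, id_prefix = "KTP")
  ktp_full <- generate_ktp(cmp$latents, config)
  ktp <- apply_missingness(ktp_full, config)
  tab <- dplyr::bind_cols(
    tibble::as_tibble(as.data.frame(cmp$table, check.names = FALSE)), ktp)
  out <- compound_table(tab, targets = names(ktp))
  attr(out, "truth") <- list(latents = cmp$latents, ktp_complete = ktp_full)
  out
}

#' Generate a phase-2 (Vss-target) dataset
#'
#' A fresh set of compounds (disjoint ids, independent latent factors) with
#' the same descriptor-generating process as phase 1, and a complete `logVss`
#' target computed from the tissue-composition equation on the generated
#' (noiseless-truth) Kt:p values, plus additive log10-scale noise.
#'
#' @param config A [synthetic_config()]; use `n_compounds = 604` for the
#'   full-sized table.
#' @param physiology A [physiology_params()].
#' @return A [compound_table()] with a `logVss` target. The `"truth"`
#'   attribute holds the latents, the complete log Kt:p columns and the
#'   noiseless `logVss`.
#' @export
generate_phase2_dataset <- function(config = synthetic_config(n_compounds = 604L),
                                    physiology = physiology_params()) {
  cfg2 <- config
  cfg2$seed <- config$seed + 5000L  # independent compounds, same mixing process
  cmp <- generate_compounds(cfg2, id_prefix = "VSS")
  ktp_log <- generate_ktp(cmp$latents, cfg2)
  ktp_lin <- as.data.frame(10^as.matrix(ktp_log))
  names(ktp_lin) <- sub("^logKtp_", "", names(ktp_log))
  vss <- compute_vss(physiology, ktp_lin)
  log_vss_true <- log10(vss)
  with_local_seed(cfg2$seed + 3L, {
    log_vss <- log_vss_true + rnorm(length(vss), 0, config$target_noise_sd)
    tab <- dplyr::bind_cols(
      tibble::as_tibble(as.data.frame(cmp$table, check.names = FALSE)),
      tibble::tibble(logVss = log_vss))
    out <- compound_table(tab, targets = "logVss")
    attr(out, "truth") <- list(latents = cmp$latents, ktp_log = ktp_log,
                               logVss_noiseless = log_vss_true)
    out
  })
}

#' Write a dataset's ground truth to JSON
#'
#' Exports the `"truth"` attribute attached by the generators (latent factors
#' and noiseless targets) so external tooling can use it as a test oracle.
#'
#' @param table A generated [compound_table()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(table, path) {
  truth <- attr(table, "truth")
  if (is.null(truth)) abort("Table carries no truth attribute.")
  jsonlite::write_json(lapply(truth, function(x) {
    if (is.matrix(x)) apply(x, 1, identity, simplify = FALSE) else x
  }), path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}
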