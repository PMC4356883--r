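---
title: "Two-phase tree-based prediction of volume of distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase tree-based prediction of volume of distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tidyvss)
```

## The problem and the model

The apparent volume of distribution at steady state, Vss (L/kg), relates a
drug's total body amount to its plasma concentration and co-determines dosing
intervals. Physiologically, Vss follows from tissue composition:

$$V_{ss} = V_p + V_e \cdot (E\!:\!P) + \sum_t V_t \cdot K_{t:p},$$

where $V_p$, $V_e$ and $V_t$ are plasma, erythrocyte and tissue volumes,
$E\!:\!P$ the erythrocyte:plasma partition coefficient and $K_{t:p}$ the
tissue:plasma partition coefficient of tissue $t$. Experimental $K_{t:p}$
values exist for only a few dozen compounds per tissue, so `tidyvss`
implements a two-phase QSPkR workflow:

1. **Phase 1** learns, for each of 13 tissues, a regressor for
   $\log_{10} K_{t:p}$ from molecular descriptors, on a small table (about
   110 compounds) with heavy per-tissue missingness. Other tissues'
   $K_{t:p}$ values are never used as inputs, because they are unknown for
   the compounds the models will later score. Each tissue's winner is the
   method with the lowest 10-fold cross-validated mean absolute error (MAE,
   always on the log10 scale) among an eight-method roster, refit on all
   labeled compounds. Tissues with fewer than `min_labeled` (default 10)
   labeled compounds are excluded (`too_few_labeled`), as are tissues whose
   winner collapses to a single constant leaf (`degenerate_model`) — a
   constant column is useless as a downstream descriptor.
2. **Phase 2** predicts $\log_{10} V_{ss}$ on a larger table (604 compounds,
   split 402 model-selection / 202 external validation) in three descriptor
   configurations: molecular descriptors plus the predicted
   $\log K_{t:p}$ columns, descriptors only, or a subset chosen by
   correlation-based feature selection (CFS) with genetic search. The
   cross-validated winner is refit on the whole model-selection set and
   scored once on the external set; external compounds never touch fitting
   or selection. The external error is reported as MAE and as the geometric
   mean fold error, $\mathrm{GMFE} = 10^{\mathrm{MAE}}$ (GMFE 2 means
   predictions are on average twofold off).

## The learners

All learners are implemented in the package (only the per-node best-split
scan is compiled C++ for speed); they share one split criterion, the
standard-deviation reduction

$$\mathrm{SDR} = \mathrm{sd}(y_{\text{node}}) - \sum_{c \in \{L,R\}}
  \frac{n_c}{n}\,\mathrm{sd}(y_c),$$

with population standard deviations and candidate thresholds at midpoints
between consecutive distinct sorted values; both children must keep at least
`min_instances` compounds. The roster:

* **M5P-4/6/8/10** — model trees with minimum leaf sizes 4–10. Leaves carry
  multivariate linear models over the descriptors used by splits on the
  root-to-leaf path or in the surrounding subtree; terms are dropped
  greedily while the estimated error $\mathrm{MAE}\cdot(n+v)/(n-v)$
  improves, and the whole tree is pruned bottom-up by the same estimate.
* **M5P-RegTree** — the regression-tree variant (leaf = mean of its training
  targets).
* **REP-Tree** — a regression tree grown on a seeded 2/3 subset and
  reduced-error-pruned on the held-out 1/3.
* **M5-Rules** — an ordered list of If-Then rules built iteratively: fit a
  constant-leaf tree, keep the best leaf (lowest adjusted MAE; ties by
  coverage, then depth) as a rule, drop the covered compounds, repeat; a
  default rule guarantees totality.
* **Bagging-M5P** — 10 bootstrap-resampled model trees, predictions
  averaged.

Ties between equal-score splits go to the lowest column index, then the
smallest threshold, so fits are deterministic. Missing descriptor cells are
imputed with the current node's column mean during fitting and with the
stored training means at prediction time. Model selection between roster
members resolves MAE ties by roster order.

## Numerical choices

Three safeguards matter in practice and are deliberate design choices:

* **Model-tree pruning is on by default.** Without it, leaf models fit on a
  handful of highly collinear descriptors extrapolate wildly on new
  compounds; the $(n+v)/(n-v)$ estimate collapses such subtrees into
  better-supported node models.
* **Node models never approach interpolation**: at most one linear term per
  three training compounds before backward elimination starts.
* **Fitted trees clamp predictions** to the training target range widened by
  5% per side. Constant leaves always lie inside the range, so this touches
  only model-tree extrapolation, where an unlucky bootstrap leaf can
  otherwise predict thousands of log units off.

Smoothing of leaf predictions through ancestor node means
(`(np + kq)/(n + k)`, `k = 15`) is implemented but off by default; no
default behavior depends on it. The variance stop is 5% of the root standard
deviation. CFS uses Pearson correlations on pairwise-complete rows, treats
constant columns as zero-correlated, and searches with a bitstring GA
(population 20, 20 generations, crossover 0.6, per-bit mutation 0.033,
tournament selection, elitism of one); an exhaustive enumerator for up to 15
descriptors serves as its oracle. The CFS subset is fixed once on the
model-selection set before cross-validation — the potential optimistic bias
of selecting before CV is accepted and documented rather than hidden.

## What the synthetic generator emulates

Real descriptor tables from commercial software and curated partition
coefficient data cannot ship with the package, so `generate_phase1_dataset()`
and `generate_phase2_dataset()` produce tables with the statistical features
the workflow depends on:

* Compounds are draws of three latent factors (think lipophilicity, acidity,
  molecular size). Each informative descriptor (80% of 300) mixes **all**
  factors with weights 0.3–0.5 of random sign plus Gaussian noise (sd 0.4);
  20% of these pass through `tanh` (mild monotone nonlinearity); the rest
  are pure noise. Mixing every factor caps any single descriptor's
  correlation with the lipophilicity factor near 0.65, while a model that
  aggregates many descriptors can do much better — this gap is what makes
  the planted importance structure identifiable.
* Tissue $\log K_{t:p}$ columns are linear in the latent factors plus noise
  (`tissue_loadings()`), with a planted truth: **adipose** loads 1.4 on
  lipophilicity with the smallest noise (0.05) and full label coverage;
  skin is second (0.35); every other tissue has small loadings (≤ 0.175)
  and noise 0.15, so lipophilicity reaches Vss almost entirely through the
  adipose and skin partition terms; **intestine** is exactly constant — the
  planted degenerate tissue.
* Vss is computed exactly from the tissue-composition equation with rounded
  human tissue volumes (`physiology_params()`), and the target is
  $\log_{10} V_{ss}$ plus noise (sd 0.1) — the log transform reflects the
  strongly right-skewed linear-scale distribution the equation produces.
* Missingness is masked per tissue at configured rates (`round(fraction*n)`
  entries, base-R round-half-to-even), down to a 3-labeled-compound tissue
  analog. Phase-1 and phase-2 tables share the descriptor-generating
  constants (fixed internal seed) but never a compound id.

The generator does **not** emulate real chemistry: no molecular structures,
no descriptor semantics, no species differences between the rat-like phase-1
targets and the human-like phase-2 targets (a per-tissue bias could be added
through `tissue_loadings()`, but none is by default). Passing tests
therefore demonstrate that the pipeline recovers structure it is told is
there — not that the models would reach any particular accuracy on real
compounds.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_instances` | 4 (roster: 4–10) | minimum compounds per leaf |
| `variance_stop_fraction` | 0.05 | stop when node sd < fraction of root sd |
| `n_trees` | 10 | bagging ensemble size |
| `min_labeled` | 10 | phase-1 threshold for attempting a tissue model |
| `n_folds` | 10 | cross-validation folds |
| `noise_fraction` | 0.10 | sensitivity-analysis perturbation |
| `n_model_selection` / `n_external` | 402 / 202 | phase-2 holdout sizes |

## Sensitivity, applicability domain, importance

`sensitivity_analysis()` perturbs one predicted descriptor column (every
compound, model-selection and external alike) by `v(1 ± 0.10)` with random
per-compound signs, refits the bagging learner with a fixed ensemble seed —
so repeats differ only in the perturbation — and averages the external GMFE
over five repeats, also reporting the perturbed descriptor's root frequency.
`applicability_domain()` flags external compounds with any descriptor value
outside the training range of a named descriptor set (missing values never
flag). `descriptor_importance()` counts, per descriptor, the ensemble
members rooting on it and those splitting a root child on it, dropping
single occurrences as bootstrap noise.

## Problem sizes used by the test suite

Unit tests run at 40–150 compounds with 20–60 descriptors and a three-method
roster. The end-to-end recovery check runs once at the workflow's reference sizes
(110 × 300 phase 1; 604 × 312 phase 2 with a 402/202 split) and then varies
the holdout-split and ensemble seeds five times over that one dataset and
registry — regenerating data and registry per seed would multiply runtime
several-fold without changing the property under test (the root-placement of
the predicted adipose descriptor). The interface accepts any sizes.

## Known limitations

* Tree fitting is exact but greedy; no split look-ahead.
* The REP-Tree holdout and the M5-Rules "best leaf" rule are this package's
  documented readings of loosely specified methods; no claim of bit-for-bit
  agreement with other toolkits is made.
* The t-test utility (`compare_external_errors()`) implements a paired test
  on per-compound absolute errors; it is a reporting aid, never part of
  selection.
* Rule sets require constant consequents; model-tree leaves must be refit as
  regression trees before rule extraction.
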