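---
title: "Inferring protein-protein interaction networks from protein expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring protein-protein interaction networks from protein expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppinet)
```

## The problem

Reverse-phase protein arrays (RPPA) measure a panel of a few hundred
proteins and phosphoproteins across many tissue samples. Which pairs of
those proteins physically or functionally interact is mostly unknown for
any particular pathological condition, yet the co-variation of their
expression across samples carries a signal about it: proteins that
interact, directly or through short signalling chains, tend to be
statistically dependent.

`ppinet` turns a samples-by-proteins expression matrix into a predicted
protein-protein interaction (PPI) network. Because no single inference
statistic dominates, it runs a battery of fourteen methods from four
families, benchmarks each against a curated gold-standard interactome, and
then lets the winners vote:

1. **Inference.** Each method produces a symmetric protein-by-protein
   score matrix (`infer_network()`).
2. **Significance.** Scores are filtered into a sparse predicted network
   (`filter_predictions()`): mutual-information methods keep scores
   strictly greater than zero (their pruning step already embodies the
   significance decision); every other method's scores are referred to a
   Gaussian graphical model (GGM) null and kept at p < 0.05.
3. **Evaluation.** Predictions are scored against a gold standard over
   the pair universe shared by the assay panel and the standard:
   TP/FP/TN/FN, precision, recall and
   \(F = 2PR/(P+R)\) (`confusion_counts()`, `f_measure()`). Indirect
   credit is available by expanding the standard to all pairs within
   shortest-path distance *k* = 2, 3, 4 (`gold_within_k()`).
4. **Consensus.** Per condition, the method with the highest direct
   (*k* = 1) F-measure is its *best method*; the union of best methods
   across conditions forms the global BM set, and each condition gets an
   ensemble network whose edge scores are the fraction of BM methods
   predicting that edge (`build_ensemble()`).

Downstream, predicted and ensemble networks can be validated against
external edge sets (overlap percentages, precision-recall curves, class
tallies, hypergeometric gene-set overlap) and characterised topologically
(summary statistics, minimum dominating sets, collective influence, a
cross-condition core module, and colored non-induced motif counts).

## The fourteen methods and their parameters

| family | methods | score |
|---|---|---|
| correlation | `SPEARMAN`, `PEARSON`, `WGCNA` | correlation coefficient; topological overlap of the \(|r|^\beta\) adjacency |
| partial correlation | `SPC`, `GENENET`, `GLASSO` | partial correlation from the (pseudo)inverse, shrunken, or L1-penalized precision matrix |
| regression | `PLS`, `RIDGE`, `LASSO`, `ELASTICNET` | symmetrized per-target regression coefficients |
| mutual information | `ARACNEA`, `ARACNEM`, `CLR`, `MRNET` | MI after DPI pruning, background z-scoring, or MRMR selection |

All methods standardize columns to zero mean and unit variance first, so
scores live on (or are rescalable to) the correlation scale that the
significance filter assumes. The tunable parameters, with defaults:

* `beta = 6` (`WGCNA`): the customary unsigned soft-threshold exponent.
* `rho` (`GLASSO`): L1 penalty; by default chosen by BIC over
  {0.01, 0.02, 0.05, 0.1, 0.2, 0.5}. `rho = 0` reduces to `SPC`.
* `folds = 10`, `seed` (regression family): k-fold cross-validation for
  the penalty (ridge/lasso/elastic net, mixing fixed at 0.5) or the
  number of PLS components; the fold assignment is seeded so results are
  reproducible. Penalties and component counts can be pinned via
  `lambda` / `ncomp`.
* `estimator`, `bins` (`estimate_mi()`): equal-frequency binning with
  \(\lceil\sqrt n\rceil\) bins by default (a standard bias/variance
  compromise for histogram MI), or the Gaussian closed form
  \(-\tfrac12\log(1-\rho^2)\) capped at \(\rho^2 = 1 - 10^{-12}\) so
  duplicated antibodies give a large finite value rather than infinity.
* `eps = 0` (`aracne()`): the data-processing-inequality tolerance. The
  DPI is evaluated for every triple on the *original* MI matrix and
  removals applied simultaneously, the convention of the original
  algorithm; the alternative sequential removal is order-dependent.
* `alpha = 0.05` (`filter_predictions()`): raw, not multiplicity-adjusted —
  the pipeline's operating point is deliberately permissive because the
  ensemble stage provides the second filter.

Regression coefficients are symmetrized with the sign-consistent
geometric mean: \(s_{ij} = \mathrm{sign}(b_{ij})\sqrt{b_{ij} b_{ji}}\)
when the two directed coefficients agree in sign and are non-zero, else
0. This discards pairs the two regressions disagree about, which is the
behaviour we want from an undirected interaction score. MRMR ties break
towards the lowest variable index so outputs are deterministic.

## The significance model

For the non-MI methods each pair score is treated as a draw from the GGM
null for the partial correlation of an *absent* edge,
\[ f(r;\kappa) \propto (1-r^2)^{(\kappa-3)/2},\qquad r\in[-1,1], \]
equivalently \(r^2 \sim \mathrm{Beta}(\tfrac12, \tfrac{\kappa-1}{2})\).
The single parameter \(\kappa\) (an effective degree of freedom) is
estimated by maximum likelihood from all \(p(p-1)/2\) scores — a
null-dominated fit, justified because true interactions are a small
minority of pairs. The p-value is the two-sided tail
\(P(|R| \ge |r|)\). Numerical choices:

* scores with \(|r| \ge 1\) (duplicated antibodies) carry no likelihood
  information; they are excluded from the fit and receive p = 0;
* if the optimizer fails or runs to a boundary, the analytic fallback
  \(\kappa = n - 1 - (p - 2)\) (the exact null for partial correlations
  given \(p-2\) others) is used;
* methods whose scores are not partial correlations are first mapped to
  the correlation scale: any score matrix with \(\max|s| > 1\) is divided
  by that maximum, and non-negative score families (TOM) are read as
  \(|r|\). This is a pragmatic calibration — the fit is per method and
  per dataset, so each method is filtered against its own empirical null
  shape;
* an all-zero score matrix (a fully shrunken or fully penalized fit) is
  not an error: it filters to an empty prediction.

On draws from the null the fitted filter is well calibrated: p-values are
uniform and the type-I rate at \(\alpha = 0.05\) is 0.05 (this is asserted
by the test suite at 10,000 draws).

## Evaluation conventions

The pair universe is the gold standard's gene set intersected with the
measured genes; pairs outside it are unknowable by construction and are
excluded from TP/FP/TN/FN. "Within *k*" is cumulative — a pair counts at
level *k* if its shortest-path distance in the gold standard is at most
*k* — because each successive indirect level is meant to augment, not
replace, the previous one; exact-distance selection is available via
`cumulative = FALSE` for sensitivity analysis. Best-method selection uses
the direct (*k* = 1) F-measure only, with exact ties broken by the
canonical method listing order (`ppi_methods()`), so the pipeline is
deterministic.

Multiple antibodies per gene (phospho-forms) are kept separate during
inference — they are distinct measurements with distinct interaction
profiles — and collapsed only at edge level when comparing to gene-level
standards: parallel antibody edges merge keeping the maximum-absolute
weight, and edges between two antibodies of the same gene become
self-loops and are dropped.

The BM set is global across conditions (a single ensemble vocabulary
makes consensus scores comparable between conditions), and each
condition's ensemble is built from *all* BM methods run on that
condition's data, not only the condition's own winner.

## PR curves and references

`pr_curve()` sweeps the distinct consensus scores in decreasing order,
scoring each threshold's edge set against a reference over the pair
universe, and appends an all-pairs point (recall 1) only when the last
threshold has not already reached full recall. When a reference resource
covers only part of the panel, pass its gene coverage as
`reference_coverage`: pairs outside the coverage can never be positives,
so they are excluded from the universe rather than being allowed to
deflate precision. With no coverage given, the full universe is used.

Gene-set overlap uses the one-sided hypergeometric tail (enrichment) with
Benjamini-Hochberg adjustment across the collection; pure intersection
reporting is the special case `fdr_max = 1, top = Inf`.

## Topology analytics

* **Minimum dominating set** — exact branch and bound (greedy upper
  bound, branching on the least-coverable undominated node) up to 300
  nodes, greedy beyond that with a warning; lexicographic tie-breaks make
  the result deterministic.
* **Collective influence** —
  \(\mathrm{CI}_\ell(i) = (k_i-1)\sum_{j \in \partial B(i,\ell)} (k_j-1)\)
  over the frontier at distance exactly \(\ell\); the default
  \(\ell = 2\) is the customary small-radius choice and is a parameter.
* **Colored motifs** — nodes must carry one label each, so multi-label
  annotations are first expanded by node replication (a node with *n*
  labels becomes *n* copies inheriting all incident edges). Counting is
  *non-induced*: within every connected node subset of size 3 or 4, every
  connected spanning edge-subset is one occurrence of its canonical
  labeled pattern. Non-induced counts are preferred for inferred PPI
  networks because they are robust to missing edges. Significance uses a
  degree-preserving rewiring null (default 100 rewired networks,
  \(10|E|\) swap attempts each, labels fixed; all seeded), with the
  one-sided p-value "fraction of rewired networks reaching the observed
  count".

## The synthetic benchmark generator

`generate_study()` builds the fixture world the test-suite and the
acceptance script run in: a random truth network (Erdős–Rényi by default,
Barabási–Albert preferential attachment as an alternative), expression
data drawn from a Gaussian graphical model whose precision-matrix support
*is* that truth, and references derived from the truth with controlled
corruption (a tissue-like network keeping 70% of true edges plus 10%
decoys; a non-interacting set sampled from the non-edges; a C1–C4 class
map). The Gaussian graphical model is the deliberate choice of data
model because it is exactly the model class the significance filter
assumes — a generator outside that class would confound calibration
failures with model mismatch.

Default study conditions: 16 conditions (mirroring a multi-cancer RPPA
panel), edge density 0.1, precision off-diagonals of magnitude 0.2–0.4
with random signs (after positive-definite diagonal inflation to minimum
eigenvalue 0.1 and unit-diagonal rescaling, planted partial correlations
land around 0.15–0.35 — weak but recoverable, which is the realistic
regime for RPPA-sized panels). Seed plumbing is one master seed with
per-condition seeds `master + index`; condition-specific re-draws of the
edge-weight magnitudes provide the condition-to-condition jitter around a
shared support. Default problem sizes in the checks are 20 genes × 100
samples (16 conditions) for the end-to-end pipeline and 30 genes × 500
samples for parameter recovery; both are sized so the whole suite runs
comfortably on a laptop while leaving the planted signal clearly
recoverable.

What the generator does *not* emulate: RPPA measurement error and
antibody cross-reactivity, batch effects, heavy-tailed or non-linear
dependencies, and multiple antibodies per gene. Passing tests therefore
demonstrate correctness of the machinery and recoverability under the
filter's own model class — not performance on real RPPA data.

## Known limitations

* The GGM null fit is a null-*dominated* approximation; on dense true
  networks (a large fraction of pairs truly interacting) \(\kappa\) is
  overestimated and the filter becomes conservative.
* Regression methods (L1-penalized neighborhood selection in particular)
  are themselves consistent Gaussian graphical model estimators, so on
  synthetic GGM data they perform within noise of the partial-correlation
  family; which family wins a given condition can be a near-tie.
* Exact minimum dominating sets are exponential in the worst case; the
  300-node exact ceiling is conservative for typical RPPA panels but the
  greedy fallback beyond it is only a \(\ln\Delta\)-approximation.
* Motif counting enumerates connected subsets explicitly; it is meant
  for the sparse inferred networks this pipeline produces (hundreds of
  nodes), not for dense graphs.
* The indirect-k evaluation augments the gold standard; it never rewires
  predictions.

## A minimal run

```{r example, eval = FALSE}
study <- generate_study(p = 20, n = 100, n_conditions = 4, seed = 1)
res <- run_pipeline(study$expressions, study$truth,
                    references = study$references, seed = 1)
res$best_methods
glance(res$ensembles[[1]])
autoplot(res$validation$pr_curves[[1]])
```
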