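---
title: "Cuprotosis patterns and the COPsig score: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuprotosis patterns and the COPsig score: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copsig)
```

## Overview

Copper-induced cell death (cuprotosis) acts through lipoylated TCA-cycle
enzymes, and the expression of its small regulator-gene panel varies
coherently across colorectal tumours. `copsig` implements the full analysis
arc built on that observation: discover expression-defined *cuprotosis
patterns* by consensus clustering over the regulator panel, characterise the
patterns with single-sample enrichment and immune/stromal scores, condense
pattern-associated differential expression into a per-patient **COPsig
score**, relate the score to survival, and extend it to drug-response
prediction and per-cell gene-set activity in single-cell data.

Every stage can run on synthetic cohorts produced by the package's seeded
generators, so the whole pipeline is testable offline; the same functions
accept real cohorts through the TSV/GMT/MTX readers.

## The synthetic cohorts: what they emulate and what they do not

The generators define the study conditions the test suite operates under.

* **Bulk cohorts** (`simulate_bulk_cohort`): log-normal expression with
  additive log2-scale subtype effects. K latent subtypes each own a disjoint
  program (a share of the regulator panel plus a signature block); batch
  membership adds a log-scale offset and a dispersion factor, after the
  biology, and values are exponentiated to an FPKM-like scale. Defaults:
  log2 baseline means `N(4, 1)`, residual SD 0.5 — chosen once as a
  realistic dynamic range and signal-to-noise for RNA-seq after light
  filtering. The multiplicative log-normal model is monotone with counts,
  which is all the rank-based stages downstream require.
* **Survival** (`simulate_survival`): exponential proportional hazards with
  closed-form inverse-CDF sampling, per-subtype log-hazard offsets or a
  linear score effect, independent exponential censoring plus an
  administrative follow-up cap. A Weibull shape parameter would add nothing
  to Cox-recovery tests, so the simpler one-parameter baseline is used.
* **Cell-line panels** (`simulate_cellline_panel`): per-compound response is
  a sparse linear function of log-scale expression plus Gaussian noise, so
  "lower AUC = more sensitive" holds by construction of the signed weights,
  and a seeded NA mask emulates incomplete screening. Roughly 15% of lines
  draw the `haematopoietic_and_lymphoid` label so the lineage-exclusion
  rule always has work to do.
* **Single cell** (`simulate_single_cell`): gamma-Poisson counts with
  per-cell log-normal library sizes, per-type marker programs, and a
  designated signature expressed at two activity levels. Each cell's
  activity mode is Bernoulli with a per-type probability (macrophages 0.10,
  epithelial 0.75, T cells 0.60 by default), which is how the
  "macrophage-enriched low-activity group" structure is planted.

None of the generators models CNV, read-level noise, probe effects,
cell-type deconvolution ground truth, or dropout beyond what gamma-Poisson
sampling produces. Passing tests therefore demonstrate that the machinery
is correct and well calibrated under these models — not that real cohorts
satisfy the models.

## Preprocessing

FPKM is converted to TPM by column normalisation (`fpkm_to_tpm`), and all
linear statistics run on `log2(TPM + 1)` (`log2_tpm`); the +1 offset is the
conventional choice and is not critical for any rank-based stage. Batch
correction (`combat_correct`) is the parametric empirical-Bayes
location-scale adjustment, with no covariates, delegated to `sva::ComBat`.
One subtlety the tests make explicit: TPM renormalisation absorbs any
*sample-wide* scale shift, so a planted uniform batch offset must be
assessed on the log-FPKM scale; gene-specific batch effects, which is what
real batches produce, survive TPM and are what ComBat removes in practice.

## Consensus clustering and choosing k

`consensus_cluster` is the Monti resampling scheme: repeatedly subsample a
fraction of samples (default 0.8, samples only, no gene resampling), run the
base clusterer for each candidate k, and record for every sample pair the
fraction of co-clusterings among co-samplings. The base clusterer is k-means
with 10 restarts on per-gene z-scored features — the reference
implementation's default in spirit; the inner algorithm is exposed nowhere
because swapping it would change nothing the consensus machinery depends
on. Pairs never co-sampled get consensus 0 (conservative and deterministic;
the count is logged). Final per-k partitions cut an average-linkage tree of
`1 - consensus`.

`select_k` minimises the proportion of ambiguous clustering,
`PAC = F(0.9) - F(0.1)` of the off-diagonal consensus CDF, as the
reproducible surrogate for visual CDF inspection. One design point was
genuinely open: with strongly separated clusters, PAC saturates at 0 for
*every* k at or below the true count, because merging two well-separated
clusters is itself a stable operation — so "ties break toward smaller k"
would systematically undershoot planted truth. Exact PAC ties are therefore
broken by the secondary diagnostic, the area under the consensus CDF: the
finer stable partition (larger area, lower mean consensus) wins, and only
the fully degenerate all-tie (areas all zero, e.g. a single point mass)
falls back to the smallest candidate. A `low_confidence` flag is raised
when even the best PAC exceeds 0.25, the regime where no partition is
stable (pure noise behaves this way).

## Enrichment scores

`ssgsea_score` is the classic single-sample enrichment: rank genes per
sample (ties mid-ranked), weight in-set cumulative mass by `rank^alpha`
(`alpha = 0.25`), subtract the uniform out-of-set mass, and *integrate* the
running sum over all positions (not its maximal deviation). Scores are
rank-based, hence invariant under monotone transforms of a sample, and
optionally min-max normalised over the whole set-by-sample matrix.
ESTIMATE-style immune/stromal scores are unnormalised ssGSEA enrichments
with the combined score their sum; `tmescore` is the difference of two
opposing signatures, so swapping them negates it. The kernel-CDF set
variation method is deliberately replaced by ssGSEA plus a per-set
z-score mean (`pathway_activity(method = "zscore")`); the two surrogates
bracket it in smoothness and both are exactly testable.

The package ships no curated immune signature GMTs — the 23-cell-type
catalogues in circulation are licence-encumbered and their provenance
varies; synthetic program sets drive all tests, and user GMTs drive real
analyses through `read_gmt`.

## Survival machinery

Kaplan-Meier, log-rank and Cox fits wrap the survival package; Cox uses
Breslow tie handling (stated explicitly because the upstream analysis is
silent), Newton-Raphson with `eps = 1e-9`, at most 50 iterations, and a
monotone-likelihood guard that caps coefficients at ±20 with a
non-convergence flag. Differential expression is the limma moderated
linear-model pipeline: two-group contrasts give a moderated t, more groups
a moderated F, both BH-adjusted with the significance flag at adjusted
p < 0.05. The shared-DEG construction is one-vs-rest per pattern
(fold change = cluster-of-interest minus rest) intersected across patterns.

`optimal_cutpoint` scans unique score values inside the [0.1, 0.9] quantile
window, maximising the standardised two-group log-rank statistic, and
reports a permutation p-value (default 1000 permutations, seeded) rather
than an asymptotic maximally-selected-rank correction: the permutation is
exact by simulation, accounts for the selection over candidates, and is far
easier to validate. The scan uses a vectorised O(n) log-rank kernel so the
permutation loop stays fast.

## The COPsig score

Construction, in order:

1. **Partition** (`partition_signature`): clusters are ordered by their KM
   median survival (a curve that never reaches 0.5 counts as best), each
   sample carries its cluster's prognostic rank, and each candidate gene
   joins signature A if its Spearman correlation with that rank is
   positive, signature B if negative. Zero or undefined correlations drop
   the gene with a warning.
2. **Prognostic prefilter** (`prognostic_filter`): univariate Cox per gene,
   keep Wald p < 0.05 — mirroring the reduction of shared DEGs to a
   prognostic subset before feature selection.
3. **Reduction** (`boruta_select`): the shadow-feature scheme — per
   iteration, append a column-shuffled copy of every feature, fit a ranger
   forest, count features beating the maximal shadow importance; a
   two-sided binomial test against Binomial(n_iter, 1/2), Bonferroni over
   features, declares confirmed/rejected, the rest tentative. The target is
   the cluster label (exposed as an argument; a survival-derived target is
   equally valid and one line away).
4. **Score** (`compute_copsig`): per signature, z-score genes, take PC1
   over samples, and fix the PCA sign so PC1 correlates positively with the
   signature's mean z-expression — without that convention the score's sign
   is irreproducible. The per-patient score is `PC1A - PC1B`. The upstream
   formula is typeset as a product of sums, but a product cannot carry the
   signed, direction-interpretable prognostic meaning the surrounding
   analysis relies on; the difference reading follows the
   expression-grading-index scheme that analysis cites, and signature
   swapping negating the score is enforced by test.
5. **Split** (`split_groups`): high means strictly above the threshold,
   ties go low; the median rule is the default, with a fixed-cutoff mode
   for externally supplied thresholds.

## Drug response

`filter_panel` applies the stated panel hygiene: drop haematopoietic and
lymphoid lines outright, then drop compounds whose NA fraction — computed
after the lineage exclusion — strictly exceeds 20% (a compound exactly at
the boundary stays). `knn_impute` fills remaining gaps from the k = 5
nearest lines by Euclidean distance over mutually observed compounds,
skipping neighbours that also lack the compound and falling back to the
column mean when none qualifies.

`train_ridge` solves the literal normal equations
`(X'X + lambda I)^-1 X'y` on gene-standardised expression with the response
standardised per compound (predictions return to the original scale), and
picks lambda from a `10^(-2..4)` grid by mean 10-fold cross-validated
Spearman correlation. The closed form is kept deliberately — the package's
contracts pin exact toy solutions that penalised-regression libraries with
their own lambda scaling cannot reproduce. `predict_response` projects
tumour samples onto the model, optionally homogenising the two cohorts
first by running the concatenated matrices through ComBat with a two-level
batch label; missing model genes contribute zero after standardisation.

## Single-cell activity

Counts are normalised to counts-per-10k and `log1p`-transformed before
variance ranking (`select_hvg`, ties broken lexicographically so the
selection is deterministic). `aucell_score` ranks each cell's genes
(descending, ties stable by gene id), counts set genes among the top 5% by
default, and normalises the recovery-curve area by its maximum; toy tests
use larger fractions so the cutoff stays at one gene or more.
`aucell_threshold` fits a two-component Gaussian mixture and thresholds at
the equal-posterior crossing between the means; when the mixture
degenerates the deepest density valley between the two highest modes is
used, and genuinely unimodal distributions take the fall-back with a
warning. Cell clustering and annotation are intentionally out of scope —
composition analysis (`composition_by_group`) consumes labels from the
generator's ground truth or from the user.

## Numerical choices and degenerate inputs

* Spearman p-values use the t approximation on mid-ranks everywhere;
  constant vectors yield missing correlations rather than errors wherever a
  table is being filled, and errors where a single value is the output.
* PAC tie tolerance is 1e-8 (exact ties up to float noise); the
  low-confidence PAC floor is 0.25.
* Cox convergence: `|dbeta| < 1e-9` or 50 iterations; separation caps at
  ±20.
* Readers reject duplicate ids and negative values naming the offenders;
  generators validate their specs naming the field.
* All stochastic stages take explicit integer seeds, and the pipeline
  derives stage seeds from one master seed, so reruns are bit-identical
  (the manifest's md5 checksums are compared in the tests).

## Problem sizes

The packaged demo (`demo_config`) uses a 600-gene, 180-sample, 3-subtype,
2-batch cohort, 100 consensus repetitions over a 10-gene regulator panel, a
60-line/3-compound cell-line panel and a 500-cell single-cell cohort —
sizes chosen so a complete run takes seconds while every stage still has
the statistical structure it needs (both signature directions populated,
stable consensus, bimodal activity). The reference analyses these stages
mirror ran at meta-cohort scale (a thousand-plus patients, 1,000 consensus
repetitions); nothing in the implementation is specific to the demo sizes.

## Known limitations

* The z-score pathway surrogate and ssGSEA bracket, but do not reproduce,
  kernel-CDF set variation scores.
* Immune phenotype labelling (excluded/desert/inflamed) is an
  interpretation layer over the enrichment outputs; the package computes
  the scores and leaves the labels to the analyst.
* T-cell dysfunction/exclusion response predictors, deconvolution methods,
  ligand-receptor inference and trajectory analysis are out of scope.
* The exponential survival generator has constant baseline hazard;
  time-varying effects and competing risks are not modelled.
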