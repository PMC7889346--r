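---
title: "Ranking drug-target interactions with adversarial BPR: model, choices, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug-target interactions with adversarial BPR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bprdti)
```

## The model and its assumptions

`bprdti` poses drug-target interaction (DTI) prediction as personalized
ranking. The data are, per cell line: a drug expression-profile matrix
(one row per compound, 978 features in L1000-style data), a target/
non-target profile matrix on the same features, and a list of positive
(drug, target) pairs. Targets that interact with *no* drug in the cell
line form the **non-target pool**; negative training pairs are sampled
from drug x non-target cells because an unannotated pair with a known
target may simply be an undiscovered interaction, whereas a non-target has
no interaction record at all. One negative is sampled per positive, so
ranking supervision is balanced at the cell-line level (the count is
matched globally, not per drug, since the data constrain it only at that
level).

Each positive (i, j) and each sampled negative (i, k) of the same drug
combine into partial-order triples (d_i, t_j, t_k): "drug i scores target
j above non-target k". By default a drug's triple group is the full cross
product of its positives and its sampled negatives, matching the
set-definition of the per-drug group; a `paired` mode (one negative per
positive, in per-drug index order) is available where a leaner triple set
is wanted.

Scores are inner products of latent factors, r_ij = F^D_i . F^T_j. The
training objective per triple is

* the BPR term `-ln sigma(r_ij - r_ik) + lambda_theta * (||F_i||^2 +
  ||F_j||^2 + ||F_k||^2)` — maximize the posterior probability of the
  observed ordering under a Gaussian prior on the factors;
* `lambda_adv` times the same ranking term re-evaluated at adversarially
  perturbed factors: each of the three factor blocks is shifted by the
  ranking-loss gradient normalized to L2 norm `epsilon` (fast-gradient).
  The perturbation is recomputed at every update, treated as a constant
  within the update, applied only to the three rows the triple touches,
  and budgeted per block — the norm constraint in the minimax formulation
  does not say whether the budget binds the concatenation or each block,
  and the per-block reading is the established convention in adversarial
  matrix factorization. The L2 regularizer is applied once, at the
  unperturbed parameters; re-applying it at the shifted parameters would
  double-count it.
* `lambda_sim` times the **dual similarity** penalty
  `sum_l (S_il - exp(-||F_i - F_l||^2))^2` for the drug row and both
  target rows, where S is a profile-similarity matrix. The Gaussian kernel
  of latent distance lives in (0, 1]; similar entities are pulled
  together, dissimilar ones pushed apart. The sum runs over *all* entities
  of the relevant side at every update (O(m f) per triple at the desk
  scales this package targets).

Assumptions worth stating: interactions are independent given the factors;
profile similarity is informative about interaction similarity (the
premise that perturbation and knockout signatures of interacting pairs
correlate); and a single global latent dimension f captures both sides.

## Similarity kernels and their numerical edges

Four kernels are available for both the drug-drug and the target-target
matrix: continuous Tanimoto `x.y / (||x||^2 + ||y||^2 - x.y)`, cosine,
a *global* SSIM (means, variances, covariance computed once over the whole
978-vector — no sliding window, since the vector is an expression
signature, not an image; population 1/n moments; stabilizers c1 = c2 =
0.001), and Spearman rank correlation computed from the rank-difference
formula with average ranks on ties.

Cosine, Spearman, and Tanimoto can be negative on real-valued profiles,
but the Gaussian latent kernel they are matched against cannot: a negative
similarity has no attainable latent distance. By default negatives are
clamped to zero (`clamp = TRUE`), which reads "dissimilar or
anti-similar" uniformly as "should be far apart in latent space". The
Tanimoto denominator can reach zero only for zero or pathologically
anti-parallel vectors; that is treated as an error rather than silently
patched. These conventions are the package's own resolution of a gap the
formulation leaves open.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `factor_size` | 25 | latent dimension; the response curve flattens near 25 on data whose intrinsic rank it brackets |
| `lambda_theta` | 0.1 | L2 weight on the triple's three factor rows |
| `lambda_sim` | 0.5 | dual-similarity weight; 0 disables the regularizer |
| `lambda_adv` | 0.3 | adversarial weight; 0 reduces training to plain BPR |
| `epsilon` | 0.1 | L2 budget of each perturbation block (dimensionless, latent units) |
| `learning_rate` | 0.03 | SGD step size |
| `n_epochs` | 100 | fixed pass count; no early stopping (none is defined for the method), the per-epoch mean loss trace is recorded instead |
| seed | 1 | governs initialization, shuffling, sampling |

Factors are initialized from N(0, 0.01^2): small enough that initial
scores are effectively zero and the first updates are driven by the
ranking signal, large enough to break symmetry. Updates to the three
touched rows are accumulated across all three loss components and applied
simultaneously (not Gauss-Seidel), so the trainer with
`lambda_adv = lambda_sim = 0` reproduces a plain BPR trajectory exactly —
the test suite asserts bit-for-bit equality against an independent
reference implementation. `-ln sigma(x)` is evaluated in softplus form, so
score gaps of several hundred neither overflow nor lose the gradient.

## What the synthetic generator emulates — and what it does not

`synthetic_dti()` plants factors G_D (m x f_true), G_T (n x f_true) from a
standard Gaussian, makes the top `interaction_rate` fraction of planted
scores among true-target columns the positives, and embeds the factors
into `F_dim` features through a fixed orthonormal random map (scaled to
unit-variance entries) plus Gaussian noise. Profile similarity therefore
correlates with factor similarity by construction, and with zero noise the
cosine similarity of two profiles equals that of their planted factors
exactly. Positives are *thresholded* from planted scores rather than
sampled through a logistic link — recovery analysis is cleaner when the
planted ordering is deterministic.

Defaults are a desk-scale shrink of a typical cell-line dataset: 60 drugs,
40 true targets, 300 non-targets, rank 5, 978 features, 5% positive rate
(120 positives), noise sd 0.3 against unit-variance signal entries. Real
catalogues are ~10x larger per side with a ~0.4% positive rate; the shrink
keeps every experiment in seconds while preserving the structural facts
the method relies on (sparsity, a large non-target pool, low-rank signal,
feature-similarity informativeness). What the generator does **not**
emulate: transcriptomic covariance structure (genes are exchangeable
here), cell-line batch effects, heavy-tailed popularity of real targets,
and label noise. Passing recovery tests on this data therefore
demonstrates the machinery — triple construction, optimization, gradients,
regularization, evaluation — not real-data performance.

## Evaluation protocols, leakage, and the negative control

Two protocols coexist, deliberately.

**Triple-level cross-validation** (`split_cv(by = "triple")`, the default,
and `bpr_dti(cv_fold = ...)`): triples are dealt to drug-stratified folds;
a positive pair generally contributes triples to several folds. This is
the protocol of the headline experiments the method reports elsewhere and
of the capacity sweep below, but it *leaks*: the held-out triples' positive
pairs were trained on, so its numbers measure reconstruction plus mild
generalization, not cold prediction.

**Strict pair-level holdout** (`split_cv(by = "pair")`,
`holdout_experiment()`): each positive pair belongs to exactly one fold,
held-out pairs never occur in training triples, and held-out AUC is
computed on *fresh* triples whose negatives are cross-drug decoys —
targets of other drugs' held-out positives that do not interact with the
drug at hand. The decoy choice matters: ranking held-out positives against
never-trained non-target columns still rewards a model that has merely
learned column popularity (positives live in popular columns,
size-biasedly, even under a label permutation), which keeps a
permuted-label control well above chance. Cross-drug decoys are drawn from
the same size-biased column distribution as the positives, so under a
label permutation positives and decoys are exchangeable and the control
AUC centers on 0.5. A single permutation replicate still has a standard
deviation of roughly 0.08 at the default test size (~20 evaluated drugs,
per-drug AUCs near-uniform under the null), so the control is reported as
a mean over ten permutation replicates.

The candidate pool for Top-k / precision / AUPR / NDCG is the full target
set minus the drug's training positives ("filtered" ranking, switchable to
"full"), so recovering a training edge is not penalized. Ties follow the
printed conventions: a tied competitor pushes a positive down (the `>=`
count), and tied triples contribute zero to AUC (strict `>`). AUPR
integrates the per-drug (recall, precision) sweep by trapezoid, anchored
at recall 0 with the precision of the top-ranked item; NDCG uses binary
gains with the 1/log2(rank + 1) discount. Per-drug metrics average drugs
with equal weight.

On "nested" cross-validation: the outer 5-fold loop is used for
reporting; where hyperparameters are selected, the natural reading is an
inner 4:1 split of each outer-training set, and the splitting primitives
support exactly that composition. The pipeline itself trains at fixed
defaults and does not tune.

## Enrichment statistics

Predicted edge lists are validated by fold enrichment
`ES = (k/n)/(m/N)` — the printed form of the statistic is typographically
collapsed in the source material and is implemented as this standard fold
ratio, consistent with the hypergeometric test it accompanies — with
`P(X >= k)` from the hypergeometric distribution (log-space internally)
and BH correction across reference sets. Reference sets are intersected
with the in-scope drug x target universe before any counting. Overlap
curves count reference hits in consecutive bins of 500 ranked predictions
(stride = bin size; an overlapping stride is available), and the "top 1%"
predicted set is cut *after* removing known training interactions. Note
that BH re-adjustment is not idempotent (re-applying the step-up rule
inflates already-adjusted values); the adjusted values are final.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run: gradient checks on 100
random instances (f <= 6, <= 8 entities); adversarial-dominance checks
against 200 random same-norm perturbations on 5 instances; recovery and a
10-replicate permuted control on the default 60 x 40 x 300 dataset with
`factor_size = 5` (the planted rank); the capacity sweep over factor sizes
{5, 10, 25, 40} and the `lambda_sim` sweep over {0, 0.3, 1.25}, each
averaged over 3 replicate seeds. These sizes were chosen so the full suite
runs in a few minutes on one CPU while keeping every statistical check
adequately powered.

## Known limitations

* Pure-R SGD: adequate at desk scale; catalogues with 10^5+ triples would
  want a compiled inner loop.
* The similarity sum per update touches all entities of a side; for very
  large sides a top-q neighbor subsample would be the natural speedup.
* Identifier handling is plain strings; no cross-referencing of compound
  or gene identifiers.
* The generator's exchangeable-gene noise model understates the
  correlation structure of real expression data; kernels that exploit that
  structure (notably SSIM) are exercised but not stressed.
* With triple-level folds, reported metrics overstate cold-start
  performance; use the strict protocol when that is the question.
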