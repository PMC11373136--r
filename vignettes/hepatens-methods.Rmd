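---
title: "Hybrid ML/DL ensembles for hepatotoxicity QSAR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid ML/DL ensembles for hepatotoxicity QSAR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Drug- and chemical-induced liver injury is a binary endpoint that can be
approached as a QSAR classification problem: learn a map from molecular
structure to the probability that a compound is hepatotoxic. No single
learner family dominates this task — nearest-neighbour methods exploit local
structural similarity, kernel machines and forests capture different
interaction structure, and small neural networks add a complementary,
smoothly parameterized decision surface. `hepatens` therefore implements a
*heterogeneous ensemble*: four shallow learners (KNN, RBF-kernel SVC with
Platt-calibrated probabilities, random forest, extremely randomized trees)
plus one or two small neural members (a two-layer LSTM over the folded
feature vector, and an MLP), combined by soft or hard voting, bootstrap
bagging, or logistic stacking on out-of-fold probabilities.

The pipeline has five stages, each exposed as ordinary functions:

1. **Curation** (`curate_compounds`): canonicalize SMILES, then apply, in a
   fixed order, parseability, single-fragment (mixture), carbon-content
   (inorganic), duplicate-collapse and ambiguity rules. The fixed order
   makes exclusion counts reproducible. Conflicting duplicate labels are
   treated as ambiguous activity and all copies are dropped: a structure
   reported both toxic and non-toxic carries no usable signal at this
   granularity. Rows with explicitly ambiguous labels are excluded before
   duplicate collapsing, so each excluded row carries exactly one reason.
2. **Featurization** (`compute_descriptors`, `morgan_fingerprints`): three
   representations — a fixed physicochemical panel; an extended 2D panel
   adding classical topological indices (Wiener, Zagreb, Randic, Balaban J,
   kappa shape, eccentricity-based) computed from the heavy-atom graph; and
   hashed circular fingerprints (the ECFP family; diameter = 2 x radius),
   folded by OR-ing blocks down to `n_bits`. Columns with any missing or
   non-finite value are dropped wholesale (`clean_features`) rather than
   imputed: descriptor failures are structural, not random, and imputation
   would invent chemistry.
3. **Feature selection** (`rank_features`, `sequential_elimination`,
   `select_optimal_subset`): features are ranked once (impurity importance
   of a seeded forest by default; a univariate |AUC - 0.5| ranker is the
   alternative), then the lowest-ranked block is removed step by step. Each
   step refits an evaluator on an internal stratified 80/20 split *of the
   training rows only* and records the validation AUC and the contribution
   statistic (AUC_w - AUC_i) / AUC_w against the all-features baseline.
   Scoring steps on the untouched test set would leak selection information
   into the final evaluation, so the test rows never participate.
4. **Ensembling** (`tox_ensemble`): members are fitted on the full training
   matrix (voting), on bootstrap resamples (bagging), or with an additional
   logistic meta-learner trained on stratified out-of-fold member
   probabilities (stacking). Member weights are always equal.
5. **Evaluation** (`classification_metrics`, `cross_validate`,
   `repeated_holdout`, `one_way_anova`): confusion-matrix metrics, rank-based
   AUC, stratified k-fold cross-validation that re-runs the *entire*
   pipeline inside each fold, repeated stratified holdouts reported as
   mean +- SD, and classical one-way ANOVA for comparing metric groups.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| fingerprint radius / bits | 2 / 2048 | ECFP4-equivalent; bits configurable (1024-bit variants exist in the literature) |
| KNN k | 5 | neighbour vote fraction is the probability |
| forest trees | 500 | the grid 100/300/500/700 is available as a vector, resolved by internal validation AUC |
| SVC | RBF, C = 1 | Platt calibration enabled; soft voting needs probabilities |
| LSTM | 2 layers x 64 units, dropout 0.2, lr 0.001, 10 epochs, batch 128 | Adam, BCE, forget-gate bias 1, per-layer gradient-norm clip 5 |
| LSTM `seq_len` | 32 | see below |
| MLP | hidden 100-50, max 500 iterations | full-batch Adam, ReLU, early stop on loss plateau; non-convergence warns but returns the model |
| test fraction | 0.2 | stratified |
| elimination step | 5% of features (min 1) | full trace always reported |
| bagging replicates | 5 per member | |
| stacking folds | 5 | logistic meta-learner |
| decision threshold | 0.5 | label = 1 iff p >= threshold; hard-vote ties go to class 1 (screening favours sensitivity) |

**LSTM input shaping.** A fingerprint is not a sequence; feeding it to a
recurrent layer requires choosing a sequence axis. One scalar per timestep
(sequence length = number of features) is the most literal reading, but
backpropagation through 2048 timesteps is prohibitively slow on a single
CPU and adds nothing statistically — the bits have no meaningful order
either way. The package therefore folds the vector into `seq_len = 32`
timesteps of `n_features/32` channels by default; `seq_len` is configurable
up to `n_features`, which recovers the scalar-per-timestep variant exactly.

**Scaling.** The min-max scaler is fitted on training rows only and applied
to evaluation rows with clipping to [0,1]; constant training columns map to
0. Fitting the scaler on all rows before splitting would be a (mild) leak.
Fingerprint matrices pass through scaling unchanged since bits are already
in [0,1].

## The synthetic generators

The reference datasets for this endpoint are assembled from literature and
toxicology databases and are not deposited in machine-readable form, so the
package ships two seeded generators that stand in for them.

`planted_fingerprints()` emulates the *statistical* shape of a fingerprint
QSAR problem: 2048 binary features of which 40 are informative, firing with
rate 0.7 in positives and 0.3 in negatives over a 0.1 background rate, 600
compounds, positive fraction 0.625 (mirroring the roughly 1618/970
imbalance of the assembled literature data). These defaults are the study
conditions for all quantitative tests; the informative indices are returned
so recovery can be measured directly. The background rate 0.1 reflects the
sparsity of hashed circular fingerprints on drug-like molecules.

`rule_labeled_smiles()` emulates the *chemical* path: scaffolds (benzene,
pyridine, phenol, toluene, alkyl chains, cyclohexane) decorated with
substituent pairs, labeled by a decidable structural rule (nitro group
present — a classic structural toxicity alert), with optional label noise
and deliberate duplicates so curation has work to do. Nitro is drawn with
probability 0.45 so classes stay usable after deduplication.

What passing tests on these generators shows: the machinery — curation,
hashing, ranking, elimination, voting, calibration, fold hygiene — behaves
correctly on problems whose ground truth is known. What it does not show:
performance on real hepatotoxicity data, whose structure–label relationship
is far weaker, noisier and more heterogeneous than a planted Bernoulli
signal or a single substructure rule. Absolute AUCs on the generators are
far higher than anything achievable on the real endpoint.

## Numerical choices and degenerate cases

- 0/0 metrics (e.g. sensitivity with no positives) are reported as `NA`,
  never silently 0.
- AUC is rank-based with ties counted one half; it equals all-pairs
  concordance counting (property-tested against a brute-force oracle).
- The AUC of a model with zero features is defined as chance, 0.5.
- `select_optimal_subset` breaks AUC ties toward fewer features.
- Feature-ranking ties break lexicographically by name, so rankings are
  deterministic.
- One-way ANOVA with zero within-group variance: equal means give F = 0,
  p = 1; unequal means give infinite F with p at the smallest positive
  double rather than an exact zero.
- All stochastic components (splits, folds, forests, SVC calibration,
  neural initialization, batching, dropout, bootstrap) are driven by
  explicit seeds; fits are bit-reproducible, and internal seeding never
  perturbs the caller's RNG stream.

## Problem sizes used by the test suite

The quantitative suites run the planted generator at its default design
point (600 x 2048, three or five seeds depending on the check) and the
chemistry path at 500 molecules; unit-level checks use smaller instances
(typically 100-300 rows, 32-512 bits) chosen to keep the full suite fast
on one CPU while leaving every statistical conclusion comfortably inside
its tolerance.

## Known limitations

- Canonicalization-level deduplication only: salts and solvates are removed
  as mixtures rather than stripped to parent structures, and tautomers are
  not standardized, so counts can differ from curation schemes that do
  either.
- The physchem/extended descriptor panels are those computable from the
  OpenBabel/ChemmineR toolchain plus in-package graph indices — a few dozen
  columns, not the several hundred of larger descriptor engines; tests
  accordingly assert properties of the panels, not their size.
- The OpenBabel SMILES parser silently repairs some malformed inputs; a
  syntactic pre-check (bracket/parenthesis balance, character set) restores
  strictness, but exotic malformed strings that survive both are
  conceivable.
- Class imbalance is left as-is (no reweighting or resampling), matching
  the reference setup; on imbalanced data the ensembles consequently show
  high sensitivity and mediocre specificity.
- No applicability-domain estimation: predictions far outside the training
  chemistry are extrapolation without warning.
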