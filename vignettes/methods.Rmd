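---
title: "Methods: metaheuristic filtering and prototype-reduced weighted KNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaheuristic filtering and prototype-reduced weighted KNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in `dasd`,
the assumptions behind them, the design decisions that were genuinely open,
and the limits of what the synthetic validation can show.

## The diagnostic problem and the two-layer design

The package targets binary diagnosis from a small, wide biomarker table:
roughly 150 samples in two near-balanced classes ("ASD" cases, coded 1, and
"TD" controls, coded 0), tens to hundreds of continuous protein-level
features, a minority of them informative, and a fraction of corrupted
training rows. Two layers process the data in order:

1. **Data filter layer.** Wrapper feature selection (`run_bgwo()`) followed
   by training-row rejection (`run_bga()`), both scored by the validation
   accuracy of an internal weighted-KNN classifier.
2. **Diagnostic layer.** An ensemble selector (`run_edm()`) fits member
   classifiers on the filtered training split and promotes the member with
   the highest validation accuracy; despite the "majority voting" name
   common for this construction, it is a single-winner argmax, and ties are
   broken by member order (SVM, DLA, EKNN).

Both filter stages need a held-out validation split for their wrapper
scores, so `dasd()` performs one stratified train/validation/test split
first and reuses it across stages. The validation and test proportions are
not prescribed by the design the pipeline follows; the package defaults to
60/20/20, a conventional compromise between training size and score
resolution at this cohort scale. Ten-fold stratified cross-validation
(`kfold_indices()`) is provided as the alternative evaluation protocol.

## Naive-Bayes weighting

`fit_weighting()` z-scores each feature with training-split statistics
(protein levels span orders of magnitude; unstandardized Euclidean
distances would be dominated by high-abundance analytes) and fits Gaussian
class-conditional parameters per class and feature, with the standard
deviation floored at `1e-6` so constant features cannot degenerate.

The mapping into weight space is the one genuinely open design point of
this stage: the construction it follows states only that a naive-Bayes
step converts features into per-class weights reflecting each feature's
support for each class, without printing a formula. The package defines
the coordinate of feature $f$ for class $c$ as normalized evidence

$$w_{cf}(x) = \frac{p_{cf}(x_f)}{p_{0f}(x_f) + p_{1f}(x_f)},$$

the minimal naive-Bayes-derived quantity with that meaning. It is bounded
in $[0,1]$, the two class coordinates of a feature sum to one, and the map
is monotone in the class density ratio — all properties the test suite
asserts. Computation goes through log densities so tail samples (e.g.
corrupted rows at six standard deviations) remain well-defined. This
choice is implementation-defined and any downstream result depends on it.

## Chimp-optimization prototype generation

`run_coa()` replaces the weighted training set (size $Q$) with $N_C$
artificial New-cases per class, encoded in each agent as a real vector of
dimension $Dim = A \cdot N_C \cdot Y_D$ laid out class-major (positive
class block first, then New-case, then coordinate). The fitness of an
agent is the fraction of training cases recovered by a $K$-nearest-neighbor
vote over its decoded New-cases. The search follows the chimp-hunting
scheme: four fitness-ordered leaders (attacker, barrier, chaser, driver)
generate per-leader candidates

$$Ch_k = L_k - Ac_k \, |Cc_k L_k - mc \odot x|,$$

averaged into the new position with probability one half, and a chaotic
relocation otherwise. Coefficients: $fc = 2 - 2\,itr/Max\_itr$;
$Ac_k = |2\,fc\,rc_{k1} - fc|$ and $Cc_k = 2\,rc_{k2}$, with the random
factors $rc$ drawn as uniform deviates scaled by eight group-specific
dynamic coefficients whose schedules mix quarter-power, third-power and
cubic terms. Those schedules are deliberately implemented exactly in their
printed, mutually inconsistent forms (they are part of the method's
definition, not free parameters), which means $rc$ can exceed 1 early in a
run even though it is nominally a "random factor between 0 and 1".

Three further points were under-determined and resolved as follows:

* **The chaotic term.** The source formula $mc = Ch_i^2 - u$ with $u = 1$
  is not confined to $[0,1]$ for arbitrary positions, although the scheme
  requires a chaotic value in that range, and assigning a scalar chaotic
  value as a new position vector is dimensionally ill-defined. The package
  normalizes each coordinate to $s = (x - lo)/(hi - lo)$, uses
  $mc_d = |s_d^2 - u|$ (guaranteed in $[0,1]$ for in-bounds positions), and
  relocates per dimension as $x_d = lo + mc_d (hi - lo)$. This is the
  minimal reading that satisfies both stated requirements.
* **Leader replacement.** The loop description is silent on elitism. The
  package replaces a leader only with a strictly fitter agent, which makes
  the attacker's fitness monotone non-decreasing — an invariant the test
  suite checks over full 100-iteration runs — and makes longer runs never
  worse than shorter ones under a fixed seed. Leader ranking ties break by
  agent index.
* **Randomness injection.** Each update's ~14 random quantities are drawn
  outside the arithmetic and passed in as a coefficient bundle, so every
  equation is unit-testable against pinned draws and a scalar per-dimension
  oracle.

Bounds default to $[0,1]$ per dimension — the range of the weight space —
and positions are clipped after every update. The stopping rule is the
iteration cap alone (default 100); no other convergence criterion is
defined by the scheme. The prototype count must strictly shrink the data
($N_C \cdot Y_D < Q$); violating configurations are errors.

## EKNN and the ensemble

`eknn()` chains weighting, prototype generation and KNN prediction.
Prediction ties are deterministic: distance ties go to the lower-index
prototype and an even vote split to the nearest neighbor's label. Two
reduction switches define reference limits used throughout the tests:
`reduce = FALSE` yields exactly the weighted-KNN classifier over the full
training set, and additionally `weight = FALSE` yields plain KNN on
z-scored features. `K` defaults to 3, the error-minimizing value for this
classifier family on panels of this shape; `select_k()` re-derives it from
a validation split (ties to the smallest candidate).

The SVM ensemble member uses a linear kernel with cost 16; the
deep-learning member is realized as a single-hidden-layer feed-forward
network (32 units, weight decay 0.01) over z-scored features — the member
contract deliberately wraps established implementations rather than
re-implementing their training mathematics. A logistic-regression member
is bundled as an always-available fallback. A member that fails to fit is
dropped with a warning; the ensemble proceeds while at least one member
remains.

## The synthetic generator and what it does (not) show

`synthetic_spec()` defaults encode the cohort the pipeline was designed
around: 154 samples (76 cases / 78 controls), 50 features of which 15 are
informative, 10% corrupted rows. Informative features are class-conditional
Gaussians with a per-feature standardized mean gap (`effect_size`, default
2.0 — the separability at which a plain 1-NN classifier on the informative
features alone clears 90% holdout accuracy, the generator's documented
sanity floor); noise features are identically distributed in both classes.
Corrupt-mode outliers redraw every feature of a row uniformly in
$[\mu + 6\sigma, \mu + 10\sigma]$ of its clean class-conditional
distribution — unambiguous ground truth for rejection experiments; a
label-flip mode is also provided. Generation is bit-reproducible under the
spec's seed.

The generator deliberately omits real-data features: protein–protein
correlation (features are independent), heavy tails, batch effects, and
missingness. Passing recovery tests on these panels therefore shows that
the optimizers do what their objectives ask on clean planted structure —
not that the pipeline's clinical performance claims transfer.

One consequence of the default separability deserves emphasis because the
acceptance-level recovery checks compute it directly. At a per-feature gap
of 2.0, a handful of informative features already saturate wrapper
validation accuracy on a 31-sample validation split. On that plateau the
sparsity penalty (default 0.01, proportional to the selected fraction) is
the only non-flat direction, so the wolf-pack selector converges to a
*minimal* discriminative subset: high precision (noise features are
discarded) but low recall of the full planted panel. For the same reason
the row-rejection objective — validation accuracy of the kept-row
classifier — is flat in the planted outliers: the classifier is already
perfect with them kept, so the elitist GA correctly returns the all-keep
mask it is seeded with. These are properties of the pinned wrapper
objectives at this separability, not search failures; the corresponding
recovery assertions in the acceptance tests document them as such. On
harder panels (smaller effects, or validation splits large enough to
resolve single-feature contributions) the same objectives do grade
candidate masks, which is the regime where wrapper filtering earns its
cost.

## Numerical and procedural choices

* Stratified splitting uses largest-remainder quotas per class, so parts
  partition the cohort exactly and class proportions stay within one
  sample of global; k-fold assignment is round-robin per class with a
  rotating offset, keeping fold sizes within one sample of each other.
* BGWO binarizes continuous wolf positions with the sigmoid transfer
  $P(bit = 1) = 1/(1 + e^{-10(x - 0.5)})$ and Bernoulli sampling; the
  encircling coefficient decreases linearly over $[2, 0]$; fitness-relevant
  randomness, like every other stage, is governed by one integer seed.
* BGA honours the "random probability" parameterization literally: in the
  default mode crossover, mutation and selection probabilities are redrawn
  uniformly each generation; a fixed-probability mode (crossover 0.9,
  per-bit mutation 0.02, tournament win 0.9) is the reproducible
  benchmarking configuration. The population is initialized keep-biased
  (probability 0.8, plus the all-keep individual), reflecting the prior
  that most training rows are valid. Masks keeping fewer than two rows of
  a class score zero — the variance estimate of the weighting stage needs
  two — which tightens the nominal one-per-class minimum by one.
* Metrics use standard one-vs-rest pooling for micro/macro averages; in
  single-label binary classification micro precision and micro recall
  therefore equal accuracy (asserted as an invariant). Undefined 0/0
  ratios are reported as 0 with a warning. F1 is the harmonic mean of
  macro precision and macro recall. No other averaging convention is
  attempted: published variants that report micro-average precision
  different from accuracy for a binary single-label task are not
  reproducible under any standard definition, and the package does not
  reverse-engineer one.
* Problem sizes in the test suite are chosen for desk-scale runs: wrapper
  populations of 8–30, 10–100 iterations, panels of 30–154 samples. The
  full-size configurations (population 20–30, 100 iterations, the 154 × 50
  panel) are exercised in the acceptance-level tests.

## Known limitations

* All wrapper scores inherit the resolution of the validation split
  (1/31 at the default split of the default cohort); differences smaller
  than one validation sample are invisible to the filters, and a mask can
  overfit a small validation split just as a model can.
* The weight-space definition, the BGWO/BGA fitness functions and transfer
  function, and the chaotic-relocation reading are implementation-defined
  where the underlying scheme is silent; they are documented above and
  isolated behind small functions so alternatives can be substituted.
* The pipeline is strictly binary-label and dense-matrix; no imputation is
  performed — missing values are a load-time error by design.
* The deep-learning member is a feed-forward stand-in honoring the member
  contract; recurrent architectures are out of scope on static tabular
  vectors.
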