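---
title: "Random-projection features and genetic-programming classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-projection features and genetic-programming classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpgp)
```

## The problem

Bulk expression studies routinely produce matrices with tens of thousands of
features (probes or genes) measured on fewer than a hundred and fifty
samples. Training a classifier directly in that space is slow, memory-hungry
and badly exposed to the curse of dimensionality. `rpgp` implements a
two-stage approach for binary classification of such data:

1. **Feature construction by random projection (RP).** The `d`-dimensional
   profiles are mapped through the origin to a `k`-dimensional
   (`k << d`) latent space with a seeded random `k x d` matrix `R` whose
   columns have unit Euclidean length:
   `X_rp = R %*% X`. The map is data-independent, so one `R` can be applied
   to training and test samples alike without information leakage.
2. **A genetic-programming (GP) classifier.** A population of arithmetic
   program trees — internal nodes drawn from `{+, -, x, /}` and leaves
   referencing feature values — is evolved against the training split. A
   program classifies a sample as positive exactly when its signed output is
   `>= 0`.

Around this core the package provides the full evaluation harness
(stratified k-fold cross-validation, repeated seeded runs, five standard
baseline classifiers) and a seeded generator of microarray-like synthetic
data, so that every stage can be exercised end to end without downloading
anything.

## Fitness: the standardized Matthews correlation coefficient

For confusion counts `TP`, `TN`, `FP`, `FN` the Matthews correlation
coefficient is

```
MCC = (TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP))
```

which equals the Pearson correlation between the 0/1 prediction and truth
vectors (the test suite verifies this identity against `stats::cor` on
thousands of random instances). When the denominator is zero — any empty
marginal — MCC is defined to be exactly 0. Fitness is the affine rescaling

```
fitness = (1 + MCC) / 2
```

onto `[0, 1]`, with 1 a perfect classifier. MCC is preferred over raw
accuracy because the target datasets are often imbalanced (e.g. 64 controls
vs 12 cases); a majority-class predictor scores 0.5, not 0.84.

Two accuracy conventions are exposed because they answer different
questions. *Training* accuracy is reported as `MCC * 100` — a correlation on
a percent scale, which can be negative; `percent_correct()` is available as
the conventional fraction. *Test* accuracy is balanced accuracy,
`(sensitivity + specificity)/2 * 100`, which is undefined when the
evaluation set lacks a class — the reason the harness enforces stratified
folds.

## The GP engine

**Representation.** Programs are full binary arithmetic trees, stored
internally as prefix-encoded integer vectors (a subtree is then always a
contiguous slice, and the genetic operators become vector splices).
Evaluation over all samples is a small C++ stack machine; an independent
recursive evaluator in the test suite pins its semantics to `1e-12`.

**Closure.** Two conventions make every program total and finite. Division
is protected: `a / b = 1` whenever `|b| < 1e-9` (the standard single-tree GP
convention; the constant 1 rather than a huge value avoids rewarding
division-by-almost-zero spikes). Additionally each node output is clamped to
`[-1e150, 1e150]`: without the clamp, depth-8 chains of `x` and `/` can
overflow double precision to `Inf` and produce `NaN` via `Inf - Inf`. With
both rules no intermediate can ever be non-finite. The clamp boundary is far
above any value reachable from realistic expression data; it exists purely
as a numerical safety net and does not affect decisions in practice.

**Decision rule.** `classify()` maps output `>= 0` to the positive class.
A signed expression with a zero threshold is the standard single-tree GP
classifier; the boundary is inclusive so that the rule is total.

**Configuration (defaults of `gp_config()`).**

| parameter | default | note |
|---|---|---|
| population size | 1024 | |
| selection | tournament, size 7 | ties broken uniformly at random |
| crossover probability | 0.8 | exclusive per-offspring choice |
| mutation probability | 0.2 | remainder = reproduction (0 by default) |
| initialization | ramped half-and-half, depths 2–8 | |
| depth cap | 8 | applies to every operator output |
| elitism | 1 | best individual copied unchanged |
| termination | 50 generations | the stopping criterion is the generation cap |

`gp_config_reduced()` (population 256, 30 generations) is the bundled
desk-scale profile used throughout the tests and examples; the problem sizes
there (up to `d = 5000`, `n = 100`) were chosen so a complete run of the
suite stays comfortable on a single CPU.

Points the configuration leaves genuinely open were resolved as follows,
and are configurable:

* *Operator application* is an exclusive choice per offspring with
  probabilities 0.8 / 0.2 / remainder; crossover and mutation never compose
  on one offspring.
* *Depth* of a single terminal is 0. The range 2–8 serves both as the
  initialization ramp and as the hard cap during evolution. Crossover
  children that would exceed the cap are re-drawn up to a bounded number of
  times, then the first parent is copied — so closure under the cap is
  unconditional. Mutation grows its replacement subtree within the depth
  budget remaining at the mutated node.
* *Ramped half-and-half* splits each depth level half "full" / half "grow";
  grow-method leaves are never placed shallower than the ramp minimum, so
  every initial tree has depth within the ramp range. Odd level counts give
  the extra tree to the grow half.
* *Elitism* copies exactly one individual (ties broken uniformly at
  random), which guarantees the best-ever fitness trace is non-decreasing —
  a property the tests assert on every run.
* All randomness flows from one seeded generator per run, so a fixed seed
  reproduces the identical best program, bit for bit.

## The harness

`run_experiment()` reproduces the benchmark design: for each repetition
`r`, the seed is `base_seed + r`; the projection matrices (one per requested
`k`) are drawn from that seed; folds are stratified so per-fold class counts
are within one of exact proportionality (round-robin dealing within each
shuffled class); and each classifier is trained per fold and scored on both
splits. One projection per repetition is shared across that repetition's
folds — legitimate because `R` never sees data — with per-fold regeneration
available behind a flag. The classifier set is GP plus `rpart` decision
trees, naive Bayes and SVM from `e1071`, `class::knn` with `k = 3`, and
`randomForest`, all at their library defaults except that the decision tree
is grown fully (`minsplit = 2`, `cp = 0`) in the style of C4.5-like tools,
which matches the near-perfect training accuracies such trees reach on
separable expression data. Whether repetitions apply to the baselines as
well is left open by the design being mirrored; here everything runs under
the same seed schedule, which costs little and keeps every cell of the
summary auditable. Summaries are mean ± sample standard deviation over all
(repetition, fold) records and are recomputable from the records at any
time.

## The synthetic generator

`generate_dataset()` emulates the *shape* of two-class microarray studies:
`n ≈ 100` samples, thousands to tens of thousands of features, a planted
informative subset, heavy independent Gaussian noise, optionally in
equicorrelated blocks (`rho = 0.5`). Each feature receives its own baseline
level drawn from `N(0, baseline_sd^2)`; real probe intensities differ
enormously between probes, and these stable offsets are what lets a
constant-free arithmetic classifier synthesize thresholds (differences of
baselines act as implicit constants). A zero-centred background would make
the zero-threshold decision rule artificially degenerate in a way real
intensity data is not.

Defaults — chosen once as a realistic two-class contrast and used by all
end-to-end checks: 100 samples, 10,000 features, 500 informative (5% of
probes differentially expressed), standardized shift 0.75, balanced classes,
unit noise, `baseline_sd = 2`. The `linear_shift` rule adds
`effect_size * noise_sd` to informative features of cases, so `effect_size`
is the standardized per-feature mean shift; with 5 informative features at
effect 2, the planted linear rule separates classes at
`d' = 2 * sqrt(5) ≈ 4.5`, i.e. better than 95% accuracy, which the tests
verify against the closed-form Gaussian overlap. The `nonlinear_ratio` rule
instead labels samples by `sign(x_a / x_b - x_c)` over three planted
features (same protected division as the primitives), so recovering it
genuinely requires `/` — under this rule labels derive from the data and
`effect_size` / `class_balance` are ignored. With `effect_size = 0` labels
are independent of the data, which the suite uses as a leakage guard: the
whole pipeline must then score inside the 99% binomial band around 50%.

## What the synthetic results do and do not show

The generator keeps features independent (or block-equicorrelated) and
Gaussian precisely so that closed-form checks are possible. That choice has
a consequence worth stating plainly. A random projection retains, in
expectation, only a `k/d` fraction of the squared class-mean separation:
if the planted signal has Mahalanobis separation `d'` in the original
space, the best any classifier can do after projecting to `k` of `d`
dimensions is about `Phi(d' * sqrt(k/d) / 2)` balanced accuracy. With a
*sparse* planted signal (say 5 informative features in 1000 at effect 2,
projected to `k = 50`) that ceiling is ~69%, and the practically reachable
accuracy is lower still, because the signal is then spread thinly over all
`k` constructed features while a flexible classifier happily overfits 50
dimensions on 90 training samples. On such data RP features do *not* beat
the raw feature set for GP, and the corresponding end-to-end checks in
`tests/testthat/test-acceptance.R` document the measured behaviour against
the more optimistic planted-recovery expectations they encode.

On real microarray data the projected-feature advantage reported for this
method rides on properties the generator deliberately does not model:
dimensionalities in the tens of thousands, and large *correlated* modules
of differentially expressed genes, which concentrate far more class signal
into each constructed feature than an independence model can. Passing the
synthetic checks therefore demonstrates that the machinery — projection,
evolution, metrics, folding, seeding — is correct and reproducible; it does
not by itself certify accuracy gains on any particular real dataset.

## Numerical and interface choices

* Delimited matrices are written with 17 significant digits (`%.17g`), so a
  write/read round trip is the identity at the bit level. On-disk
  orientation (features-in-rows vs samples-in-rows) is always an explicit
  flag, never guessed — silent transposes are the classic failure mode when
  `d >> N`.
* Missing cells are a hard error by default; per-feature mean imputation is
  available behind an explicit flag. No normalization or log-transform is
  applied by the loaders: the method is defined on whatever units the input
  matrix carries, and preprocessing is the caller's decision.
* ARFF input (numeric attributes plus one nominal class attribute) is
  supported via `foreign::read.arff` as a convenience for Weka-formatted
  exports; delimited text is the primary dialect.
* Labels must align with matrix columns in order; `assert_aligned()` fails
  loudly rather than reordering.
* Best programs serialize as S-expressions, e.g.
  `(div (add x3 x17) (sub x4 x9))` with 1-based feature indices, and parse
  back; fitness traces export as two-column TSV.

## Known limitations

* Binary classification only; no multi-class MCC generalization.
* The terminal set is feature values only — no ephemeral random constants.
  Thresholds must be synthesized from baseline differences, which is
  intentional (it matches the method) but limits the classifier on
  zero-centred data.
* The generator does not simulate probe-level artifacts (background,
  saturation, batch effects) or heavy-tailed intensity distributions, and
  its independence assumptions understate the RP advantage expected on real
  co-expressed gene modules (see above).
* GEO/SOFT parsing is out of scope; bring your own delimited matrix.
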