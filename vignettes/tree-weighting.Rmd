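---
title: "Tree-level stacking for multi-study ensembles: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-level stacking for multi-study ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treestack)
```

## The problem

When several studies measure the same outcome over a shared feature set,
training on any one study tends to overstate accuracy on the others, and
pooling everything into one training set (the *Merged* learner) ignores
between-study differences in how features relate to the outcome. A
cross-study ensemble instead trains a single-study learner (SSL) per study
and combines them,

$$\hat Y(x) = b_0 + \sum_j w_j \, \hat Y_j(x),$$

with weights chosen to reward *cross-study* prediction: each SSL is scored
on the training studies it was not fitted to. With random forests as the
SSL there is a further choice this package is built around: weight each
forest as a unit (*Weighting Forests*), or extract the individual trees and
weight each of them (*Weighting Trees*), so that a tree that generalizes
across studies can be up-weighted even when the rest of its forest does
not. Two benchmarks complete the comparison: *Merged* (one forest on the
row-concatenated studies) and *Unweighted* (the plain average of the K
per-study forests). All four strategies consume and produce identical data
shapes, and every strategy holds the same total number of trees (the merged
forest gets `K * m` trees) so comparisons are not confounded by ensemble
size.

## Stacking weights

Let `T` be the N × J matrix whose column j stacks component j's predictions
on every training observation (N = total training observations; J = K
forests or K·m trees) and `Y` the stacked outcomes. The weights solve

$$\min_{w \ge 0,\, b_0} \; \lVert Y - b_0 - T w \rVert^2 + \lambda \lVert w \rVert^2 ,$$

a non-negative ridge regression with an unpenalized, unconstrained
intercept. The non-negativity constraint (after Breiman's stacked
regressions) keeps the ensemble an additive blend of its members; ridge
shrinkage spreads weight across components rather than zeroing them, which
helps when a component that looks weak in training carries signal for an
unseen study. Weights are deliberately **not** normalized to sum to one —
the fitted scale and intercept absorb calibration — and `w = 0` is allowed
(the feasible set must be closed; exact zeros are meaningful). A lasso
penalty and an intercept-free variant are available behind configuration
switches but are not defaults.

Numerically, `solve_nn_ridge()` works on the normal equations: for each
penalty it solves the non-negative quadratic program exactly with a
Lawson–Hanson-style active-set iteration, warm-started along the descending
λ path (the active set changes little between neighboring penalties, so a
100-point path costs little more than a single solve). The objective above
is what the solver minimizes; tests compare its objective value against a
brute-force oracle that enumerates every active set, and against an
independent Lawson–Hanson implementation on the ridge-augmented least
squares form. Columns of `T` are standardized internally before
penalization and the weights back-transformed; positive rescaling preserves
non-negativity, and a zero-variance column (e.g. a constant component)
receives weight 0 with a warning. An all-constant outcome returns
`w = 0` with the intercept at `mean(Y)`.

λ is selected by 10-fold cross-validation over a log-spaced 100-point grid
spanning `N·10^{-8}` to `N·10^{3}` (the standardized Gram diagonal is of
order N, so this covers effectively unpenalized through fully shrunk
fits). Folds are observation-level and seeded; study-level folds are
available via `fold_type = "study"` for users worried about within-study
leakage inflating the apparent value of a component's own-study
predictions. Relatedly, `T` includes each component's refit predictions on
its own training study by default; `oob_own_study = TRUE` substitutes
out-of-bag predictions for those rows at the forest level (an individual
tree has no alternative prediction for its in-bag rows, so the flag is a
no-op at tree level).

## Forests and trees

`train_forest()` wraps `ranger` (10 trees per forest by default, `mtry = 9`
for p = 100) and records what tree-level ensembling needs: per-tree in-bag
counts (hence out-of-bag rows), per-tree split-variable multisets, and the
training data. Ten trees per forest keeps a full four-strategy comparison
cheap while preserving the ordering of the approaches; `mtry = 9` at
p = 100 is deliberately far below the regression default p/3, which
produces diverse trees whose individual cross-study merit the stacking can
discriminate — both are configurable. The minimum node size is left at the
backing learner's regression default. Forest predictions are exactly the
mean of member-tree predictions (probability means for binary outcomes),
which yields two identities the tests assert at 1e-10 or tighter:
extracted-tree averages reproduce the forest, and a forest-level fit equals
a tree-level ensemble run at the implied weights `w_k / m`.

## What the simulator emulates

`build_collection()` realizes the multi-study conditions the evaluation is
built on: K = 10 training and V = 5 validation studies of 100 samples each
(real multi-study gene-expression collections span roughly 40–500 samples
per study), p = 100 features of which 10 carry the outcome through a
linear model. Coefficients are drawn uniformly from
`[-5, -0.5] ∪ [0.5, 5]`, so no true effect is vanishingly small.

*Feature-effect heterogeneity* is a per-study location shift of the
coefficient vector: study k draws its coefficients uniformly from
`[c - l, c + l]`, once per study. Five training studies get a low level
(`l = 0.25`), five a high level (1 at baseline), and validation studies an
intermediate 0.4 at baseline; heterogeneity sweeps move the high level and
give validation studies half of it. *Feature-distribution heterogeneity*
comes from independent feature draws per study. Features are
block-correlated Gaussian (blocks of 10, within-block correlation 0.3) —
an analytic stand-in for gene-expression covariance; `resample` mode
instead draws rows from a user-supplied matrix when realistic marginals
matter. Two baseline designs isolate feature-effect heterogeneity:
`repeated_single_study` reuses one feature matrix for every training study,
and `pseudo_split` shuffles one source matrix into 5 equal parts (4 train,
1 validate; remainder rows join the last part).

Interactions enter as all three pairwise products of 3 of the 10 true
variables, each with coefficient `s × (random sign)`; the strength `s`
(default 2, the midpoint of the 0–3 grid the evaluation sweeps) is the
axis along which the share of outcome variance explained by interactions
grows. Scenarios place the interaction terms in exactly 2 (or 6) training
studies and 2 validation studies; which studies, like which training
studies get the low perturbation level, is randomized per iteration.
Outcomes add Gaussian noise with sd 1 by default — the signal from
coefficients of magnitude 0.5–5 dominates, but the knob exposes
signal-to-noise directly. Binary outcomes pass the standardized linear
predictor through a logistic link and sample Bernoulli draws; ensembles
then stack predicted probabilities with the same squared-error objective
and are scored by log loss, with probabilities clipped to
`[1e-15, 1 - 1e-15]`.

What the simulator does **not** emulate: real expression data's heavy
tails, batch effects, and correlation structure beyond blocks; survival
outcomes (binary outcomes stand in for a dichotomized endpoint); and
missing data (the containers reject it). Passing tests therefore show the
method behaves as designed under controlled heterogeneity, not that the
specific RMSE values transfer to any particular real collection.

## Evaluation design

`run_scenario()` builds a fresh collection per iteration, fits every
strategy on the same training studies, and scores them on the identical
validation studies — RMSE for continuous outcomes, log loss for binary.
Per-study scores are averaged with equal study weight (so a large
validation study cannot dominate), and scenario summaries report the mean,
standard error, 1.96·SE confidence half-width, and percent change versus
Merged. Iterations are independently seeded from the master seed: results
are order-independent, any single iteration is reproducible in isolation,
and a failed iteration is recorded and skipped rather than aborting the
run. The default 20 iterations keeps a four-strategy scenario under two
minutes on one core; 100 iterations reproduces the reference conditions
when more precision is wanted.

`run_heterogeneity_sweep()` holds `l_low = 0.25`, sets
`l_validate = level / 2`, and — deliberately — reuses the same
per-iteration seeds at every level. With common random numbers the same
generative model and features appear at each level and the perturbation
draws scale with `l`, so level contrasts are paired and free of
between-level simulation noise; with 20 iterations the monotone growth of
RMSE in heterogeneity is visible for every strategy, which independent
seed streams would bury in Monte-Carlo error. Smoothing of curves, where
wanted, is a plotting concern; all reported numbers are raw means.

## Diagnostics

The link between a tree's stacking weight and its anatomy is summarized
by: `freq_true_vars`, the fraction of a tree's split nodes using a true
variable (a zero-split tree reports 0; the alternative distinct-variable
reading is deliberately not used, as the per-node fraction is what stays
in [0, 1] regardless of tree depth); `n_interaction_vars`, the count of
distinct interaction-involved variables among its splits; and out-of-bag
permutation importance — per tree, the OOB error increase after permuting
a predictor, averaged over trees and normalized by the standard deviation
of the per-tree differences. One seeded whole-column permutation per
variable per forest is evaluated on each tree's OOB rows; permuting only
within each tree's OOB subset would change nothing structurally but cost
m× the prediction calls. A variable no tree splits on has exactly zero
importance; negative importances are floored at 0 before forming the
true-variable share so the proportion stays in [0, 1] (an all-zero vector
returns 0 with a warning). Weight-decile summaries sort ascending with
ties broken by component index and report bottom-10%, top-10% and overall
means; ensembles with fewer than 10 trees report only the overall band.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config()          # K = 10, V = 5, n = 100, p = 100
sim <- build_collection(cfg, iteration_seed = 42)
wt  <- fit_ensemble("weighting_trees", sim, seed = 3)
mg  <- fit_ensemble("merged", sim, seed = 3)
val <- validation_studies(sim$collection)[[1]]
rmse(predict(wt, val$features), val$outcome)
rmse(predict(mg, val$features), val$outcome)
weight_decile_summary(tree_level_weights(wt))
```

At these conditions the tree-weighted ensemble typically beats the merged
forest by 10–20% in validation RMSE, with its weight distribution showing
the characteristic long upper tail: a top decile several-fold above the
0.01 equal-weight reference and a bottom decile an order of magnitude
below it.

## Known limitations

Stacking refits are the dominant cost at tree level (J = K·m columns); the
warm-started active-set path keeps a 100-point CV sweep near half a second
at J = 100, N = 1000, but very large K·m would call for a solver with
screening. Classification support covers binary outcomes only, and the
squared-error probability stacking, while faithful to the regression
objective, is not a proper-scoring-rule fit. The permutation-importance
normalization is unstable when a variable appears in very few trees (the
per-tree difference SD is then estimated from a handful of values); the
raw means are returned alongside for that reason.
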