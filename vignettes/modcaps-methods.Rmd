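---
title: "modcaps methods: model, numerics, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{modcaps methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Biological classification tasks often mix data sources that differ in type
and length: one-hot clinical factors next to dozens of real-valued read
metrics, or a single scRNA-seq matrix that prior knowledge (TF→target
relations, PPI subnetworks, regulons) splits into overlapping gene groups.
modcaps treats every such block as a *source*, standardizes each with its
own encoder, and classifies with a dynamic-routing capsule layer whose
routing weights double as an importance measure.

Per source `i` with `r_i` features, the encoder is a single linear map
followed by tanh, producing a primary capsule `u_i = tanh(W_pi x_i)` of
common length `n`. Prediction vectors `û_{j|i} = W_ij u_i` (length `m`) feed
the routing loop; the type capsule `v_j = squash(s_j)` has length
`‖s_j‖²/(0.5 + ‖s_j‖²) < 1`, read as the probability of class `j`.

**Assumptions.** Sources are meaningful groupings (the model never regroups
features); a single linear-tanh layer suffices to standardize each source
(no deep encoders); class evidence is expressible as agreement between
per-source predictions in a shared `m`-dimensional space. Interpretability
rests on reading the coupling `c_ij` — a softmax-normalized agreement weight
— as the contribution of source `i` to class `j`; couplings are relative
weights (each source's couplings sum to 1 across classes), not calibrated
effect sizes.

## Tunable parameters

| Parameter | Default | Meaning / why this default |
|---|---|---|
| `n` | 8 | primary-capsule length; the stated standardization width |
| `m` | 16 | type-capsule length; standard capsule-network practice |
| `r` | 3 | routing iterations; standard practice, unstated in the source method |
| `squash_const` | 0.5 | squash denominator constant as printed in the method (the original CapsNet uses 1); configurable |
| `m_plus, m_minus, lambda_down` | 0.9, 0.1, 0.5 | margin-loss hinges; the referenced implementation's loss, never printed in the method description |
| `learning_rate, batch_size, epochs` | 1e-3, 128, 50 | Adam at desk scale; unstated upstream, chosen once for convergence on the acceptance fixtures |
| `split_ratio` | 0.9 | the stated 9:1 train/validation division, stratified by class |
| `repeats` | 9 | the stated number of independent repeats averaged into the final heatmap |
| `n_rep` (permutation importance) | 5 | shuffles per feature; unstated upstream |

## Numerical and design choices

**"normalize" in the routing loop.** The routing pseudocode normalizes the
weighted sum `s_j` each iteration and finally squashes `s_j`. Read
literally, the squash input would always have unit norm and every class
score would be the constant `1/(0.5+1)`: lengths could not encode
probability. We therefore L2-normalize on *non-final* iterations only (the
normalized vector is used for the agreement dot products) and squash the
raw final weighted sum — the behavior of the Keras capsule implementation
the method builds on. `normalize_every_iter = TRUE` exposes the literal
reading for comparison.

**Logit update.** Logits are *overwritten* each iteration
(`b_ij ← û_{j|i}·s_j`), as the pseudocode states, not accumulated as in the
original CapsNet; `accumulate_logits = TRUE` exposes the accumulating
variant. With `r = 1` the logits stay zero and couplings are exactly
uniform.

**Gradients with detached routing.** This stack has no automatic
differentiation, so training uses analytic gradients: margin loss →
`dL/ds_j = g_j · 2h s_j/(h+‖s_j‖²)²` → through the coupling-weighted sum,
the routing maps `W_ij`, tanh, and the encoder maps. The coupling
coefficients are treated as *constants* of the forward pass rather than
unrolling the routing recursion into the gradient. This is a common capsule
training shortcut; its practical effect here is measured, not assumed: the
acceptance fixture trains to ≥ 0.99 validation accuracy and recovers all
planted sources (test-acceptance.R, criterion 4). Couplings still become
informative because they are recomputed by agreement at every forward pass.

**Stability and ties.** Softmax subtracts the row maximum before
exponentiating; `squash(0) = 0` by definition; L2 normalization leaves zero
vectors at zero; argmax ties break to the lowest class index; ranking ties
break to the lowest source index. Checkpoints serialize weights with 17
significant digits, which round-trips IEEE doubles exactly.

**Gene-set decomposition.** Matching is exact and case-sensitive
(`case_insensitive = TRUE` folds both sides); a prior gene absent from the
matrix contributes a zero column and still counts toward `r_i`, so the
model structure is fixed by the prior, not by the measured panel. Sets that
overlap *duplicate* their shared columns — each primary capsule owns its
input copy, matching the per-source encoder formulation. Expression values
are used as provided (`log1p = FALSE` by default, since the source method
states no transformation).

**Importance reporting.** Couplings are extracted with weights frozen over
the full dataset by default (the per-class averages in the source method
are over samples of that class; whether they used train, validation or all
samples is unstated — `data` is caller-specified). Reported scores are raw
averaged couplings; `normalize = TRUE` in `top_k_sources()` applies
per-row min-max scaling for cross-model comparison plots (the normalization
behind published comparison figures is unstated; min-max is our choice and
does not affect ranks).

## The synthetic world

`generate_modular()` plants signal as a Gaussian mean shift: informative
numeric features gain `+δ` (default 2) for their linked class over
`Normal(0, σ²)` noise (σ = 1); informative one-hot sources fire a
class-linked category with probability `p = 0.9`. `δ = 0` disables *all*
planted signal — including the one-hot linkage — so the null control is a
dataset with no informative source at all.
`generate_expression_with_sets()` adds the prior-knowledge layout: 500
genes, 60 regulon-like sets of 8 genes (10% drawn from the shared
universe, so sets overlap), 7 classes of 2000 cells, 2 relevant sets per
class, rectified-Gaussian expression `max(0, Normal)` to keep values
non-negative without a count model. Set labels are gene symbols and contain
their own label with probability 0.15, so labeling-TF exclusion has work to
do.

What this emulates: block structure, heterogeneous source types, overlap,
missing genes, class-linked group signal. What it does **not** emulate:
scRNA-seq count noise (negative binomial, dropout), batch effects,
correlated features within a source, unbalanced classes. A green
planted-recovery test therefore establishes that the *mechanism* — routing
couplings concentrating on informative sources — works under clean additive
signal; it does not certify performance on real single-cell data.

The acceptance fixture (criteria 4–5) is stated once: 5 classes, 10 numeric
sources of 5 features, source `i` informative for class `((i-1) mod 5)+1`
(exactly 2 planted sources per class), δ = 2, σ = 1, 2000 samples, 9:1
stratified split, 9 repeats, seed 1, training defaults above. None of these
values were adjusted after observing test outcomes.

## Known limitations

- Training cost grows with `l × k` (one `m × n` routing map per
  source–class pair); the 696-source scale of the original application is
  feasible but slow in plain R — the package targets desk-scale validation
  and medium problems.
- The detached-coupling gradient is an approximation; exact
  routing-unrolled gradients could differ on harder, low-signal problems.
- Headline numbers of the original study (variant-call AUC 0.94/0.99/0.97,
  accuracy 0.873, importance correlation 0.876, ~97% scRNA accuracy, ~90%
  top-30 overlap) depend on external datasets and prior files that are not
  packaged; they are documented reference points, not CI gates, and nothing
  in the test suite asserts them.
- `evaluate()` reports one-vs-rest AUC from capsule lengths; lengths are
  bounded in `[0, 1)` but not calibrated probabilities.
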