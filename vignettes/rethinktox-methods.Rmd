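---
title: "Methods: dose-response featurization, multi-label balancing, and the attention rethinking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response featurization, multi-label balancing, and the attention rethinking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own science: the models
it fits, the assumptions behind them, the parameters that matter, the
numerical choices made where the design was genuinely open, and the
limits of what its synthetic studies demonstrate.  The companion README
shows the user-facing workflow.

## 1. The prediction problem

Each sample is one compound profiled in a target organ: a feature
vector `x ∈ R^dim` derived from gene expression at three dose levels,
and a binary vector `Y ∈ {0,1}^L` of histopathological findings
(L is 20 by default, mirroring a 12-liver + 8-kidney finding panel).
Findings are sparse, strongly imbalanced, and correlated — a compound
that causes necrosis often causes cellular infiltration too.  The
package's core learner is built to exploit exactly that correlation.

## 2. Dose-response featurization (`fit_gene_curve`, `build_rmax_features`)

**Model.**  Expression of a responsive gene across the ordinal dose
codes d = 1, 2, 3 (low/middle/high; absolute doses differ per compound,
so only the ordering is meaningful) is modelled as a 3-parameter
logistic

r(d) = baseline + (plateau − baseline) / (1 + exp(−slope (d − ec50))),

with the baseline pinned to the observed low-dose response.  The
extracted feature is the **maximal response R_max**, the largest value
the fitted curve attains over the tested dose range.

**Why the curve value, not the asymptote.**  Three points do not
identify the upper asymptote: a one-parameter family of logistics
interpolates any monotone triple, and the asymptote varies freely along
it.  The curve's value on the tested range, however, is pinned by the
data.  R_max is therefore evaluated at the extreme doses of the fitted
curve, which for noiseless saturating curves recovers the generating
plateau to a fraction of a percent (the acceptance script recomputes
this: median relative error well below 1% over 200 random noiseless
triples).

**Fitting.**  The amplitude enters the least-squares problem linearly,
so it is profiled out in closed form and the search runs over
(ec50, slope) only: a coarse grid (ec50 spanning the dose range ±0.75,
slope magnitudes 0.4–16 on a log scale, both signs), two vectorised
local zooms, and — in the single-curve interface — a Nelder–Mead polish.
The vectorised path fits a full compounds × genes table in one pass
(roughly 24,000 triples per second-scale call at the default study
size), which is what keeps the pipeline at desk scale.

**Validity and gene filtering.**  A fit is *valid* when its residual
sum of squares is at most `rss_tolerance` (default 0.1, squared
expression units — consistent with per-dose measurement noise of
~0.1–0.15) and the response range is at least `flat_tolerance`
(default 0.3 expression units).  Flat series carry no dose signal;
non-monotone series cannot be approached by any logistic and leave a
large residual; both are filtered.  A gene is retained when its fit is
valid for all compounds (`min_valid_fraction = 1`), the conservative
rule appropriate when a single erratic compound should disqualify a
probe; the fraction is configurable.

**Open points resolved.**  Fitting is per (compound, gene) with one
sample emitted per compound, not pooled across compounds.  Control
(vehicle) samples are not part of the fit input; the three treated dose
levels are.  An alternative — response relative to control — would
change the baseline interpretation but not the machinery.

## 3. Improved MLSMOTE (`mlsmote_augment`)

**Diagnostics.**  `IRLbl(l) = max_l' count(l') / count(l)` and `MeanIR`
(mean over labels with at least one positive; empty labels are flagged
infinite and excluded).

**One pass.**  For every minority label (IRLbl above MeanIR), every
sample in its positive bag seeds one synthetic sample: features are
interpolated toward a uniformly chosen one of its k = 5 nearest bag
neighbours, `x_new = x_seed + u (x_neigh − x_seed)`, `u ~ U(0,1)` — so
synthetic compounds stay inside the minority region — and labels are
set by majority vote over the seed plus k neighbours.  k-NN ties break
by sample index, so runs are bit-reproducible given the seed.

**Vote scope and the all-zero guard.**  With votes restricted to the
minority bag (`vote_scope = "bag"`, the default and the classic
formulation) the triggering label is present in every voter and always
wins, so balancing is effective.  With dataset-wide voting
(`vote_scope = "dataset"`) a rare finding's samples typically sit among
no-finding neighbours, the trigger can be out-voted, and the ranking
can return an all-zero vector — a synthetic "compound" with no finding,
generated from minority seeds, which would dilute rather than enrich
the minority class.  The guard handles that case: by default it sets
the triggering minority label (guaranteeing every synthetic sample
carries at least one finding, and termination); `guard = "discard"`
drops the sample instead.  A re-draw alternative would be vacuous here,
because the vote does not depend on the re-drawn interpolation partner.

**Stopping.**  Passes repeat until MeanIR reaches
`target_mean_ir` (default 1.5) or `max_rounds` (default 5) passes have
run; a pass that fails to reduce MeanIR is discarded and iteration
stops, so augmentation never worsens the imbalance — this is checked
property-style across 100 seeded runs in the test suite.  On the
default synthetic study MeanIR falls but does not reach the target: the
rarest findings (1–2 positive compounds) cannot be oversampled (bags
below 2 are skipped with a warning) while their IRLbl keeps growing
with the majority counts.  That is the honest behaviour at desk scale;
the large augmentation factors reported on real archives require many
more compounds per finding.

## 4. The attention rethinking network (`rethinknet`)

**Architecture.**  Input layer → attention block → recurrent layer →
dense sigmoid head.  The feature vector is replicated across T
recurrent steps ("rethinking" iterations); each step's hidden state is
decoded by a shared dense layer into label scores `Ŷ^(t)`, and the
recurrent state carries the memory of the previous tentative prediction
into the next iteration, so label correlations sharpen the later
guesses.  `Ŷ^(T)` thresholded at 0.5 (configurable) is the prediction.
Because all weights are shared across steps, the trainable parameter
count does not depend on T (asserted in the tests for feature-axis
attention and for the no-attention ablation).

**Attention block.**  A dense layer on the input produces logits; a
softmax turns them into a weight distribution; the block's output is
the input times the broadcast weights.  Two numerical choices matter:

* *Axis.*  The default softmax runs over the feature (gene) axis —
  one weight per gene per sample, matching the intent of weighting
  important genes.  A step-axis variant (softmax over the T replicated
  steps per gene) is provided; note its logit parameters necessarily
  scale with T.
* *Rescaling and regularisation.*  Raw softmax weights average 1/dim
  and would shrink every input ~50-fold at dim = 50, burying the
  signal; the block therefore multiplies by `dim · p` so that uniform
  attention is the identity map.  The attention dense weights start at
  zero (uniform attention — the neutral initial state) and the
  sample-dependent part of the logits carries an L2 penalty
  (`attention_decay`, default 0.1) toward uniformity: attention is
  meant to encode feature importance that is *consistent across
  samples*, and unpenalised it degenerates into per-sample
  memorisation that destroys generalisation (observable on the
  separable benchmark by setting `attention_decay = 0`).  The shared
  per-gene offsets are unpenalised — they are the global importance
  profile the block exists to learn.

**Recurrent cell.**  LSTM (default; forget-gate bias initialised to 1)
or simple recurrent tanh cell (`cell = "srn"`), both hand-implemented
with backpropagation through time and verified against numerical
differentiation in the test suite.  `attention = "off"` yields the
plain rethinking-network ablation.

**Loss and training.**  Cost-sensitive re-weighted binary
cross-entropy, averaged over samples, iterations and labels, with
per-label weights `w_l` proportional to inverse prevalence, clamped at
`weight_cap` (default 20; labels with no positives get the cap, with a
warning) and normalised to mean exactly 1 — so the loss scale is
comparable to the unweighted case and uniform weights reduce it to
plain mean BCE (asserted in tests).  Optimisation is mini-batch Adam
(learning rate 0.01, batch 32, 100 epochs by default); initialisation
is Glorot-uniform.  All randomness derives from `seed`, and same-seed
runs reproduce epoch-1 losses exactly.

**Defaults.**  T = 5 (appropriate for the larger liver-style panels;
T = 3 suffices for smaller ones — performance saturates in T), hidden
units 32.  The hidden size, learning rate and epoch budget are the
package's own defaults, chosen for minutes-scale CPU training at the
synthetic study sizes, not values claimed from any external experiment.

## 5. Baselines and feature selection

Binary relevance trains one independent binary model per label;
classifier chains append the *true* preceding labels as extra training
columns and feed *predicted* labels forward at inference (the standard
construction), in dataset label order by default.  Base learners are
injected as factories — logistic regression (`glm`), random forest
(`randomForest`), linear SVM with Platt scaling (`e1071`) — plus a
deterministic decision stump used as a transparent stub in tests.  The
per-label 5-NN model votes over Euclidean neighbours with ties counted
positive.

Gene ranking uses the two-group one-way ANOVA F statistic per
(gene, label), aggregated across labels by mean (default; max
available).  Zero between-group variance scores 0; zero within-group
variance with distinct means is capped at `F_MAX = 1e12` to preserve
the ordering without infinities; single-class labels are excluded with
a warning.  The subset search deletes genes from the bottom of the
ranking along a (default geometric) size grid, scores each prefix with
a caller-supplied accuracy evaluator — in the CLI this is mean
cross-validated subset accuracy of a binary-relevance model — and
returns the subset maximising

Fitness = α·ACC + (1−α)·(D_total − λ·D_selected)/D_total,

α = 0.6, λ = 10 by default; ties break toward the smaller subset.  The
amplification factor λ keeps the size penalty meaningful when the
selected subset is a small fraction of the panel; the second term may
legitimately go negative once λ·D_selected exceeds D_total.

## 6. Evaluation suite (`evaluate_multilabel`)

Subset accuracy (exact vector match), Jaccard pair accuracy (empty
union counts as 1: a correctly predicted no-finding compound should not
be penalised), per-label accuracy, per-label confusion counts, and the
macro summaries (average label accuracy, sensitivity, specificity, F1).
Macro ratios with zero denominators are excluded from their mean with a
warning by default (`zero_denominator = "zero"` counts them as 0
instead).  ROC/AUC is micro-averaged — all (sample, label) pairs pooled,
threshold sweep, trapezoidal area, which equals the rank-sum statistic
with midrank ties — with a macro mode available.  The whole suite is
cross-checked against an independent nested-loop oracle to 1e−12 on a
thousand random instances in the acceptance tests.

## 7. Pipeline modes (`run_crossval`, `run_holdout`)

`paper_faithful` follows the literal published procedure: augment the
whole dataset, normalise, then split into K folds — synthetic samples
can land in test folds, which inflates apparent performance but is the
faithful reproduction target.  `leak_free` is the methodologically
safer default recommendation: split the *original* samples, augment
and fit the normaliser on each training portion only, and always
evaluate on untouched originals; the MLSMOTE provenance of every fold
is recorded so the absence of train/test leakage is verifiable (and is
verified in the acceptance tests).  Normalisation is per-gene z-score
(population standard deviation; constant genes map to 0 with scale
recorded as 1).  K = 5 by default.  Every stochastic stage — fold
assignment, oversampling, model initialisation and shuffling — derives
from the single run seed.

## 8. The synthetic generator (`simulate_dataset`)

What it emulates: per-compound expression at exactly three dose levels
at one time point; informative genes following logistic dose-response
curves (per-gene baseline U(4,8), amplitude 1, ec50 U(1.6,2.4), slope
U(3,6), per-dose Gaussian noise sd 0.1) whose maximal response shifts
by `effect_size` (default 0.5) when the gene's associated finding is
active; flat noise genes; 20 findings with a geometric prevalence
ladder from 0.4 down to 0.02 (strong imbalance) and pairwise label
dependencies encoded as conditional probabilities P(j | i), validated
as probabilities and recovered empirically in the tests.  Default
sizes — 120 compounds, 200 genes, 25% informative — keep a full
simulate → featurize → augment → 5-fold crossval run in minutes on one
CPU; the learning benchmark (`make_separable_benchmark`, n = 600,
dim = 50, L = 5, orthonormal label directions, margin 0.5) is sized the
same way.

What it does **not** emulate: real marginal expression distributions,
probe-level correlation structure, compound dose heterogeneity,
batch effects, or the label noise of manual histopathology annotation.
Passing tests on this generator therefore demonstrates that the
machinery is correct and that the pipeline recovers planted structure;
it does not certify accuracy levels on real archives, which depend on
thousands-fold larger augmented sample sizes and real biological
signal.

## 9. Known limitations

* Three dose points cannot identify a sigmoid's asymptote; R_max is
  deliberately the on-range maximum (§2).
* The rarest findings (bags of one) cannot be oversampled and bound
  the achievable MeanIR (§3).
* Subset accuracy on 20 sparse labels at ~100 original compounds is
  intrinsically low; the per-label and ranking metrics are the
  informative ones at that scale (§6, README example).
* The network trains single-threaded on CPU; runtimes are tuned for
  the default study sizes, and much larger panels would warrant a
  compiled backend.
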