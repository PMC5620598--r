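---
title: "Open-set E-Nose classification: models, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-set E-Nose classification: models, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enosebox)
```

## The problem

A metal-oxide gas-sensor array produces, for every odor exposure, a vector
of steady-state load voltages — one feature per sensor. Supervised
classifiers trained on such signatures work well on odors from the classes
they were trained on, but an E-Nose in the field also meets odors from
*outside* its training set, and its sensors respond to those too. A
classifier whose decision regions tile the whole feature space (k-NN, linear
SVM, an MLP regressing the class label) has no way to answer "none of the
above": every out-of-training sample becomes a false alarm. The package
implements one closed-boundary classifier designed to fix this — the
minimum–maximum–mean (MMM) hyperbox method — alongside five standard
comparators and an evaluation protocol that measures all three outcome
types on out-of-training data: false positives, unknown-class assignments,
and correct rejections.

## The MMM model and its assumptions

Training stores four class-by-sensor matrices computed from the training
rows of each class: maxima `Q`, minima `V`, means `U`, standard deviations
`S`. Class *m*'s decision region is the axis-aligned hyperbox
`[V[m, ], Q[m, ]]`, boundaries inclusive. Classification tests box
membership elementwise; no containing box means rejection, several
containing boxes are resolved by the nearest class mean (Euclidean), and an
exact distance tie goes to the lowest class label so the rule is
deterministic and order-independent.

The implicit assumption is that a class's support is approximately a
product of per-sensor intervals. That holds well when class dispersion is
roughly independent noise per sensor (as in averaged steady-state
voltages), and badly when classes have strongly correlated sensor
responses, where the box over-covers the true support.

A min–max box fitted on `L` samples systematically underestimates the class
region: a fresh same-class sample falls inside a given sensor's observed
range with probability `(L - 1) / (L + 1)`, so with `L = 14` training rows
and 8 sensors only about `(13/15)^8 ≈ 32%` of genuine class samples land
inside the initial box on all sensors at once. Boundary expansion exists to
repair exactly this: each round adds `eta * S[m, ]` to `Q[m, ]` and
subtracts it from `V[m, ]`, and rounds continue until the validation error
reaches a threshold or a round limit. Defaults are `eta = 0.1111` (11.11%
of the class standard deviations per round), `error_threshold = 0.02`
(2%, near the error rates typical of this kind of fruit-odor data), and
`max_rounds = 10`. The expansion is symmetric in `Q` and `V` and uniform
across classes; per-class or asymmetric schedules are out of scope. The
model with the smallest validation error seen is returned, so an expansion
that starts admitting wrong-class samples cannot degrade the result.

Two details are deliberate interpretations rather than mechanical choices.
First, the validation error is the 0/1 misassignment fraction (a rejection
of a trained-class row counts as an error). A sum of squared differences
between integer class labels is also provided as a diagnostic
(`mmm_squared_error`), but it depends on how the labels happen to be
numbered and is not used for model selection. Second, expansion widens both
the maximum and minimum boundaries; widening only the maxima would make the
boxes drift upward rather than grow.

## The comparators

All five comparators are implemented from their defining equations, not
wrapped from a library, because their *prediction semantics* on
out-of-training data is the object of study:

- **k-NN** (default `k = 3`: odd, not a multiple of the 9 trained classes)
  votes among the k Euclidean-nearest stored rows. A residual vote tie —
  possible when the neighborhood spans three or more classes — goes to the
  tied class owning the single nearest neighbor.
- **SVM**: hard-margin linear dual per class pair, solved by a
  general-purpose interior-point quadratic optimizer with the constraints
  `alpha >= 0`, `sum(alpha * t) = 0`; weights from the dual solution, bias
  from the KKT condition averaged over support vectors. The data are
  centered internally before the solve (the separator is translation
  equivariant, so only the bias needs shifting back) and a small diagonal
  ridge, escalated on failure, keeps the Gram matrix numerically positive
  definite. A soft-margin box `0 <= alpha <= C` (default `C = 10` in the
  multiclass wrapper) handles non-separable draws; `C = Inf` reproduces the
  hard-margin dual. Multiclass is one-vs-one plurality voting with
  nearest-class-mean tie-breaking.
- **MLP**: N–10–1 network, tan-sigmoid hidden units with biases fixed at 1,
  a single linear output regressing the integer class label, per-sample
  gradient descent. The backpropagated error terms are the exact gradients
  of the half squared error for this architecture (`delta_out = y - t`
  for the linear output, hidden factor `1 - h^2` for tanh); the package
  verifies them against finite differences in its test suite. Weight
  initialization is uniform in (−0.5, 0.5) from the run seed.
- **GRNN**: one Gaussian unit per training row with the training label as
  output weight; the output is the kernel-weighted label average. The
  kernel sum doubles as an in-distribution score: below `1e-6` the input is
  rejected. This gives the GRNN its closed, hyperspheric boundary.
- **RBFNN**: same centers, but output weights solved from
  `w2 = Phi^{-1} t` (pseudo-inverse fallback for ill-conditioned kernels),
  so the network interpolates its training targets exactly when `Phi` is
  full-rank. Rejection thresholding is off by default: a far-field input
  decays to an output near 0, which rounds to "unknown class 0" rather
  than a rejection — the characteristic failure shape of this model in
  open-set evaluation.

MLP, GRNN and RBFNN round their continuous output to the nearest integer
label, halves away from zero; a rounded value outside `1..M` is an
unknown-class label, counted separately from both trained assignments and
rejections. Features are standardized per sensor (z-score fitted on the
training split) before all distance-based models (k-NN, SVM, GRNN, RBFNN),
since the sensors span different voltage ranges; kernel widths are
therefore in standardized units. The MLP consumes raw voltages, matching
its formulation as a plain regression on the inputs.

One ambiguity was left as-is: the source method description mentions
majority voting between pairwise SVMs "by the k-NN method"; only the
tie-break (nearest class mean) has a defensible reading, and nothing
further was guessed.

## The synthetic generator

No dataset is deposited for the original experiment, so the generator
emulates its statistical structure rather than its measurements:

- **Design**: 8 sensors; 12 classes = 4 fruit types × 3 ripeness states;
  20 replicates per class (240 rows); banana/sapodilla/pineapple trained
  (labels 1–9), mango irrelevant (labels 10–12). These counts are the
  experiment's own.
- **Signatures**: stylized, not digitized from published figures (only
  plots exist). Sensors 1–2 sit near 0.2–0.3 V with negligible class
  variation; sensors 3–8 carry distinct class-varying patterns on a 0–5 V
  scale (the sensors are powered at 5 V, bounding plausible outputs), with
  ripeness scaling the response (×0.65 unripe, ×1.0 ripe, ×1.25 rotten).
  Baselines are 0.1–0.3 V; dispersions 0.02 V (sensors 1–2) and 0.08 V
  (sensors 3–8); response time constant 20 s.
- **Noise**: i.i.d. Gaussian per sensor around the class signature — the
  simplest model consistent with features that are averaged steady-state
  voltages. Steady-state features can also be derived from simulated
  first-order exposure curves (`generate_time_series` +
  `steady_state_features`).
- **Separation**: `enforce_separation` shifts each irrelevant class's
  signature on one designated sensor to `(margin + 4)` dispersions above
  the largest trained-class maximum, then has generation resample any
  residual row that comes within `margin` dispersions of every trained
  box. The default margin of 3 dispersions puts the irrelevant odors
  cleanly outside the trained hyperboxes — the regime in which the original
  irrelevant (mango) data behaved under the closed-boundary models — while
  remaining unremarkable to closed-world classifiers, which classify them
  anyway.

What the generator does *not* emulate: gas-concentration kinetics,
humidity/temperature effects, sensor drift, and cross-sensor correlation.
Passing tests on this generator therefore demonstrate the classifiers'
open-set *semantics* (who can reject, who must false-alarm, and the
arithmetic of the reports), not field performance on real fruit odors. In
particular the trained-class accuracy of MMM here (tight boxes, see above)
is pessimistic relative to what the original experiment reports, because
the 8 synthetic sensors are independent; correlated real sensors make box
coverage less punishing. The trained-class error tables on synthetic data
should be read with that caveat.

## Split protocol and numerical choices

- **Splits** are stratified per class (the original per-class test counts
  are equal, which implies stratification), shuffled within class from a
  seed. Sizes per class of `L`: `floor(0.70 L)` train, `floor(0.15 L)`
  validation, remainder test — giving 14/3/3 under 70/15/15 and 14/0/6
  under 70/30 for `L = 20`, hence test sets of 27 and 54 over 9 classes.
  k-NN and SVM use 70/30 (they need no validation split); MMM, GRNN,
  RBFNN and MLP use 70/15/15.
- **Percentages** in reports are printed to 4 decimal places, halves
  rounded away from zero (1/54 → 1.8519%).
- **Seeds**: one global seed fans out to stage seeds by a fixed offset
  scheme (`derive_seed`), so generation, splitting and initialization are
  independently reproducible; every generator function restores the
  caller's RNG state.
- **Degenerate inputs**: a single-point class yields a zero-width box with
  `S = 0` (expansion is then a no-op for that class); constant sensors get
  unit scale in the standardizer; an ill-conditioned RBF kernel falls back
  to the Moore–Penrose pseudo-inverse; PCA clamps round-off-negative
  eigenvalues and fixes component signs (largest-magnitude loading
  positive). Model JSON is written with 17 significant digits so round
  trips are bit-exact.
- **PCA** uses the sample covariance (n − 1); it serves visualization
  only and plays no role in classification.

## Problem sizes

The shipped tests and the acceptance script run the full design (240 rows,
8 sensors) for end-to-end checks and small 2-D/3-D instances for the
property checks against brute-force oracles (box membership, sort-and-vote
k-NN, margin search over orientations, finite-difference gradients); the
multi-seed comparison in the tests uses 2 seeds and a model subset. These
sizes keep the whole suite in the order of seconds while exercising every
code path; `run_comparison` scales to the 10-seed, 6-model table directly.

## Known limitations

- The hyperbox region ignores sensor correlation; strongly correlated
  classes are over-covered, increasing overlap ties.
- Uniform expansion can only trade rejection errors against boundary
  overlap globally; a per-class schedule (out of scope) could do better
  when validation errors localize.
- The GRNN/RBFNN rejection threshold on the kernel sum is a fixed constant
  in standardized-feature space; it is the mechanism's simplest form, not a
  calibrated novelty score.
- Hard-margin SVM training fails on non-separable data by construction;
  the soft-margin option is the practical default for noisy draws.
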