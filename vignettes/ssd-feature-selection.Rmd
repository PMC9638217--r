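---
title: "Wrapper feature selection with the Social Ski-Driver and Adaptive Beta Hill Climbing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper feature selection with the Social Ski-Driver and Adaptive Beta Hill Climbing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Given a table of `n` samples by `d` numeric features with a binary label
(in the motivating application: deep features of mammogram mass patches,
benign vs malignant), wrapper feature selection searches for the binary
mask `m` minimizing

    Fitness(m) = w * alpha(m) + (1 - w) * |s| / d

where `alpha(m)` is the classification error of a k-nearest-neighbour
classifier restricted to the selected columns and evaluated on a held-out
part of the data, `|s| = sum(m)`, and `w` weights error against subset
size. Lower is better; the two terms are deliberately antagonistic.

`ssdfs` implements this with a binary **Social Ski-Driver** (SSD) swarm.
Each agent carries a binary location (a mask), a real-valued velocity, and
its personal best. The swarm's shared attractor is the **mean global best**
(MGB), the elementwise average of the three best masks found so far.
Velocities are updated as

    V_j = h * f(r1_j) * (PB_j - L_j) + f(r2_j) * (MGB_j - L_j)

with `f` equal to `sin` or `cos` — one fair coin per agent per update
chooses the branch, and each term gets a fresh uniform draw per dimension.
There is deliberately **no inertia term**: the rule is implemented exactly
as stated, so iteration dynamics are purely attraction-driven. The
exploration weight decays geometrically each iteration, `h <- r * h`
(defaults `h0 = 100`, `r = 0.9`), moving the swarm from exploration to
exploitation.

Because masks are binary, the velocity acts through a V-shaped transfer
function `V(x) = |x| / sqrt(1 + x^2)`: per dimension, the bit flips to its
complement when `V(velocity_j)` exceeds a fresh uniform draw, else it is
kept. The transfer function saturates toward 1, which is why unbounded
early velocities (with `h0 = 100` they are large) need no clamping.

After each binarization the mask is refined by **Adaptive Beta Hill
Climbing** (ABHC): for `z = 1..MT`, a real-valued neighbour
`L'_j = L_j ± rand * N(z)` is drawn inside the shrinking radius
`N(z) = 1 - z^(1/c) / MT^(1/c)`, mixed with the incumbent by the growing
keep-probability `Beta(z) = (Ma - Mi) * z / MT + Mi`, clipped to `[0, 1]`,
thresholded at 0.5, and accepted only on a **strict** fitness improvement.
Strictness guarantees the refinement never worsens the agent and that
improvement chains terminate.

## Design choices in the genuinely open places

* **Flip target of the binarization.** The update rule is written
  self-referentially (the transfer of a location deciding that same
  location). We follow the standard V-shaped binary-optimization
  convention: the transfer function is applied to the *updated velocity*
  component, and a success flips the agent's *current bit* to its
  complement. This preserves the usual semantics (large velocity ⇒ likely
  change) while keeping agents purely binary; the continuous
  position-plus-velocity rule is superseded by the transfer step.
* **Weight semantics of `w`.** The fitness formula is implemented verbatim
  with default `w = 0.2`, which puts weight 0.2 on the error and 0.8 on
  the subset-size term. Descriptions of this family of fitness functions
  elsewhere attach the large weight (e.g. 0.98) to the error; the two
  conventions contradict each other, so the formula is implemented exactly
  as written and `w` is an explicit argument — pass `w = 0.98` for
  error-dominant selection. See "Behaviour under strong subset-size
  pressure" below for the practical consequence.
* **Top-3 as an archive.** MGB averages the three best *distinct* masks
  found anywhere so far (an elitist archive), not the current population's
  top three. This stabilizes the attractor and makes the best-so-far
  fitness history non-increasing by construction. Ties are broken by
  smaller subsets, then by lexicographically smallest mask, making every
  run deterministic.
* **Initialization.** Masks start uniform Bernoulli(0.5) (empty masks
  repaired to a single random bit), velocities start at zero, so the first
  iteration is purely attraction-driven.
* **Empty masks.** The fitness is undefined at `|s| = 0`; an empty mask is
  assigned the worst fitness 1.0, and the stochastic operators repair
  all-zero results by switching one uniformly chosen bit on (flagged via an
  attribute).
* **ABHC on bits.** The neighbourhood step is real-valued while solutions
  are bits, so ABHC operates on a relaxed `[0, 1]` representation with
  clip + 0.5 threshold (ties to 1). This keeps both the neighbourhood and
  mutation rules literal and still returns valid masks. The mutation keeps
  the original value where `Beta > rand` — note this orientation makes
  `Beta` a *keep* probability that grows over the local search, the
  opposite of the usual beta-hill-climbing mutation rate; it is implemented
  as specified and flagged here for users.
* **KNN settings.** `k = 5` by default (standard wrapper practice), odd
  enforced so binary votes cannot tie; distance ties break by lower
  train-row index (stable ordering) and forced vote ties (even `k`) by the
  single nearest neighbour — full determinism. The wrapped classifier is
  written in the package because these tie rules are part of the contract.
* **Fitness split.** Each fitness evaluation uses one stratified 80/20
  hold-out split fixed for the whole run (configurable via
  `test_fraction`, or pass a `split_pair` explicitly to compare runs on
  identical data). Cross-validation would multiply the cost of every
  evaluation; the split is part of the returned object so results are
  auditable.
* **Standardization.** Features are z-scored with *training* statistics
  (population, divide-by-n SD); constant training columns map to 0 in both
  parts, keeping the transform total, deterministic and idempotent.
* **Reproducibility.** One master seed spawns one independent
  L'Ecuyer-CMRG substream per agent (`rng_streams()`), so replays are
  bit-identical and independent of how much any one agent draws. Fitness
  values are memoized per mask; the evaluation counter includes memoized
  hits, and is bounded by `PS * (1 + iterations * (1 + MT))`.

## The synthetic generator

`sim_feature_table()` emulates the kind of feature table the selector is
meant for, with unambiguous ground truth: informative columns are
unit-variance normals whose class means differ by `class_separation` (in
SD units), redundant columns are noisy *copies* of informative columns
(round-robin sources, noise SD 0.1 by default) rather than general linear
combinations — so "recovered via a copy" is well defined — and noise
columns are label-independent standard normals. Labels are balanced
exactly rather than by coin flips, which keeps stratified splits stable at
small `n`. Class separation 3 is the package's reference condition for
"clearly recoverable signal": it gives a single-feature Bayes error of
about 7 %, comfortably detectable at `n = 200`.

What the generator does **not** emulate: correlated informative features,
heteroscedastic classes, class imbalance, label noise, and the heavy
feature correlation structure of real CNN embeddings. Passing tests on
this generator therefore demonstrate the optimizer's search behaviour and
the pipeline's correctness, not clinical performance.

`sim_blob_images()` provides the image-side analogue: positives contain a
bright Gaussian blob at random position/width over smooth background
texture, negatives texture only — enough to smoke-test the extractor, in
no sense a mammogram simulation.

## Behaviour under strong subset-size pressure

A property worth understanding before interpreting recovery scores: the
fitness is strictly increasing in `|s|` for every `w < 1`, so whenever a
small subset reaches (near-)minimal hold-out error, the *global optimum*
is that small subset. At class separation 3, one or two informative
columns already achieve ~0–7 % error, so the optimizer — when it works
correctly — selects 1–3 features and leaves the other informative columns
out. The acceptance script quantifies this: on the 64-feature condition it
reports mean subset sizes around 2 and mean informative recall around 0.2,
*with the selected-subset fitness beating the all-features mask on every
run*. High informative recall under these conditions would indicate a
broken minimizer, not a better one. Users who want large informative
subsets should weaken the size term (`w` close to 1) or lower the class
separation of the benchmark.

## The attention-aided extractor

`build_extractor()` assembles, natively in R (im2col convolutions backed
by BLAS), a VGG-16-layout backbone: five blocks of 3×3 same-padding
convolutions with ReLU (2-2-3-3-3 layers, 64-128-256-512-512 channels)
each followed by 2×2 max-pooling. The backbone weights are randomly
initialized (He scaling) and frozen — only the layers above it train:

* a **1×1 locally-connected attention layer** (independent weights per
  spatial position) with **sigmoid** activation, chosen because the
  weighted average needs nonnegative, not-all-zero weights — a sigmoid map
  cannot be identically zero;
* **weighted global average pooling**: per channel,
  `sum(a * f) / sum(a)` — the renormalization by the attention mass makes
  the output invariant to positive rescaling of the attention map and
  reduces exactly to plain GAP under uniform attention;
* dropout 0.5, a dense **bottleneck of 128 units** whose ReLU activations
  are the exported deep features, dropout 0.25, and a 1-unit sigmoid head.
  The two dropouts sit before and after the bottleneck; with a 512-channel
  pooled vector, the 128-unit bottleneck is what makes a "quarter of the
  features" subset equal 32.

Training is minibatch SGD (batch 64) on binary cross-entropy with analytic
backpropagation through the head — including through the weighted-GAP
ratio and the attention sigmoid — with initial learning rate 1e-2, halved
after the third epoch (both configurable; some published configurations
use 1e-3, so the rate is an explicit argument). Because the backbone is
frozen its activations are computed once per image and cached across
epochs. Inference disables dropout, so feature extraction is
deterministic. The default input size is 299×299 (the native patch size
of the motivating dataset); any other size is accepted and resampled with
a message, and tests use 32–48 px inputs where the architecture's
contracts (pooling identity, 128-d output, freeze behaviour) are
size-independent.

## Numerical and testing choices

* Exact Mann-Whitney p-values are computed by complete enumeration of rank
  assignments (midranks for ties) when `n1 + n2 <= 12`; beyond that a
  normal approximation is used with tie-corrected variance, a continuity
  correction, and an Edgeworth kurtosis term based on the exact fourth
  cumulant of U — on Gaussian 8-vs-8 samples the two paths agree to a few
  10^-4. `stats::wilcox.test` serves as an independent cross-check in the
  test suite, never as the implementation.
* The five-simulation protocol reports the mean and *sample* (n−1)
  standard deviation; the test suite pins this convention against a fixed
  five-value example.
* The exhaustive oracle (`d <= 16`) enumerates all non-empty masks with
  the same memoized evaluator the optimizer uses, and the optimizer is
  required (in tests) to match its optimum on a d = 8 problem for at least
  4 of 5 seeds — at desk scale the stochastic search should essentially
  always find the global optimum.
* Problem sizes in the test suite and acceptance script — n = 200–300,
  d = 8–64, populations of 4–10 agents, 3–40 iterations, MT = 2–10 —
  were chosen so a full run completes in well under a minute on one CPU
  while still exercising every code path; they are the package's reference
  desk-scale conditions, not tuning targets.

## Known limitations

* The wrapped classifier is KNN only; no alternative wrapped models.
* ABHC is the only local search shipped; the refinement slot in
  `ssd_select()` is not pluggable from the public API.
* The extractor has no pretrained weights and no GPU path; it is a
  correctness-faithful implementation at desk scale, not a performance
  tool. Multi-class labels, sparse inputs and missing values are out of
  scope throughout.
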