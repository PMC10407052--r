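---
title: "Group coding of visual numerosity: models, generators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group coding of visual numerosity: models, generators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

When an object-recognition network looks at a scene, its final
classifier layer does more than name the dominant object: every unit
shows some activation, and these co-activations ("sidebands") carry
information beyond the top category. This package implements an analysis
pipeline for one such signal — the number of objects in the scene.
The working hypothesis has three parts:

1. **Group coding.** Numerosity is represented by the joint activation
   pattern of the category layer: with more items, the per-unit mean
   activation across pictures rises while the cross-picture standard
   deviation falls (units respond more, and more consistently).
2. **Decodability.** A small readout network — the activations of
   monotonically tuned units, one hidden layer, one output unit — can
   estimate the item count, and behaves like a human observer in a
   two-alternative comparison task (an S-shaped psychometric curve over
   numerical distance, with a compressive bias at the extremes).
3. **Embedding dependence.** Pictures whose objects are well *embedded*
   in the network's category manifolds — high maximum correlation
   between each object's activation vector and some category's mean
   profile — support sharper numerosity discrimination, for networks
   and for human observers alike (tested by representational
   similarity analysis across agents).

Full-scale versions of these analyses require large photographic
datasets and a pretrained deep network. The package therefore couples
every analysis stage to seeded synthetic generators that reproduce the
*statistical structure* of the problem at desk scale, so that the whole
pipeline is testable end to end without downloads.

## The planted-structure activation generator

`gen_activation_dataset()` draws a pictures x units table of
non-negative responses. Its model, per picture $i$ with numerosity
group $g \in \{1..7\}$, category $c_i$ and embedding fidelity $f_i$:

$$x_i = \max\!\big(0,\; f_i\,(\mu_g + P_{c_i} + \varepsilon_i) +
(1-f_i)\,\eta_i\big)$$

* $\mu_g$: baseline mean (default 0.15) for background units; for the
  $n_\text{inc}$ planted increasing units the mean grows by
  `slope_mean` (default 0.05) per numerosity level, for the
  $n_\text{dec}$ decreasing units it falls symmetrically.
* $\varepsilon_i$: Gaussian noise with `baseline_sigma` (default 0.15);
  for planted units the standard deviation shrinks by `sigma_scale`
  (default 0.9) per level — the "more consistent with more items"
  signature. Responses are rectified at zero, matching the
  post-rectification character of classifier inputs;
  `planted_population_moments()` gives the implied rectified moments
  in closed form, and the test suite holds the generator to them.
* $P_{c_i}$: the picture's category profile row
  (`gen_category_profiles()`), peaking at the category's preferred
  unit (`diag_strength`, default 0.8, weight `profile_scale` = 1).
  Two deliberate refinements: profile rows are category *means*, so
  their background scatter is half the picture-level sigma; and the
  preferred-unit response is the most stereotyped one (half noise),
  which stabilizes the per-picture maximum that the normalization
  step divides by.
* $\eta_i$: unstructured noise with the baseline moments. Because
  $f_i$ convexly mixes the structured vector with noise, it maps
  directly onto the Pearson coefficient used by the embedding module —
  the single knob the embedding analyses need.

The planted-unit layout and the profiles are derived from the
configuration seed alone, while picture-level randomness follows a
separate `picture_seed`; training and validation sets drawn from the
same configuration therefore share one "network structure", as two
image sets shown to the same network would.

**Why these defaults.** The reference conditions are 50 increasing and
15 decreasing planted units in a 300-unit layer, slope 0.05,
`sigma_scale` 0.9, 1000 training pictures per group. Planted counts,
slope and shrink follow the reference analysis; `baseline_sigma` =
0.15 was chosen once so that the comparison task operates in the
psychophysically informative regime (roughly 75–95% correct at
mid distances rather than at ceiling), which is where embedding
effects are measurable. The mixed-fidelity condition spans
$f \in [0.1, 1]$ so that the inferior subset is genuinely degraded.

## Stimulus synthesis

`gen_image_dataset()` draws procedural texture objects (ten
color/pattern families) on black backgrounds — enough structure for a
small classifier, no downloads. Two stimulus families are built from
them:

* **Mosaics** (`compose_mosaic()`): 1–7 sub-blocks in a grid whose
  cell size is the maximum sub-block extent. The grid is the
  factorization rows x cols = n closest to square (1x5 and 1x7 for the
  primes), so every slot is filled. This departs from the more common
  fixed-shape grid with black filler: at desk scale an unfilled slot
  makes the covered fraction of the canvas a numerosity cue that even
  survives heavy noise overlays, confounding the noise-robustness
  analysis.
* **Area-matched scenes** (`compose_ellipse_scene()`): objects are
  cropped to their content box, masked by the inscribed ellipse with a
  Gaussian-faded rim (`clip_ellipse()`), scaled so that the summed
  area matches one target for *every* numerosity (`solve_scales()`
  scans 1000 random ±25% jitter combinations and keeps the best), and
  placed in distinct jittered grid cells — so neither total area nor
  overlap can cue the count. The desk default (400 canvas, 4x4 grid,
  target 30²x7; the test suite uses 240 / 18²x7) is the full-scale
  geometry (2000 canvas, 500-pixel cells, 250²x7) scaled uniformly;
  the fade kernel scales with it.

The degraded variants follow the same conventions throughout: white
noise is i.i.d. uniform in [0, 255] per channel, overlays are additive
then clipped; `apply_region_variant()` dissects foreground and
background by the soft ellipse masks; `phase_scramble()` adds one
Hermitian random-phase field to all channels, preserving the amplitude
spectrum to numerical precision (the DC phase is kept, so constant
images are fixed points). The "inverted Gaussian" rim is implemented
as the binary ellipse mask blurred by a k x k Gaussian kernel
(sigma = k/6) and re-masked, which is exactly a radial attenuation from
1 deep inside to 0 at the rim; the unit tests verify it against a
dense direct convolution.

## The mock backbone

`train_mock_backbone()` provides the layer contract of an
object-classification network at toy scale: a `last_conv` feature map
and a `classifier` layer, deterministic in evaluation. The
architecture is deliberately simple: block-mean resize to 64 px, a
4x4 grid pooling of mean RGB plus per-cell edge energy (mean absolute
gradients), a fixed random 1x1 channel mixing with rectification, and
a trained linear softmax readout. Two choices matter:

* **Edge energy is divisively normalized** by the picture's global
  edge energy — the canonical contrast-normalization computation. It
  keeps occupied-cell features scaling like the color channel under
  area matching (totals independent of the count) and makes pixel
  noise saturate the edge channel, which is what the noise-robustness
  sweep measures.
* **The classifier is linear in the pooled features**, so the
  untrained (random-weight) control is genuinely free of built-in
  numerosity detectors.

This backbone is *not* a miniature deep network, and its untrained
variant is more transparent than a deep one: a decoder trained
directly on untrained-backbone activations of compositional stimuli
can still exploit occupancy and dispersion statistics (estimates of
rank correlation around 0.8 in our measurements). The paper-analogue
claim that does transfer is structural: on area-matched scenes the
untrained classifier layer contains *no selectable monotone units*, so
the group-coding pattern that the trained analysis builds on is absent.
The decoding-level null is therefore measured where it is well defined
— on classifier activations with no numerosity structure at all
(`slope_mean = 0`, `sigma_scale = 1`, no planted units), the
generator's explicit untrained-layer analogue.

## Statistics and numerical choices

* **Normalization**: per picture, responses map to [0, 1] by min–max
  over units; constant rows become all-zero and are flagged degenerate
  rather than dropped, keeping picture counts stable downstream.
* **Deciles**: the 9th decile of per-unit means and 1st decile of
  per-unit standard deviations use linear interpolation between order
  statistics (R quantile type 7); the convention is documented because
  "decile" alone does not fix one, and the tests pin it against a
  direct sort-based oracle. Under the default conditions the mean
  decile rises strictly with the count; the standard-deviation decile
  falls clearly overall but its step between the lowest counts is
  shallow (only the planted units' 10% shrink separates groups 1 and
  2, partially offset by normalization coupling).
* **Unit selection**: strict monotonicity of the seven group means
  plus a per-consecutive-pair significance screen at alpha = 0.1,
  uncorrected (it is a screening threshold). The pairwise test is a
  Welch two-sample t-test across pictures: the reference describes
  paired tests, but pictures are not paired across numerosity groups,
  so no pairing unit exists; the discrepancy is recorded here.
* **Decoder**: selected units → 2000 hidden units (configurable; the
  test suite uses 64–128) → one output; mean squared error against
  the integer count; full-batch Adam with learning rate 0.01, up to
  300 epochs, early stopping on a seeded 90/10 validation split with
  patience 25. The reference fixes none of these; a learning rate of
  1e-3 under 100 full-batch epochs underfits badly, so the defaults
  were raised until training converges on the reference-scale data.
  MSE training naturally produces the observed compressive bias
  (overestimation at one item, underestimation at seven).
* **Comparison task**: pictures are drawn with replacement across
  trials (without replacement within a diagonal trial); "A > B" iff
  the decoded estimate of A exceeds B's, exact ties broken by a
  seeded fair coin. Cells (a, b) and (b, a) replay the same seeded
  trials mirrored, making $S(d) + S(-d) = 1$ exact for $d \neq 0$ —
  a structural identity the tests assert at machine precision.
  The diagonal stores one orientation, so $S(0)$ remains a genuine
  statistical estimate of chance.
* **Side-bias screen** for ingested trial logs: participants whose
  overall left-choice rate leaves [0.35, 0.65] are flagged (the
  reference excluded strongly biased observers without giving a
  number; the threshold is configurable and logged, never silently
  applied).
* **RSA**: the condition-level dissimilarity matrix fills
  $|S(i-j) - 0.5|$ (discriminability) into one 7x7 block per
  condition, assembled block-diagonally; comparisons use the
  within-condition upper triangles only, because the between-condition
  cells are structural zeros, not measurements. The alternative
  reading — concatenating the two rate curves and correlating — is
  available via `method = "concat"`. Agreement is Spearman, tested
  across references with the one-sided signed-rank test under FDR
  control. Two shuffling scopes are provided: item shuffling (within
  blocks; preserves the condition contrast) and entry shuffling (fully
  destructive). Calibration analysis showed that a *single* shuffled
  candidate shared across the twelve references is anticonservative —
  all twelve correlations inherit one random alignment draw — so the
  null simulations permute each reference's entries independently,
  which respects participant exchangeability and holds the empirical
  rejection rate at or below the nominal 5%.
* **Null controls**: a decoder trained on shuffled numerosity labels
  acquires a random but *consistent* ordering of the seven group-mean
  outputs (the effective sample for any rank statistic is the seven
  groups, not the 700 pictures), so single-draw correlations scatter
  widely around zero; the package's null claim is the centring, tested
  over independent shuffle replicates. A decoder trained on
  structure-free activations is the sharper null: it carries no
  information at any sample size, and a fully collapsed constant
  readout is scored as zero rank correlation by definition.
* **Noise-robustness trend**: discrimination at distance 3 is
  non-increasing in the noise weight up to the binomial sampling error
  of the aggregated cells; once performance reaches the chance floor,
  consecutive weights differ only by that sampling noise, so exact
  weak inequality would be a coin flip rather than a scientific claim.

## What the synthetic data do and do not show

The generators reproduce the statistical skeleton of the analyses:
planted monotone units with shrinking variance, diagonal-dominant
category profiles, a fidelity knob that provably maps onto the
embedding coefficient, area-matched compositional geometry, and
logistic comparison behaviour with counterbalanced sides. Passing
tests therefore demonstrate that every stage — normalization, group
statistics, selection, decoding, comparison, embedding, RSA — computes
what it claims and recovers planted ground truth at the stated
operating conditions.

They do not demonstrate anything about real photographs or a real
pretrained network: category structure here is planted rather than
learned, the mock backbone has one pooled layer rather than a deep
hierarchy, and the full-scale headline numbers (specific F statistics,
48/13 and 16/24 unit counts, 66–72% accuracies) depend on those
external assets. The backbone adapter accepts any object satisfying
the layer contract, so a real network can be dropped in where one is
available.

## Problem sizes

The shipped analyses and tests use: 300-unit layers with 1000/150
pictures per group (training/validation), 400 per group for the
mixed-fidelity study, 10x30 toy images at 64 px, 150 mosaics and 150
scenes per numerosity at 240 px, comparison designs of 100 (33 for
subsets) trials per cell with 10 repetitions, twelve reference agents
at 150 trials per cell, and 100 permutation-null simulations.
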