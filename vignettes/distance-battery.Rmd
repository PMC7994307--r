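---
title: "A distance-based battery of perceptual and neural properties for layered visual representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A distance-based battery of perceptual and neural properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perceptBattery)
```

## The idea: perceptual phenomena as distance comparisons

Many classic phenomena of human vision and of single neurons in high-level
visual cortex can be recast as statements about *distances* between
stimulus representations.  A Thatcherized face looks grotesque upright but
nearly normal upside down: the representational distance between a normal
and a Thatcherized face should therefore be larger upright than inverted.
Left-right mirror images are confused more readily than up-down mirror
images; a change in the global arrangement of a hierarchical pattern is
more salient than a change in its local elements; discriminability of bar
length follows relative, not absolute, differences (Weber's law); and so
on.  Once each phenomenon is written as a comparison of two distances
\(d_a\) and \(d_b\), a single normalized **contrast index**

\[
\mathrm{CI} = \frac{d_a - d_b}{d_a + d_b} \in [-1, 1]
\]

measures its presence in *any* representation that maps images to feature
vectors — a pixel grid, a layer of a convolutional network, a population of
recorded neurons.  `perceptBattery` implements twelve such tests, each
defined over a purpose-built synthetic stimulus family, and evaluates them
layer by layer for any extractor obeying a small adapter contract.
Distances are Euclidean by default (city-block and one-minus-Pearson are
available); an index profile across layers ends in a presence verdict at
the last fully connected layer.

The battery is self-contained: no external image sets or pretrained
weights are required.  The built-in extractors are a pixel representation,
a seeded *untrained* convolutional network (conv/relu/pool blocks followed
by fully connected layers, Gaussian fan-in-scaled weights), and a family of
analytic surrogates that realize known response laws exactly and serve as
oracles for the index procedures.  A user-supplied extractor (for example
an adapter around a pretrained network) plugs in through the same
contract: an ordered layer list plus a function mapping an image to one
vector per layer.

## The twelve experiments

1. **Thatcher effect.** Schematic faces with exactly known eye/mouth boxes;
   Thatcherization flips pixel rows inside each box.  Index: contrast of
   the normal-vs-Thatcherized distance upright versus inverted.  For any
   pixel-like representation the index is *exactly zero*: inversion (a
   180° rotation) is a fixed pixel permutation applied to both members of
   a pair and Euclidean distance is permutation invariant.  This null is
   the battery's built-in sanity check.
2. **Mirror confusion.** Asymmetric silhouettes (half of them 90°-rotated
   copies, so elongation cannot bias the comparison) with left-right and
   up-down mirrors.  Positive index: left-right mirrors closer.
3. **Scene incongruence.** Objects composited, pixel-identically, onto
   their own (congruent) or another object's (incongruent) context
   texture.  Index: contrast of each scene's distance to the object's
   average feature vector.  A surrogate classifier additionally yields
   top-1/top-5 accuracies on congruent vs incongruent scenes.
4. **Multiple-object normalization.** 49 objects at 3 locations (147
   singletons), 200 pairs and 200 triplets composed pixelwise from the
   singletons.  For units responsive at all three locations, the display
   response is regressed on the sum of singleton responses: slope 0.5 for
   pairs and 1/3 for triplets is the signature of response averaging
   (divisive normalization).
5. **Correlated sparseness.** Reference shapes, morphlines between them,
   textures, and silhouettes.  Unit sparseness
   \(S = \bigl(1 - (\sum r_i/n)^2 / \sum (r_i^2/n)\bigr)/(1 - 1/n)\)
   is computed per subset (after min-max normalization) and correlated
   across units between subsets.
6. **Weber's law.** Bars whose default length ladder mixes geometric and
   arithmetic spacing, so absolute and relative length differences
   decorrelate (their correlation is about 0.86 on the default ladder;
   a purely geometric ladder would confound the two predictors).
   Reported: \(r_{rel} - r_{abs}\), positive under Weber-like coding.
7. **Relative size.** Two-part silhouettes whose part sizes cross at two
   levels (2 × 2 tetrads).  Entries (unit × tetrad) are ranked by the
   interaction \(|r_{11} + r_{22} - r_{12} - r_{21}|\); the top 7% are
   kept; the index contrasts incongruent (\(|r_{12}-r_{21}|\)) with
   congruent (\(|r_{11}-r_{22}|\)) response differences.
8. **Surface invariance.** Patterns on tilted surfaces, tilts crossed
   independently; congruent cells share the pattern-relative-to-surface
   geometry.  As (7) with responses normalized first and a 9% fraction.
9. **3D processing.** Line-drawing pairs whose members differ by identical
   junction strokes, embedded either in an isometric (3D-looking) outline
   or in two flat control outlines.  Index per family and control
   condition: contrast of the 3D-pair distance with the control-pair
   distance.
10. **Occlusion and depth ordering.** Square/disk displays: occluded vs
    unoccluded arrangements, two depth orders, and 2D controls carrying
    the *identical* pixel-difference mask.  Index: \((d_2 - d_1)/(d_2 +
    d_1)\) with \(d_2\) the control-pair distance, positive when occlusion
    costs less than the equivalent 2D change.
11. **Object parts.** Seven two-part objects broken at a natural cut (the
    seam between the generating part contours) or an unnatural cut (a
    fixed offset into the lower part); break = background gap, preserving
    foreground area exactly.  Index 11A contrasts the two break distances.
    Experiment 11B fits the **part-sum model** (below) to the 49-object
    recombination sets and reports the natural-part advantage
    \(r_{natural} - r_{unnatural}\).
12. **Global advantage.** A 7 × 7 grid combining seven shapes at the
    global and the local scale.  \(d_{global}\) is the mean distance over
    the 147 pairs differing only globally, \(d_{local}\) over the 147
    pairs differing only locally; the index is their contrast.

## The part-sum dissimilarity model

For two-part objects AB and CD the model writes the dissimilarity as

\[
d(AB, CD) = C_{AC} + C_{BD} + X_{AD} + X_{BC} + W_{AB} + W_{CD} + c,
\]

with corresponding-part terms (C), across-location terms (X),
within-object terms (W) and a constant.  With 49 objects built from 7
parts there are \(\binom{49}{2} = 1176\) equations and \(3 \times
\binom{7}{2} + 1 = 64\) unknowns, solved by least squares (SVD;
minimum-norm with a warning if rank-deficient).  A relation between two
copies of the *same* part contributes nothing — the convention that keeps
exactly 21 columns per family; how same-part relations enter the design is
not otherwise determined, and this choice is declared rather than
inferred.  Model performance is evaluated as the observed-vs-predicted
correlation on the 21 pairs between the 7 common objects (the diagonal of
both recombination sets).  The battery fits the full 1176-pair system;
a subsampling option exists but no particular subset is privileged.

## What the synthetic generators emulate — and what they do not

Every generator is a pure function of its parameters and an integer seed:
reruns are bit-identical, counts are exact (147 singletons, 49
hierarchical stimuli, 24 tetrads, 49 + 49 composites), and all images are
8-bit grayscale on a square canvas (224 px by default; the battery's
default analyses use 64 px).  The families emulate the *structure* of the
original experimental stimuli — known eye/mouth boxes, mirror/rotation
companions, pixel-identical object insertion, singleton-composed displays,
morphline interpolation, decorrelated length ladders, factorial tetrads,
stroke-identical drawing pairs, seam-defined parts, position/shape
factorized hierarchical patterns — but *not* their natural-image content:
no photographic faces, objects or textures, no photorealistic rendering.
Consequently, passing tests demonstrate that the battery's machinery
measures what it claims on representations with known ground truth
(surrogates, pixels, seeded random networks); they do not by themselves
establish how a pretrained network behaves on natural stimuli.  The
"natural" vs "unnatural" cut of the part generator is likewise a
structural stand-in (contour-junction seam vs offset cut) for the
perceptual definition.

Geometry defaults (sizes, spacings, stroke widths, jitters) are declared
package choices scaled to the canvas, selected once for legible,
non-degenerate stimuli at 48–224 px; they are not derived from any source
imagery.

## Numerical and design choices

- **Visual activity.** "Non-zero variance" uses a relative tolerance
  (1e-12 of the mean-square response): exact zero tests are fragile in
  floating arithmetic.  The multiple-object analysis requires variance at
  *each* of the three locations separately.
- **Undefined items.** When \(d_a + d_b = 0\) the contrast index is
  undefined; items are excluded and counted, never imputed as 0, and a
  layer with no defined items is flagged undefined rather than dropped.
  A notable case: for the *pixel* representation the two parts of a size
  tetrad never overlap, every pixel depends on at most one part's size,
  all interactions are exactly zero and the relative-size layer is
  flagged undefined — the honest answer for a separable representation.
- **Slope fits** use ordinary least squares with a free intercept; all
  analytic oracle cases are intercept-insensitive.
- **Correlations** are Pearson throughout.
- **Tetrad selection** pools (unit, tetrad) entries per layer and keeps
  \(\lceil f N \rceil\) with stable tie-breaking in entry order; s.e.m. is
  reported across selected entries.  Within-unit "distance" between two
  scalar responses is the absolute difference (a vector variant across
  units is a config option).
- **Scene average.** The object's average feature vector is the mean over
  *all* of that object's images (isolated + both scenes).  Averaging over
  the two scenes alone — an alternative the package exposes as
  `average = "scenes"` — degenerates when there is exactly one congruent
  and one incongruent scene: the average is then their midpoint and the
  index is identically zero, so it is not the default.
- **Global-advantage s.e.m.** is a seeded bootstrap over pairs (the index
  is a ratio of means, so no per-item decomposition exists); 500
  resamples by default in the battery, 1000 in the standalone function.
- **Morphline sparseness** is averaged across the four morphlines before
  correlating with the reference-set sparseness; units must be active on
  both subsets of a pairing, and responses are normalized across the
  union of the two subsets being compared.
- **Presence rule.** "Present" means: at the last fully connected layer,
  the mean index is positive and exceeds its s.e.m. in magnitude.
  Single-layer profiles (the pixel representation) are judged at their
  only layer.  The rule is recorded in every report's provenance.
- **Random-network initialization** is zero-mean Gaussian with
  sd = 1/sqrt(fan-in) and zero biases, keeping deep activations in range
  so selectivity analyses are non-degenerate.  Unit subsampling for the
  normalization scatter (when a layer exceeds `nUnitsSample`) is uniform
  without replacement under the config seed.

## Problem sizes

The battery defaults are the study conditions: 20 faces, 100 mirror
objects, 40 scene objects, 49 objects × 3 locations with 200 pairs and 200
triplets, 8 reference shapes with 4 morphlines (5 intermediate steps),
128 textures and 128 silhouettes, the 10-length default bar ladder, 24
size tetrads, 6 patterns × 4 surfaces, 3 drawing families, 7 part objects
(49 + 49 composites), and the 7 × 7 hierarchical grid.  The package's own
analyses and tests run these at a 64-px canvas with the small reference
convnet, where a full 12-experiment battery takes well under a minute on
one CPU; the canvas, network width and set sizes all scale up from the
config.

## Known limitations

- The reference convnet is untrained by design; the battery characterizes
  *architectures and representations*, not trained object recognition,
  unless the user supplies a trained extractor through the adapter.
- Surrogate extractors read stimulus tags, not pixels; they validate the
  index procedures, not the generators' visual content.
- The part-sum generative oracle operates at the distance level: exact
  part-sum distances are not generally embeddable as Euclidean distances
  between activation vectors.
- Weber's law is tested for bar length only; an intensity variant is
  deliberately out of scope.
- Human and monkey comparison values ship only as annotation constants
  with provenance strings; the battery does not re-estimate them.

## A minimal run

```{r example, eval = FALSE}
cfg <- batteryConfig(extractor = "refnet", imageSize = 64, seed = 1)
report <- runBattery(cfg)
report@verdicts
writeBatteryReport(report, "battery_out", plots = TRUE)
```
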