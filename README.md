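# perceptBattery

Distance-based perceptual and neural property indices for layered visual
feature representations.

## What this is for

Many hallmark phenomena of human vision and of high-level visual cortex —
the Thatcher effect, mirror confusion, scene incongruence, multiple-object
response normalization, correlated sparseness, Weber's law for length,
relative-size and surface-invariant coding, 3D shape processing, occlusion
and depth ordering, natural part decomposition, and the global shape
advantage — can be recast as comparisons between representational
distances.  For two distances `d_a` and `d_b` the shared statistic is the
normalized contrast index

    CI = (d_a − d_b) / (d_a + d_b)  ∈  [−1, 1],

computed per layer of any representation that maps images to feature
vectors, with distances Euclidean by default.  `perceptBattery` implements
all twelve tests end to end for researchers studying what untrained or
trained layered networks share with biological vision: it generates the
required synthetic stimulus families deterministically from a seed,
extracts layer-wise activations through built-in extractors (pixel
representation, seeded random convnet, analytic surrogates) or a
user-supplied adapter, computes every index with exclusion accounting, and
reports per-layer profiles with a presence verdict at the last fully
connected layer.

Experiment 11B additionally fits the part-sum linear dissimilarity model

    d(AB, CD) = C_AC + C_BD + X_AD + X_BC + W_AB + W_CD + constant

(1176 equations, 64 unknowns for 49 two-part objects built from 7 parts),
evaluated on the 21 pairs between the common objects, giving the
natural-part advantage `r_natural − r_unnatural`.

## Worked example

Compute the Thatcher-effect profile of an untrained reference convnet on
20 schematic faces:

```r
library(perceptBattery)
faces <- makeFaces(20, seed = 1, size = 64)
ts    <- thatcherStimuli(faces)            # upright/inverted x normal/Thatcherized
net   <- referenceConvnet(seed = 1, inputSize = 64)
acts  <- extractFeatures(net, ts)
thatcherIndex(ts, acts)
```

```
   layer  name  kind      mean     sem  n excluded defined
1      0 input input  0.000000 0.00000 20        0    TRUE
2      1 conv1  conv  0.000000 0.00000 20        0    TRUE
3      2 relu1  relu  0.000431 0.00105 20        0    TRUE
...
11    10   fc1    fc -0.014239 0.01378 20        0    TRUE
12    11 relu4  relu -0.004379 0.01969 20        0    TRUE
13    12   fc2    fc  0.012914 0.03285 20        0    TRUE
```

Each row is one layer: `mean` is the Thatcher index averaged over the 20
faces and `sem` its standard error.  At the input (pixel) layer the index
is exactly 0 — inversion is a pixel permutation, so upright and inverted
pairs are equidistant — and in this untrained network it stays near 0
through the last fully connected layer (`fc2`: 0.013 ± 0.033), so the
presence verdict is `absent`: random wiring alone does not produce the
Thatcher effect.

The full battery over all twelve experiments:

```r
cfg    <- batteryConfig(extractor = "refnet", imageSize = 64, seed = 1)
report <- runBattery(cfg)
report@verdicts                     # one present/absent verdict per experiment
writeBatteryReport(report, "battery_out", plots = TRUE)
```

A command-line wrapper with `generate` (write a stimulus family as PNGs)
and `run` verbs is provided at `inst/scripts/run_battery.R`.

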