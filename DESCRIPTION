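Package: perceptBattery
Title: Distance-Based Perceptual and Neural Property Indices for Layered
    Visual Feature Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic visual stimulus families (schematic faces,
    silhouettes, bars, tetrads, line drawings, hierarchical shapes), extracts
    layer-wise feature vectors through built-in pixel, random-convolutional and
    analytic surrogate extractors, and computes a battery of twelve
    distance-based indices of perceptual and neural properties: the Thatcher
    effect, mirror confusion, scene incongruence, multiple-object
    normalization, correlated sparseness, Weber's law for length, relative
    size, surface invariance, 3D processing, occlusion and depth ordering,
    natural part decomposition (including a part-sum linear dissimilarity
    model), and the global shape advantage. Each index is a normalized
    contrast of Euclidean distances between activation vectors, reported per
    layer with a presence verdict at the last fully connected layer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    png,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'battery.R'
    'draw.R'
    'export.R'
    'features.R'
    'indices.R'
    'metrics.R'
    'partsum.R'
    'stimuli-depth.R'
    'stimuli-faces.R'
    'stimuli-objects.R'
    'stimuli-parts.R'
    'stimuli-shapes.R'
    'stimuli-tetrads.R'
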