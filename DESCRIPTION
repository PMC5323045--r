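Package: stgmorph
Title: Morphometric Analysis of Stomatogastric Ganglion Neuron Skeletons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphology of unipolar invertebrate neurons from 3D
    skeletal reconstructions. Parses and writes SWC and NEURON hoc skeleton
    files; computes soma-to-tip path statistics (length, tortuosity, branch
    order), total wiring, furcation profiles, branch angles, symmetry
    indices, Rall powers at branch points, a linearized (somatofugal
    path-length) Sholl profile, and Gaussian kernel spatial density maps.
    Decomposes neurons rooted on a primary neurite into subtrees, fits
    elliptical neuritic fields to subtree tip clusters, and tests spatial
    tiling of the neuropil with a tip-scrambling bootstrap. Grows synthetic
    minimal spanning neurite trees under a wiring cost with a balancing
    factor and compares their morphometric distributions to real neurons.
    Includes a synthetic unipolar-neuron generator with full ground truth
    and a configuration-driven batch pipeline with group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    car,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
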