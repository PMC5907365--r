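Package: regmaxs
Title: Spatial Registration of Neuron Morphologies by Maximizing Volume Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Co-registers pairs (Reg-MaxS) and groups (Reg-MaxS-N) of neuron
    morphologies given in SWC format by maximizing the overlap of the voxel
    volumes they occupy across a sequence of spatial scales. Provides SWC
    reading/writing/resampling, affine transform utilities including the
    measure of anisotropic scaling (MAS), voxel-based pairwise and
    occupancy-based group dissimilarity measures (Earth-Mover-Distance on
    occupancy histograms), multi-scale exhaustive-search parameter
    estimation, a synthetic morphology generator with randomized transform
    and noise test suites, registration performance statistics (exact sign
    test over corresponding-point distances), a PCA-based baseline
    registration, and dendritic density profiles with maximal projections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
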