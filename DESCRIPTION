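Package: rfdseg
Title: Rough-Fuzzy Feature Discretization and Deep-Supervised Segmentation for Retinal OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for segmenting fluid lesions in retinal optical coherence
    tomography (OCT) volumes with a rough-fuzzy discretization pre-module.
    Pixel brightness is fuzzified by fuzzy c-means clustering, candidate
    breakpoints are scored by the approximate precision of rough fuzzy sets,
    and a genetic algorithm selects a parsimonious discretization scheme that
    removes speckle noise and redundant grey levels before the image enters a
    compact 3D encoder-decoder network with dual attention, attention
    refinement and deep supervision. Includes a seeded layered-retina phantom
    generator, a full surface-distance metric suite (DSC, HD95, ASD,
    sensitivity, specificity), and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    png,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
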