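Package: msotmix
Title: Spectral Mixture Analysis for Multispectral Optoacoustic Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing multispectral optoacoustic (photoacoustic)
    image stacks of soft tissue. Provides a synthetic layered tissue-phantom
    generator with known chromophore ground truth and depth-dependent spectral
    coloring; sparse regularized non-negative matrix factorization for
    data-driven spectral unmixing together with constrained linear (NNLS) and
    vertex-component-analysis comparators; a zero-inflated Bernoulli/Box-Cox
    model that standardizes unmixing coefficients across components and
    depths; Sorensen-Dice and Pearson co-occurrence statistics of spectral
    components with nerve-versus-reference contrasts; and hierarchical Ward
    clustering of presence-pattern mixture classes with spectral fingerprints
    and their entropy. A pipeline driver chains the stages reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    pracma,
    ape
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
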