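Package: scatcomp
Title: Dietary Competition Analysis for Large Carnivores from Scat and
    Camera-Trap Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying dietary competition among sympatric
    large carnivores from scat contents and camera-trap surveys. Implements
    pseudo-replication filtering of scat records, diet composition as
    frequency of occurrence and biomass-corrected proportions (Weaver and
    Ackerman regressions with stomach-capacity caps), scat-level Jaccard and
    Bray-Curtis dissimilarities with a permutation PERMANOVA stratified by
    year, Pianka diet overlap with a richness-preserving randomization null,
    standardised Levins niche breadth, Jacobs' prey-preference index driven
    by camera-trap relative abundance, species accumulation curves, and a
    synthetic-study generator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
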