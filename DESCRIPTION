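Package: scatdiet
Title: Diet DNA-Metabarcoding Analysis of Pinniped Scat Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing predator diet from DNA-metabarcoding of scat
    samples, built around the Galapagos sea lion study system. Takes an
    OTU-by-sample read-count table with negative controls and BLAST-style
    taxonomy hits, applies a negative-control-based decontamination cascade
    (tag-switch floor, contaminant screening, control-based and minor-OTU
    filters, low-coverage sample exclusion), assigns prey taxonomy with
    checklist confirmation and identity bands, and summarises diet through
    percent of occurrence, prey richness and sample- and read-based
    rarefaction. Inferential comparisons among rookeries are implemented from
    first principles: Jaccard distances, PERMANOVA with sequential sums of
    squares, PERMDISP multivariate dispersion tests, nonmetric
    multidimensional scaling, Schoener diet overlap and indicator species
    analysis (IndVal), all with seeded permutation tests. A synthetic-data
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
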