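Package: TriComp
Title: Polar-Coordinate Classification of Three-Group Expression Patterns
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Collapses three-group comparisons of gene expression (such as
    counts from cells sorted into the G1, S and G2/M phases of the cell
    cycle) into two polar coordinates per gene: an angle theta in [0, 360)
    degrees encoding the relative expression pattern across the three
    ordered groups, and a radius r encoding the magnitude of that pattern
    in log2 units. Genes are assigned to six 60-degree pattern categories,
    subsets are compared against a background distribution with a
    log-likelihood-ratio (G) test or an exact multinomial test, and phase
    angles from independent datasets or external periodic descriptors
    (e.g. circadian time) are compared on the circle. Includes CPM/RPKM
    normalisation, a per-gene three-group ANOVA with Benjamini-Hochberg
    correction and stringency filtering, a negative-binomial simulator of
    phase-sorted RNA-seq with known per-gene phase and amplitude, readers
    and writers for the tabular formats involved, polar and distribution
    plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    rlang,
    limma
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
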