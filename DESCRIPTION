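Package: hicratio
Title: Comparative Hi-C Analysis of Bacterial Chromosome Reorganization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for differential analysis of bacterial Hi-C contact maps
    on circular genomes: restriction-fragment attribution and binning of
    aligned read pairs, sequential component normalization (SCN) with
    sparse-bin masking, log2 ratio matrices, distance-stratified ratio
    scalograms, virtual 4C profiles, windowed Z-transformation, and
    quantification of distance-independent "butterfly wing" stripes such as
    those that appear when topoisomerase IV is inactivated in Escherichia
    coli. Includes a synthetic contact-map and read-pair generator that
    plants parameterized versions of each signature (power-law distance
    decay, precatenane-like mid-range boosts, terminus insulation with a
    dif border, additive wing hubs) and statistics for fluorescent-foci
    coordinate tables (interfocal distances, colocalization fractions,
    variance F tests, relative cell-axis positions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
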