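Package: nhejTransloc
Title: Reconstruction and Classification of NHEJ Translocation Breakpoint Junctions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing breakpoint junctions of chromosomal
    translocations formed by nonhomologous end-joining (NHEJ) between two
    endonuclease-induced double-strand breaks with 4-nt 3' overhangs.
    Given an assay definition (the two broken ends and their flanking
    context) and observed junction sequences, the package enumerates all
    minimal repair events (trimming, annealing register, microhomology,
    templated gap-filling) that reconstruct each junction exactly, selects
    the most parsimonious explanation, and classifies it into a mechanistic
    repair taxonomy (gap-filling-mediated, microhomology-mediated, direct
    ligation, end-bridging). A seeded simulator generates junction cohorts
    under per-mechanism mixtures and plating experiments, and cohort
    statistics (survival and translocation frequencies, medians, fold
    changes, Mann-Whitney and chi-square comparisons, repair-type
    distribution tables) reproduce the quantitative analyses such assays
    require.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: SequenceMatching, Alignment, Software
RoxygenNote: 7.3.3
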