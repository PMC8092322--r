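Package: trnaswitch
Title: Detection and Analysis of tRNA Anticodon Suppressor Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying anticodon switching in tRNA gene families and its
    phenotypic consequences in yeast. Implements closest-nonequal-neighbour scanning
    of tRNA gene pools for anticodon switches with neighbour-joining trees and
    bootstrap support, strand-aware scanning of multi-sample variant sets for
    substitutions at anticodon positions, a heat-shock codon-demand statistic with
    Kruskal-Wallis testing and 2^-ddCt fold-change arithmetic, a temperature-dependent
    nearest-neighbour folding-energy model for tRNA secondary structures with
    rapid-tRNA-decay flagging, proteome-level mistranslation statistics (valid-value
    filtering, detection-limit imputation, substitution fractions, distribution-shift
    tests, and an S0-moderated t-test with permutation-based FDR), Mendelian
    tetrad-viability models for suppressed essential-gene deletions, and synthetic-data
    generators with exported ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    jsonlite,
    stats,
    utils,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
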