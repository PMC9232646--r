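Package: neochrom
Title: Design, Assembly Planning and SCRaMbLE Simulation for Synthetic
    Neo-Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing synthetic yeast neo-chromosomes from
    pan-genomic DNA fragments and for analysing the experiments built
    around them. Implements Sc2.0-style sequence recoding (terminal
    TAG to TAA stop-codon substitution), synonymous-codon watermarks,
    symmetric loxPsym site insertion, division of a design into
    synthesis chunks with homology overhangs and restriction flanks,
    alternating-marker assembly planning, junction-primer design with
    nearest-neighbor melting temperatures, in-silico homologous
    recombination assembly, telomerator-style linearization,
    Cre/loxPsym SCRaMbLE recombination simulation with a segment-level
    structural-variant caller and coverage-based copy-number
    estimation, and the phenotype statistics used to characterise such
    strains: specific growth rates, phenotype-microarray maximum curve
    height classification, and mitotic (segregational) stability.
    Ships seeded synthetic-data generators for every input so the full
    pipeline can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
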