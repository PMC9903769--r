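Package: magscape
Title: Dereplication, Biogeography, Functional Landscape and Niche
    Projection for Environmental Eukaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for collections of
    metagenome-assembled genomes (MAGs) and single-cell amplified genomes
    (SAGs) recovered from marine metagenomic surveys. Implements genome
    dereplication from pairwise average nucleotide identity (ANI) tables,
    breadth-of-coverage detection and completion-corrected read recruitment
    summaries, a marker-gene novelty score based on RNA polymerase best-hit
    identities, genome-wide functional classification by hierarchical
    clustering of function occurrence profiles with Welch ANOVA and
    Games-Howell differential-occurrence statistics, consensus annotation of
    remote-homology gene clusters, and Gaussian-envelope environmental niche
    models projected onto gridded climatologies with change attribution to
    individual environmental drivers. A seeded synthetic-data generator
    emulates all pipeline inputs with planted, recoverable structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
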