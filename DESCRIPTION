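Package: phagepipe
Title: Phage Discovery, Cataloguing and Virome Ecology from Metagenome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering double-stranded DNA phage
    genomes among assembled metagenome contigs with a six-criterion
    classifier (genome size, viral k-mer signal, hallmark genes, bacterial
    marker exclusion, database-hit comparison and provirus fraction),
    building a species-level vOTU and family-level viral-cluster catalogue
    (greedy ANI clustering, Markov clustering of shared proteins, taxonomy
    voting, lifestyle calls), predicting bacterial hosts from CRISPR
    spacer-protospacer matches, quantifying viral abundance by mapping
    reads to viral hallmark genes (RPKM), and running the downstream
    virome ecology and metadata-association statistics (diversity,
    phage-host correlations, defence-system tertiles, univariate and
    stepwise multivariable regression, PERMANOVA). A synthetic-community
    generator plants ground truth (circular phages, plasmids, prophages,
    CRISPR arrays, abundance coupling and metadata effects) so that every
    stage can be benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
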