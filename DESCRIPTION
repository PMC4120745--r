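Package: orf1evo
Title: Domain Architecture Classification and Reticulate Evolution of LINE ORF1 Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the modular first open reading frame (ORF1) of
    Jockey-superfamily LINE retrotransposons. Annotates ORF1 protein domains by
    position-specific scoring against a packaged profile library with an
    empirical probability calibration, detects coiled-coil segments, classifies
    ordered domain architectures into ORF1 types I-V with subtypes A-C, builds
    bootstrap-supported neighbor-joining phylogenies from concatenated
    endonuclease and reverse-transcriptase domains, clusters RNA-recognition-motif
    units by force-directed all-vs-all similarity, and flags putative horizontal
    ORF1 acquisition from incongruence between ORF1 and ORF2 trees. A
    reticulate-evolution simulator (tree-like ORF2, modular ORF1 with domain
    gain/loss and cross-lineage transfer) provides ground-truthed data for every
    stage, and a transcription of the published subgroup/domain summary table is
    bundled as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
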