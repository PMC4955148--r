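Package: spminer
Title: Profile-HMM Mining and Characterization of Fungal Sugar Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for discovering and characterizing substrate-specific
    sugar transporters of the major facilitator superfamily. Builds a
    function-specific profile hidden Markov model from a curated multiple
    sequence alignment of validated transporters, scores whole proteomes by
    Forward/Viterbi log-odds to rank candidate homologs, clusters top hits
    with neighbor joining plus bootstrap support, reports substrate-
    discriminating sequence motifs and conserved residues, scans promoter
    regions for transcription-factor binding motifs, and fits Michaelis-Menten
    uptake kinetics and specific growth rates from assay data. Includes a
    synthetic-data module that simulates protein families, planted-homolog
    proteomes, uptake assays and growth curves so that every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
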