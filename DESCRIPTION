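Package: ionmut
Title: Heavy-Ion Mutagenesis Dosimetry, Junction Calling and
    Mutation-Spectrum Statistics
Version: 0.1.0
Authors@R:
    person("ionmut", "developers", email = "ionmut@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing heavy-ion (high linear energy transfer)
    mutagenesis experiments in plants. Converts between absorbed dose,
    LET and particle fluence per nucleus area; calls the single mutation
    event separating a wild-type/mutant amplicon pair, including its
    left-aligned placement, placement-ambiguity interval and junction
    microhomology; classifies rearrangement junctions into
    microhomology, blunt and filler-DNA joints; summarises mutation
    spectra (transition/transversion, small alteration versus
    rearrangement) and computes screening mutation frequencies with
    exact binomial intervals. A synthetic-data generator produces
    amplicon pairs, translocation junctions and screening cohorts with
    known ground truth so that every stage of the pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
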