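Package: betle
Title: Design and Analysis Toolkit for Bivalent Traffic-Light CRISPR Reporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with bivalent traffic-light CRISPR editing
    reporters: frame-constrained codon design of exchangeable target
    sequences (stop-codon-free in all three reading frames), validation and
    Type IIS (Esp3I) cassette exchange of annotated reporter constructs,
    in-silico Cas editing and amplicon read simulation, classification of
    amplicon sequencing reads into editing outcomes (N-1/N-2/in-frame/HDR)
    by haplotype counting over guide windows, phenotype prediction for
    single- and multi-integrant cells, and transgene integration-site
    mapping from tagmentation-style junction reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
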