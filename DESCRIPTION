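Package: nbcascade
Title: Boolean Network Screening and Robustness of the Drosophila
    Neuroblast Temporal Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the gene regulatory network that drives
    sequential expression of the temporal transcription factors Hunchback,
    Kruppel, Pdm and Castor in Drosophila neuroblasts.  Implements a
    synchronous three-level Boolean model of the cascade, exhaustive
    enumeration of all candidate sign networks against wild-type and mutant
    expression criteria, extraction of the common (minimum) regulatory
    circuit, network-distance and degree-preserving reconnection statistics,
    and a stochastic continuous transcription-translation model used to score
    the robustness of the surviving networks against parameter variation and
    expression noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
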