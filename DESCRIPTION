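Package: peptag
Title: Integrative Peptide Identification from Tandem Mass Spectra via
    De Novo Sequence Tags and Database Searching
Version: 0.1.0
Authors@R:
    person("peptag", "developers", email = "peptag@example.org",
           role = c("aut", "cre"))
Description: Identifies peptides from tandem mass spectra by combining de
    novo sequencing with protein database searching. Spectra are
    preprocessed (baseline normalisation, four-level intensity
    discretisation, sliding-window denoising, five m/z regions), turned
    into a spectrum graph whose vertices are scored by the likelihood
    ratio of a trainable Bayesian fragmentation network, and long
    sequence tags are extracted from top-ranking antisymmetric paths by
    progressive alignment. Tags are queried error-tolerantly against an
    in-silico tryptic digest using a mass-spectrometry-tailored BLOSUM62
    substitution matrix (similarity score Ss), candidates are re-scored
    by matching nine theoretical fragment-ion types (correlation score
    Sc), and both evidence streams are combined into a final ranked
    score with delta-score confidence and target-decoy false discovery
    rate estimation. A synthetic spectrum and database generator makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
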