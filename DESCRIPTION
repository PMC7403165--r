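Package: gpcmix
Title: Mixture Modelling of Grapheme-Phoneme Correspondence Use in Pseudoword Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcribed pseudoword reading-aloud
    responses. Estimates per-reader weights on simple versus
    context-sensitive grapheme-phoneme correspondences by exact constrained
    least squares over the probability simplex, quantifies response
    variability with item- and participant-level Shannon entropy, computes
    orthographic-cluster frequency, consistency and pronunciation-entropy
    statistics from a pronounced wordlist, and scores test-retest response
    overlap across sessions. Includes a seeded generator of synthetic
    trial-level response tables (mixture-of-rules responders with a random
    lapse process) for parameter-recovery studies, and a pipeline driver
    that runs the full analysis and writes tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
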