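Package: migrainechain
Title: Markov-Chain Analysis of Migraine Attacks from Daily Headache Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for counting and modelling migraine attacks recorded in
    daily headache diaries. Implements the Fill48 imputation of
    migraine-locked days (single migraine-free days sandwiched between
    migraine days), segmentation of diaries into discrete attacks, mapping
    of diary days to the states of an (n+2)-state discrete-time Markov
    chain with a post-attack quarantine state, estimation of onset and
    continuation transition probabilities with continuity-corrected Wilson
    score intervals, duration-trend tests, patient-level bootstrap
    uncertainty, and a seedable generative simulator of the chain including
    a treatment-masking mode that manufactures migraine-locked days.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
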