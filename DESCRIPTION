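Package: eventseg
Title: Automated Event Segmentation and Embedding-Based Recall Scoring
    for Narrative Text
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how readers segment written narratives into
    events and how well they later recall them. Provides word-level boundary
    coordinates and parsing of language-model "segmented copy" output via
    token alignment, leave-one-out point-biserial agreement indices,
    split-group permutation tests of between-group boundary consistency,
    normative-boundary extraction, embedding-based recall scoring through
    square-resized Spearman similarity matrices, intersubject temporal
    agreement (diagonal versus reverse-diagonal), split-half reliability with
    a permutation null and Spearman-Brown correction, and synthetic cohort
    generators (segmenters, recalls, gist raters, mock generation clients)
    so every analysis can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
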