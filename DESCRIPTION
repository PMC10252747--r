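Package: agpscreen
Title: Proteome Mining for Classical Arabinogalactan Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens protein sequence collections for classical
    arabinogalactan proteins (AGPs) using the three classical criteria:
    biased Pro/Ala/Ser/Thr (PAST) amino-acid composition, presence of an
    N-terminal secretory signal peptide, and repeats of the dipeptides AP,
    PA, SP and TP in the mature protein.  Also provides the sequence
    comparison utilities used in prolyl 4-hydroxylase (P4H) family
    analysis: Needleman-Wunsch global alignment with affine gap penalties,
    percent identity under two denominator conventions, gap-based removal
    of alignment columns, and nearest-reference grouping by percent
    identity.  A seeded synthetic-proteome generator plants classical AGPs
    and single-criterion decoys so that the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
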