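Package: shdss
Title: Knowledge-Based Therapy Verification over Semantic NFC Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-based clinical decision support toolkit. Implements a
    structural reasoner for the ALN description logic (acyclic terminology
    unfolding, normalization, satisfiability and subsumption), the non-standard
    matchmaking inferences Concept Contraction and Concept Abduction with
    penalty scoring, a therapy verification and ranking workflow driven by a
    context-aware utility function (contraindication and drug-interaction
    detection, ranked substitute suggestions), and a binary NFC Data Exchange
    Format (NDEF) codec that carries compressed OWL annotations on emulated
    tags. Ships a small rheumatology demonstration knowledge graph and a
    deterministic synthetic annotation corpus for compression studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
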