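Package: vaccalign
Title: Ontology-Based Alignment of Vaccine Coding Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns vaccine coding systems used in electronic health record
    databases by analysing their multilingual free-text code descriptors
    against an ontology of vaccine descriptions. Descriptors are tagged with
    ontology classes using a dictionary-based longest-match tagger, compiled
    into description-logic class expressions, and normalized to property
    values (immunization targets, strategies, ingredients, valences, routes)
    with a built-in EL-style subsumption reasoner supporting subclass axioms,
    existential assertions and property chains. Source codes are assigned to
    their closest target codes under token, class, equivalence and
    property-value similarity with threshold and hierarchy-aware tie
    breaking, and alignments are scored against reference mappings by
    precision, recall and F-score. Includes a curated miniature ontology, a
    seeded generator of synthetic multilingual benchmark coding systems with
    gold alignments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stringi,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
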