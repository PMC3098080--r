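Package: ontoslim
Title: Automatic, Data-Driven Generation of Ontology Slims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates context-specific ontology slims (reduced, high-level
    subsets of a DAG-structured ontology such as the Gene Ontology) directly
    from an annotated dataset. Parses OBO ontology files and GAF annotation
    files, synchronizes annotations against the current ontology version by
    resolving obsolete and alternative identifiers, scores every term with an
    information-content metric that combines annotation mass with a
    graph-complexity penalty, selects slim terms above a threshold with path
    closure to the namespace root, maps original annotations onto the slim
    with typed (is_a/part_of) relations, and performs slim-aware
    hypergeometric enrichment with Bonferroni and Benjamini-Hochberg
    corrections. Includes deterministic synthetic-fixture generators for
    ontologies, annotation sets, and ontology version pairs with planted
    obsolescence events.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
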