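Package: ontosensu
Title: Collaborative Anatomy Ontology Curation with Sensu-Based Synonym
    and Homonym Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for building and curating anatomy ontologies from the
    literature. Records term usages as 'sensu' triples (reference, concept
    referent, term) and infers synonymy, homonymy and published acts of
    synonymy from them; maintains a validated store of concepts with
    genus-differentia definitions, typed relationships forming a directed
    acyclic graph, and controlled-vocabulary tags; reasons over the
    is_a/part_of hierarchy (ancestor queries, property propagation); exports
    to OBO 1.2 and annotated Newick; proofs free text against the ontology
    lexicon and extracts candidate terms; and reports census statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
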