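Package: taxograft
Title: Build Taxonomy Ontologies by Grafting Heterogeneous Sources onto a
    Backbone Hierarchy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for synthesizing a single rank-annotated taxonomy
    ontology from heterogeneous taxonomic compilations. A broad-coverage
    backbone (NCBI-taxdump-style dumps) is combined with specialist sources
    (OBO 1.2 ontologies, flat tabular checklists) by subtree replacement
    grafting, with synonym lists merged across sources by primary-name
    matching. Fossil taxa from PaleoDB-style exports are filtered
    (non-diagnostic material, invalid names, taxa lacking a parent
    classification) and grafted at the lowest inclusive node; disused taxa
    are obsoleted with their valid children reattached at the root, and
    subspecies are demoted to typed synonyms of their species. Builds are
    driven by a declarative YAML configuration, assign stable release
    identifiers, emit a canonical (byte-reproducible) OBO 1.2 serialization
    with has_rank and is_extinct annotations, and produce a machine-readable
    audit of every graft, merge, filter and obsoletion decision. A synthetic
    taxonomy simulator with ground truth supports end-to-end testing of
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
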