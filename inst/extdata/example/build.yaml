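id_namespace: TXO
ontology: example-vertebrate-taxonomy
backbone:
  label: ncbi
  format: taxdump
  prefix: NCBI
  names: names.dmp
  nodes: nodes.dmp
sources:
  - label: tto
    format: obo
    path: tto.obo
    mode: REPLACE
    attachment: Actinopterygii
  - label: aweb
    format: tabular
    path: amphibia.tsv
    mode: REPLACE
    attachment: Amphibia
    prefix: AWEB
    columns:
      root_name: Amphibia
      root_rank: class
      higher:
        order: order
        family: family
      genus: genus
      epithet: species
      common_name: common_name
      synonyms: synonyms
  - label: pbdb
    format: paleodb
    path: fossils.tsv
    mode: FOSSIL
    prefix: PBDB
filters:
  - EXCLUDE_NONDIAGNOSTIC
  - EXCLUDE_INVALID
  - EXCLUDE_PARENTLESS
curated:
  - action: comment
    name: Mammalia
    rationale: Allotherian orders retained pending revision of published treatments.
output:
  obo: out/taxonomy.obo
  report: out/report.json
  registry: out/registry.tsv
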