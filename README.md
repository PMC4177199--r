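# taxograft

Build a single, rank-annotated taxonomy ontology from heterogeneous
taxonomic compilations.

Integrating biodiversity or phenotype data requires one taxonomy that
covers both extant and extinct taxa, carries the synonyms and common names
under which taxa appear in the literature, and supports subsumption queries
(data attached to *Rodentia* or *Primates* must be returned by a query on
*Mammalia*). No single source provides this: broad backbones (NCBI-style
taxonomies) are coarse and mostly extant; specialist sources (curated fish
or amphibian taxonomies) are authoritative but narrow; fossil compilations
mix valid taxa with trace-fossil names, invalid names and taxa that cannot
be placed. `taxograft` synthesizes them.

## The method

The build is a fixed pipeline over a forest of taxon terms (ontology
classes with one `is_a` parent, typed synonyms, cross-references, and
`has_rank` / `is_extinct` annotations):

1. **Backbone import** — an NCBI-taxdump-style dump provides the initial
   hierarchy; every term keeps a cross-reference to its source record.
2. **Replacement grafting** — specialist taxonomies replace designated
   backbone subtrees (e.g. a teleost ontology under *Actinopterygii*, an
   amphibian checklist under *Amphibia*). The attachment node keeps its
   backbone identity; synonym lists are merged across sources by
   primary-name matching, with homonyms disambiguated by rank or shared
   ancestor and otherwise reported rather than guessed.
3. **Fossil filtering and placement** — PaleoDB-style rows associated with
   non-diagnostic material (tracks, eggshells), invalid names, or no parent
   classification are excluded; the surviving subtrees are grafted at the
   lowest node of the proto-ontology that includes them, walking each
   subtree root's recorded ancestry.
4. **Obsoletion** — taxa flagged *disused* become obsolete terms (retained
   for identifier stability, removed from the hierarchy); their valid
   children are reattached at the root for curator review.
5. **Subspecies demotion** — subspecies become `SUBSPECIES`-typed synonyms
   of their species, following the practice of the major specialist
   sources.
6. **Stable identifiers** — terms are reminted into the release namespace;
   a registry keyed by (primary name, source) keeps ids stable across
   releases, retired ids are never reused, and each term's source ids
   survive as xrefs (the provenance mechanism).

The product is a canonical OBO 1.2 file — stanzas and tags in fixed sorted
order, so equal inputs give byte-identical output — plus a JSON merge
report auditing every graft, merge, filter, obsoletion and demotion, and
the id registry. The whole build is driven by one declarative YAML
configuration, so a release is reproduced with a single command.

## Worked example

A small build mirroring the real construction ships in
`inst/extdata/example/`: a 12-term backbone dump, a 7-term teleost OBO
source replacing *Actinopterygii*, a 3-row amphibian checklist replacing
*Amphibia*, and an 8-row fossil table containing a disused order, a junior
synonym, a trace fossil, an invalid name and a parentless row.

```r
library(taxograft)
res <- cmd_build(system.file("extdata", "example", "build.yaml",
                             package = "taxograft"),
                 out_dir = "out")
#> [load] backbone ncbi: 12 terms
#> [load] source tto (REPLACE): 7 terms
#> [load] source aweb (REPLACE): 10 terms
#> [load] source pbdb (FOSSIL): 7 terms
#> [merge] 26 terms, 3 filtered, 1 obsoleted, 1 demoted
#> [write] obo=out/taxonomy.obo
```

26 terms survive: the three junk fossil rows are filtered, the disused
order *Multituberculata* is obsoleted (its valid genus *Ptilodus* moves to
the root), and the subspecies *Danio rerio frankei* is demoted to a
synonym. The zebrafish term shows the merged provenance — its backbone
record, its specialist-source record, and its former subspecies:

```r
get_term(res$graph, find_by_name(res$graph, "Danio rerio"))
#> <taxon_term> TXO:0000014 "Danio rerio"
#>   rank:   RANK:0000028
#>   parent: TXO:0000012
#>   synonyms: 3
#>   xrefs:   NCBI:6 TTO:0000005 TTO:0000006
```

Subsumption queries work over the merged product — *Amphibia* now returns
all 9 checklist-derived descendants:

```r
length(descendants(res$graph, find_by_name(res$graph, "Amphibia")))
#> [1] 9
```

A shell entry point wrapping the same functions is in
`inst/scripts/taxograft` (`build`, `validate`, `simulate` subcommands).

Because real source releases change continuously, correctness is
established against simulated sources: `generate_taxonomy()` plants a
ground-truth tree with synonyms, common names, misspellings, extinct and
disused taxa, subspecies and deliberate homonyms; `fragment_into_sources()`
writes it out as backbone/specialist/fossil files; and the merge must
reconstruct the planted truth exactly (`verify_recovery()`).

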