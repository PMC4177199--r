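---
title: "Building taxonomy ontologies by grafting heterogeneous sources"
author: "taxograft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building taxonomy ontologies by grafting heterogeneous sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxograft)
```

## The model

`taxograft` treats a taxonomy as a forest of ontology classes. Each taxon
term has exactly one `is_a` parent (or none, for roots and obsolete
terms), an optional rank drawn from a controlled vocabulary via the
`has_rank` annotation pattern, a set of typed synonyms, a set of
cross-references to source records, and `is_extinct` / `is_obsolete`
flags. The simple class hierarchy is a deliberate modeling choice: it
makes data aggregation a transitive-closure query (`descendants()`,
`is_subsumed_by()`), which is what downstream knowledgebases need.
Multiple parentage is rejected at load time — all supported source
dialects are trees, and a forest keeps subsumption queries unambiguous.
Obsolete terms remain in the term map, queryable by id and name, but are
excluded from the hierarchy and from subsumption; this follows OBO
obsoletion semantics and is what makes identifier retirement safe for
annotations that still point at an old term.

Synonyms carry an OBO scope and an open type tag. The type tags are the
load-bearing part — they distinguish taxonomic junior synonyms
(`TAXONOMIC`), vernacular names (`COMMONNAME`), spelling variants
(`MISSPELLING`) and demoted subspecies (`SUBSPECIES`). Scopes are assigned
by a fixed package-wide convention, since source formats rarely state
them: taxonomic synonyms are `RELATED` (synonymy judgments can be
subjective), common names and misspellings are `EXACT` (they denote the
same concept), and demoted subspecies are `NARROW` (a subspecies name
denotes a narrower concept than its species). Deduplication is on
(normalized name, type tag), and on conflict the pre-existing scope wins,
so merging is order-stable.

Name normalization trims and collapses whitespace but is case-sensitive.
Scientific names are case-meaningful (genus capitalized, epithet
lower-case), and case-folding would create false homonym merges between,
say, a genus and a vernacular word.

## The pipeline and its fixed stage order

A build runs: backbone import → replacement grafts → curated directives →
fossil filter and placement → obsoletion of disused taxa → subspecies
demotion → stable id assignment → validation. The order matters and is
fixed: grafts must precede fossil placement so that fossil subtrees can
anchor to specialist-provided families; obsoletion must precede demotion
so a reattached subspecies is not demoted onto the wrong parent; ids are
assigned last so every surviving term gets exactly one release id.

**Matching.** Cross-source merging is by primary-name equality, which is
vulnerable to homonymy. The disambiguation ladder is: unique candidate →
unique candidate of equal rank → unique candidate sharing an ancestor
name → give up and report. Reporting rather than guessing is a design
choice: an unresolved homonym is a curation item, not something an
automated build should decide. Curated directives (`move`, `merge`,
`comment`), each with a mandatory free-text rationale copied into the
term's comment, are the escape hatch for cases name matching cannot
express (e.g. cross-genus synonymies such as *Rana catesbeiana* /
*Lithobates catesbeianus*).

**Replacement grafting.** All backbone descendants of the attachment node
are removed and the specialist tree is installed beneath it. The
attachment term keeps its backbone identity — this is what makes grafts
local: nothing outside the subtree is touched, which the test suite checks
bit-for-bit. Removed backbone terms that name-match an installed term
donate their synonyms and xrefs (and their id, as an xref), so no
provenance is lost; unmatched removals are reported as dropped rather than
silently discarded.

**Fossil handling.** Status-table rows are loaded permissively (valid,
disused *and* invalid rows become terms) and all exclusion is done by
explicit filter rules — non-diagnostic material, invalid names, taxa with
no parent classification — because the rules are policy, not parsing.
Rules are pure predicates on the status row, hence order-independent.
Children of a removed term re-parent to the nearest surviving in-table
ancestor. Each surviving subtree is then placed at the lowest inclusive
node: terms whose names match the proto-ontology merge into it; an
unmatched subtree root walks its recorded ancestor names (nearest first)
and attaches to the first that resolves. "Lowest inclusive node" is not
published as an algorithm anywhere; this ancestry-walk reading is the
package's own interpretation, and subtrees with no resolvable ancestor
fall back to the global root with an `unplaced` finding instead of being
dropped. Likewise "attached at the root" for valid children of disused
taxa is read as the single global root, with every reattachment reported
for curator review.

**Identifier stability.** The stable key is (normalized primary name,
source label of first introduction). Terms whose key appears in the prior
release's registry keep their id; new terms get sequential ids after the
prior maximum, in sorted-key order, so assignment is deterministic.
Duplicate keys — deliberate homonyms within one source — get a
deterministic ordinal suffix by pre-assignment id. The returned registry
is the prior registry plus new assignments, so a retired key's id remains
reserved forever; reuse would silently re-target downstream annotations.
Each term's pre-assignment id becomes an xref, which is how the product
ontology records that a term came from, say, both the backbone and a
specialist source.

## Serialization

The OBO 1.2 writer is canonical: stanzas sorted by id, tags in fixed
order, synonym and xref lines sorted in C collation (locale-independent
radix sort). Two builds from equal inputs are byte-identical — a property
the acceptance suite asserts — which makes releases diffable and
verifiable. A `date:` header line is written only when a date is passed
explicitly; an unconditional timestamp would break byte-reproducibility.
Synonym source labels are not serialized (OBO's trailing dbxref list is
left empty), so the round-trip contract covers ids, names, parents,
synonym name/scope/type, xrefs, ranks, flags and comments — not synonym
source attribution. Unrecognized stanza tags are preserved opaquely per
term and re-emitted, so foreign annotations survive a read–write cycle.
The writer refuses graphs with cycles or unresolved parents; findings come
from `validate_taxonomy()`, which reports (rather than throws) cycles,
orphans, obsolete terms retaining parents, duplicate names and rank
inversions.

## The rank vocabulary

Ranks are data, not code: a packaged TSV of canonical names, integer
levels and source aliases, loadable and extensible per project
(`build_rank_vocab()`). Levels (smaller = more inclusive) exist only on
the standard Linnaean ladder plus common intercalated ranks; ranks without
a level (botanical and infrasubspecific ranks) are `INCOMPARABLE`, because
no total order over all published ranks is defensible. The comparisons the
pipeline actually needs — rank-inversion checks and rank-based homonym
disambiguation — only require the ladder. The shipped table is a
practical superset of what vertebrate sources use; no claim is made that
it reproduces any external vocabulary's exact term set. Rank-free terms
are legal everywhere, and unknown rank strings are findings, not errors.

## The simulator and what passing tests mean

`generate_taxonomy()` builds a ground-truth tree under a fixed root with
two designated specialist clades — one carried by an OBO-format source
(TTO-like), one by a flat checklist (AmphibiaWeb-like) — plus background
clades covered only by the backbone. It plants every feature the pipeline
must handle: typed synonyms, common names, misspellings (only in the
OBO-format clade, the one dialect that can express them), whole extinct
genera and families, disused taxa, mixed families listed by both an extant
source and the fossil table, subspecies, deliberate genus homonyms across
families, and junk fossil rows (trace material, interposed invalid names,
parentless rows). A higher taxon all of whose members are extinct is
itself extinct — an extant family with no extant species cannot appear in
a species-level checklist, so extinct status propagates upward (never onto
the designated clade roots).

Default parameters are chosen to resemble the shape of real inputs at desk
scale: 500 species, mean genus size 3, 15% of genera extinct (half that
rate for whole families), 20% of extinct higher taxa disused, 15% synonym
and 25% common-name rates, 5% misspelling rate, 6% subspecies rate, 2%
homonym rate, and small rates of junk fossil rows. The end-to-end suite
runs 50 seeds at this size (~750 terms per run); sizes were chosen so the
whole suite exercises every rule many times while staying fast enough to
run habitually.

`fragment_into_sources()` coarsens the backbone inside specialist clades
(clade root, orders and species only — no families or genera), gives the
specialist sources full coverage of their clades, and routes every extinct
taxon through the fossil table. The expected merge result is derived
*declaratively* from the planted facts — which taxa survive, who their
parents are after obsoletion and demotion, which synonyms with which tags,
and which source namespaces must appear among each term's xrefs — not by
running the merge code, so recovery checks are a genuine oracle.

What passing does **not** show: real sources contain encoding noise,
inconsistent rank usage, genuinely conflicting hierarchies between
sources, and curation-level judgment calls (monophyly of supraspecific
names); none of these are modeled. The simulator also keeps extinction
genus-granular (no mixed extant/extinct genera) and plants homonyms only
among extant genera. Conclusions from green tests are about the merge
rules, not about the fidelity of any real-world release.

## Degenerate inputs and tie-breaks

Empty specialist sources (a bare root) prune the attachment subtree and
report every dropped name. A taxdump record whose parent is itself is the
root, not a cycle. Fossil rows whose parent name is absent from the table
load parentless and flagged; their fate (exclusion or attachment) is
decided by the filter rules and ancestry walk, not the reader. Duplicate
checklist rows are idempotent. Subspecies under a non-species parent, or
with children, are left in place with a finding rather than demoted.
Disused chains (disused under disused) obsolete every link and reattach
the first non-disused descendants exactly once. A disused fossil row that
name-merges onto a pre-existing extant term is *not* obsoleted — that
collision is a curation flag, and obsoleting an extant backbone term on
fossil evidence would be destructive.

## Known limitations

- REPLACE grafting is strictly subtree-local; a specialist source that
  disagrees with the backbone about placements *outside* its clade is
  out of scope and such terms surface only as dropped/unresolved reports.
- No fuzzy name matching: misspellings enter only as explicitly tagged
  synonyms. This is deliberate (silent fuzzy merges are how taxonomies
  corrupt), but it means real-world spelling drift needs curated
  directives.
- The PaleoDB reader consumes a normalized seven-column table; mapping a
  live export's columns onto it is left to preprocessing.
- OWL/RDF output, taxon-as-individual modeling and reasoning beyond
  subsumption are out of scope; the OBO file is the canonical product.
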