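---
title: "Curating anatomy ontologies from the literature with ontosensu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating anatomy ontologies from the literature with ontosensu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontosensu)
```

## The curation model

Anatomical knowledge in groups like the Hymenoptera is scattered across
partially overlapping lexicons: the same structure carries many names, and
the same name ("paramere" is the canonical horror story) has been applied to
mutually incompatible structures by different authors. ontosensu implements
the curation model that turns this situation into data. Its unit of
evidence is the **sensu**: the triple *(reference, referent concept set,
term)* recording that a particular publication used a particular label for a
particular concept (or, occasionally, a combination of concepts). Concepts
themselves are anonymous until documented; labels are free-floating strings
until a sensu ties them to a concept.

From the sensu table three relations are *computed rather than asserted*:

* **synonymy** — two terms with sensus pointing at the same referent set;
* **homonymy** — one term with sensus pointing at two or more distinct
  referent sets;
* **acts of synonymy** — a single reference tying two or more terms to the
  same referent, i.e. a published synonymization.

Referent identity is exact set equality. Two composite usages that overlap
without being equal (the paramere example has referent sets
{389,1084} and {707,389,1084}) are distinct referents, hence evidence of
homonymy, not synonymy: the curation view treats all such usages as
incompatible. Because nested referent pairs are plausibly refinements
rather than conflicts, `homonyms()` flags them in a separate `has_nested`
column so downstream consumers can filter; it does not change the count.

Synonymy at a fixed referent is an equivalence relation on the terms with a
sensu to that referent; the test suite checks the partition property on
random stores. Inference is insensitive to insertion order (all reports are
canonically sorted) and language-agnostic: a German and an English label on
the same referent are synonyms. Nothing smarter is attempted — no fuzzy
matching, no cross-ontology alignment.

## The store and its invariants

The store is a list of tibbles, one per record type, manipulated through
`add_*()` verbs that enforce invariants at insertion time:

* identifiers unique across record tables;
* `(text, language)` unique among terms;
* relationship triples unique; hierarchy relations (is_a, part_of) reject
  self-loops and any edge that would close a directed cycle — the error
  names the offending path;
* sensu referents non-empty, `(term, referent, reference)` unique, and at
  most one `obo_label` sensu per concept (the 1:1 label used in OBO
  exports);
* tag keywords drawn from a configurable controlled vocabulary.

`validate_onto()` re-checks everything plus referential integrity and
returns a findings tibble rather than failing, mirroring the report style
of an ontology editor's validation pass. Two findings are deliberately
warnings, not errors, because the workflow needs to represent them: a
released concept relating to a still-candidate object (the store permits
drafting below released classes), and a released non-root concept with no
hierarchy parent.

Two design points deserve justification:

* **The root exemption.** A released concept must carry a genus-differentia
  definition, but the genus of the hierarchy root would have to be another
  concept — which by definition it does not have. The unique root (the one
  released concept with no outgoing hierarchy edge) is therefore exempt
  from the genus requirement; it still needs definition text. Roots are
  created released directly by the curator, matching a workflow in which
  the upper-level classes arrive pre-defined from a reference anatomy
  ontology rather than being minted locally.
* **Release preconditions are strict.** `release_concept()` demands all
  three of definition, single-referent sensu and is_a parent, and mints
  serials `PREFIX:NNNNNNN` (7 digits, zero-padded) that are strictly
  increasing and gap-free within a session; the serial counter persists in
  the native JSON document, so reloading a store does not re-use serials.
  Records are never hard-deleted once released; deprecation is a
  `quarantined` tag.

Persistence is a single pretty-printed JSON document with stable key order,
chosen over a relational layout so stores diff cleanly under version
control; `read_onto(write_onto(s))` is record-for-record identical.

## Reasoning

`ancestors()`/`descendants()` compute reachability over user-selected
transitive hierarchy relations (mixed is_a/part_of chains allowed, as in
"femur part_of leg, fore leg is_a leg"). `propagate_property()` implements
the inference those chains license: a quality asserted on a class ("legs
are yellow") is inherited by every concept whose chain reaches it — the
fore leg because it *is a* leg, the femur because it is *part of* one.
Propagation is strictly downward; nothing is inferred about a whole from
its parts. Whether part_of propagation is biologically sound for an
arbitrary quality is the curator's call, not the package's — the machinery
simply reports each inference with its witnessing relationship chain so it
can be audited. `attaches_to` is stored and exported but excluded from
reasoning: it is neither transitive nor a hierarchy relation, and
requesting it raises an error rather than silently returning something.

`census()` summarizes a store in the style of cross-ontology comparison
tables: concept/term/sensu counts, percentage defined, and the distribution
of concepts by the number of relationships *in which the concept is the
subject*. The counting direction and relation scope of the classic table
are ambiguous; we count subject-side over all relation types by default,
with `hierarchy_only = TRUE` to restrict. A 0-relationships bin is added so
the bins always conserve the concept total (the classic table starts at 1).

## OBO and Newick export

`export_obo()` writes OBO 1.2: one `[Term]` stanza per released concept,
sorted by id, candidates excluded, definitions rendered as "A *genus label*
that *differentia*." with sensu references as definition dbxrefs. Synonym
scope is EXACT for labels whose sensu referent is exactly the concept and
RELATED for labels that reach the concept only through a composite
referent (flagged with a trailing comment) — the format has no native way
to say "this label names a combination including this class", so composite
provenance is lossy by design, and `import_obo()` recovers the released
projection only: ids, names, EXACT synonyms, relationships. The header
`date:` defaults to the current time like any release stamp; pass a fixed
value to make exports byte-identical across runs (stores deliberately carry
no wall-clock state, so seeded fixtures are reproducible).

`export_newick()` flattens the released hierarchy to a tree for standard
viewers. The hierarchy is a DAG; the flattening strategy is node
duplication, with `_2`, `_3`... suffixes disambiguating copies under
multiple parents. The default edge set is all hierarchy relations (the
leg example's femur hangs under leg by part_of and should appear in the
tree); pass `rel_types = "is_a"` for the pure subsumption tree. With
`annotate = TRUE` each node carries a `[&labels=N]` comment giving its
number of distinct sensu-linked labels, the quantity viewers use to colour
label-rich regions; comments follow the square-bracket convention, which
some strict parsers require stripping first.

## Text proofing

`proof()` marks up free text against the term lexicon: case-insensitive,
word-boundary, leftmost-longest matching, multi-word terms matched as
phrases that may span whitespace only. Tokenization keeps internal hyphens
("fore-leg" is one token — anatomical terms are frequently hyphenated) and
splits on everything else. Plural folding (naive trailing "s"/"es"
stripping) is available but off by default: exact matching is the
conservative choice when the output feeds curation. Homonymous matches are
flagged ambiguous with every referent set listed. Matching candidate
(unreleased) concept labels is the default, with `released_only = TRUE` to
restrict — a proofer that cannot see drafts would hide exactly the terms
the curators are working on. `render_annotations()` emits hyperlinked HTML
(URI template with an `{id}` placeholder) or a TSV table;
`extract_candidates()` inverts the process, harvesting unknown, stop-word
free n-grams that do not overlap any accepted annotation, frequency-ranked
— the semi-automatic intake path for new terms.

## Fixtures and what the tests do (and do not) show

`build_fixture()` generates the worked examples used across the
documentation — the leg/femur/fore-leg reasoning store, the five-way
paramere homonymy, the minimal three-term/two-concept inference demo, the
phallobase/gonocoxite IX synonym pair — plus seeded random ontologies:
`n_concepts` candidates with hierarchy edges drawn only from later to
earlier creation order (acyclic by construction) at `edge_prob`
(default 0.08), a term pool, and `n_sensus` random sensus of which 10% get
two-concept composite referents. Member labels in the paramere fixture are
invented placeholders; the historical structure names exist only as figure
overlays in the source literature.

The random generator emulates the *shape* of a curated anatomy ontology
(sparse DAG, many-to-many term-concept links, composite usages) but none of
its content: real synonymy is clustered by anatomical system and by author
lineage, real referent sets are far from uniform, and real stores carry an
order of magnitude more terms than concepts. Corpus-level counts of a
curated ontology (thousands of concepts and sensus) are therefore not
reproducible here and are not targets; what the tests establish instead is
that on any store the inference engine agrees exactly with exhaustive
brute-force oracles (synonym pairs, homonyms, acts at ≤500 sensus;
reachability on ≤200-concept DAGs; leftmost-longest matching on ≤1000
characters), that exports round-trip, and that census bins conserve totals.
Problem sizes in the suite (stores of 15–200 concepts, up to ~400 sensus)
were chosen so the whole suite runs in well under a minute while still
exercising every code path several times.

## Numerical and degenerate-input choices

* Preferred-label ties (equal `order_rank`, no `obo_label`) break on the
  lowest term uid; every report is totally ordered so output is
  deterministic byte-for-byte.
* Empty stores are valid everywhere: `census()` returns zeros,
  `homonyms()`/`acts_of_synonymy()` empty tibbles, `proof()` warns on an
  empty lexicon and returns no annotations.
* Serial allocation takes `max(existing serial, session counter) + 1`, so
  hand-assigned public ids (e.g. an imported root) and minted ids cannot
  collide.
* `import_obo()` recovers the differentia from definitions matching
  "A ... that ...", otherwise keeps the whole definition text; the genus is
  the first is_a parent. Dangling relationship targets are dropped with a
  warning rather than imported as ghosts.

## Known limitations

Single-user, in-memory; no concurrency, no web layer, no image handling.
OWL export is out of scope (standard OBO tooling handles that conversion).
Synonym detection is exact; no approximate string matching. Multilingual
content is modeled (terms carry a language) but only inference semantics,
not display or per-language preferred labels, are language-aware.
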