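# ontosensu

Anatomy-ontology curation as evidence, not assertion. `ontosensu` is an R
toolkit for building controlled anatomical vocabularies from the literature,
aimed at taxonomists and biodiversity informaticians who need to reconcile
decades of partially overlapping lexicons (insect anatomy is the motivating
case: the same sclerite may carry a dozen names, and one name — "paramere" —
has been applied to flatly incompatible structures).

The core object is the **sensu**: the triple

> (reference *R*, referent concept set *C*, term *T*)

recording that publication *R* used label *T* for concept(s) *C*. Terms and
concepts are kept independent; every lexical claim is backed by a citation.
Synonymy and homonymy are then *computed* from the sensu table:

- **synonyms** — terms *T₁ ≠ T₂* with sensus whose referent sets are equal
  (exact set equality);
- **homonyms** — a term *T* whose sensus carry ≥ 2 distinct referent sets;
- **acts of synonymy** — one reference linking ≥ 2 terms to the same
  referent (a published synonymization).

Around this sit a validated store (typed records, genus-differentia
definitions, a DAG of `is_a`/`part_of`/`attaches_to` relationships,
controlled-vocabulary tags, JSON persistence), identifier release
(`PREFIX:NNNNNNN`), DAG reasoning (ancestor queries and downward property
propagation with witnessing chains), OBO 1.2 and annotated Newick export, a
text "proofer" that hyperlinks free text against the lexicon and harvests
candidate terms, and census statistics for comparing ontologies.

## Worked example

Five publications used "paramere" for five incompatible referent sets —
three single concepts and two composites. Encode the usages as sensus and
the homonymy falls out:

```r
library(ontosensu)

store <- build_fixture("paramere")   # 5 sensus for one term, 5 references
homonyms(store)
#> # A tibble: 1 × 6
#>   term       text     n_referents referents  supporting_sensus has_nested
#>   <chr>      <chr>          <int> <list>     <list>            <lgl>
#> 1 t_paramere paramere           5 <list [5]> <chr [5]>         TRUE

cat(report_tsv(store, homonyms(store)), sep = "\n")
#> term	referents	supporting_sensus
#> paramere	HAO:0000389;HAO:0001084|HAO:0000389;HAO:0000707;HAO:0001084|HAO:0000389|HAO:0000395|HAO:0000707	s10;s6;s7;s8;s9
```

One term, five referent sets (`;` joins members within a set, `|` joins
sets): a five-way homonym. `has_nested = TRUE` flags that one composite set
contains another — possibly a refinement rather than a conflict, left to
the curator.

Reasoning over the classic leg example — given "legs are yellow", the fore
leg inherits the property because it *is a* leg, the femur because it is
*part of* one:

```r
leg <- build_fixture("leg_example")
propagate_property(leg, "leg", "yellow")
#> # A tibble: 3 × 4
#>   concept  property provenance via
#>   <chr>    <chr>    <chr>      <list>
#> 1 leg      yellow   asserted   <chr [0]>
#> 2 femur    yellow   inferred   <chr [1]>
#> 3 fore_leg yellow   inferred   <chr [1]>

glance(leg)                # one-row census: 4 concepts, 75% defined, ...
export_newick(leg)
#> [1] "((femur,fore_leg)leg)anatomical_entity;"
cat(export_obo(leg, date = "01:01:2026 00:00"))   # OBO 1.2, 4 [Term] stanzas
```

A shell entry point wrapping the same functions ships in `inst/cli/`
(subcommands `fixture`, `validate`, `release`, `export-obo`, `import-obo`,
`export-newick`, `census`, `synonyms`, `homonyms`, `acts`, `proof`,
`extract-candidates`; `-` reads standard input so they compose in
pipelines).

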