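# vaccalign

Vaccine exposure in European electronic health record (EHR) databases is
recorded with many different coding systems and drug vocabularies — general
clinical terminologies, drug classifications, and database-specific code
lists with descriptors in several languages. Multi-database vaccine
benefit–risk studies therefore start with a tedious manual harmonization
step: deciding, for every source code, which code in a target system means
the same vaccine group. **vaccalign** automates this alignment by analysing
the free-text code descriptors against an ontology of vaccine descriptions,
for pharmacoepidemiologists and medical-informatics teams preparing EHR
databases for collaborative studies.

## Method

A vaccine code is defined by a short descriptor such as `"Hepatitis A,
inactivated"` or `"Vacuna antigripal"`. The package represents descriptors
in three stages:

1. **Identification** — the ontology dictionary (all terms of all classes,
   in all languages) is matched against the normalized descriptor with a
   greedy longest-match tagger, giving the identified class set *C(t)*.
2. **Compilation** — each identified class compiles to a description-logic
   expression according to its property category: a vaccine class stands
   for itself, while a strategy, immunization target (pathogen or disease),
   ingredient, valence or route *c* becomes `Vaccine ⊓ ∃p.c` with the
   corresponding property *p*. A set of classes compiles to the
   conjunction; the result is the compiled vaccine class
   *V(t) = ⟦C(t)⟧*.
3. **Normalization** — the property values *P(t)* assign to each vaccine
   property *p* every named class *c* in the range of *p* with
   `ontology ⊨ V(t) ⊑ Vaccine ⊓ ∃p.c`.

Entailment is decided by a built-in subsumption reasoner for the EL
fragment the ontology uses (conjunction, existential restriction, subclass
axioms, binary property chains). Property chains propagate immunization
targets and strategies from active ingredients to the containing vaccine
(`has-ingredient ∘ immunizes-against ⇒ immunizes-against`) and unify
pathogens with the diseases they cause, so `"Flu vaccine"`,
`"Influenza virus vaccine"`, `"IIV3"` and the product `"Influvac"` all
normalize to the same value `[immunizes-against: {Influenza}]`.

Codes are aligned by scoring each source code against every target code
under one of four similarity methods — **Tokens** (Jaccard coefficient of
token sets), **Classes** (Jaccard of *C(t)*), **Equivalence** (1 iff the
*V(t)* are mutually subsumed), **Properties** (0 if the
immunizes-against sets differ, else Jaccard of the pooled
(property, value) pairs) — and assigning the highest-scoring target(s)
when the score strictly exceeds a threshold (default 0.1). Ties in a
hierarchical target system keep only the most general tied codes.
Alignments are evaluated against reference mappings by precision
TP/(TP+FP), recall TP/(TP+FN) and F-score (harmonic mean), with macro and
micro averages and a threshold sweep.

## Worked example

A Spanish source code list aligned to an English target list over the
bundled miniature ontology:

```r
library(vaccalign)
ont <- read_ontology(system.file("extdata", "mini_vacco.yaml", package = "vaccalign"))
ix  <- classify(ont)

property_values("DTwP", ix)
#> has-ingredient: {}
#> has-route: {}
#> has-strategy: {Inactivated}
#> has-valence: {}
#> immunizes-against: {Diphtheria, Pertussis, Tetanus}

src <- read_coding_system(system.file("extdata", "example_source_es.tsv", package = "vaccalign"))
tgt <- read_coding_system(system.file("extdata", "example_target_en.tsv", package = "vaccalign"))
al  <- align_codes(src, tgt, method = "properties", threshold = 0.1, index = ix)
al
#> Alignment (method = properties, threshold = 0.1): 5 assignment(s), 0 unassigned source code(s)
#>   source target score
#> 1    B01    T01     1
#> 2    B02    T02     1
#> 3    B03    T03     1
#> 4    B04    T04     1
#> 5    B05    T05     1

ref <- read_reference(system.file("extdata", "example_reference.tsv", package = "vaccalign"))
evaluate_alignment(al, ref)
#> TP 5  FP 0  FN 0 | precision 1.000  recall 1.000  F 1.000
```

Every Spanish code (e.g. `B01` `"Vacuna antigripal"`) is assigned its
English counterpart (`T01` `"Influenza virus vaccine"`) at similarity 1:
both normalize to identical property values even though the descriptors
share no words. The same operations are available from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","vacco.R",package="vaccalign"))')" \
    analyse --ontology inst/extdata/mini_vacco.yaml "Live/attenuated influenza vaccine"
#> C(t): {Influenza, Live-attenuated}
#> V(t): Vaccine and (immunizes-against some Influenza) and (has-strategy some Live-attenuated)
#> P(t): [has-strategy: {Live-attenuated}; immunizes-against: {Influenza}]
```

plus `align`, `evaluate`, `sweep` and `make-benchmark` subcommands.

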