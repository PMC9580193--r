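---
title: "Aligning vaccine coding systems with an ontology of vaccine descriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning vaccine coding systems with an ontology of vaccine descriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaccalign)
```

## The problem

Vaccine exposure in EHR databases is recorded through heterogeneous coding
systems: clinical terminologies, drug classifications, and custom code
lists whose descriptors may be in English, Spanish, Italian or Catalan.
Three features make aligning them hard: descriptors in different languages
share no words; equivalent vaccine groups are described through different
properties (a disease, `"Flu vaccine"`, versus its pathogen,
`"Influenza virus vaccine"`, versus an abbreviation, `"IIV3"`, versus a
product, `"Influvac"`); and source and target systems differ in
granularity. vaccalign addresses all three by normalizing every descriptor
into an explicit, language-independent property representation before
comparing codes.

## The ontology and its reasoner

The knowledge base is an ontology whose structure is fixed by seven
fundamental property categories — `Vaccine`, `Valence`, `Route`,
`Ingredient`, `Strategy`, `Disease`, `Pathogen` — under which every class
must fall (checked at validation). Classes carry multilingual terms;
object properties (`immunizes-against`, `has-strategy`, `has-ingredient`,
`has-valence`, `has-route`, `causes`, `caused-by`) have a domain and
ranges; existential assertions state `subject ⊑ ∃p.filler`; and binary
property chains `p1 ∘ p2 ⇒ p` propagate relations.

The expressiveness is deliberately restricted to the EL fragment —
conjunction, existential restriction, subclass axioms, and length-2
chains. Every construct the descriptor analysis needs falls inside it, it
is decidable in polynomial time, and it admits a simple completion
procedure. Chains longer than two properties are rejected at load time.
Negation, disjunction and cardinality are out of scope; one known
consequence is that residual groups such as "other viral vaccines" cannot
be represented.

`classify()` materializes the deductive closure under four rules iterated
to a fixpoint: reflexive–transitive subclass closure, inheritance of
existentials along the subclass relation, filler generalization, and
chain application. Compound expressions are handled by internalization,
the standard EL technique: each compound expression becomes a fresh
anonymous named class (named conjuncts as parents, existentials as
assertions, compound fillers recursively), the ontology is re-classified,
and the query becomes a lookup. This keeps the reasoner a single
algorithm. The test suite checks the closure against an independent naive
fixpoint oracle — a deliberately unindexed enumeration of all derivable
facts — on randomly generated ontologies of up to 12 classes, 3 properties
and 2 chains.

Determinism is enforced throughout: classes, labels and properties are
iterated and serialized in lexicographic order, so closures, file output
and alignments are reproducible bit for bit.

## From descriptor to property values

* **Identification.** Descriptors are normalized (lower case, accents
  folded to ASCII, split on non-alphanumeric characters, digits kept — so
  `"3-valent"` yields tokens `3, valent`) and scanned left-to-right with
  greedy longest match against the ontology dictionary, optionally
  restricted by language. Ambiguous terms return *all* their classes and
  are reported when the dictionary is built: surfacing both readings is
  the least lossy choice, and ambiguity is a known error source of
  dictionary tagging. Matches of the seven category classes themselves
  (the bare word "vaccine") are recorded in the spans but dropped from
  C(t): they carry no specific information and the compilation
  reintroduces the vaccine category.
* **Compilation.** Classes compile by category (`Vaccine` classes stand
  for themselves; any property class *c* becomes `Vaccine ⊓ ∃p.c`), and a
  set compiles to the conjunction in sorted order with the shared
  `Vaccine` conjunct deduplicated. The empty set compiles to bare
  `Vaccine` and is flagged *uninformative*. Uninformative codes score 0
  against everything — including other uninformative codes — because two
  descriptors the dictionary cannot read are not evidence of the same
  vaccine; treating them as equal would spuriously align every unparsed
  code.
* **Normalization.** P(t) collects, for each property whose domain lies
  under `Vaccine`, every named range subclass entailed for V(t). All
  entailed non-category fillers are reported, not only the most specific:
  Jaccard overlap over a richer set is well defined, and the value sets
  are meant to be an explicit image of everything the ontology implies.
  With `exclude_roots = TRUE` (the default) the seven category classes
  are removed from the value sets — every vaccine with any target would
  otherwise carry `Disease`, making all pairs overlap.

Valences are matched only when textually present (`"trivalent"`, or a
defining axiom as in `IIV3`); the number of immunization targets is never
converted into a valence, since no such rule is part of the method.

## Curation of the causal links in the bundled ontology

The miniature ontology `mini_vacco()` declares both unification chains
(`immunizes-against ∘ causes ⇒ immunizes-against` and
`immunizes-against ∘ caused-by ⇒ immunizes-against`) and curates the
causal *assertions* asymmetrically: every pathogen `causes` its disease,
while the disease-to-pathogen (`caused-by`) link is declared only for
cervical cancer/HPV. This keeps group- and product-level descriptors
normalizing to disease-level immunization targets (`P("DTwP")` lists
exactly Diphtheria, Tetanus, Pertussis; all four influenza descriptors
normalize to `{Influenza}`), while the HPV pair demonstrates full
two-way interchangeability — `"Vaccine against cervical cancer"` and
`"Human papillomavirus vaccine"` come out equivalent. Users who want
two-way unification everywhere simply assert `caused-by` links (as the
synthetic benchmark ontology does); users who want none can disable the
chains per ontology file or through the CLI config.

## Similarity methods and alignment

All four methods are symmetric and bounded in [0, 1]:

| method | representation | score |
|---|---|---|
| Tokens | normalized token set | Jaccard |
| Classes | C(t) | Jaccard, 0 if either set empty |
| Equivalence | V(t) | 1 iff mutual subsumption, else 0 |
| Properties | P(t) | 0 if immunizes-against sets differ, else Jaccard of pooled (property, value) pairs |

Two readings of "the immunizes-against values differed" are defensible;
the default `targets_gate = "equal"` takes the literal one (any set
inequality zeroes the score), which also explains why the remaining
properties drive graded overlap while targets must match exactly. The
alternative (`"overlap"`: the gate fires only on disjoint sets) is a
configuration switch. Likewise the overlap universe is not fixed by the
verbal definition; pooling (property, value) pairs across all properties
keeps every property commensurable and is the implemented reading.

Assignment: each source code receives the target(s) attaining the maximal
score when that score is strictly greater than the threshold. The default
threshold of 0.1 is the value with the highest average F-score when the
threshold is swept from 0 to 1 in steps of 0.1. Ties (equal maximal
scores, compared with an absolute tolerance of 1e-9 to absorb floating
point) are all assigned, unless the target system is hierarchical, in
which case only the most general tied targets survive — defined minimally
as those with no proper ancestor inside the tied set, not as global
roots. An external tagger (any function descriptor → concept-id set) can
be registered as a fifth, Jaccard-scored method; no English-only external
concept normalizer is bundled.

Evaluation counts generated pairs literally: a tie-expanded assignment
contributes each pair individually, so a correct member is a TP and the
extra members are FPs. Measures with a zero denominator are 0. Macro
averages are unweighted means over source systems; micro averages sum the
confusion counts first. `threshold_sweep()` computes the similarity
matrix once and re-assigns per threshold, which also makes the
subset property of assignments (and hence non-increasing recall) easy to
verify.

## The synthetic benchmark

Real reference sets for vaccine-code alignment are proprietary or
externally licensed, so the package ships a seeded generator instead.
It emulates the documented difficulty axes: the two sides describe the
same `n_groups` vaccine groups in different styles (pathogen name vs
disease name vs abbreviation vs product vs strategy/route/valence
decorated) and different languages (synthetic pseudoword lexicons with
disjoint syllable inventories, so cross-lingual descriptors share no
tokens), with optional term dropout, distractor tokens, out-of-dictionary
synonym substitution, and an optional two-level target hierarchy whose
gold alignment points at the most specific representable code. Each
benchmark is a pure function of its spec, including the seed.

Defaults are the study conditions used throughout the tests: 20 groups,
pathogen-name English source versus disease-name Spanish target, no
noise. On that configuration the Properties method recovers the gold
alignment exactly (the causal links make P(t) identical within and
distinct across groups by construction), and under 20 % term dropout the
directional ordering F(Properties) ≥ F(Classes) ≥ F(Tokens) is expected,
mirroring the qualitative advantage of property normalization over class
overlap over raw tokens on multilingual, style-mismatched data. Noise
levels beyond that (0.3/0.35/0.7 dropout, 0.2–0.3 distractor rates) are
used in the monotonicity tests with 6–12 groups and 20 seeds, sizes at
which the whole suite and the acceptance script run in well under a
minute each.

What the generator does **not** emulate: real lexical ambiguity and
dictionary incompleteness (its lexicons are exact by construction),
contextual knowledge such as which vaccines are authorized in a country,
semantically duplicated target codes, and codes defined without any
vaccine property. Passing the benchmark therefore demonstrates the
correctness of the pipeline's mechanics — tagging, reasoning,
normalization, assignment, evaluation — not field performance on real
coding systems, whose error profile is dominated by exactly those missing
features.

## Degenerate inputs and conventions

Empty text normalizes to an empty token sequence and an empty C(t);
Jaccard of two empty sets is 0; an empty target system yields a warning
and all-unassigned output; an empty result list is an error for the
averaging functions; a threshold of 1.0 can never assign (strict
comparison). Cycles in class parents or code parents, references to
undeclared entities, duplicate codes, and multi-target references are
all validation errors raised with the offending identifiers named.

## Limitations

The reasoner is complete only for the EL-with-chains fragment it
implements; it is not an OWL2-DL reasoner and does not support
individuals, datatypes, negation or cardinality. Dictionary tagging is
exact after normalization — no stemming, no fuzzy matching, no machine
translation; multilingual coverage is whatever the ontology's labels
provide. The bundled miniature ontology is a curated fixture for
demonstration and testing, not a production vocabulary; real alignment
work requires an ontology whose class and term coverage matches the
coding systems at hand.
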