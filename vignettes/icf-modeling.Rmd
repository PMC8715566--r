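---
title: "Modeling ICF assessments: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ICF assessments: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icfkit)
```

# The problem

The ICF describes functioning through coded categories and qualifiers, but
a flat code/qualifier table underdetermines the semantics: the same digit
means different things on different components, an activity's relation to
its agent is mediated by a dated health state, participation is a property
of *an assessed activity* rather than of a category, and an environmental
factor's effect can legally be recorded against three different kinds of
target. `icfkit` makes each of those distinctions explicit, in a structure
deliberately shaped like an OWL ontology so that models export to Turtle
and can be handed to external reasoners.

This package covers the Activities & Participation and Environmental
Factors components only. Body Functions and Body Structures are reserved
extension points: the aggregation and influence machinery accepts them
structurally (`InfluenceableComponent` handles exist for all three
health-domain components), but no qualifier scales or category semantics
are implemented for them.

# Reified relations instead of property stacks

An assessment statement like "changing position, performance mildly
difficult, in Peter's March health state" is a relation of arity four. We
reify it: a `QualifiedActivity` individual carries one `activity` link to
a category, at most one `performance` and one `capacity` Difficulty value,
at most one `destination`, and exactly one `partOf` link to its health
state. The alternative — twelve distinct object properties, one per
qualifier value — was rejected because it multiplies the vocabulary by the
scale size and couples the schema to the value set.

Two modeling consequences are worth spelling out:

* **Agents are indirect.** A qualified activity has no direct link to a
  human; `agent_of()` resolves through the health state. This keeps a
  single source of truth for "whose assessment is this" and makes
  longitudinal states cheap.
* **Absent qualifiers stay absent.** The E. fixture records an activity
  with no qualifier at all; we represent that as missing, not as digit 8,
  because multiplicity of `performance` is 0..1 and "not specified" is
  itself a codable value with different meaning.

The influence of a contextual factor is the same pattern at arity three:
an `Influence` individual with exactly one `factor`, exactly one target,
exactly one polarity level, and an optional manner.

# Qualifier scales

Three closed scales are shipped, each an enumerated class whose values are
individuals (individuals can be the subject of further statements —
groupings, annotations — which bare literals cannot):

| scale | digits | labels |
|---|---|---|
| Difficulty | 0 1 2 3 4 8 | no problem, mild, moderate, severe, complete, some |
| Hindrance | 0 1 2 3 4 8 | no, mild, moderate, severe, complete, some |
| Facilitation | 0 1 2 3 4 8 | no, mild, moderate, substantial, complete, some |

Design decisions:

* **Digit 8 ("some") on Difficulty.** The two influence scales need a
  "some / not specified" member (a vague magnitude such as "less difficulty
  with ibuprofen" codes as *some facilitation*). We give Difficulty the
  symmetric member, using 8 because the ICF generic scale reserves 8 for
  "not specified". Worked difficulty examples only ever use 0–4, so this
  member is never produced by profile encoding; it is available for direct
  use.
* **Percent bands** default to the ICF generic scale (0–4, 5–24, 25–49,
  50–95, 96–100 for digits 0–4). They are configurable via a YAML override
  (mainly for localization of labels); an override must keep the bands a
  partition of 0–100, and digit 8 carries no band.
* **Suffix dialect.** Profiles use the standard annotation: `.d` is
  difficulty on a d-code and hindrance on an e-code; `+d` is facilitation
  and only legal on e-codes. The dispatch lives in
  `parse_qualifier_suffix()` and nowhere else.
* **Closure.** `icf_scale()` returns the identical object on every call;
  there is no API to add values at run time.

# Categories, blocks and the partial registry

Codes parse independently of any registry: a component letter (`b s d e`)
plus 1/3/4/5 digits (chapter / second / third / fourth level). The
registry adds titles, kinds and the hierarchy. Blocks such as `d330-d349`
are labeled code *ranges*, not codes: `icf_parse_code()` rejects range
syntax, only registry files may contain block rows, and a category whose
stored parent is a block must fall inside the block's range. Blocks take
part in the stored hierarchy but are not emitted as OWL classes; a
category below a block subclasses the block's chapter instead, so the
exported class tree is purely code-prefix-driven. This is a choice: blocks
are treated as structural grouping devices, not classification units.

The registry is deliberately partial (the full WHO catalogue runs to
hundreds of categories). Every operation works on any subset; an unknown
but well-formed code is usable everywhere and surfaces in validation as a
*warning*, not an error.

# Participation

Activities and participation share a single category list; whether an
action is a participation depends on the subject under assessment, so no
category is ever pre-tagged. Participation is instance-level and defined:
a qualified activity is a participation exactly when its `destination`
points at a life situation. Life situations are label-only individuals —
we found no defensible taxonomy for them, and a free label is what the
assessment actually records. `is_participation()` computes the defined
class; property tests check it against an exhaustive row-scan oracle.

# Influences and the three coding conventions

`add_influence()` accepts any of three target kinds, and
`convention_of()` recovers the convention by target-type dispatch: health
state → 1, component handle → 2, qualified activity → 3. Further
decisions:

* **Polarity is an exclusive-or.** The stored representation has two level
  columns (`facilitation_level`, `barrier_level`) precisely so that the
  XOR constraint is a checkable property of data rather than an accident
  of the API; fault injection can build the illegal both-levels state and
  validation must catch it.
* **Direction of the polarity relation.** We write
  `(target, facilitatedBy, influence)` and declare `facilitates` as its
  inverse, so that `facilitates` ranges over the union of the three target
  classes — this keeps the Facilitator/Barrier equivalent-class
  definitions in terms of `facilitates`/`hinders` natural, and matches the
  English reading of "facilitated by".
* **Manner enumeration is closed at seven members** (presence, absence,
  accessibility, quality, dependability, variability, unspecified). An
  open "etc." is untestable; unspecified is the honest default for
  sources that do not state an origin.
* **Personal factors may influence** (the `factor` range is the whole
  contextual-factor class) but carry no code, since the ICF does not
  classify them.
* **Profile encoding under convention 3** attaches each e-row to the most
  recently encoded d-row's activity. Profile tables carry no explicit
  linkage, and adjacency is the only order-preserving reading; an e-row
  with no preceding d-row is an error. Convention 1 is the default, as in
  the worked profiles.

# Validation

`icf_validate()` runs all rules and reports every violation at once —
iterative model refinement wants the full list, not the first failure.
Severities: disjointness, cardinality and domain/range breaches are
errors; unregistered codes are warnings (partial registry by design). A
model passes iff it has no errors. The rule inventory is public
(`validation_rules()`), and the synthetic generator can inject, for each
rule, a mutation that breaches exactly that rule exactly once — the test
suite uses this for a completeness check of the rule set. Mutations write
the model tables directly, because the constructor API refuses to build
the illegal states.

# Serialization

Turtle is the canonical syntax. The writer is deterministic (fixed section
order, model row order within sections), so identical models serialize
byte-identically and file diffs are meaningful. The export contains the
construct mapping one would expect from the formalization: every 0..1
relation as an `owl:FunctionalProperty`, every exact-1 as a cardinality-1
restriction, disjointness axioms for each mutually exclusive sibling set,
the four defined classes as `owl:equivalentClass` axioms (the
Facilitator/Barrier definitions over the `owl:unionOf` of the three target
classes), inverse-property axioms, enumerated classes via `owl:oneOf`, and
descriptive definitions as comments.

Other choices:

* **SUMO by IRI.** Upper-ontology bridges are emitted as
  `rdfs:subClassOf` / `rdfs:subPropertyOf` links to SUMO IRIs without
  importing SUMO; the file stays desk-sized and merges cleanly with a full
  import. The bridge table is queryable (`sumo_mappings()`); the
  `influencedBy` entry deliberately carries an `unspecified-target` marker
  rather than a guessed SUMO property.
* **Categories are punned.** A category appears as a class (`icf:D410`,
  subclass of its parent) whose individuals are concrete actions
  (`Changing_position a icf:D410`). Treating categories simultaneously as
  individuals of `ICFCategory` is legal OWL 2 punning; we document it
  rather than emit the second assertion.
* **The reader is restricted.** `read_turtle()` re-imports only this
  ontology's vocabulary — it is a round-trip loader, not a general RDF
  parser (no general-purpose RDF library exists in this package's R
  dependency set, and the round-trip grammar is a small fixed subset:
  prefixed names, quoted literals, `;` groups). Identifiers are
  constrained to `[A-Za-z0-9_]+` at export time, which is what makes the
  restricted grammar sufficient. The test suite additionally checks the
  export against an independent third-party RDF parser.

# The synthetic generator

`generate_synthetic()` emulates a single-subject categorical assessment:
activity categories drawn uniformly from the registry's A&P categories,
80% of activities carrying a performance digit drawn uniformly from 0–4
(the rest unqualified, as in sparse real profiles), participation
assigned independently per activity at the requested rate, influences
attached per convention with uniform polarity, level in {0–4, 8} and a
50% chance of a stated manner, and a 15% share of personal (uncoded)
factors. Counts and rate are the experimenter's dials; everything else is
fixed so that two calls with the same seed are triple-identical, and the
generator restores the caller's RNG state.

What it does *not* emulate — and hence what passing property suites do
not show about real data: clinically plausible co-occurrence of
categories, correlation between difficulty and environmental barriers,
multi-subject or longitudinal structure, and free-text labels. The
generator exists to exercise the model's logic (defined-class inference,
serialization, validation), not to simulate an epidemiology.

The property suites run at sizes chosen to exercise the logic densely
while keeping the default test run quick: 100 seeded models per suite,
each well under 1,000 entities (3–40 activities, up to ~11 influences).
Inference is compared against brute-force row-scan oracles; serialization
by exact triple-set equality after a write/read cycle.

# Known limitations

* Body Functions / Body Structures qualifiers and semantics are not
  implemented (reserved extension points only).
* No OWL-DL reasoning: only the named constraints are enforced natively.
  The export is the escape hatch — external reasoners can consume it.
* Whether an influence may target entities across different health states
  is not constrained; all shipped examples stay within one state.
* How environmental effects on body functions (e.g. a drug's
  physiological effect) should be modeled is left open; the convention-3
  mechanism records the co-occurrence, not the mechanism, and no
  quantitative interaction (a facilitator numerically changing a
  performance digit) is modeled.
* The shipped registry is a small seed; users load their own subsets via
  `icf_load_registry()`.
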