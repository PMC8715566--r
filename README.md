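# icfkit

Ontology-backed encoding of functioning assessments coded with the WHO
**International Classification of Functioning, Disability and Health (ICF)**,
restricted to the two components that describe what a person does and what
surrounds them: **Activities & Participation** (`d` codes) and
**Environmental Factors** (`e` codes).

Clinicians record ICF assessments as *categorical profiles* — tables of
code/qualifier pairs such as `d410 .1` ("changing basic body positions, mild
difficulty") or `e1151 +3` ("assistive mobility products, substantial
facilitator"). Those tables flatten away structure that matters: *whose*
health state an observation belongs to, whether an activity is a
*participation* in a life situation, and *what exactly* an environmental
factor facilitates or hinders. `icfkit` represents that structure the way a
description-logic model would, and is aimed at classification researchers,
terminologists and informaticians who need ICF data as a queryable,
validatable, exportable knowledge graph.

## The model

Two reified n-ary relations carry the semantics:

* **QualifiedActivity** — a quaternary relation binding an Activities &
  Participation category to a health state with two independent difficulty
  measurements (`performance`, `capacity`, both 0–4 or 8 on the Difficulty
  scale) and an optional `destination`. A health state aggregates its
  qualified activities via `partOf` and links to its subject via `agent`;
  an activity's agent is always reached indirectly through its state.

* **Influence** — a ternary relation binding a contextual factor to a target
  with exactly one polarity: a `facilitationLevel` (Facilitation scale) or a
  `barrierLevel` (Hindrance scale), plus an optional influencing manner.
  The target encodes the ICF coding convention: the whole health state
  (convention 1), one component of it (convention 2), or a single qualified
  activity (convention 3).

Membership of the interesting classes is *defined*, never asserted:

```
QualifiedParticipativeActivity ≡ QualifiedActivity ⊓ ∃destination.LifeSituation
Facilitator ≡ Influence ⊓ ∃facilitates.(HealthState ⊔ InfluenceableComponent ⊔ QualifiedActivity)
Barrier     ≡ Influence ⊓ ∃hinders.(HealthState ⊔ InfluenceableComponent ⊔ QualifiedActivity)
InfluencingFactor ≡ ContextualFactor ⊓ ∃factor⁻.Influence
```

Qualifier values are individuals of closed enumerated classes (so they can
be the subject of further statements), categories live in a partial,
extensible registry, and every class and property with a counterpart in the
SUMO upper ontology carries a subclass/subproperty bridge. Models validate
against the formalized constraints (disjointness, cardinality, domain/range)
and serialize to OWL/Turtle, from which they re-import losslessly.

## Worked example

A spinal-cord-injury profile: four mobility/employment activities with
problem qualifiers, plus three environmental factors coded against the
whole health state (convention 1).

```r
library(icfkit)

profile <- data.frame(
  code      = c("d4153", "d4154", "d465", "d850", "e1151", "e155", "e580"),
  qualifier = c(".0",    ".2",    ".3",   ".4",   "+3",    ".3",   "+2"))

model <- encode_profile(profile, subject = "Conrad", label = "2019_oct_2")
model
#> <icf_model>
#>   humans:                1
#>   health states:         1
#>   qualified activities: 4 (0 participations)
#>   contextual factors:    3
#>   influences:            3

classify_influence(model)
#>        Conrad_state_1_assistive_products_for_personal_mobility_1
#>                                                    "Facilitator"
#> Conrad_state_1_design_construction_of_building_for_private_use_1
#>                                                        "Barrier"
#>            Conrad_state_1_health_services_systems_and_policies_1
#>                                                    "Facilitator"

icf_query(model, "facilitators")
#> # A tibble: 2 × 3
#>   factor                                     code  label
#>   <chr>                                      <chr> <chr>
#> 1 Assistive_products_for_personal_mobility_1 e1151 Assistive products for perso…
#> 2 Health_services_systems_and_policies_1     e580  Health services, systems and…
```

The suffix dialect resolves against the code's component: `.3` on `d465`
is *severe difficulty*, the same digit on `e155` is a *severe barrier*, and
`+3` on `e1151` is *substantial facilitation*. `export_owl(model,
"conrad.ttl")` writes the model (schema axioms plus individuals) as
deterministic Turtle; `read_turtle("conrad.ttl")` brings it back with an
identical triple set. `icf_validate(model)` reports every constraint
violation at once, and `icf_fixtures()` returns four ready-made case-study
models used throughout the documentation.

A thin command-line wrapper ships at `inst/cli/icfkit` with subcommands
`encode`, `validate`, `export`, `query` and `synth` (see `?icf_cli`).

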