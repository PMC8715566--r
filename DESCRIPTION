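Package: icfkit
Title: Ontology-Backed Encoding of ICF Functioning Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing assessments coded with the WHO
    International Classification of Functioning, Disability and Health
    (ICF), restricted to the Activities & Participation and Environmental
    Factors components. Provides a typed category registry, enumerated
    qualifier scales (difficulty, hindrance, facilitation), reified n-ary
    relations for qualified activities and contextual-factor influences,
    the three ICF environmental-factor coding conventions, defined-class
    inference (participation, facilitator, barrier, influencing factor),
    consistency validation, SUMO upper-ontology bridges, and deterministic
    OWL/Turtle serialization with re-import. Ships the worked case-study
    fixtures and a seeded synthetic-profile generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
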