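test_that("triple emission follows the relation vocabulary, deterministically", {
  vocab <- c("activity", "performance", "capacity", "destination", "partOf",
             "agent", "factor", "influencingManner", "barrierLevel",
             "facilitationLevel", "facilitatedBy", "hindrancedBy")
  m <- tiny_model() |> set_destination("anna_state_1_d440_1", "book club")
  tr <- to_triples(m)
  expect_true(all(tr$predicate %in% vocab))
  expect_identical(tr, to_triples(m))

  # qualifier values appear as individuals, never digits
  expect_equal(tr$object[tr$predicate == "performance"], "MILD_difficulty")
  expect_equal(tr$object[tr$predicate == "barrierLevel"], "MODERATE_hindrance")

  # empty health state emits exactly its subject link
  e <- icf_model() |> add_human("h") |> add_health_state("h", "t")
  expect_equal(to_triples(e),
               tibble::tibble(subject = "h_state_1", predicate = "agent",
                              object = "h"))

  # models with errors are rejected
  bad <- tiny_model()
  bad$influences$barrier_level[2] <- 1L
  expect_error(to_triples(bad), "does not validate")
})

test_that("worked-example triples match the conceptual model's assertions", {
  fx <- icf_fixtures()
  peter <- to_triples(fx$peter)
  expect_true(nrow(dplyr::filter(peter,
    subject == "Peter_state_1_changing_position_1",
    predicate == "performance", object == "MILD_difficulty")) == 1)
  e <- to_triples(fx$e_case)
  expect_true(nrow(dplyr::filter(e,
    subject == "E_state_1_reacting_1", predicate == "partOf",
    object == "E_state_1")) == 1)
})

test_that("turtle export/import round-trips all fixtures", {
  for (m in icf_fixtures()) {
    path <- withr::local_tempfile(fileext = ".ttl")
    export_owl(m, path)
    expect_identical(to_triples(read_turtle(path)), to_triples(m))
  }
})

test_that("export is byte-deterministic and carries the formalization axioms", {
  m <- icf_fixtures()$conrad
  expect_identical(export_owl(m), export_owl(m))

  schema <- paste(export_owl(icf_model(), include_data = FALSE), collapse = "\n")
  # defined classes as equivalent-class axioms; Facilitator/Barrier over the
  # union of the three legal target classes
  expect_match(schema, "icf:Facilitator a owl:Class ;", fixed = TRUE)
  expect_match(schema, paste0(
    "owl:onProperty icf:facilitates ; owl:someValuesFrom [ a owl:Class ; ",
    "owl:unionOf ( icf:HealthState icf:InfluenceableComponent ",
    "icf:QualifiedActivity ) ]"), fixed = TRUE)
  expect_match(schema, "owl:onProperty icf:hinders", fixed = TRUE)
  expect_match(schema,
    "owl:onProperty icf:destination ; owl:someValuesFrom icf:LifeSituation",
    fixed = TRUE)
  expect_match(schema,
    "owl:onProperty [ owl:inverseOf icf:factor ] ; owl:someValuesFrom icf:Influence",
    fixed = TRUE)
  # functional axioms for every 0..1 relation, exact cardinality for exact-1
  for (p in c("performance", "capacity", "destination", "partOf", "agent",
              "factor", "influencingManner", "facilitationLevel", "barrierLevel"))
    expect_match(schema, paste0("icf:", p, " a owl:ObjectProperty ;\n    a owl:FunctionalProperty"),
                 fixed = TRUE)
  expect_match(schema, 'owl:cardinality "1"', fixed = TRUE)
  # inverse properties and disjointness
  expect_match(schema, "owl:inverseOf icf:facilitatedBy", fixed = TRUE)
  expect_match(schema, "owl:inverseOf icf:hindrancedBy", fixed = TRUE)
  expect_match(schema, "owl:disjointWith icf:PersonalFactor", fixed = TRUE)
  expect_match(schema, "owl:disjointWith icf:ContextualFactor", fixed = TRUE)
  # enumerated qualifier classes
  expect_match(schema, "owl:oneOf ( icf:NO_PROBLEM_difficulty", fixed = TRUE)
  expect_match(schema, "owl:oneOf ( icf:PRESENCE_manner", fixed = TRUE)
})

test_that("SUMO bridge table names the documented mappings", {
  sm <- sumo_mappings()
  expect_equal(sumo_lookup("PersonalFactor"), "BiologicalAttribute")
  expect_equal(sumo_lookup("EnvironmentalFactor"), "Physical")
  expect_equal(sumo_lookup("partOf"), "part")
  expect_equal(sumo_lookup("ICFCategory"), "Taxonomy")
  expect_equal(sumo_lookup("Difficulty"), "SubjectiveAssessmentAttribute")
  expect_setequal(
    sm$entity[sm$sumo == "IntentionalProcess" & !is.na(sm$sumo)],
    c("QualifiedActivity", "ActivityAndParticipation", "LifeSituation"))
  # each local entity maps to at most one SUMO entity
  expect_false(anyDuplicated(sm$entity) > 0)
  # the influencedBy bridge target is explicitly unspecified, not guessed
  expect_true(is.na(sm$sumo[sm$entity == "influencedBy"]))
  expect_equal(sm$note[sm$entity == "influencedBy"], "unspecified-target")
  expect_error(sumo_lookup("Nonesuch"), "no SUMO mapping")
  # bridges surface in the export as subclass/subproperty links to SUMO IRIs
  schema <- paste(export_owl(icf_model(), include_data = FALSE), collapse = "\n")
  expect_match(schema, "rdfs:subClassOf sumo:BiologicalAttribute", fixed = TRUE)
  expect_match(schema, "rdfs:subPropertyOf sumo:part", fixed = TRUE)
  expect_match(schema, "rdfs:subClassOf sumo:Taxonomy", fixed = TRUE)
})

test_that("an independent RDF parser accepts the export", {
  # rdflib (Python) as external oracle: the Turtle must be standards-valid
  path <- withr::local_tempfile(fileext = ".ttl")
  export_owl(icf_fixtures()$john, path)
  out <- system2("python",
                 c("-c", shQuote(paste0(
                   "import rdflib; g = rdflib.Graph(); g.parse('", path,
                   "', format='turtle'); print(len(g))"))),
                 stdout = TRUE, stderr = TRUE)
  n <- suppressWarnings(as.integer(tail(out, 1)))
  expect_false(is.na(n))
  expect_gt(n, 100)
})

test_that("labels with quotes and backslashes survive the round trip", {
  m <- icf_model() |>
    add_human("h", 'says "hi" \\ there') |>
    add_health_state("h", "t_1") |>
    add_qualified_activity("h_state_1", "d410") |>
    set_destination("h_state_1_d410_1", 'club "99"')
  m2 <- read_turtle(export_owl(m))
  expect_identical(m2$humans$name, m$humans$name)
  expect_identical(m2$situations$label, m$situations$label)
  expect_identical(to_triples(m2), to_triples(m))
})
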