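ICF_NS <- "https://example.org/icf#"
DATA_NS <- "https://example.org/icf/data#"
SUMO_NS <- "http://www.ontologyportal.org/SUMO.owl#"

category_class <- function(code) {
  paste0(toupper(substr(code, 1, 1)), substring(code, 2))
}

scale_of_digit <- function(scale_name, digit, scales) {
  tb <- icf_scale(scale_name, scales)
  tb$individual[match(digit, tb$digit)]
}

assert_serializable_ids <- function(model) {
  ids <- c(model$humans$id, model$states$id, model$activities$id,
           model$activities$activity, model$situations$id, model$factors$id,
           model$components$id, model$influences$id)
  bad <- ids[!grepl("^[A-Za-z0-9_]+$", ids)]
  if (length(bad))
    abort(paste0("identifiers must match [A-Za-z0-9_]+ for serialization: ",
                 paste(unique(bad), collapse = ", ")))
}

#' Translate a model into triples
#'
#' Emits the complete, deterministic triple set of a model, using the
#' relation vocabulary of the conceptual model: each health state links to
#' its subject via `agent`; each qualified activity emits `partOf`,
#' `activity` and its optional `performance` / `capacity` / `destination`;
#' each component handle emits its `partOf` binding; each influence emits
#' the polarity relation from its target (`facilitatedBy` / `hindrancedBy`),
#' `factor`, its level (`facilitationLevel` / `barrierLevel`) and optional
#' `influencingManner`. Qualifier values appear as their individuals
#' (`MILD_difficulty`, ...), never as bare digits.
#'
#' @param model An `icf_model`. Must validate (no errors) unless
#'   `validate = FALSE`.
#' @param validate Reject models with validation errors (default `TRUE`).
#' @return Tibble with columns `subject`, `predicate`, `object`.
#' @examples
#' to_triples(icf_fixtures()$e_case)
#' @export
to_triples <- function(model, validate = TRUE) {
  stopifnot(inherits(model, "icf_model"))
  if (validate) {
    rep <- icf_validate(model)
    if (!rep$passed)
      abort(paste0("model does not validate (",
                   sum(rep$violations$severity == "error"), " errors); ",
                   "run icf_validate() for the report"))
  }
  sc <- model$scales
  tr <- function(s, p, o) tibble(subject = s, predicate = p, object = o)
  out <- list(tr(model$states$id, "agent", model$states$subject))
  for (i in seq_len(nrow(model$activities))) {
    a <- model$activities[i, ]
    out <- c(out, list(
      tr(a$id, "partOf", a$state),
      tr(a$id, "activity", a$activity),
      if (!is.na(a$performance))
        tr(a$id, "performance", scale_of_digit("Difficulty", a$performance, sc)),
      if (!is.na(a$capacity))
        tr(a$id, "capacity", scale_of_digit("Difficulty", a$capacity, sc)),
      if (!is.na(a$destination)) tr(a$id, "destination", a$destination)))
  }
  out <- c(out, list(tr(model$components$id, "partOf", model$components$state)))
  for (i in seq_len(nrow(model$influences))) {
    f <- model$influences[i, ]
    facil <- !is.na(f$facilitation_level)
    out <- c(out, list(
      tr(f$target, if (facil) "facilitatedBy" else "hindrancedBy", f$id),
      tr(f$id, "factor", f$factor),
      if (facil) tr(f$id, "facilitationLevel",
                    scale_of_digit("Facilitation", f$facilitation_level, sc))
      else tr(f$id, "barrierLevel",
              scale_of_digit("Hindrance", f$barrier_level, sc)),
      if (!is.na(f$manner))
        tr(f$id, "influencingManner", manner_individual(f$manner))))
  }
  bind_rows(out)
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}

ttl_lit <- function(x) paste0('"', ttl_escape(x), '"')

schema_properties <- function() {
  # name, super, domain, range, functional, exact1 on classes, inverse_of
  tribble(
    ~name, ~super, ~domain, ~range, ~functional, ~exact1, ~inverse_of, ~comment,
    "manner", NA, "icf:QualifiedActivity", "icf:Difficulty", FALSE, NA, NA,
      "Quality of how an activity's execution takes place.",
    "performance", "icf:manner", "icf:QualifiedActivity", "icf:Difficulty", TRUE, NA, NA,
      "Difficulty of the activity as executed in the current environment.",
    "capacity", "icf:manner", "icf:QualifiedActivity", "icf:Difficulty", TRUE, NA, NA,
      "Difficulty of the activity as the subject's theoretical ability.",
    "activity", NA, "icf:QualifiedActivity", "icf:ActivityAndParticipation", TRUE,
      "icf:QualifiedActivity", NA,
      "The concrete action being assessed.",
    "destination", NA, "icf:QualifiedActivity", "icf:LifeSituation", TRUE, NA, NA,
      "Life situation the subject intends to take part in; present only for participation.",
    "partOf", NA,
      "[ a owl:Class ; owl:unionOf ( icf:QualifiedActivity icf:InfluenceableComponent ) ]",
      "icf:HealthState", TRUE, "icf:QualifiedActivity icf:InfluenceableComponent", NA,
      "Aggregation of assessments into one health state.",
    "agent", NA, "icf:HealthState", "icf:Human", TRUE, "icf:HealthState", NA,
      "Subject whose functioning the health state describes.",
    "factor", NA, "icf:Influence", "icf:ContextualFactor", TRUE, "icf:Influence", NA,
      "Contextual factor exerting the influence.",
    "influencingManner", NA, "icf:Influence", "icf:InfluencingManner", TRUE, NA, NA,
      "How the factor exerts its influence (presence, absence, accessibility, ...).",
    "facilitationLevel", NA, "icf:Influence", "icf:Facilitation", TRUE, NA, NA,
      "Extent of a positive influence.",
    "barrierLevel", NA, "icf:Influence", "icf:Hindrance", TRUE, NA, NA,
      "Extent of a negative influence.",
    "influencedBy", NA,
      "[ a owl:Class ; owl:unionOf ( icf:HealthState icf:InfluenceableComponent icf:QualifiedActivity ) ]",
      "icf:Influence", FALSE, NA, NA,
      "The influenced entity undergoes an influence. Upper-ontology bridge target: unspecified.",
    "facilitatedBy", "icf:influencedBy", NA, "icf:Influence", FALSE, NA, NA,
      "Positive (facilitating) influence on the entity.",
    "hindrancedBy", "icf:influencedBy", NA, "icf:Influence", FALSE, NA, NA,
      "Negative (hindering) influence on the entity.",
    "influences", NA, "icf:Influence", NA, FALSE, NA, "influencedBy",
      "Inverse of influencedBy.",
    "facilitates", "icf:influences", "icf:Influence", NA, FALSE, NA, "facilitatedBy",
      "Inverse of facilitatedBy.",
    "hinders", "icf:influences", "icf:Influence", NA, FALSE, NA, "hindrancedBy",
      "Inverse of hindrancedBy."
  )
}

#' SUMO upper-ontology bridge table
#'
#' Each local class or property that has a SUMO counterpart is bridged with
#' a subclass / subproperty link; the bridge is carried by IRI reference, so
#' the model stays mergeable with a full SUMO import without shipping one.
#' The `influencedBy` property is recorded with an explicit
#' `unspecified-target` marker: it participates in the bridge but its SUMO
#' counterpart is not fixed.
#'
#' @return Tibble: `entity`, `entity_type` (`class`/`property`), `sumo`,
#'   `relation` (`subClassOf`/`subPropertyOf`), `note`.
#' @examples
#' sumo_lookup("PersonalFactor")
#' @export
sumo_mappings <- function() {
  tribble(
    ~entity, ~entity_type, ~sumo, ~relation, ~note,
    "ICFCategory", "class", "Taxonomy", "subClassOf", NA,
    "Qualifier", "class", "Attribute", "subClassOf", NA,
    "Difficulty", "class", "SubjectiveAssessmentAttribute", "subClassOf", NA,
    "Human", "class", "Human", "subClassOf", NA,
    "QualifiedActivity", "class", "IntentionalProcess", "subClassOf", NA,
    "ActivityAndParticipation", "class", "IntentionalProcess", "subClassOf", NA,
    "LifeSituation", "class", "IntentionalProcess", "subClassOf", NA,
    "PersonalFactor", "class", "BiologicalAttribute", "subClassOf", NA,
    "EnvironmentalFactor", "class", "Physical", "subClassOf", NA,
    "ContextualFactor", "class", "Entity", "subClassOf", NA,
    "performance", "property", "manner", "subPropertyOf", NA,
    "capacity", "property", "manner", "subPropertyOf", NA,
    "partOf", "property", "part", "subPropertyOf", NA,
    "destination", "property", "destination", "subPropertyOf", NA,
    "agent", "property", "agent", "subPropertyOf", NA,
    "influencedBy", "property", NA, "subPropertyOf", "unspecified-target"
  )
}

#' @rdname sumo_mappings
#' @param entity Local entity name.
#' @return For `sumo_lookup()`: the SUMO entity name (`NA` if the bridge
#'   target is unspecified); errors for unmapped entities.
#' @export
sumo_lookup <- function(entity) {
  m <- sumo_mappings()
  i <- match(entity, m$entity)
  if (is.na(i)) abort(paste0("no SUMO mapping recorded for: ", entity))
  m$sumo[i]
}

schema_lines <- function(model) {
  sc <- model$scales
  L <- character()
  add <- function(...) L <<- c(L, ...)

  add("icf:Ontology a owl:Ontology ;",
      '    rdfs:comment "ICF Activities & Participation and Environmental Factors model." .',
      "")
  cls <- function(name, parents = NULL, comment = NULL, disjoint = NULL) {
    body <- c("a owl:Class",
              if (length(parents)) paste0("rdfs:subClassOf ", parents),
              if (!is.null(comment)) paste0("rdfs:comment ", ttl_lit(comment)),
              if (length(disjoint)) paste0("owl:disjointWith ", disjoint))
    add(paste0("icf:", name, " ", paste(body, collapse = " ;\n    "), " ."), "")
  }
  cls("ICF", comment = "The classification framework: categories plus qualifiers.")
  cls("ICFCategory", paste0("sumo:", sumo_lookup("ICFCategory")),
      "A classification unit: chapter, block or category.")
  cls("HealthDomain", "icf:ICFCategory",
      "Categories describing health and health-related domains.",
      disjoint = "icf:ContextualFactor")
  cls("ContextualFactor", c("icf:ICFCategory", paste0("sumo:", sumo_lookup("ContextualFactor"))),
      "External or personal modulators of functioning.")
  cls("BodyFunction", "icf:HealthDomain", "Physiological functions of body systems.",
      disjoint = c("icf:BodyStructure", "icf:ActivityAndParticipation"))
  cls("BodyStructure", "icf:HealthDomain", "Anatomical parts of the body.",
      disjoint = "icf:ActivityAndParticipation")
  cls("ActivityAndParticipation",
      c("icf:HealthDomain", paste0("sumo:", sumo_lookup("ActivityAndParticipation"))),
      "Purposeful actions, tasks and areas of life.")
  cls("EnvironmentalFactor",
      c("icf:ContextualFactor", paste0("sumo:", sumo_lookup("EnvironmentalFactor"))),
      "Physical, social and attitudinal surroundings of the subject.",
      disjoint = "icf:PersonalFactor")
  cls("PersonalFactor",
      c("icf:ContextualFactor", paste0("sumo:", sumo_lookup("PersonalFactor"))),
      "Features of the person that are not part of the health condition.")
  cls("Qualifier", paste0("sumo:", sumo_lookup("Qualifier")),
      "A measured quality of functioning; values are individuals of enumerated classes.")
  cls("Human", paste0("sumo:", sumo_lookup("Human")), "An assessment subject.")
  cls("HealthState", NULL, "A dated snapshot of one person's functioning.")
  cls("QualifiedActivity", paste0("sumo:", sumo_lookup("QualifiedActivity")),
      "Reified quaternary relation: an activity executed by the subject of a health state, with performance and capacity difficulty values.")
  cls("LifeSituation", paste0("sumo:", sumo_lookup("LifeSituation")),
      "A societal situation an action is directed at.")
  cls("Influence", NULL,
      "Reified ternary relation between a contextual factor, an influenced entity and a qualifier level.")
  cls("InfluenceableComponent", NULL,
      "Per-health-state component handle used by coding convention 2.")
  cls("InfluencingManner", NULL,
      "How a factor exerts its influence; closed enumeration.")

  # enumerated qualifier classes
  for (nm in names(sc)) {
    tb <- sc[[nm]]
    sumo_parent <- attr(tb, "sumo")
    add(paste0("icf:", nm, " a owl:Class ; rdfs:subClassOf icf:Qualifier",
               if (!is.na(sumo_parent)) paste0(", sumo:", sumo_parent) else "",
               " ;"),
        paste0("    owl:equivalentClass [ a owl:Class ; owl:oneOf ( ",
               paste0("icf:", tb$individual, collapse = " "), " ) ] ."), "")
    for (i in seq_len(nrow(tb)))
      add(paste0("icf:", tb$individual[i], " a owl:NamedIndividual , icf:", nm,
                 " ; rdfs:label ", ttl_lit(paste(tb$digit[i], tb$label[i])),
                 " ."))
    add("")
  }
  mi <- manner_individual(influencing_manners())
  add(paste0("icf:InfluencingManner owl:equivalentClass [ a owl:Class ; owl:oneOf ( ",
             paste0("icf:", mi, collapse = " "), " ) ] ."))
  add(paste0("icf:", mi, " a owl:NamedIndividual , icf:InfluencingManner ."), "")

  # object properties
  props <- schema_properties()
  sm <- sumo_mappings()
  for (i in seq_len(nrow(props))) {
    p <- props[i, ]
    sumo_row <- sm[sm$entity == p$name & sm$entity_type == "property", ]
    supers <- c(if (!is.na(p$super)) p$super,
                if (nrow(sumo_row) && !is.na(sumo_row$sumo))
                  paste0("sumo:", sumo_row$sumo))
    body <- c("a owl:ObjectProperty",
              if (p$functional) "a owl:FunctionalProperty",
              if (length(supers)) paste0("rdfs:subPropertyOf ", paste(supers, collapse = " , ")),
              if (!is.na(p$domain)) paste0("rdfs:domain ", p$domain),
              if (!is.na(p$range)) paste0("rdfs:range ", p$range),
              if (!is.na(p$inverse_of)) paste0("owl:inverseOf icf:", p$inverse_of),
              paste0("rdfs:comment ", ttl_lit(p$comment)))
    add(paste0("icf:", p$name, " ", paste(body, collapse = " ;\n    "), " ."), "")
    if (!is.na(p$exact1)) {
      for (cl in strsplit(p$exact1, " ")[[1]])
        add(paste0(cl, " rdfs:subClassOf [ a owl:Restriction ; owl:onProperty icf:",
                   p$name,
                   ' ; owl:cardinality "1"^^xsd:nonNegativeInteger ] .'), "")
    }
  }

  # defined classes
  union3 <- "[ a owl:Class ; owl:unionOf ( icf:HealthState icf:InfluenceableComponent icf:QualifiedActivity ) ]"
  add("icf:QualifiedParticipativeActivity a owl:Class ;",
      '    rdfs:comment "Defined class: a qualified activity whose destination is a life situation." ;',
      "    owl:equivalentClass [ a owl:Class ; owl:intersectionOf ( icf:QualifiedActivity",
      "        [ a owl:Restriction ; owl:onProperty icf:destination ; owl:someValuesFrom icf:LifeSituation ] ) ] .",
      "",
      "icf:Facilitator a owl:Class ;",
      '    rdfs:comment "Defined class: an influence reaching its target through facilitation." ;',
      "    owl:equivalentClass [ a owl:Class ; owl:intersectionOf ( icf:Influence",
      paste0("        [ a owl:Restriction ; owl:onProperty icf:facilitates ; owl:someValuesFrom ",
             union3, " ] ) ] ."),
      "",
      "icf:Barrier a owl:Class ;",
      '    rdfs:comment "Defined class: an influence reaching its target through hindrance." ;',
      "    owl:equivalentClass [ a owl:Class ; owl:intersectionOf ( icf:Influence",
      paste0("        [ a owl:Restriction ; owl:onProperty icf:hinders ; owl:someValuesFrom ",
             union3, " ] ) ] ."),
      "",
      "icf:InfluencingFactor a owl:Class ;",
      '    rdfs:comment "Defined class: a contextual factor that exerts at least one influence." ;',
      "    owl:equivalentClass [ a owl:Class ; owl:intersectionOf ( icf:ContextualFactor",
      "        [ a owl:Restriction ; owl:onProperty [ owl:inverseOf icf:factor ] ; owl:someValuesFrom icf:Influence ] ) ] .",
      "")

  # registry categories as classes under their component roots
  reg <- model$registry
  nodes <- reg[reg$kind != "block", ]
  parent_cls <- function(code, parent) {
    if (is.na(parent)) return(paste0("icf:", icf_component_class(substr(code, 1, 1))))
    pk <- reg$kind[match(parent, reg$code)]
    if (identical(pk, "block")) parent <- reg$parent[match(parent, reg$code)]
    paste0("icf:", category_class(parent))
  }
  for (i in seq_len(nrow(nodes)))
    add(paste0("icf:", category_class(nodes$code[i]), " a owl:Class ; rdfs:subClassOf ",
               parent_cls(nodes$code[i], nodes$parent[i]),
               " ; rdfs:label ", ttl_lit(nodes$title[i]), " ."))
  add("")
  L
}

data_lines <- function(model) {
  sc <- model$scales
  L <- character()
  add <- function(...) L <<- c(L, ...)
  for (i in seq_len(nrow(model$humans)))
    add(paste0(":", model$humans$id[i], " a icf:Human ; rdfs:label ",
               ttl_lit(model$humans$name[i]), " ."))
  for (i in seq_len(nrow(model$situations)))
    add(paste0(":", model$situations$id[i], " a icf:LifeSituation ; rdfs:label ",
               ttl_lit(model$situations$label[i]), " ."))
  for (i in seq_len(nrow(model$states)))
    add(paste0(":", model$states$id[i], " a icf:HealthState ; icf:agent :",
               model$states$subject[i], " ; rdfs:label ",
               ttl_lit(model$states$label[i]), " ."))
  acts <- model$activities[!duplicated(model$activities$activity), ]
  for (i in seq_len(nrow(acts)))
    add(paste0(":", acts$activity[i], " a icf:", category_class(acts$code[i]), " ."))
  for (i in seq_len(nrow(model$factors))) {
    f <- model$factors[i, ]
    type <- if (f$kind == "environmental") category_class(f$code) else "PersonalFactor"
    add(paste0(":", f$id, " a icf:", type, " ; rdfs:label ", ttl_lit(f$label), " ."))
  }
  for (i in seq_len(nrow(model$activities))) {
    a <- model$activities[i, ]
    body <- c("a icf:QualifiedActivity",
              paste0("icf:partOf :", a$state),
              paste0("icf:activity :", a$activity),
              if (!is.na(a$performance))
                paste0("icf:performance icf:",
                       scale_of_digit("Difficulty", a$performance, sc)),
              if (!is.na(a$capacity))
                paste0("icf:capacity icf:",
                       scale_of_digit("Difficulty", a$capacity, sc)),
              if (!is.na(a$destination)) paste0("icf:destination :", a$destination))
    add(paste0(":", a$id, " ", paste(body, collapse = " ;\n    "), " ."))
  }
  for (i in seq_len(nrow(model$components))) {
    cmp <- model$components[i, ]
    add(paste0(":", cmp$id, " a icf:InfluenceableComponent ; icf:partOf :",
               cmp$state, " ; rdfs:label ", ttl_lit(cmp$component), " ."))
  }
  for (i in seq_len(nrow(model$influences))) {
    f <- model$influences[i, ]
    facil <- !is.na(f$facilitation_level)
    body <- c("a icf:Influence",
              paste0("icf:factor :", f$factor),
              if (facil) paste0("icf:facilitationLevel icf:",
                                scale_of_digit("Facilitation", f$facilitation_level, sc))
              else paste0("icf:barrierLevel icf:",
                          scale_of_digit("Hindrance", f$barrier_level, sc)),
              if (!is.na(f$manner))
                paste0("icf:influencingManner icf:", manner_individual(f$manner)))
    add(paste0(":", f$id, " ", paste(body, collapse = " ;\n    "), " ."))
    add(paste0(":", f$target, " icf:",
               if (facil) "facilitatedBy" else "hindrancedBy", " :", f$id, " ."))
  }
  L
}

#' Export a model as OWL/Turtle
#'
#' Serializes the full ontology -- the fixed upper schema (classes, object
#' properties with domain/range, functional-property axioms for every 0..1
#' multiplicity, exact-cardinality-1 restrictions, disjointness, the four
#' defined classes as equivalent-class axioms, inverse properties, SUMO
#' bridges, enumerated qualifier classes), the loaded registry categories as
#' subclasses, and (optionally) the model's individuals. Output is
#' deterministic: identical models serialize to identical bytes.
#'
#' @param model An `icf_model`.
#' @param path Output file; omit to get the Turtle text back invisibly.
#' @param include_data Serialize the model's individuals (default `TRUE`);
#'   `FALSE` gives a schema-only export.
#' @param validate Passed to the pre-export validation (as in
#'   [to_triples()]).
#' @return Character vector of Turtle lines, invisibly.
#' @seealso [read_turtle()] for the restricted re-import.
#' @export
export_owl <- function(model, path = NULL, include_data = TRUE, validate = TRUE) {
  stopifnot(inherits(model, "icf_model"))
  if (include_data) {
    assert_serializable_ids(model)
    if (validate) {
      rep <- icf_validate(model)
      if (!rep$passed) abort("model does not validate; see icf_validate()")
    }
  }
  L <- c(
    paste0("@prefix icf: <", ICF_NS, "> ."),
    paste0("@prefix : <", DATA_NS, "> ."),
    paste0("@prefix sumo: <", SUMO_NS, "> ."),
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "",
    schema_lines(model),
    if (include_data) c("# -- individuals --", data_lines(model)))
  if (!is.null(path)) writeLines(L, path, useBytes = TRUE)
  invisible(L)
}

tokenize_turtle <- function(text) {
  # replace quoted literals and angle-bracket IRIs with placeholders so that
  # statement splitting on '.' / ';' is safe
  stash <- character()
  repl <- function(pattern, text) {
    repeat {
      m <- regexpr(pattern, text, perl = TRUE)
      if (m == -1) return(text)
      tok <- regmatches(text, m)
      stash[length(stash) + 1] <<- tok
      regmatches(text, m) <- paste0("\x01", length(stash), "\x01")
    }
  }
  text <- repl('"(?:[^"\\\\]|\\\\.)*"', text)
  text <- repl("<[^>]*>", text)
  list(text = text, stash = stash)
}

untoken <- function(x, stash) {
  m <- str_match(x, "^\x01([0-9]+)\x01$")
  if (is.na(m[1, 1])) return(x)
  stash[as.integer(m[1, 2])]
}

unescape_lit <- function(tok) {
  inner <- substr(tok, 2, nchar(tok) - 1)
  inner <- gsub('\\"', '"', inner, fixed = TRUE)
  gsub("\\\\", "\\", inner, fixed = TRUE)
}

#' Re-import a Turtle export
#'
#' Parses Turtle previously written by [export_owl()] back into an
#' `icf_model`. The reader is restricted to this ontology's vocabulary: it
#' reconstructs the data individuals (humans, life situations, health
#' states, activities, factors, component handles, influences) and ignores
#' the schema axioms, which are fixed. Round trip holds:
#' `to_triples(read_turtle(f))` equals `to_triples(model)` for the model
#' that wrote `f`.
#'
#' @param path Path to a `.ttl` file, or a character vector of Turtle lines.
#' @param registry,scales Registry and scales for the rebuilt model.
#' @return An `icf_model`.
#' @export
read_turtle <- function(path, registry = icf_registry(), scales = icf_scales()) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path, warn = FALSE)
           else path
  if (!length(lines) || !any(nzchar(str_trim(lines))))
    abort("unreadable model file: empty input")
  lines <- lines[!grepl("^\\s*#", lines)]
  tk <- tokenize_turtle(paste(lines, collapse = "\n"))
  text <- gsub("@prefix[^.]*\\.", "", tk$text)
  stmts <- str_trim(str_split(text, "\\.\\s", simplify = FALSE)[[1]])
  stmts <- sub("\\.$", "", stmts)
  stmts <- str_trim(stmts[nzchar(str_trim(stmts))])

  triples <- list()
  for (st in stmts) {
    toks <- strsplit(str_trim(st), "[ \n]+")[[1]]
    if (!length(toks) || !startsWith(toks[1], ":")) next  # data subjects only
    subj <- substring(toks[1], 2)
    rest <- paste(toks[-1], collapse = " ")
    for (grp in str_trim(strsplit(rest, ";", fixed = TRUE)[[1]])) {
      pt <- strsplit(grp, " +")[[1]]
      if (length(pt) < 2) next
      pred <- pt[1]
      for (obj in pt[-1]) {
        if (obj == ",") next
        triples[[length(triples) + 1]] <-
          tibble(subject = subj, predicate = pred,
                 object = untoken(obj, tk$stash))
      }
    }
  }
  tt <- if (length(triples)) bind_rows(triples) else
    tibble(subject = character(), predicate = character(), object = character())

  model <- icf_model(registry = registry, scales = scales)
  of <- function(s, p) {
    o <- tt$object[tt$subject == s & tt$predicate == p]
    if (length(o)) o[1] else NA_character_
  }
  lbl <- function(s) {
    o <- of(s, "rdfs:label")
    if (is.na(o)) NA_character_ else unescape_lit(o)
  }
  strip <- function(x, prefix) substring(x, nchar(prefix) + 1)
  types <- tt[tt$predicate == "a" & startsWith(tt$object, "icf:"), ]
  types$class <- strip(types$object, "icf:")
  subj_of_type <- function(cl) unique(types$subject[types$class == cl])
  rev_digit <- function(ind, scale) {
    tb <- icf_scale(scale, scales)
    d <- tb$digit[match(ind, tb$individual)]
    if (is.na(d)) abort(paste0("unknown ", scale, " individual: ", ind))
    d
  }

  for (h in subj_of_type("Human"))
    model <- add_human(model, h, lbl(h) %|na|% h)
  for (s in subj_of_type("LifeSituation")) {
    model$situations <- add_row(model$situations, id = s, label = lbl(s) %|na|% s)
  }
  for (s in subj_of_type("HealthState"))
    model <- add_health_state(model, strip(of(s, "icf:agent"), ":"),
                              lbl(s) %|na|% s, id = s)
  cat_types <- types[grepl("^[BSDE][0-9]+$", types$class), ]
  code_of_ind <- setNames(
    paste0(tolower(substr(cat_types$class, 1, 1)), substring(cat_types$class, 2)),
    cat_types$subject)
  for (q in subj_of_type("QualifiedActivity")) {
    act <- strip(of(q, "icf:activity"), ":")
    perf <- of(q, "icf:performance"); cap <- of(q, "icf:capacity")
    model <- add_qualified_activity(
      model, strip(of(q, "icf:partOf"), ":"), unname(code_of_ind[act]),
      performance = if (!is.na(perf)) rev_digit(strip(perf, "icf:"), "Difficulty"),
      capacity = if (!is.na(cap)) rev_digit(strip(cap, "icf:"), "Difficulty"),
      id = q, activity = act)
    dest <- of(q, "icf:destination")
    if (!is.na(dest)) {
      sid <- strip(dest, ":")
      i <- match(q, model$activities$id)
      model$activities$destination[i] <- sid
    }
  }
  for (f in cat_types$subject[startsWith(cat_types$class, "E")])
    model <- add_factor(model, id = f, kind = "environmental",
                        code = unname(code_of_ind[f]), label = lbl(f))
  for (f in subj_of_type("PersonalFactor"))
    model <- add_factor(model, id = f, kind = "personal", label = lbl(f) %|na|% f)
  for (cmp in subj_of_type("InfluenceableComponent"))
    model <- add_component_handle(model, strip(of(cmp, "icf:partOf"), ":"),
                                  component = lbl(cmp), id = cmp)
  pol <- tt[tt$predicate %in% c("icf:facilitatedBy", "icf:hindrancedBy"), ]
  for (i2 in subj_of_type("Influence")) {
    j <- match(paste0(":", i2), pol$object)
    if (is.na(j)) abort(paste0("influence without polarity link: ", i2))
    facil <- pol$predicate[j] == "icf:facilitatedBy"
    lev <- of(i2, if (facil) "icf:facilitationLevel" else "icf:barrierLevel")
    man <- of(i2, "icf:influencingManner")
    model <- add_influence(
      model, target = pol$subject[j], factor = strip(of(i2, "icf:factor"), ":"),
      polarity = if (facil) "facilitation" else "hindrance",
      level = rev_digit(strip(lev, "icf:"),
                        if (facil) "Facilitation" else "Hindrance"),
      manner = if (!is.na(man)) tolower(sub("_manner$", "",
                                            strip(man, "icf:"))),
      id = i2)
  }
  model
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a
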