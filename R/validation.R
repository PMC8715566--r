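violation <- function(rule, severity, entity, message) {
  tibble(rule = rule, severity = severity, entity = entity, message = message)
}

no_violations <- function() {
  tibble(rule = character(), severity = character(),
         entity = character(), message = character())
}

#' Disjointness checks
#'
#' Flags entities that land in two mutually exclusive classes:
#' a contextual factor typed both environmental and personal; a code from
#' the contextual-factor side used where a health-domain category belongs
#' (an e-code as a qualified activity's category) or vice versa (a b/s/d
#' code on an environmental factor).
#'
#' @param model An `icf_model`.
#' @return Tibble of violations (possibly empty).
#' @export
check_disjointness <- function(model) {
  stopifnot(inherits(model, "icf_model"))
  v <- no_violations()

  dup <- model$factors |>
    summarise(kinds = n_distinct(.data$kind), .by = "id") |>
    filter(.data$kinds > 1)
  if (nrow(dup))
    v <- bind_rows(v, violation("disjoint_factor_kind", "error", dup$id,
      "contextual factor typed both environmental and personal"))

  bad_act <- model$activities |>
    filter(icf_is_code(.data$code) &
             substr(.data$code, 1, 1) %in% c("e"))
  if (nrow(bad_act))
    v <- bind_rows(v, violation("disjoint_component_code", "error", bad_act$id,
      paste0("contextual-factor code ", bad_act$code,
             " used as a health-domain (A&P) category")))

  bad_fac <- model$factors |>
    filter(.data$kind == "environmental", !is.na(.data$code),
           icf_is_code(.data$code), substr(.data$code, 1, 1) != "e")
  if (nrow(bad_fac))
    v <- bind_rows(v, violation("disjoint_component_code", "error", bad_fac$id,
      paste0("health-domain code ", bad_fac$code,
             " used as an environmental factor")))
  v
}

#' Cardinality checks
#'
#' Enforces the multiplicities of the reified relations: every qualified
#' activity and component handle belongs to exactly one existing health
#' state; a set destination resolves to exactly one life situation; every
#' influence names exactly one existing factor and carries exactly one of
#' facilitation level / barrier level.
#'
#' @param model An `icf_model`.
#' @return Tibble of violations (possibly empty).
#' @export
check_cardinality <- function(model) {
  stopifnot(inherits(model, "icf_model"))
  v <- no_violations()

  multi <- unique(model$activities$id[duplicated(model$activities$id)])
  if (length(multi))
    v <- bind_rows(v, violation("card_activity_state", "error", multi,
      "qualified activity claimed by more than one health state"))
  orphan <- model$activities |> filter(!.data$state %in% model$states$id,
                                       !.data$id %in% multi)
  if (nrow(orphan))
    v <- bind_rows(v, violation("card_activity_state", "error", orphan$id,
      paste0("qualified activity belongs to no existing health state (",
             orphan$state, ")")))

  bad_dest <- model$activities |>
    filter(!is.na(.data$destination), !.data$destination %in% model$situations$id)
  if (nrow(bad_dest))
    v <- bind_rows(v, violation("card_destination", "error", bad_dest$id,
      paste0("destination ", bad_dest$destination, " is not a life situation")))

  orphan_comp <- model$components |> filter(!.data$state %in% model$states$id)
  if (nrow(orphan_comp))
    v <- bind_rows(v, violation("card_activity_state", "error", orphan_comp$id,
      "influenceable component bound to no existing health state"))

  no_factor <- model$influences |> filter(!.data$factor %in% model$factors$id)
  if (nrow(no_factor))
    v <- bind_rows(v, violation("card_influence_factor", "error", no_factor$id,
      paste0("influence names no existing factor (", no_factor$factor, ")")))

  both <- model$influences |>
    filter(!is.na(.data$facilitation_level) & !is.na(.data$barrier_level))
  if (nrow(both))
    v <- bind_rows(v, violation("card_influence_polarity", "error", both$id,
      "influence carries both a facilitation level and a barrier level"))
  neither <- model$influences |>
    filter(is.na(.data$facilitation_level) & is.na(.data$barrier_level))
  if (nrow(neither))
    v <- bind_rows(v, violation("card_influence_polarity", "error", neither$id,
      "influence carries no qualifier level"))

  no_target <- model$influences |>
    filter(!.data$target %in% influence_targets(model)$id)
  if (nrow(no_target))
    v <- bind_rows(v, violation("card_influence_target", "error", no_target$id,
      paste0("influence target does not exist (", no_target$target, ")")))
  v
}

check_domain_range <- function(model) {
  v <- no_violations()
  sc <- model$scales

  bad_subj <- model$states |> filter(!.data$subject %in% model$humans$id)
  if (nrow(bad_subj))
    v <- bind_rows(v, violation("domain_state_subject", "error", bad_subj$id,
      paste0("health state subject is not a human (", bad_subj$subject, ")")))

  diff_digits <- icf_scale("Difficulty", sc)$digit
  for (col in c("performance", "capacity")) {
    bad <- model$activities |>
      filter(!is.na(.data[[col]]), !.data[[col]] %in% diff_digits)
    if (nrow(bad))
      v <- bind_rows(v, violation("range_qualifier_digit", "error", bad$id,
        paste0(col, " digit ", bad[[col]], " outside the Difficulty scale")))
  }
  bad_f <- model$influences |>
    filter(!is.na(.data$facilitation_level),
           !.data$facilitation_level %in% icf_scale("Facilitation", sc)$digit)
  if (nrow(bad_f))
    v <- bind_rows(v, violation("range_qualifier_digit", "error", bad_f$id,
      paste0("facilitation level ", bad_f$facilitation_level,
             " outside the Facilitation scale")))
  bad_b <- model$influences |>
    filter(!is.na(.data$barrier_level),
           !.data$barrier_level %in% icf_scale("Hindrance", sc)$digit)
  if (nrow(bad_b))
    v <- bind_rows(v, violation("range_qualifier_digit", "error", bad_b$id,
      paste0("barrier level ", bad_b$barrier_level,
             " outside the Hindrance scale")))

  bad_m <- model$influences |>
    filter(!is.na(.data$manner), !.data$manner %in% influencing_manners())
  if (nrow(bad_m))
    v <- bind_rows(v, violation("domain_manner", "error", bad_m$id,
      paste0("unknown influencing manner: ", bad_m$manner)))

  unreg_a <- model$activities |>
    filter(!map_lgl(.data$code, registry_has, registry = model$registry))
  if (nrow(unreg_a))
    v <- bind_rows(v, violation("unregistered_code", "warning", unreg_a$id,
      paste0("code ", unreg_a$code, " is not in the loaded registry")))
  unreg_f <- model$factors |>
    filter(.data$kind == "environmental", !is.na(.data$code),
           substr(.data$code, 1, 1) == "e",
           !map_lgl(.data$code, registry_has, registry = model$registry))
  if (nrow(unreg_f))
    v <- bind_rows(v, violation("unregistered_code", "warning", unreg_f$id,
      paste0("code ", unreg_f$code, " is not in the loaded registry")))
  v
}

#' Validate a model
#'
#' Runs every consistency rule -- disjointness, cardinality, domain/range,
#' registry membership -- and reports all violations at once (never
#' fail-fast), deterministically ordered. Disjointness, cardinality and
#' domain/range breaches are errors; an unregistered code is a warning,
#' because the registry is partial by design. The model passes iff it has
#' no errors.
#'
#' @param model An `icf_model`.
#' @return An `icf_validation`: list with `violations` (tibble: `rule`,
#'   `severity`, `entity`, `message`) and `passed`.
#' @examples
#' icf_validate(icf_fixtures()$peter)
#' @export
icf_validate <- function(model) {
  stopifnot(inherits(model, "icf_model"))
  v <- bind_rows(check_disjointness(model), check_cardinality(model),
                 check_domain_range(model)) |>
    arrange(.data$rule, .data$entity, .data$message)
  structure(list(violations = v,
                 passed = !any(v$severity == "error")),
            class = "icf_validation")
}

#' All validation rule identifiers
#'
#' @return Character vector of rule ids, each triggerable by a fault
#'   injection in [generate_synthetic()].
#' @export
validation_rules <- function() {
  c("disjoint_factor_kind", "disjoint_component_code", "card_activity_state",
    "card_destination", "card_influence_factor", "card_influence_polarity",
    "card_influence_target", "domain_state_subject", "range_qualifier_digit",
    "domain_manner", "unregistered_code")
}

#' @export
print.icf_validation <- function(x, ...) {
  cat("<icf_validation> ", if (x$passed) "passed" else "FAILED", "\n", sep = "")
  if (nrow(x$violations)) {
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s: %s -- %s\n", x$violations$severity[i],
                  x$violations$rule[i], x$violations$entity[i],
                  x$violations$message[i]))
  } else cat("  no violations\n")
  invisible(x)
}

#' @rdname icf_validate
#' @param x An `icf_validation`.
#' @param ... Unused.
#' @export
tidy.icf_validation <- function(x, ...) x$violations

#' @rdname icf_validate
#' @export
glance.icf_validation <- function(x, ...) {
  tibble(passed = x$passed,
         n_errors = sum(x$violations$severity == "error"),
         n_warnings = sum(x$violations$severity == "warning"))
}

#' Render a validation report as JSON
#'
#' @param x An `icf_validation`.
#' @return JSON string.
#' @export
validation_json <- function(x) {
  stopifnot(inherits(x, "icf_validation"))
  jsonlite::toJSON(list(passed = x$passed, violations = x$violations),
                   auto_unbox = TRUE, pretty = TRUE)
}
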