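#' Influencing manners
#'
#' The closed enumeration of reasons *how* a contextual factor exerts its
#' influence: by being present or absent, by how accessible, dependable or
#' variable it is, by its quality, or unspecified.
#'
#' @return Character vector of the seven manner names.
#' @export
influencing_manners <- function() {
  c("presence", "absence", "accessibility", "quality",
    "dependability", "variability", "unspecified")
}

manner_individual <- function(manner) {
  ifelse(is.na(manner), NA_character_, paste0(toupper(manner), "_manner"))
}

#' Add a contextual factor
#'
#' Environmental and personal factors are disjoint kinds of contextual
#' factor. Environmental factors are physical things and carry an
#' Environmental Factors (e) code; personal factors (age, profession,
#' coping style, ...) are attributes of the person and carry no code --
#' the ICF does not classify them.
#'
#' @param model An `icf_model`.
#' @param id Identifier, e.g. `"Ibuprofen_1"`; default slug of the label.
#' @param kind `"environmental"` or `"personal"`.
#' @param code e-code, required iff `kind = "environmental"`.
#' @param label Display label; defaults to the registry title of `code`.
#' @return The updated model.
#' @export
add_factor <- function(model, id = NULL, kind = c("environmental", "personal"),
                       code = NULL, label = NULL) {
  stopifnot(inherits(model, "icf_model"))
  kind <- match.arg(kind)
  if (kind == "environmental") {
    if (is.null(code)) abort("environmental factors need an e-code")
    if (icf_parse_code(code)$component != "e")
      abort(paste0(code, " is not an Environmental Factors code"))
    label <- label %||% registry_title(model$registry, code) %||% code
    if (is.na(label)) label <- code
  } else {
    if (!is.null(code)) abort("personal factors carry no code")
    code <- NA_character_
    if (is.null(label)) abort("personal factors need a label")
  }
  id <- id %||% paste0(slugify(label), "_1")
  check_new_id(model, id, "contextual factor")
  model$factors <- add_row(model$factors, id = id, kind = kind,
                           code = code, label = label)
  model
}

#' Add an influenceable-component handle (coding convention 2)
#'
#' Under the second ICF coding convention an environmental factor is coded
#' against one *component* of a health state rather than the whole state or
#' a single activity. The handle reifies that attachment point: one per
#' (state, component) pair.
#'
#' @param model An `icf_model`.
#' @param state Id of an existing health state.
#' @param component `"ActivityAndParticipation"`, `"BodyFunction"` or
#'   `"BodyStructure"`.
#' @param id Optional id; default `<state>_<component>_component`.
#' @return The updated model.
#' @export
add_component_handle <- function(model, state,
                                 component = c("ActivityAndParticipation",
                                               "BodyFunction", "BodyStructure"),
                                 id = NULL) {
  stopifnot(inherits(model, "icf_model"))
  component <- match.arg(component)
  if (!state %in% model$states$id) abort(paste0("unknown health state: ", state))
  existing <- model$components$id[model$components$state == state &
                                    model$components$component == component]
  if (length(existing)) return(model)
  id <- id %||% paste0(state, "_", component, "_component")
  check_new_id(model, id, "influenceable component")
  model$components <- add_row(model$components, id = id, state = state,
                              component = component)
  model
}

influence_targets <- function(model) {
  bind_rows(
    tibble(id = model$states$id, target_type = "health_state"),
    tibble(id = model$components$id, target_type = "component"),
    tibble(id = model$activities$id, target_type = "activity"))
}

resolve_level <- function(level, polarity, scales) {
  scale <- if (polarity == "facilitation") "Facilitation" else "Hindrance"
  if (is.data.frame(level)) {
    if (!identical(level$scale, scale))
      abort(paste0("level from the ", level$scale, " scale does not match ",
                   polarity, " polarity (needs ", scale, ")"))
    return(level$digit)
  }
  icf_value(scale, level, scales)$digit
}

#' Record an influence
#'
#' The reified ternary relation: a contextual factor influences a target --
#' a whole health state (coding convention 1), an influenceable component
#' (convention 2) or a single qualified activity (convention 3) -- with one
#' polarity. A facilitation influence carries a `facilitationLevel` from the
#' Facilitation scale; a hindrance influence a `barrierLevel` from the
#' Hindrance scale; exactly one of the two, matching the polarity. The
#' influencing manner is optional.
#'
#' @param model An `icf_model`.
#' @param target Id of a health state, component handle or qualified
#'   activity.
#' @param factor Id of a contextual factor.
#' @param polarity `"facilitation"` or `"hindrance"`.
#' @param level Qualifier value: digit, label, or a row from [icf_value()]
#'   (which must come from the scale matching the polarity).
#' @param manner Optional influencing manner, see [influencing_manners()].
#' @param id Optional id; default `<target>_<tolower(factor)>`.
#' @return The updated model.
#' @export
add_influence <- function(model, target, factor,
                          polarity = c("facilitation", "hindrance"),
                          level, manner = NULL, id = NULL) {
  stopifnot(inherits(model, "icf_model"))
  polarity <- match.arg(polarity)
  if (is.null(target) || is.null(factor)) abort("target and factor are required")
  if (!factor %in% model$factors$id) abort(paste0("unknown factor: ", factor))
  if (!target %in% influence_targets(model)$id)
    abort(paste0("unknown influence target: ", target))
  digit <- resolve_level(level, polarity, model$scales)
  if (!is.null(manner) && !manner %in% influencing_manners())
    abort(paste0("unknown influencing manner: ", manner))
  id <- id %||% paste0(target, "_", tolower(factor))
  check_new_id(model, id, "influence")
  model$influences <- add_row(
    model$influences, id = id, factor = factor, target = target,
    facilitation_level = if (polarity == "facilitation") digit else NA_integer_,
    barrier_level = if (polarity == "hindrance") digit else NA_integer_,
    manner = manner %||% NA_character_)
  model
}

#' Which coding convention does an influence use?
#'
#' Dispatch on the target's type: a health state is convention 1, an
#' influenceable component convention 2, a qualified activity convention 3.
#'
#' @param model An `icf_model`.
#' @param influence Optional id(s); default all influences.
#' @return Named integer vector in `{1, 2, 3}`.
#' @export
convention_of <- function(model, influence = NULL) {
  stopifnot(inherits(model, "icf_model"))
  inf <- model$influences
  if (!is.null(influence)) {
    if (!all(influence %in% inf$id))
      abort(paste0("unknown influence: ",
                   paste(setdiff(influence, inf$id), collapse = ", ")))
    inf <- inf[match(influence, inf$id), ]
  }
  tt <- influence_targets(model)
  conv <- c(health_state = 1L, component = 2L, activity = 3L)
  setNames(unname(conv[tt$target_type[match(inf$target, tt$id)]]), inf$id)
}

#' Facilitator / Barrier membership (defined classes)
#'
#' An influence is a Facilitator when it reaches its target through the
#' facilitation relation (it carries a `facilitationLevel`), a Barrier when
#' through the hindrance relation. Membership is inferred, never asserted,
#' and the two classes are disjoint.
#'
#' @param model An `icf_model`.
#' @param influence Optional id(s); default all influences.
#' @return Named character vector, `"Facilitator"` or `"Barrier"`.
#' @export
classify_influence <- function(model, influence = NULL) {
  stopifnot(inherits(model, "icf_model"))
  inf <- model$influences
  if (!is.null(influence)) {
    if (!all(influence %in% inf$id))
      abort(paste0("unknown influence: ",
                   paste(setdiff(influence, inf$id), collapse = ", ")))
    inf <- inf[match(influence, inf$id), ]
  }
  setNames(if_else(!is.na(inf$facilitation_level), "Facilitator", "Barrier"),
           inf$id)
}

#' Factors that exert some influence (defined class)
#'
#' The InfluencingFactor class: contextual factors appearing as the factor
#' of at least one influence.
#'
#' @param model An `icf_model`.
#' @return Character vector of factor ids, in first-use order.
#' @export
influencing_factors <- function(model) {
  stopifnot(inherits(model, "icf_model"))
  intersect(model$factors$id, model$influences$factor)
}
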