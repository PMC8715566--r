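#' Create an empty ICF model
#'
#' An `icf_model` holds one coherent set of assessments: humans, health
#' states (snapshots of a person's functioning), qualified activities (the
#' reified relation binding an Activities & Participation category to a
#' health state with optional performance / capacity difficulty values and
#' an optional destination life situation), contextual factors, and the
#' reified Influence relations that attach factors to targets. All tables
#' are plain tibbles, so the model composes with dplyr; the piped verbs
#' ([add_human()], [add_health_state()], [add_qualified_activity()],
#' [add_influence()], ...) each return the updated model.
#'
#' @param registry Category registry, default [icf_registry()].
#' @param scales Qualifier scales, default [icf_scales()].
#' @return An `icf_model`.
#' @examples
#' m <- icf_model() |>
#'   add_human("Peter", "Peter Taylor") |>
#'   add_health_state("Peter", "2021_mar_17") |>
#'   add_qualified_activity("Peter_state_1", "d410", performance = 1)
#' m
#' @export
icf_model <- function(registry = icf_registry(), scales = icf_scales()) {
  structure(list(
    humans = tibble(id = character(), name = character()),
    states = tibble(id = character(), subject = character(), label = character()),
    activities = tibble(id = character(), state = character(), code = character(),
                        activity = character(), performance = integer(),
                        capacity = integer(), destination = character()),
    situations = tibble(id = character(), label = character()),
    factors = tibble(id = character(), kind = character(), code = character(),
                     label = character()),
    components = tibble(id = character(), state = character(), component = character()),
    influences = tibble(id = character(), factor = character(), target = character(),
                        facilitation_level = integer(), barrier_level = integer(),
                        manner = character()),
    registry = registry, scales = scales
  ), class = "icf_model")
}

slugify <- function(x) {
  s <- gsub("[^A-Za-z0-9]+", "_", x)
  s <- gsub("^_+|_+$", "", s)
  ifelse(nzchar(s), s, "x")
}

check_new_id <- function(model, id, what) {
  all_ids <- c(model$humans$id, model$states$id, model$activities$id,
               model$situations$id, model$factors$id, model$components$id,
               model$influences$id)
  if (id %in% all_ids)
    abort(paste0("identifier already used in this model: ", id, " (", what, ")"))
  id
}

#' Add a human (assessment subject)
#'
#' @param model An `icf_model`.
#' @param id Identifier, unique in the model.
#' @param name Display name (defaults to the id).
#' @return The updated model.
#' @export
add_human <- function(model, id, name = id) {
  stopifnot(inherits(model, "icf_model"))
  check_new_id(model, id, "human")
  model$humans <- add_row(model$humans, id = id, name = name)
  model
}

#' Open a new health state
#'
#' A health state is a dated snapshot of one person's functioning; all
#' qualified activities (and influences, under coding convention 1) hang off
#' it. A subject may have any number of states (longitudinal snapshots).
#'
#' @param model An `icf_model`.
#' @param subject Id of an existing human.
#' @param label Free-text assessment label, typically a date tag such as
#'   `"2021_mar_17"`.
#' @param id Optional explicit id; default `<subject>_state_<n>`.
#' @return The updated model.
#' @export
add_health_state <- function(model, subject, label, id = NULL) {
  stopifnot(inherits(model, "icf_model"))
  if (!subject %in% model$humans$id)
    abort(paste0("unknown subject: ", subject))
  id <- id %||% paste0(subject, "_state_", sum(model$states$subject == subject) + 1L)
  check_new_id(model, id, "health state")
  model$states <- add_row(model$states, id = id, subject = subject, label = label)
  model
}

resolve_difficulty <- function(value, scales, arg) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) return(NA_integer_)
  if (is.data.frame(value)) {
    if (!identical(value$scale, "Difficulty"))
      abort(paste0(arg, " must come from the Difficulty scale, not ", value$scale))
    return(value$digit)
  }
  icf_value("Difficulty", value, scales)$digit
}

#' Record a qualified activity
#'
#' The reified quaternary relation of the model: *this* activity category,
#' executed by the subject of *this* health state, with optional performance
#' and capacity difficulty values. Performance and capacity are distinct
#' sub-relations of manner and never affect one another. Absent qualifiers
#' stay absent (they are not coded as digit 8).
#'
#' @param model An `icf_model`.
#' @param state Id of an existing health state.
#' @param code An Activities & Participation (d) category code.
#' @param performance,capacity Optional Difficulty values, given as digit,
#'   label, or a row from [icf_value()].
#' @param id Optional explicit id; default `<state>_<code>_<n>`.
#' @param activity Optional name for the concrete action individual (an
#'   instance of the category), e.g. `"Changing_position"`; default
#'   `<code>_<n>`.
#' @return The updated model.
#' @export
add_qualified_activity <- function(model, state, code, performance = NULL,
                                   capacity = NULL, id = NULL, activity = NULL) {
  stopifnot(inherits(model, "icf_model"))
  if (!state %in% model$states$id) abort(paste0("unknown health state: ", state))
  parsed <- icf_parse_code(code)
  if (parsed$component != "d")
    abort(paste0(code, " is not an Activities & Participation category"))
  n <- sum(model$activities$state == state & model$activities$code == code) + 1L
  id <- id %||% paste0(state, "_", code, "_", n)
  check_new_id(model, id, "qualified activity")
  activity <- activity %||% paste0(code, "_", sum(model$activities$code == code) + 1L)
  model$activities <- add_row(
    model$activities, id = id, state = state, code = code, activity = activity,
    performance = resolve_difficulty(performance, model$scales, "performance"),
    capacity = resolve_difficulty(capacity, model$scales, "capacity"),
    destination = NA_character_)
  model
}

#' Point a qualified activity at a life situation
#'
#' Setting a destination marks the activity as *participation*: the action
#' is performed in order to take part in a life situation. Life situations
#' are free-text-labeled individuals with no taxonomy of their own. A
#' qualified activity has at most one destination; overwriting requires
#' `replace = TRUE`.
#'
#' @param model An `icf_model`.
#' @param activity Id of a qualified activity.
#' @param situation Life-situation label (an individual is created or
#'   reused), or the id of an existing situation.
#' @param replace Allow overwriting an existing destination.
#' @return The updated model.
#' @export
set_destination <- function(model, activity, situation, replace = FALSE) {
  stopifnot(inherits(model, "icf_model"))
  i <- match(activity, model$activities$id)
  if (is.na(i)) abort(paste0("unknown qualified activity: ", activity))
  if (!is.na(model$activities$destination[i]) && !replace)
    abort(paste0(activity, " already has a destination; use replace = TRUE"))
  sid <- if (situation %in% model$situations$id) situation else slugify(situation)
  if (!sid %in% model$situations$id) {
    check_new_id(model, sid, "life situation")
    model$situations <- add_row(model$situations, id = sid, label = situation)
  }
  model$activities$destination[i] <- sid
  model
}

#' Participation membership (defined class)
#'
#' A qualified activity is a participation exactly when it has a destination
#' toward a life situation. This is inferred from structure, never asserted:
#' no category is pre-tagged as participation, because whether an action has
#' societal relevance depends on the subject under assessment.
#'
#' @param model An `icf_model`.
#' @param activity Optional id(s); default all qualified activities.
#' @return Named logical vector.
#' @export
is_participation <- function(model, activity = NULL) {
  stopifnot(inherits(model, "icf_model"))
  acts <- model$activities
  if (!is.null(activity)) {
    if (!all(activity %in% acts$id))
      abort(paste0("unknown qualified activity: ",
                   paste(setdiff(activity, acts$id), collapse = ", ")))
    acts <- acts[match(activity, acts$id), ]
  }
  setNames(!is.na(acts$destination) & acts$destination %in% model$situations$id,
           acts$id)
}

#' Qualified activities that are participations
#'
#' @param model An `icf_model`.
#' @return Tibble of the participation rows joined with situation labels.
#' @export
participations <- function(model) {
  stopifnot(inherits(model, "icf_model"))
  model$activities |>
    filter(is_participation(model)) |>
    left_join(rename(model$situations, destination = "id",
                     situation = "label"), by = "destination")
}

#' Agent of a qualified activity
#'
#' The activity's agent is reached indirectly: the subject of the health
#' state the activity is part of (there is no direct activity-to-human
#' link in the model).
#'
#' @param model An `icf_model`.
#' @param activity Id(s) of qualified activities.
#' @return Character vector of human ids.
#' @export
agent_of <- function(model, activity) {
  stopifnot(inherits(model, "icf_model"))
  i <- match(activity, model$activities$id)
  if (anyNA(i))
    abort(paste0("unknown qualified activity: ",
                 paste(activity[is.na(i)], collapse = ", ")))
  st <- match(model$activities$state[i], model$states$id)
  if (anyNA(st))
    abort(paste0("detached qualified activity (health state missing): ",
                 paste(activity[is.na(st)], collapse = ", ")))
  model$states$subject[st]
}

#' @export
print.icf_model <- function(x, ...) {
  cat("<icf_model>\n")
  cat("  humans:               ", nrow(x$humans), "\n")
  cat("  health states:        ", nrow(x$states), "\n")
  cat("  qualified activities: ", nrow(x$activities),
      " (", sum(is_participation(x)), " participations)\n", sep = "")
  cat("  contextual factors:   ", nrow(x$factors), "\n")
  cat("  influences:           ", nrow(x$influences), "\n")
  invisible(x)
}
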