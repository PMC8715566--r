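#' Read an ICF categorical profile
#'
#' A categorical profile is the tabular form clinicians record: one row per
#' coded observation, `code` plus `qualifier` suffix (`".1"` for a problem
#' digit on a d-code, `".3"` / `"+3"` for barrier / facilitator on an
#' e-code), optionally a `section` column carrying the table section the
#' row came from (`problem`, `facilitator`, `barrier`).
#'
#' @param x A data frame with columns `code`, `qualifier` and optionally
#'   `section`, or a path to a CSV file (UTF-8, header row).
#' @param scales Qualifier scales used to resolve suffixes.
#' @return Tibble preserving row order: `code`, `qualifier`, `section`,
#'   plus the resolved `kind`, `digit`, `label`.
#' @examples
#' read_profile(data.frame(code = c("d410", "e1151"),
#'                         qualifier = c(".1", "+3")))
#' @export
read_profile <- function(x, scales = icf_scales()) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_csv(x, col_types = readr::cols(.default = "c"))
  }
  stopifnot(is.data.frame(x))
  if (!all(c("code", "qualifier") %in% names(x)))
    abort("profile needs columns: code, qualifier")
  rows <- as_tibble(x)
  if (!"section" %in% names(rows)) rows$section <- NA_character_
  if (nrow(rows) == 0)
    return(tibble(code = character(), qualifier = character(),
                  section = character(), kind = character(),
                  digit = integer(), label = character()))
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    parsed <- tryCatch({
      icf_parse_code(rows$code[i])
      q <- if (is.na(rows$qualifier[i]) || !nzchar(str_trim(rows$qualifier[i])))
        tibble(kind = NA_character_, digit = NA_integer_, label = NA_character_)
      else parse_qualifier_suffix(rows$qualifier[i], rows$code[i], scales)
      q
    }, error = function(e) {
      abort(paste0("profile row ", i, " (", rows$code[i], rows$qualifier[i],
                   "): ", conditionMessage(e)))
    })
    out[[i]] <- tibble(code = rows$code[i], qualifier = rows$qualifier[i],
                       section = rows$section[i], kind = parsed$kind,
                       digit = parsed$digit, label = parsed$label)
  }
  bind_rows(out)
}

#' Encode a categorical profile as a model
#'
#' Builds one health state for the subject. Every d-row becomes a qualified
#' activity whose *performance* qualifier carries the problem digit (the
#' capacity qualifier is left unset unless the source supplies a second
#' digit, which profile tables here do not). Every e-row becomes an
#' environmental factor plus one influence, attached according to
#' `ef_convention`: 1 targets the whole health state, 2 the Activities &
#' Participation component handle, 3 the most recently encoded qualified
#' activity. Polarity comes from the suffix (`+` facilitation, `.`
#' hindrance).
#'
#' @param rows Profile rows from [read_profile()] (or a raw data frame,
#'   which is passed through it).
#' @param subject Subject id (a human is created).
#' @param label Health-state label.
#' @param ef_convention Environmental-factor coding convention, 1 (default),
#'   2 or 3.
#' @param name Display name of the subject (defaults to `subject`).
#' @param model Optional model to extend; default a fresh [icf_model()].
#' @return A validated `icf_model`.
#' @examples
#' peter <- read_profile(data.frame(
#'   code = c("d410", "d4200", "d440", "d445"),
#'   qualifier = c(".1", ".2", ".4", ".3"))) |>
#'   encode_profile("Peter", "2021_mar_17")
#' @export
encode_profile <- function(rows, subject, label, ef_convention = 1,
                           name = subject, model = NULL) {
  if (!all(c("kind", "digit") %in% names(rows))) rows <- read_profile(rows)
  if (!ef_convention %in% 1:3)
    abort(paste0("unknown coding convention: ", ef_convention))
  model <- model %||% icf_model()
  model <- add_human(model, subject, name)
  model <- add_health_state(model, subject, label)
  state <- tail(model$states$id, 1)
  last_qa <- NULL
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    comp <- icf_parse_code(r$code)$component
    if (comp == "d") {
      if (!is.na(r$kind) && r$kind != "difficulty")
        abort(paste0("profile row ", i, ": ", r$kind,
                     " qualifier is not legal on a d-code"))
      model <- add_qualified_activity(
        model, state, r$code,
        performance = if (!is.na(r$digit)) r$digit)
      last_qa <- tail(model$activities$id, 1)
    } else if (comp == "e") {
      if (is.na(r$kind))
        abort(paste0("profile row ", i, ": e-code without a qualifier suffix"))
      model <- add_factor(model, kind = "environmental", code = r$code)
      fid <- tail(model$factors$id, 1)
      target <- switch(as.character(ef_convention),
        "1" = state,
        "2" = {
          model <- add_component_handle(model, state, "ActivityAndParticipation")
          model$components$id[model$components$state == state &
                                model$components$component == "ActivityAndParticipation"]
        },
        "3" = {
          if (is.null(last_qa))
            abort(paste0("profile row ", i,
                         ": convention 3 needs a preceding d-row to attach to"))
          last_qa
        })
      model <- add_influence(model, target, fid,
                             polarity = r$kind, level = r$digit)
    } else {
      abort(paste0("profile row ", i, ": component ", comp,
                   " is outside the modeled scope"))
    }
  }
  model
}

#' The worked case-study fixtures
#'
#' Four small models built in code, with the individual names used
#' throughout the package documentation:
#'
#' * `e_case` -- a single unqualified activity (d7202, reacting with
#'   physical aggression), no qualifier recorded;
#' * `peter` -- a tetraplegia categorical profile: four mobility activities
#'   with performance difficulties 1, 2, 4, 3;
#' * `conrad` -- a spinal-cord-injury profile with difficulties 0, 2, 3, 4
#'   plus three environmental factors coded under convention 1
#'   (two facilitators: e1151 +3, e580 +2; one barrier: e155 .3);
#' * `john` -- a convention-3 scenario: lifting with severe difficulty,
#'   facilitated to an unspecified ("some") extent by a drug (e1101).
#'
#' @return Named list of validated `icf_model`s.
#' @examples
#' names(icf_fixtures())
#' @export
icf_fixtures <- function() {
  e_case <- icf_model() |>
    add_human("E", "E.") |>
    add_health_state("E", "2020_june_6") |>
    add_qualified_activity("E_state_1", "d7202",
                           id = "E_state_1_reacting_1", activity = "Reacting")

  peter <- icf_model() |>
    add_human("Peter", "Peter Taylor") |>
    add_health_state("Peter", "2021_mar_17") |>
    add_qualified_activity("Peter_state_1", "d410", performance = 1,
                           id = "Peter_state_1_changing_position_1",
                           activity = "Changing_position") |>
    add_qualified_activity("Peter_state_1", "d4200", performance = 2,
                           id = "Peter_state_1_transferring_1",
                           activity = "Transferring") |>
    add_qualified_activity("Peter_state_1", "d440", performance = 4,
                           id = "Peter_state_1_fine_hand_use_1",
                           activity = "Fine_hand_use") |>
    add_qualified_activity("Peter_state_1", "d445", performance = 3,
                           id = "Peter_state_1_hand_arm_use_1",
                           activity = "Hand_arm_use")

  conrad <- icf_model() |>
    add_human("Conrad") |>
    add_health_state("Conrad", "2019_oct_2") |>
    add_qualified_activity("Conrad_state_1", "d4153", performance = 0,
                           id = "Conrad_state_1_sitting_position_1",
                           activity = "Sitting_position") |>
    add_qualified_activity("Conrad_state_1", "d4154", performance = 2,
                           id = "Conrad_state_1_standing_position_1",
                           activity = "Standing_position") |>
    add_qualified_activity("Conrad_state_1", "d465", performance = 3,
                           id = "Conrad_state_1_moving_equipment_1",
                           activity = "Moving_with_equipment") |>
    add_qualified_activity("Conrad_state_1", "d850", performance = 4,
                           id = "Conrad_state_1_employment_1",
                           activity = "Remunerative_employment") |>
    add_factor(id = "Assistive_mobility_products_1", kind = "environmental",
               code = "e1151") |>
    add_factor(id = "Private_building_design_1", kind = "environmental",
               code = "e155") |>
    add_factor(id = "Health_services_1", kind = "environmental",
               code = "e580") |>
    add_influence("Conrad_state_1", "Assistive_mobility_products_1",
                  polarity = "facilitation", level = 3) |>
    add_influence("Conrad_state_1", "Private_building_design_1",
                  polarity = "hindrance", level = 3) |>
    add_influence("Conrad_state_1", "Health_services_1",
                  polarity = "facilitation", level = 2)

  john <- icf_model() |>
    add_human("John", "John Smith") |>
    add_health_state("John", "2018_feb_4", id = "John_state_2") |>
    add_qualified_activity("John_state_2", "d4300", performance = 3,
                           id = "John_state_2_lifting_1",
                           activity = "Lifting_1") |>
    add_factor(id = "Ibuprofen_1", kind = "environmental", code = "e1101",
               label = "Ibuprofen") |>
    add_influence("John_state_2_lifting_1", "Ibuprofen_1",
                  polarity = "facilitation", level = "some")

  list(e_case = e_case, peter = peter, conrad = conrad, john = john)
}
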