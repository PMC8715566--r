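#' Tidy an ICF model into one row per assessment
#'
#' One row per qualified activity and per influence, joined with subjects,
#' registry titles and qualifier labels -- the analysis-ready flat form of
#' the model.
#'
#' @param x An `icf_model`.
#' @param ... Unused.
#' @return Tibble: `state`, `subject`, `record` (id), `type`
#'   (`"activity"`/`"influence"`), `code`, `title`, `qualifier`
#'   (`performance`, `facilitation`, `hindrance`), `digit`, `label`,
#'   `participation`, `convention`.
#' @export
tidy.icf_model <- function(x, ...) {
  reg <- x$registry
  acts <- x$activities |>
    mutate(qualifier = "performance", digit = .data$performance) |>
    select("id", "state", "code", "qualifier", "digit", "destination")
  caps <- x$activities |>
    filter(!is.na(.data$capacity)) |>
    mutate(qualifier = "capacity", digit = .data$capacity) |>
    select("id", "state", "code", "qualifier", "digit", "destination")
  a <- bind_rows(acts, caps) |>
    mutate(type = "activity",
           label = map_chr(.data$digit, function(d)
             if (is.na(d)) NA_character_
             else icf_value("Difficulty", d, x$scales)$label),
           participation = unname(is_participation(x)[.data$id]),
           convention = NA_integer_)
  tt <- influence_targets(x)
  inf <- x$influences |>
    mutate(qualifier = if_else(!is.na(.data$facilitation_level),
                               "facilitation", "hindrance"),
           digit = coalesce(.data$facilitation_level, .data$barrier_level),
           code = as.character(x$factors$code[match(.data$factor, x$factors$id)]),
           state = NA_character_, destination = NA_character_,
           type = "influence",
           participation = NA,
           label = map_chr(seq_len(n()), function(i)
             icf_value(if (is.na(.data$facilitation_level[i])) "Hindrance"
                       else "Facilitation",
                       coalesce(.data$facilitation_level,
                                .data$barrier_level)[i], x$scales)$label),
           convention = unname(convention_of(x)[.data$id])) |>
    select("id", "state", "code", "qualifier", "digit", "destination",
           "type", "label", "participation", "convention")
  out <- bind_rows(a, inf) |>
    mutate(title = registry_title(reg, .data$code),
           subject = x$states$subject[match(.data$state, x$states$id)]) |>
    rename(record = "id") |>
    select("state", "subject", "record", "type", "code", "title",
           "qualifier", "digit", "label", "participation", "convention")
  out
}

#' One-row model summary
#'
#' @param x An `icf_model`.
#' @param ... Unused.
#' @return One-row tibble of entity counts and defined-class sizes.
#' @export
glance.icf_model <- function(x, ...) {
  cls <- classify_influence(x)
  tibble(
    humans = nrow(x$humans),
    health_states = nrow(x$states),
    qualified_activities = nrow(x$activities),
    participations = sum(is_participation(x)),
    factors = nrow(x$factors),
    influences = nrow(x$influences),
    facilitators = sum(cls == "Facilitator"),
    barriers = sum(cls == "Barrier"),
    influencing_factors = length(influencing_factors(x)),
    life_situations = nrow(x$situations))
}

#' Plot a model's qualifier profile
#'
#' Bar chart of qualifier digits per code, one facet per health state;
#' activity performance bars point with difficulty, influence bars are
#' colored by polarity -- the visual analogue of an ICF categorical
#' profile table.
#'
#' @param object An `icf_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.icf_model <- function(object, ...) {
  td <- tidy(object) |>
    filter(!is.na(.data$digit)) |>
    mutate(state = coalesce(.data$state, "environmental factors"),
           item = paste0(.data$code, " ", coalesce(.data$title, "")))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$digit, y = .data$item,
                                   fill = .data$qualifier)) +
    ggplot2::geom_col(orientation = "y") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$state), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_x_continuous(breaks = c(0:4, 8), limits = c(0, 8.5)) +
    ggplot2::labs(x = "qualifier digit", y = NULL, fill = "qualifier") +
    ggplot2::theme_minimal()
}

#' Plot a validation report
#'
#' @param object An `icf_validation`.
#' @param ... Unused.
#' @return A ggplot of violation counts by rule and severity.
#' @export
autoplot.icf_validation <- function(object, ...) {
  v <- object$violations
  if (!nrow(v)) v <- tibble(rule = "none", severity = "none")
  ggplot2::ggplot(v, ggplot2::aes(y = .data$rule, fill = .data$severity)) +
    ggplot2::geom_bar(orientation = "y") +
    ggplot2::labs(y = NULL, x = "violations") +
    ggplot2::theme_minimal()
}
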