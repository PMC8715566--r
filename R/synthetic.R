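#' Generate a seeded synthetic model
#'
#' Builds a reproducible single-subject assessment for property testing and
#' demonstrations, mirroring the three validation scenarios: activities
#' alone, participation, and activities with environmental factors.
#' Activity categories are drawn from the registry's Activities &
#' Participation categories with random performance digits (a fixed 80%
#' carry a performance value, the rest stay unqualified); each activity
#' independently becomes a participation with probability
#' `participation_rate`; influences are attached per coding convention with
#' random polarity, level and manner. The same seed always yields the same
#' model (and therefore the same triple set).
#'
#' Fault injection supports the validation suite: each rule id from
#' [validation_rules()] names a mutation that makes the finished model
#' breach exactly that rule, exactly once.
#'
#' @param n_activities Number of qualified activities.
#' @param n_influences Integer vector of length 3: influences to attach
#'   under conventions 1, 2 and 3 respectively.
#' @param participation_rate Probability in `[0, 1]` that an activity gets
#'   a life-situation destination.
#' @param faults Character vector of rule ids to inject (default none).
#' @param seed Integer seed; the generator never touches the global RNG
#'   stream outside its own scope.
#' @param registry,scales Passed to [icf_model()].
#' @return An `icf_model` (validating iff `faults` is empty).
#' @examples
#' m <- generate_synthetic(n_activities = 5, participation_rate = 0.4, seed = 7)
#' icf_validate(m)$passed
#' @export
generate_synthetic <- function(n_activities = 10, n_influences = c(2, 1, 1),
                               participation_rate = 0, faults = character(),
                               seed = 1, registry = icf_registry(),
                               scales = icf_scales()) {
  stopifnot(n_activities >= 0, length(n_influences) == 3, all(n_influences >= 0),
            participation_rate >= 0, participation_rate <= 1)
  unknown <- setdiff(faults, validation_rules())
  if (length(unknown))
    abort(paste0("unknown fault rule: ", paste(unknown, collapse = ", ")))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  d_codes <- registry$code[registry$kind == "category" & registry$component == "d"]
  e_codes <- registry$code[registry$kind == "category" & registry$component == "e"]
  diff_digits <- 0:4

  model <- icf_model(registry = registry, scales = scales) |>
    add_human("subject_1", "Synthetic subject") |>
    add_health_state("subject_1", "synthetic_assessment")
  state <- "subject_1_state_1"

  for (i in seq_len(n_activities)) {
    has_perf <- runif(1) < 0.8
    model <- add_qualified_activity(
      model, state, sample(d_codes, 1),
      performance = if (has_perf) sample(diff_digits, 1),
      id = paste0("qa_", i))
    if (runif(1) < participation_rate)
      model <- set_destination(model, paste0("qa_", i),
                               paste0("life_situation_", i))
  }

  n_fac <- sum(n_influences)
  fac_ids <- character(0)
  for (j in seq_len(n_fac)) {
    personal <- runif(1) < 0.15
    id <- paste0("factor_", j)
    model <- if (personal)
      add_factor(model, id = id, kind = "personal",
                 label = paste0("personal trait ", j))
    else
      add_factor(model, id = id, kind = "environmental",
                 code = sample(e_codes, 1))
    fac_ids <- c(fac_ids, id)
  }
  if (n_influences[2] > 0)
    model <- add_component_handle(model, state, "ActivityAndParticipation",
                                  id = "comp_1")
  k <- 0
  for (conv in 1:3) {
    for (j in seq_len(n_influences[conv])) {
      k <- k + 1
      target <- switch(conv, state, "comp_1", {
        if (n_activities == 0)
          abort("convention-3 influences need at least one activity")
        paste0("qa_", sample(n_activities, 1))
      })
      polarity <- sample(c("facilitation", "hindrance"), 1)
      model <- add_influence(
        model, target, fac_ids[k], polarity = polarity,
        level = sample(c(0:4, 8L), 1),
        manner = if (runif(1) < 0.5) sample(influencing_manners(), 1),
        id = paste0("influence_", k))
    }
  }
  inject_faults(model, faults)
}

# Each mutation breaches exactly its own rule, exactly once; mutations write
# the tibbles directly because the constructor verbs refuse to build the
# breach.
inject_faults <- function(model, faults) {
  for (f in faults) {
    model <- switch(f,
      disjoint_factor_kind = {
        model$factors <- add_row(model$factors, id = "fault_factor",
                                 kind = "environmental", code = "e1151",
                                 label = "fault")
        model$factors <- add_row(model$factors, id = "fault_factor",
                                 kind = "personal", code = NA_character_,
                                 label = "fault")
        model
      },
      disjoint_component_code = {
        model$activities <- add_row(model$activities, id = "fault_activity",
                                    state = model$states$id[1], code = "e155",
                                    activity = "fault_act",
                                    performance = NA_integer_,
                                    capacity = NA_integer_,
                                    destination = NA_character_)
        model
      },
      card_activity_state = {
        model$activities <- add_row(model$activities, id = "fault_orphan_qa",
                                    state = "no_such_state", code = "d410",
                                    activity = "fault_act2",
                                    performance = NA_integer_,
                                    capacity = NA_integer_,
                                    destination = NA_character_)
        model
      },
      card_destination = {
        model$activities <- add_row(model$activities, id = "fault_dest_qa",
                                    state = model$states$id[1], code = "d410",
                                    activity = "fault_act3",
                                    performance = NA_integer_,
                                    capacity = NA_integer_,
                                    destination = "no_such_situation")
        model
      },
      card_influence_factor = {
        model$influences <- add_row(model$influences, id = "fault_inf_factor",
                                    factor = "no_such_factor",
                                    target = model$states$id[1],
                                    facilitation_level = 1L,
                                    barrier_level = NA_integer_,
                                    manner = NA_character_)
        model
      },
      card_influence_polarity = {
        model <- add_factor(model, id = "fault_pol_factor",
                            kind = "environmental", code = "e580")
        model$influences <- add_row(model$influences, id = "fault_inf_polarity",
                                    factor = "fault_pol_factor",
                                    target = model$states$id[1],
                                    facilitation_level = 2L, barrier_level = 2L,
                                    manner = NA_character_)
        model
      },
      card_influence_target = {
        model <- add_factor(model, id = "fault_tgt_factor",
                            kind = "environmental", code = "e110")
        model$influences <- add_row(model$influences, id = "fault_inf_target",
                                    factor = "fault_tgt_factor",
                                    target = "no_such_target",
                                    facilitation_level = 1L,
                                    barrier_level = NA_integer_,
                                    manner = NA_character_)
        model
      },
      domain_state_subject = {
        model$states <- add_row(model$states, id = "fault_state",
                                subject = "no_such_human", label = "fault")
        model
      },
      range_qualifier_digit = {
        model$activities <- add_row(model$activities, id = "fault_digit_qa",
                                    state = model$states$id[1], code = "d410",
                                    activity = "fault_act4", performance = 9L,
                                    capacity = NA_integer_,
                                    destination = NA_character_)
        model
      },
      domain_manner = {
        model <- add_factor(model, id = "fault_man_factor",
                            kind = "environmental", code = "e115")
        model$influences <- add_row(model$influences, id = "fault_inf_manner",
                                    factor = "fault_man_factor",
                                    target = model$states$id[1],
                                    facilitation_level = 1L,
                                    barrier_level = NA_integer_,
                                    manner = "telepathy")
        model
      },
      unregistered_code = {
        model$activities <- add_row(model$activities, id = "fault_unreg_qa",
                                    state = model$states$id[1], code = "d499",
                                    activity = "fault_act5",
                                    performance = NA_integer_,
                                    capacity = NA_integer_,
                                    destination = NA_character_)
        model
      })
  }
  model
}
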