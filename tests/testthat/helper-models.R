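# shared builders and independent brute-force oracles

tiny_model <- function() {
  icf_model() |>
    add_human("anna", "Anna") |>
    add_health_state("anna", "2022_jan_1") |>
    add_qualified_activity("anna_state_1", "d410", performance = 1,
                           capacity = 2) |>
    add_qualified_activity("anna_state_1", "d440") |>
    add_factor(id = "ramp_1", kind = "environmental", code = "e155") |>
    add_factor(id = "grit_1", kind = "personal", label = "determination") |>
    add_component_handle("anna_state_1", "ActivityAndParticipation") |>
    add_influence("anna_state_1", "ramp_1", "hindrance", 2) |>
    add_influence("anna_state_1_ActivityAndParticipation_component",
                  "grit_1", "facilitation", 1)
}

# exhaustive row-by-row oracles, independent of the vectorized implementation
oracle_participation <- function(model) {
  out <- logical(nrow(model$activities))
  for (i in seq_len(nrow(model$activities))) {
    d <- model$activities$destination[i]
    out[i] <- !is.na(d) && any(model$situations$id == d)
  }
  setNames(out, model$activities$id)
}

oracle_classify <- function(model) {
  out <- character(nrow(model$influences))
  for (i in seq_len(nrow(model$influences))) {
    out[i] <- if (!is.na(model$influences$facilitation_level[i]))
      "Facilitator" else "Barrier"
  }
  setNames(out, model$influences$id)
}

oracle_influencing_factors <- function(model) {
  hits <- character(0)
  for (f in model$factors$id) {
    for (j in seq_len(nrow(model$influences))) {
      if (model$influences$factor[j] == f) { hits <- c(hits, f); break }
    }
  }
  hits
}

oracle_convention <- function(model) {
  out <- integer(nrow(model$influences))
  for (i in seq_len(nrow(model$influences))) {
    t <- model$influences$target[i]
    out[i] <- if (any(model$states$id == t)) 1L
      else if (any(model$components$id == t)) 2L
      else 3L
  }
  setNames(out, model$influences$id)
}
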