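test_that("health states aggregate qualified activities for one subject", {
  m <- icf_model() |>
    add_human("peter", "Peter") |>
    add_health_state("peter", "2021_mar_17") |>
    add_health_state("peter", "2021_nov_02")
  expect_equal(m$states$id, c("peter_state_1", "peter_state_2"))

  m <- add_qualified_activity(m, "peter_state_1", "d410", performance = "mild")
  expect_equal(m$activities$performance, 1L)
  expect_true(is.na(m$activities$capacity))

  expect_error(add_health_state(m, "nobody", "x"), "unknown subject")
  expect_error(add_qualified_activity(m, "peter_state_1", "e155"),
               "not an Activities & Participation")
  expect_error(
    add_qualified_activity(m, "peter_state_1", "d410",
                           performance = icf_value("Hindrance", 2)),
    "Difficulty")
})

test_that("performance and capacity are independent sub-relations", {
  m <- icf_model() |>
    add_human("h") |>
    add_health_state("h", "t") |>
    add_qualified_activity("h_state_1", "d410", performance = 1)
  before <- m$activities$performance
  m$activities$capacity[1] <- 3L
  expect_equal(m$activities$performance, before)
  tr <- to_triples(m)
  expect_true(all(c("performance", "capacity") %in% tr$predicate))
  expect_equal(tr$object[tr$predicate == "capacity"], "SEVERE_difficulty")
})

test_that("destination is optional, single, and drives participation", {
  m <- tiny_model()
  expect_equal(unname(is_participation(m)), c(FALSE, FALSE))

  m <- set_destination(m, "anna_state_1_d440_1", "team sport event")
  expect_true(is_participation(m, "anna_state_1_d440_1"))
  expect_false(is_participation(m, "anna_state_1_d410_1"))
  expect_equal(participations(m)$situation, "team sport event")

  expect_error(set_destination(m, "anna_state_1_d440_1", "choir"),
               "already has a destination")
  m <- set_destination(m, "anna_state_1_d440_1", "choir", replace = TRUE)
  expect_equal(participations(m)$situation, "choir")
})

test_that("participation inference equals the exhaustive oracle", {
  for (seed in 1:12) {
    m <- generate_synthetic(n_activities = 25, n_influences = c(0, 0, 0),
                            participation_rate = seed / 15, seed = seed)
    expect_identical(is_participation(m), oracle_participation(m))
  }
})

test_that("agents are reached indirectly through the health state", {
  fx <- icf_fixtures()
  expect_equal(unname(agent_of(fx$peter, "Peter_state_1_changing_position_1")),
               "Peter")
  expect_equal(unname(agent_of(fx$john, "John_state_2_lifting_1")), "John")

  m <- tiny_model()
  m$activities$state[1] <- "gone_state"
  expect_error(agent_of(m, m$activities$id[1]), "detached")
})

test_that("aggregation integrity: parts back-reference their state bijectively", {
  fx <- icf_fixtures()
  for (m in fx) {
    for (s in m$states$id) {
      parts <- m$activities$id[m$activities$state == s]
      expect_false(anyDuplicated(parts) > 0)
      expect_setequal(m$activities$state[match(parts, m$activities$id)], s)
    }
  }
})
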