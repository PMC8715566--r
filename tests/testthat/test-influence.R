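test_that("factor kinds are disjoint and carry codes appropriately", {
  m <- icf_model() |> add_human("h") |> add_health_state("h", "t")
  expect_error(add_factor(m, kind = "environmental"), "need an e-code")
  expect_error(add_factor(m, kind = "environmental", code = "d410"),
               "not an Environmental Factors code")
  expect_error(add_factor(m, kind = "personal", code = "e155", label = "x"),
               "carry no code")
  m <- add_factor(m, kind = "environmental", code = "e580")
  expect_equal(m$factors$label, "Health services, systems and policies")
})

test_that("influence polarity and level scale must agree", {
  m <- tiny_model()
  expect_error(
    add_influence(m, "anna_state_1", "ramp_1", "facilitation",
                  level = icf_value("Hindrance", 3)),
    "does not match")
  expect_error(
    add_influence(m, "anna_state_1", "ramp_1", "hindrance", level = "substantial"),
    "no value")
  expect_error(add_influence(m, "anna_state_1", "nobody", "hindrance", 1),
               "unknown factor")
  expect_error(add_influence(m, "nowhere", "ramp_1", "hindrance", 1),
               "unknown influence target")
  expect_error(add_influence(m, "anna_state_1", "ramp_1", "hindrance", 1,
                             manner = "telepathy"), "unknown influencing manner")
})

test_that("every influence has exactly one polarity level (XOR)", {
  for (seed in 1:10) {
    m <- generate_synthetic(n_activities = 8, n_influences = c(3, 2, 3),
                            seed = seed)
    one <- xor(!is.na(m$influences$facilitation_level),
               !is.na(m$influences$barrier_level))
    expect_true(all(one))
    # polarity relation in the triple set agrees with the level column
    tr <- to_triples(m)
    pol <- tr[tr$predicate %in% c("facilitatedBy", "hindrancedBy"), ]
    for (i in seq_len(nrow(m$influences))) {
      f <- m$influences[i, ]
      expect_equal(pol$predicate[pol$object == f$id],
                   if (is.na(f$barrier_level)) "facilitatedBy" else "hindrancedBy")
    }
  }
})

test_that("conventions dispatch on the target type and partition influences", {
  fx <- icf_fixtures()
  expect_equal(unname(convention_of(fx$conrad)), c(1L, 1L, 1L))
  expect_equal(unname(convention_of(fx$john)), 3L)

  m <- tiny_model()
  expect_equal(unname(convention_of(m)), c(1L, 2L))

  for (seed in 1:10) {
    s <- generate_synthetic(n_activities = 6, n_influences = c(2, 2, 2),
                            seed = seed)
    conv <- convention_of(s)
    expect_identical(conv, oracle_convention(s))
    expect_equal(sum(conv == 1) + sum(conv == 2) + sum(conv == 3), length(conv))
    expect_setequal(unique(conv), 1:3)
  }
})

test_that("facilitator/barrier classification matches the brute-force oracle", {
  for (seed in 1:20) {
    m <- generate_synthetic(n_activities = 10, n_influences = c(3, 1, 2),
                            participation_rate = 0.3, seed = seed)
    cls <- classify_influence(m)
    expect_identical(cls, oracle_classify(m))
    expect_true(all(cls %in% c("Facilitator", "Barrier")))  # total, disjoint
    expect_identical(influencing_factors(m), oracle_influencing_factors(m))
  }
})

test_that("personal factors can influence without carrying a code", {
  m <- tiny_model()
  cls <- classify_influence(m)
  expect_equal(unname(cls[m$influences$factor == "grit_1"]), "Facilitator")
  expect_true("grit_1" %in% influencing_factors(m))
  expect_true(is.na(m$factors$code[m$factors$id == "grit_1"]))
})

test_that("influencing factors form the defined class, not the factor list", {
  m <- tiny_model() |>
    add_factor(id = "unused_1", kind = "environmental", code = "e115")
  expect_false("unused_1" %in% influencing_factors(m))
  empty <- icf_model() |> add_human("h")
  expect_length(influencing_factors(empty), 0)
})
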