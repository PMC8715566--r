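peter_rows <- function() {
  data.frame(code = c("d410", "d4200", "d440", "d445"),
             qualifier = c(".1", ".2", ".4", ".3"))
}

conrad_rows <- function() {
  data.frame(code = c("d4153", "d4154", "d465", "d850", "e1151", "e155", "e580"),
             qualifier = c(".0", ".2", ".3", ".4", "+3", ".3", "+2"),
             section = c(rep("problem", 4), "facilitator", "barrier",
                         "facilitator"))
}

test_that("profile reading preserves order and resolves qualifiers", {
  rows <- read_profile(conrad_rows())
  expect_equal(nrow(rows), 7)
  expect_equal(rows$code, conrad_rows()$code)
  expect_equal(rows$kind,
               c(rep("difficulty", 4), "facilitation", "hindrance",
                 "facilitation"))
  expect_equal(rows$digit, c(0L, 2L, 3L, 4L, 3L, 3L, 2L))

  expect_error(read_profile(data.frame(code = "q123", qualifier = ".1")),
               "row 1")
  expect_error(read_profile(data.frame(code = "d410", qualifier = "+1")),
               "row 1")
  expect_equal(nrow(read_profile(data.frame(code = character(),
                                            qualifier = character()))), 0)
})

test_that("profile CSV files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(conrad_rows(), path)
  expect_equal(read_profile(path)$digit, read_profile(conrad_rows())$digit)
})

test_that("encoding a profile builds one validated state per subject", {
  m <- encode_profile(peter_rows(), "Peter", "2021_mar_17")
  expect_true(icf_validate(m)$passed)
  expect_equal(nrow(m$states), 1)
  expect_equal(nrow(m$activities), 4)
  expect_equal(m$activities$performance[m$activities$code == "d440"], 4L)
  expect_true(all(is.na(m$activities$capacity)))

  expect_error(encode_profile(peter_rows(), "P", "t", ef_convention = 7),
               "unknown coding convention")
  empty <- encode_profile(data.frame(code = character(),
                                     qualifier = character()), "S", "t")
  expect_true(icf_validate(empty)$passed)
  expect_equal(nrow(empty$activities), 0)
})

test_that("the three conventions attach environmental factors differently", {
  for (conv in 1:3) {
    m <- encode_profile(conrad_rows(), "Conrad", "t", ef_convention = conv)
    expect_true(icf_validate(m)$passed)
    expect_equal(nrow(m$influences), 3)
    expect_equal(unname(convention_of(m)), rep(conv, 3))
  }
  # convention 3 with no preceding activity has nothing to attach to
  e_only <- data.frame(code = "e155", qualifier = ".2")
  expect_error(encode_profile(e_only, "S", "t", ef_convention = 3),
               "preceding d-row")
})

test_that("fixtures reproduce the printed individual names and validate", {
  fx <- icf_fixtures()
  expect_named(fx, c("e_case", "peter", "conrad", "john"))
  for (m in fx) expect_true(icf_validate(m)$passed)

  expect_true("E_state_1_reacting_1" %in% fx$e_case$activities$id)
  expect_true(is.na(fx$e_case$activities$performance))  # no qualifier recorded
  expect_true("Peter_state_1_changing_position_1" %in% fx$peter$activities$id)
  expect_true("John_state_2_lifting_1_ibuprofen_1" %in% fx$john$influences$id)
  expect_equal(fx$john$factors$label, "Ibuprofen")

  # querying back each coded pair reproduces the printed digits
  expect_equal(
    fx$peter$activities$performance[match(c("d410", "d4200", "d440", "d445"),
                                          fx$peter$activities$code)],
    c(1L, 2L, 4L, 3L))
  expect_equal(
    fx$conrad$activities$performance[match(c("d4153", "d4154", "d465", "d850"),
                                           fx$conrad$activities$code)],
    c(0L, 2L, 3L, 4L))
  expect_equal(fx$john$influences$facilitation_level, 8L)  # "some"
})

test_that("synthetic generation is seeded and reproducible", {
  a <- generate_synthetic(10, c(2, 1, 1), participation_rate = 0.5, seed = 7)
  b <- generate_synthetic(10, c(2, 1, 1), participation_rate = 0.5, seed = 7)
  expect_identical(to_triples(a), to_triples(b))
  c2 <- generate_synthetic(10, c(2, 1, 1), participation_rate = 0.5, seed = 8)
  expect_false(identical(to_triples(a), to_triples(c2)))

  none <- generate_synthetic(10, c(0, 0, 0), participation_rate = 0, seed = 7)
  expect_equal(sum(is_participation(none)), 0)
  expect_equal(nrow(none$influences), 0)

  all_part <- generate_synthetic(8, c(0, 0, 0), participation_rate = 1, seed = 7)
  expect_equal(sum(is_participation(all_part)), 8)

  # generation does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(generate_synthetic(5, c(1, 0, 0), seed = 99))
  expect_identical(runif(1), x1)
})

test_that("re-encoding identical input yields isomorphic models", {
  m1 <- encode_profile(conrad_rows(), "Conrad", "t")
  m2 <- encode_profile(conrad_rows(), "Conrad", "t")
  expect_identical(to_triples(m1), to_triples(m2))
})
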