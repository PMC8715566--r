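test_that("the three scales carry the expected enumerations", {
  expect_equal(icf_scale("Hindrance")$label,
               c("no", "mild", "moderate", "severe", "complete", "some"))
  expect_equal(icf_scale("Facilitation")$label,
               c("no", "mild", "moderate", "substantial", "complete", "some"))
  expect_equal(icf_scale("Difficulty")$digit, c(0L, 1L, 2L, 3L, 4L, 8L))
  expect_error(icf_scale("Impairment"), "unknown qualifier scale")
})

test_that("scales behave as closed enumerated classes", {
  # identity, not equal copies
  expect_identical(icf_scale("Difficulty"), icf_scale("Difficulty"))
  for (nm in names(icf_scales())) {
    tb <- icf_scale(nm)
    expect_false(anyDuplicated(tb$digit) > 0)
    expect_false(anyDuplicated(tb$label) > 0)
    # digit <-> label bijection through icf_value
    for (i in seq_len(nrow(tb))) {
      expect_equal(icf_value(nm, tb$digit[i])$label, tb$label[i])
      expect_equal(icf_value(nm, tb$label[i])$digit, tb$digit[i])
    }
    # percent bands partition 0-100 for digits 0-4
    bands <- tb[tb$digit <= 4, ]
    expect_equal(bands$lo[1], 0)
    expect_equal(bands$hi[5], 100)
    expect_equal(bands$lo[-1], bands$hi[-5] + 1)
  }
})

test_that("value lookup resolves digits and labels and rejects strangers", {
  expect_equal(icf_value("Facilitation", 3)$label, "substantial")
  expect_equal(icf_value("Difficulty", "no problem")$digit, 0L)
  expect_equal(icf_value("Facilitation", 3)$individual, "SUBSTANTIAL_facilitation")
  expect_error(icf_value("Hindrance", 7), "no value 7")
  expect_error(icf_value("Difficulty", "huge"), "no value")
})

test_that("suffix parsing dispatches on the code's component", {
  expect_equal(parse_qualifier_suffix("+3", "e1151")$kind, "facilitation")
  expect_equal(parse_qualifier_suffix("+3", "e1151")$label, "substantial")
  d <- parse_qualifier_suffix(".2", "d4200")
  expect_equal(d$kind, "difficulty")
  expect_equal(d$label, "moderate")
  expect_equal(parse_qualifier_suffix(".3", "e155")$kind, "hindrance")
  expect_error(parse_qualifier_suffix(".9", "d410"), "outside")
  expect_error(parse_qualifier_suffix("+2", "d410"), "only legal on e-codes")
  expect_error(parse_qualifier_suffix("x2", "d410"), "malformed")
})

test_that("seven ICF qualifier names are on record", {
  expect_length(icf_qualifier_names(), 7)
  expect_true(all(c("performance", "capacity", "barrier", "facilitator")
                  %in% icf_qualifier_names()))
})

test_that("YAML overrides relabel but cannot break the scale", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Difficulty:",
               "  - digit: 1",
               "    label: lieve"), path)
  sc <- icf_scales(overrides = path)
  expect_equal(icf_value("Difficulty", 1, sc)$label, "lieve")
  expect_equal(icf_value("Difficulty", 1, sc)$individual, "LIEVE_difficulty")
  # base scales untouched
  expect_equal(icf_value("Difficulty", 1)$label, "mild")

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Difficulty:",
               "  - digit: 1",
               "    lo: 10"), bad)
  expect_error(icf_scales(overrides = bad), "partition")

  worse <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Difficulty:",
               "  - digit: 7",
               "    label: x"), worse)
  expect_error(icf_scales(overrides = worse), "outside")
})
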