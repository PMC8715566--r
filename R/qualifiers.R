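#' @title Qualifier scales
#' @description The ICF measures functioning with *qualifiers*: closed,
#' ordered value sets. Three scales are modeled here, matching the
#' Activities & Participation and Environmental Factors scope:
#'
#' * **Difficulty** -- extent of a problem in executing an activity
#'   (performance and capacity both draw from it);
#' * **Hindrance** -- extent of a negative environmental influence (barrier);
#' * **Facilitation** -- extent of a positive environmental influence.
#'
#' Each value carries a digit, a label and (for digits 0--4) a percent band
#' of the generic ICF scale. Digit 8 is the "some / not specified" value used
#' when a magnitude is stated vaguely. Values are *individuals* of an
#' enumerated class, not bare literals, so they can be the subject of further
#' statements; the `individual` column holds their stable names
#' (`MILD_difficulty`, `SOME_facilitation`, ...). Scales are closed: the
#' objects returned are built once at load time and [icf_scale()] always
#' hands back the identical object.
#' @name qualifier-scales
NULL

scale_tbl <- function(name, labels, sumo) {
  stopifnot(length(labels) == 6)
  out <- tibble(
    scale = name,
    digit = c(0L, 1L, 2L, 3L, 4L, 8L),
    label = labels,
    lo = c(0, 5, 25, 50, 96, NA),
    hi = c(4, 24, 49, 95, 100, NA),
    individual = paste0(toupper(gsub(" ", "_", labels)), "_", tolower(name))
  )
  attr(out, "sumo") <- sumo
  class(out) <- c("icf_scale", class(out))
  out
}

build_scales <- function() {
  list(
    Difficulty = scale_tbl("Difficulty",
      c("no problem", "mild", "moderate", "severe", "complete", "some"),
      "SubjectiveAssessmentAttribute"),
    Hindrance = scale_tbl("Hindrance",
      c("no", "mild", "moderate", "severe", "complete", "some"), NA_character_),
    Facilitation = scale_tbl("Facilitation",
      c("no", "mild", "moderate", "substantial", "complete", "some"),
      NA_character_)
  )
}

the_scales <- new.env(parent = emptyenv())

#' The three qualifier scales
#'
#' @param overrides Optional path to a YAML file overriding labels and/or
#'   percent bands, keyed by scale name; each entry is a list of
#'   `{digit, label, lo, hi}` records. Digits must stay within
#'   `{0,1,2,3,4,8}` and the 0--4 bands must partition 0--100 without
#'   overlap (localization support, not a way to widen a scale).
#' @return Named list of three `icf_scale` tibbles
#'   (`Difficulty`, `Hindrance`, `Facilitation`).
#' @export
icf_scales <- function(overrides = NULL) {
  if (is.null(the_scales$base)) the_scales$base <- build_scales()
  if (is.null(overrides)) return(the_scales$base)
  ov <- yaml::read_yaml(overrides)
  scales <- the_scales$base
  for (nm in names(ov)) {
    if (!nm %in% names(scales)) abort(paste0("unknown scale in override: ", nm))
    tb <- scales[[nm]]
    for (rec in ov[[nm]]) {
      i <- match(rec$digit, tb$digit)
      if (is.na(i)) abort(paste0("digit ", rec$digit, " outside the ", nm, " scale"))
      if (!is.null(rec$label)) tb$label[i] <- rec$label
      if (!is.null(rec$lo)) tb$lo[i] <- rec$lo
      if (!is.null(rec$hi)) tb$hi[i] <- rec$hi
    }
    if (anyDuplicated(tb$label)) abort(paste0("duplicate labels in scale ", nm))
    tb$individual <- paste0(toupper(gsub(" ", "_", tb$label)), "_", tolower(nm))
    bands <- tb[tb$digit <= 4, ]
    bands <- bands[order(bands$lo), ]
    if (bands$lo[1] != 0 || bands$hi[5] != 100 ||
        any(bands$lo[-1] != bands$hi[-5] + 1))
      abort(paste0("percent bands of ", nm, " must partition 0-100"))
    scales[[nm]] <- tb
  }
  scales
}

#' Look up one qualifier scale
#'
#' @param name `"Difficulty"`, `"Hindrance"` or `"Facilitation"`.
#' @param scales A scale set from [icf_scales()].
#' @return The `icf_scale` tibble. Repeated calls return the identical
#'   object (enumerated-class closure).
#' @examples
#' icf_scale("Facilitation")
#' @export
icf_scale <- function(name, scales = icf_scales()) {
  if (!name %in% names(scales))
    abort(paste0("unknown qualifier scale: ", name,
                 " (have: ", paste(names(scales), collapse = ", "), ")"))
  scales[[name]]
}

#' Look up one qualifier value by digit or label
#'
#' @param scale Scale name.
#' @param key Digit (`0,1,2,3,4,8`) or label (e.g. `"substantial"`).
#' @param scales A scale set from [icf_scales()].
#' @return One-row tibble (`scale`, `digit`, `label`, `lo`, `hi`,
#'   `individual`).
#' @examples
#' icf_value("Facilitation", 3)
#' icf_value("Difficulty", "no problem")
#' @export
icf_value <- function(scale, key, scales = icf_scales()) {
  tb <- icf_scale(scale, scales)
  i <- if (is.numeric(key)) match(as.integer(key), tb$digit) else match(key, tb$label)
  if (is.na(i))
    abort(paste0("no value ", deparse(key), " in the ", scale, " scale"))
  tb[i, ]
}

#' The seven ICF qualifier names
#'
#' The classification's own list of qualifiers (only performance, capacity,
#' barrier and facilitator fall inside this package's modeling scope; the
#' rest belong to Body Functions / Body Structures).
#'
#' @return Character vector of length 7.
#' @export
icf_qualifier_names <- function() {
  c("impairment", "nature of change", "localization",
    "performance", "capacity", "barrier", "facilitator")
}

#' Parse a qualifier suffix against a code's component
#'
#' Standard ICF annotation separates the qualifier from the code with `.`
#' or, for facilitators, `+`. The same `.` digit means *difficulty* on a
#' d-code but *hindrance* (barrier) on an e-code; `+` is only legal on
#' e-codes.
#'
#' @param suffix Suffix text such as `".2"` or `"+3"`.
#' @param code The code the suffix annotates (decides the scale).
#' @param scales A scale set from [icf_scales()].
#' @return One-row tibble: `kind` (`"difficulty"`, `"hindrance"`,
#'   `"facilitation"`), plus the resolved value columns.
#' @examples
#' parse_qualifier_suffix("+3", "e1151")
#' parse_qualifier_suffix(".2", "d4200")
#' @export
parse_qualifier_suffix <- function(suffix, code, scales = icf_scales()) {
  comp <- icf_parse_code(code)$component
  m <- str_match(str_trim(suffix), "^([.+])([0-9])$")
  if (is.na(m[1, 1]))
    abort(paste0("malformed qualifier suffix: ", deparse(suffix)))
  op <- m[1, 2]
  digit <- as.integer(m[1, 3])
  kind <- if (op == "+") {
    if (comp != "e") abort("'+' (facilitation) is only legal on e-codes")
    "facilitation"
  } else if (comp == "e") "hindrance" else if (comp == "d") "difficulty" else {
    abort("qualifier suffixes are modeled for d- and e-codes only")
  }
  scale <- c(difficulty = "Difficulty", hindrance = "Hindrance",
             facilitation = "Facilitation")[[kind]]
  tb <- icf_scale(scale, scales)
  if (!digit %in% tb$digit)
    abort(paste0("digit ", digit, " outside the ", scale, " scale"))
  bind_cols(tibble(kind = kind), icf_value(scale, digit, scales))
}
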