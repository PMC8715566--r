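#' Parse ICF category codes
#'
#' An ICF code is a component letter followed by a digit string: `b` Body
#' Functions, `s` Body Structures, `d` Activities & Participation, `e`
#' Environmental Factors. The digit count fixes the hierarchical level:
#' 1 digit is a chapter, 3 digits a second-level category, 4 digits third
#' level, 5 digits fourth level. Block range notation such as `"d330-d349"`
#' is *not* a code and is rejected here; it is accepted only in registry
#' files (see [icf_load_registry()]).
#'
#' @param x Character vector of code strings, e.g. `c("d410", "e1151")`.
#' @return A tibble with one row per input: `code`, `component` (letter),
#'   `digits`, `level` (`"chapter"`, `"second"`, `"third"`, `"fourth"`).
#' @examples
#' icf_parse_code(c("d410", "e1151", "d4"))
#' @export
icf_parse_code <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(tibble(code = character(), component = character(),
                                    digits = character(), level = character()))
  bad_empty <- is.na(x) | !nzchar(x)
  if (any(bad_empty)) abort("empty ICF code")
  if (any(grepl("-", x, fixed = TRUE)))
    abort(paste0("block range notation is not a code: ",
                 paste(x[grepl("-", x, fixed = TRUE)], collapse = ", ")))
  comp <- substr(x, 1, 1)
  digits <- substring(x, 2)
  bad_comp <- !comp %in% c("b", "s", "d", "e")
  if (any(bad_comp))
    abort(paste0("unknown ICF component letter in: ",
                 paste(unique(x[bad_comp]), collapse = ", ")))
  bad_dig <- !grepl("^[0-9]+$", digits)
  if (any(bad_dig))
    abort(paste0("non-numeric digits in ICF code: ",
                 paste(unique(x[bad_dig]), collapse = ", ")))
  lv <- c(`1` = "chapter", `3` = "second", `4` = "third", `5` = "fourth")
  nd <- as.character(nchar(digits))
  bad_len <- !nd %in% names(lv)
  if (any(bad_len))
    abort(paste0("wrong digit count (expect 1, 3, 4 or 5) in: ",
                 paste(unique(x[bad_len]), collapse = ", ")))
  tibble(code = x, component = comp, digits = digits, level = unname(lv[nd]))
}

#' Is a string a syntactically valid ICF code?
#'
#' @param x Character vector.
#' @return Logical vector, `TRUE` where [icf_parse_code()] would accept.
#' @export
icf_is_code <- function(x) {
  grepl("^[bsde]([0-9]|[0-9]{3,5})$", x) & !grepl("^[bsde][0-9]{2}$", x) &
    nchar(x) <= 6
}

#' Parent of an ICF code
#'
#' Chapters have no parent (`NA`). A second-level code's parent is its
#' chapter (letter plus first digit); deeper codes drop their last digit.
#'
#' @param x Character vector of valid codes.
#' @return Character vector of parent codes, `NA` for chapters.
#' @examples
#' icf_parent_code(c("d4153", "d410", "d4"))
#' @export
icf_parent_code <- function(x) {
  p <- icf_parse_code(x)
  ifelse(p$level == "chapter", NA_character_,
         ifelse(p$level == "second", paste0(p$component, substr(p$digits, 1, 1)),
                substr(x, 1, nchar(x) - 1L)))
}

icf_component_class <- function(letter) {
  c(b = "BodyFunction", s = "BodyStructure",
    d = "ActivityAndParticipation", e = "EnvironmentalFactor")[letter]
}

block_bounds <- function(code) {
  m <- str_match(code, "^([bsde])([0-9]{3,5})-([bsde])?([0-9]{3,5})$")
  if (is.na(m[1, 1])) return(NULL)
  list(component = m[1, 2], lo = m[1, 3], hi = m[1, 5] %||% m[1, 4])
}

#' Load a category registry
#'
#' Builds the classification scheme used by a model: chapters, blocks and
#' categories of the four ICF components, each with a parent reference.
#' Blocks are labeled code *ranges* (`"d330-d349"`), structural units that
#' group categories inside a chapter; they are never parsed as codes. The
#' registry is deliberately partial -- any subset of the WHO catalogue can be
#' loaded and unknown codes remain parseable (they are flagged as
#' unregistered by [icf_validate()], not rejected).
#'
#' Invariants enforced here: codes are unique; every non-chapter row names a
#' parent that exists; a category's code extends its parent's code by one
#' digit (for a block parent, the code must fall inside the block's range);
#' a block's range stays inside its chapter.
#'
#' @param x A data frame with columns `code`, `title`, `kind`
#'   (`chapter`/`block`/`category`), `parent`, or a path to a TSV file with
#'   those columns (UTF-8, `#` comment lines allowed).
#' @return A tibble of class `icf_registry` with added `component` and
#'   `level` columns.
#' @seealso [icf_registry()] for the bundled seed registry.
#' @export
icf_load_registry <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_tsv(x, comment = "#", col_types = "cccc",
                         na = c("", "NA"))
  }
  stopifnot(is.data.frame(x))
  need <- c("code", "title", "kind", "parent")
  if (!all(need %in% names(x)))
    abort(paste0("registry needs columns: ", paste(need, collapse = ", ")))
  reg <- as_tibble(x)[need]
  if (anyDuplicated(reg$code))
    abort(paste0("duplicate registry code: ",
                 paste(unique(reg$code[duplicated(reg$code)]), collapse = ", ")))
  bad_kind <- !reg$kind %in% c("chapter", "block", "category")
  if (any(bad_kind))
    abort(paste0("unknown registry kind: ", paste(unique(reg$kind[bad_kind]), collapse = ", ")))

  is_block <- reg$kind == "block"
  parsed <- icf_parse_code(reg$code[!is_block])
  comp <- lev <- rep(NA_character_, nrow(reg))
  comp[!is_block] <- parsed$component
  lev[!is_block] <- parsed$level
  if (any(is_block)) {
    bb <- lapply(reg$code[is_block], block_bounds)
    if (any(vapply(bb, is.null, logical(1))))
      abort("block rows must use range notation like d330-d349")
    comp[is_block] <- vapply(bb, `[[`, character(1), "component")
    lev[is_block] <- "block"
  }
  chapter_ok <- lev == "chapter"
  if (any(chapter_ok & !is.na(reg$parent)))
    abort("chapters are roots and take no parent")
  needs_parent <- !chapter_ok
  if (any(needs_parent & is.na(reg$parent)))
    abort(paste0("missing parent for: ",
                 paste(reg$code[needs_parent & is.na(reg$parent)], collapse = ", ")))
  orphan <- needs_parent & !is.na(reg$parent) & !reg$parent %in% reg$code
  if (any(orphan))
    abort(paste0("orphan parent reference: ",
                 paste(unique(reg$parent[orphan]), collapse = ", ")))

  # prefix / containment discipline
  for (i in which(needs_parent)) {
    par <- reg$parent[i]
    pk <- reg$kind[match(par, reg$code)]
    if (is_block[i]) {
      bb <- block_bounds(reg$code[i])
      if (substr(bb$lo, 1, 1) != substring(par, 2) || pk != "chapter")
        abort(paste0("block ", reg$code[i], " outside its chapter ", par))
    } else if (pk == "block") {
      bb <- block_bounds(par)
      d3 <- substr(paste0(substring(reg$code[i], 2), "00"), 1, 3)
      if (comp[i] != bb$component || d3 < bb$lo || d3 > bb$hi)
        abort(paste0("code ", reg$code[i], " outside block range ", par))
    } else {
      expected <- icf_parent_code(reg$code[i])
      if (!identical(expected, par))
        abort(paste0("code ", reg$code[i], " is not a prefix-extension of parent ", par))
    }
  }
  out <- reg
  out$component <- unname(comp)
  out$level <- unname(lev)
  class(out) <- c("icf_registry", class(out))
  out
}

#' Bundled seed registry
#'
#' The registry shipped with the package: the nine Activities & Participation
#' chapters, the five Environmental Factors chapters, two example blocks and
#' the categories used by the worked case studies. It is intentionally a
#' small subset of the WHO catalogue.
#'
#' @param path Optional path to an alternative registry TSV.
#' @return An `icf_registry` tibble.
#' @examples
#' reg <- icf_registry()
#' dplyr::filter(reg, kind == "chapter", component == "d")
#' @export
icf_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "icf_registry.tsv", package = "icfkit")
  icf_load_registry(path)
}

#' Chapters of a component
#'
#' @param registry An `icf_registry`.
#' @param component Component letter (default `"d"`).
#' @return Tibble of chapter rows.
#' @export
icf_chapters <- function(registry, component = "d") {
  filter(registry, .data$kind == "chapter", .data$component == !!component)
}

registry_has <- function(registry, code) code %in% registry$code

registry_title <- function(registry, code) {
  registry$title[match(code, registry$code)]
}

#' @export
print.icf_registry <- function(x, ...) {
  cat("<icf_registry> ", nrow(x), " nodes (",
      sum(x$kind == "chapter"), " chapters, ",
      sum(x$kind == "block"), " blocks, ",
      sum(x$kind == "category"), " categories)\n", sep = "")
  NextMethod()
}
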