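#' Define a choice-experiment attribute
#'
#' An attribute is one dimension of a hypothetical alternative (e.g. condom
#' use) with a small number of discrete levels. Categorical attributes are
#' effects coded for analysis: an L-level attribute contributes L-1 contrast
#' columns, the last-listed level acts as the reference and is coded -1 on
#' every contrast, so the implied level utilities sum to zero within the
#' attribute. Attributes with `coding = "continuous"` instead contribute a
#' single column holding the numeric value of the assigned level (used for
#' money in GMD).
#'
#' @param name attribute name (syntactic, unique within a design).
#' @param levels character vector of at least two unique level labels.
#' @param coding `"effects"` or `"continuous"`.
#' @param numeric_values per-level numeric values; required when
#'   `coding = "continuous"`, optional otherwise (kept so an effects-coded
#'   money attribute can later be recoded continuously).
#' @param units free-text units (e.g. `"GMD"`).
#' @return An object of class `attribute_spec`.
#' @export
attribute_spec <- function(name, levels, coding = c("effects", "continuous"),
                           numeric_values = NULL, units = "") {
  coding <- match.arg(coding)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L)
    stop_dce("attribute '%s' needs at least 2 levels", name)
  if (anyDuplicated(levels))
    stop_dce("attribute '%s' has duplicated level labels", name)
  if (coding == "continuous" && is.null(numeric_values))
    stop_dce("attribute '%s': continuous coding requires numeric_values", name)
  if (!is.null(numeric_values)) {
    numeric_values <- as.numeric(numeric_values)
    if (length(numeric_values) != length(levels))
      stop_dce("attribute '%s': numeric_values must match levels (%d vs %d)",
               name, length(numeric_values), length(levels))
  }
  structure(
    list(name = name, levels = levels, coding = coding,
         numeric_values = numeric_values, units = units),
    class = "attribute_spec"
  )
}

#' @export
print.attribute_spec <- function(x, ...) {
  cat(sprintf("<attribute '%s' (%s, %d levels)>\n", x$name, x$coding,
              length(x$levels)))
  cat(paste0("  - ", x$levels, collapse = "\n"), "\n")
  invisible(x)
}

n_levels <- function(a) length(a$levels)

check_attributes <- function(attributes) {
  if (length(attributes) == 0L) stop_dce("empty attribute list")
  ok <- vapply(attributes, inherits, logical(1), "attribute_spec")
  if (!all(ok)) stop_dce("all elements must be attribute_spec objects")
  nm <- vapply(attributes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_dce("duplicated attribute names")
  invisible(attributes)
}

#' Read an attribute/design configuration file
#'
#' Reads a YAML (or JSON) file listing attributes, levels, coding and
#' numeric values, plus an optional `design` block with `n_tasks`,
#' `n_profile_alternatives` and `has_opt_out`. The questionnaire shipped
#' with the package is available via
#' `system.file("extdata", "tourist_partnership_attributes.yaml", package = "dcekit")`.
#'
#' @param path path to the configuration file.
#' @return list with elements `attributes` (list of [attribute_spec()]) and
#'   `design` (list of design settings, possibly empty).
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop_dce("design config not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$attributes)) stop_dce("config has no 'attributes' block")
  attributes <- lapply(raw$attributes, function(a) {
    attribute_spec(name = a$name, levels = a$levels,
                   coding = a$coding %||% "effects",
                   numeric_values = a$numeric_values, units = a$units %||% "")
  })
  check_attributes(attributes)
  list(attributes = attributes, design = raw$design %||% list())
}

#' Enumerate the full factorial of profiles
#'
#' Every combination of one level per attribute, as a matrix of level
#' indices with one row per profile and one column per attribute.
#'
#' @param attributes list of [attribute_spec()].
#' @return integer matrix, `prod(levels)` rows, columns named by attribute.
#' @export
full_factorial <- function(attributes) {
  check_attributes(attributes)
  grid <- do.call(expand.grid, c(
    lapply(attributes, function(a) seq_len(n_levels(a))),
    KEEP.OUT.ATTRS = FALSE
  ))
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, vapply(attributes, `[[`, character(1), "name"))
  storage.mode(m) <- "integer"
  m
}

# Column catalogue: one row per coded column, mapping columns back to
# attributes and levels. The opt-out constant is always the last column.
coding_catalogue <- function(attributes, opt_out = TRUE) {
  check_attributes(attributes)
  rows <- lapply(attributes, function(a) {
    if (a$coding == "effects") {
      k <- n_levels(a) - 1L
      data.frame(
        column = paste0(a$name, ".", seq_len(k)),
        attribute = a$name,
        level_index = seq_len(k),
        level_label = a$levels[seq_len(k)],
        type = "effects",
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(column = a$name, attribute = a$name, level_index = NA_integer_,
                 level_label = NA_character_, type = "continuous",
                 stringsAsFactors = FALSE)
    }
  })
  if (opt_out) {
    rows <- c(rows, list(data.frame(
      column = "opt_out", attribute = "opt_out", level_index = NA_integer_,
      level_label = NA_character_, type = "constant", stringsAsFactors = FALSE
    )))
  }
  do.call(rbind, rows)
}

#' Effects-code a single profile
#'
#' Maps an assignment of one level per attribute to its coded row. An
#' L-level effects-coded attribute contributes L-1 columns: level k < L is
#' the unit vector with 1 in position k, the reference (last) level is -1
#' everywhere. Continuous attributes contribute their numeric value.
#'
#' @param profile integer vector of level indices, one per attribute (order
#'   of `attributes`), or a named vector/list.
#' @param attributes list of [attribute_spec()].
#' @param opt_out if `TRUE` an `opt_out` column (0 for profile rows) is
#'   appended so rows align with full design matrices.
#' @return named numeric vector of coded values.
#' @export
effects_code <- function(profile, attributes, opt_out = TRUE) {
  check_attributes(attributes)
  nm <- vapply(attributes, `[[`, character(1), "name")
  if (!is.null(names(profile))) profile <- unlist(profile)[nm]
  profile <- as.integer(profile)
  if (length(profile) != length(attributes))
    stop_dce("profile has %d entries for %d attributes",
             length(profile), length(attributes))
  out <- numeric(0)
  for (i in seq_along(attributes)) {
    a <- attributes[[i]]
    L <- n_levels(a)
    lev <- profile[i]
    if (is.na(lev) || lev < 1L || lev > L)
      stop_dce("attribute '%s': level index %s out of range 1..%d",
               a$name, as.character(profile[i]), L)
    if (a$coding == "effects") {
      v <- numeric(L - 1L)
      if (lev < L) v[lev] <- 1 else v[] <- -1
      names(v) <- paste0(a$name, ".", seq_len(L - 1L))
    } else {
      v <- stats::setNames(a$numeric_values[lev], a$name)
    }
    out <- c(out, v)
  }
  if (opt_out) out <- c(out, opt_out = 0)
  out
}

# Code a matrix of profiles (rows = profiles, cols = attributes) in one go.
code_profiles <- function(profiles, attributes, opt_out = TRUE) {
  cat_ <- coding_catalogue(attributes, opt_out = opt_out)
  m <- t(apply(profiles, 1L, effects_code, attributes = attributes,
               opt_out = opt_out))
  colnames(m) <- cat_$column
  m
}

# The coded row representing the opt-out alternative: all attribute columns
# zero, opt-out constant one.
opt_out_row <- function(attributes) {
  cat_ <- coding_catalogue(attributes, opt_out = TRUE)
  stats::setNames(as.numeric(cat_$column == "opt_out"), cat_$column)
}
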