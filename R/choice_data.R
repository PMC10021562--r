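#' Long-format choice dataset
#'
#' Wraps a data frame with one row per respondent x task x alternative:
#' identifier columns `respondent_id`, `task_id`, `alt_id`, a 0/1 `chosen`
#' indicator, a 0/1 `opt_out` indicator and the coded attribute columns
#' named by the coding catalogue. Invariants enforced: exactly one chosen
#' alternative per (respondent, task); a constant number of alternatives per
#' task; opt-out rows carry zeros in all attribute columns.
#'
#' @param df data frame as above.
#' @param catalogue coding catalogue as produced internally from the
#'   attribute list; defaults to treating every non-identifier column as a
#'   coded column.
#' @param attributes optional list of [attribute_spec()] retained for
#'   level-utility reporting.
#' @return object of classes `choice_dataset` and `data.frame`.
#' @export
choice_dataset <- function(df, catalogue = NULL, attributes = NULL) {
  id_cols <- c("respondent_id", "task_id", "alt_id", "chosen")
  missing <- setdiff(id_cols, names(df))
  if (length(missing))
    stop_dce("choice data lacks required columns: %s",
             paste(missing, collapse = ", "))
  if (is.null(catalogue)) {
    coded <- setdiff(names(df), id_cols)
    catalogue <- data.frame(column = coded, attribute = NA_character_,
                            level_index = NA_integer_,
                            level_label = NA_character_,
                            type = ifelse(coded == "opt_out", "constant",
                                          "unknown"),
                            stringsAsFactors = FALSE)
  }
  missing_coded <- setdiff(catalogue$column, names(df))
  if (length(missing_coded))
    stop_dce("coded columns missing from data: %s",
             paste(missing_coded, collapse = ", "))
  df <- as.data.frame(df)[, c(id_cols, catalogue$column)]
  out <- structure(df, catalogue = catalogue, attributes = attributes,
                   class = c("choice_dataset", "data.frame"))
  validate_choice_dataset(out)
  out
}

#' @export
print.choice_dataset <- function(x, ...) {
  n_resp <- length(unique(x$respondent_id))
  n_tasks <- nrow(unique(as.data.frame(x)[c("respondent_id", "task_id")]))
  cat(sprintf("<choice_dataset: %d respondents, %d tasks, %d rows>\n",
              n_resp, n_tasks, nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

coded_columns <- function(dataset) attr(dataset, "catalogue")$column

# Design matrix (rows x coded columns) and convenience indexes.
dataset_matrix <- function(dataset) {
  as.matrix(as.data.frame(dataset)[, coded_columns(dataset), drop = FALSE])
}

task_key <- function(dataset) {
  interaction(dataset$respondent_id, dataset$task_id, drop = TRUE, lex.order = TRUE)
}

validate_choice_dataset <- function(dataset) {
  key <- task_key(dataset)
  chosen_per_task <- tapply(dataset$chosen, key, sum)
  bad <- names(chosen_per_task)[chosen_per_task != 1]
  if (length(bad))
    stop_dce("each (respondent, task) needs exactly one chosen=1; violated for: %s",
             paste(utils::head(bad, 5L), collapse = ", "))
  sizes <- table(key)
  if (length(unique(as.integer(sizes))) != 1L)
    stop_dce("alternatives-per-task is not constant (saw sizes %s)",
             paste(sort(unique(as.integer(sizes))), collapse = ", "))
  if ("opt_out" %in% names(dataset)) {
    attr_cols <- setdiff(coded_columns(dataset), "opt_out")
    if (length(attr_cols)) {
      oo <- dataset$opt_out == 1
      if (any(oo) && any(abs(as.matrix(dataset[oo, attr_cols, drop = FALSE])) > 0))
        stop_dce("opt-out rows must have all attribute columns equal to 0")
    }
  }
  invisible(dataset)
}

#' Read / write long-format choice data
#'
#' `read_choice_data()` accepts either pre-coded files (columns
#' `respondent_id`, `task_id`, `alt_id`, `chosen`, `opt_out`, then coded
#' columns) or raw-label files (the same identifier columns plus one column
#' per attribute holding level labels) together with a design configuration,
#' in which case effects/continuous coding is applied internally. Files are
#' tab- or comma-separated (inferred from the extension: `.csv` means
#' comma). `write_choice_data()` writes the coded representation;
#' a written file reads back identically.
#'
#' @param path file path.
#' @param design_config result of [read_design_config()], or a list of
#'   [attribute_spec()]; required for raw-label files.
#' @return a [choice_dataset()].
#' @export
read_choice_data <- function(path, design_config = NULL) {
  if (!file.exists(path)) stop_dce("choice data file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE)
  attributes <- NULL
  if (!is.null(design_config)) {
    attributes <- if (!is.null(design_config$attributes))
      design_config$attributes else design_config
    check_attributes(attributes)
  }
  attr_names <- if (is.null(attributes)) character(0) else
    vapply(attributes, `[[`, character(1), "name")
  raw_label <- length(attr_names) > 0 && all(attr_names %in% names(df)) &&
    any(vapply(df[attr_names], is.character, logical(1)))
  if (raw_label) {
    idx <- matrix(0L, nrow(df), length(attributes))
    oo <- df$opt_out %||% rep(0L, nrow(df))
    for (i in seq_along(attributes)) {
      a <- attributes[[i]]
      lab <- df[[a$name]]
      m <- match(lab, a$levels)
      bad <- which(is.na(m) & oo != 1 & !is.na(lab) & nzchar(lab))
      if (length(bad))
        stop_dce("unknown level label for attribute '%s' at data row(s) %s",
                 a$name, paste(utils::head(bad, 5L), collapse = ", "))
      idx[, i] <- m
    }
    coded <- matrix(0, nrow(df), nrow(coding_catalogue(attributes)))
    colnames(coded) <- coding_catalogue(attributes)$column
    for (r in seq_len(nrow(df))) {
      coded[r, ] <- if (oo[r] == 1) opt_out_row(attributes)
                    else effects_code(idx[r, ], attributes)
    }
    df <- cbind(df[c("respondent_id", "task_id", "alt_id", "chosen")],
                as.data.frame(coded, check.names = FALSE))
    return(choice_dataset(df, coding_catalogue(attributes), attributes))
  }
  catalogue <- if (is.null(attributes)) NULL else coding_catalogue(attributes)
  choice_dataset(df, catalogue, attributes)
}

#' @rdname read_choice_data
#' @param dataset a [choice_dataset()].
#' @export
write_choice_data <- function(dataset, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(dataset), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
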