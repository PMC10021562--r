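#' Score the WHO-5 wellbeing index
#'
#' Sums the five items (each 0-5) to the raw 0-25 total and flags poor
#' wellbeing when the total falls under half of the possible score
#' (total < 12.5).
#'
#' @param items numeric vector of 5 item responses in 0..5.
#' @return list with `total` (0-25) and `low` flag.
#' @export
score_who5 <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 5L) stop_dce("WHO-5 needs exactly 5 items, got %d",
                                    length(items))
  if (any(is.na(items)) || any(items < 0) || any(items > 5) ||
      any(items != round(items)))
    stop_dce("WHO-5 items must be integers in 0..5")
  total <- sum(items)
  list(total = total, low = total < 12.5)
}

#' Score the nine-item HIV knowledge tool
#'
#' Counts correct items and assigns the reporting categories used for the
#' survey: `very_high` for a perfect 9/9, `low` for fewer than 6 correct,
#' `mid` otherwise.
#'
#' @param items logical (or 0/1) vector of length 9, `TRUE` = correct.
#' @return list with `count` (0-9) and `category`.
#' @export
score_hiv_knowledge <- function(items) {
  if (length(items) != 9L)
    stop_dce("HIV knowledge tool has 9 items, got %d", length(items))
  items <- as.logical(items)
  if (any(is.na(items))) stop_dce("HIV knowledge items must be TRUE/FALSE")
  count <- sum(items)
  category <- if (count == 9L) "very_high" else if (count < 6L) "low" else "mid"
  list(count = count, category = category)
}

#' Score the Household Hunger Scale
#'
#' Aggregates the three occurrence/frequency questions to the standard 0-6
#' score (each item scored 0 = never, 1 = rarely/sometimes, 2 = often) and
#' categorises: 0-1 none/low, 2-3 moderate, 4-6 high. The analysis flag
#' marks moderate-or-high hunger (the covariate used in the risk
#' regressions). Missing items propagate to a missing category so the
#' record drops out listwise downstream. Cut-points are overridable.
#'
#' @param items numeric vector of 3 item scores in 0..2 (NA allowed).
#' @param cutpoints length-2 increasing vector: minimum scores for
#'   `moderate` and `high`.
#' @return list with `score` (0-6 or NA), `category` (`"none_low"`,
#'   `"moderate"`, `"high"` or NA) and `flag` (moderate-or-high; NA when
#'   missing).
#' @export
score_household_hunger <- function(items, cutpoints = c(2, 4)) {
  items <- as.numeric(items)
  if (length(items) != 3L)
    stop_dce("Household Hunger Scale has 3 items, got %d", length(items))
  if (any(is.na(items)))
    return(list(score = NA_real_, category = NA_character_, flag = NA))
  if (any(items < 0) || any(items > 2) || any(items != round(items)))
    stop_dce("hunger items must be integers in 0..2")
  stopifnot(length(cutpoints) == 2L, diff(cutpoints) > 0)
  score <- sum(items)
  category <- if (score >= cutpoints[2]) "high"
              else if (score >= cutpoints[1]) "moderate" else "none_low"
  list(score = score, category = category, flag = category != "none_low")
}

#' Derive the fixed analysis covariates from raw survey records
#'
#' Appends the scored covariates used across the five risk-behaviour
#' regressions to a respondent data frame: `who5_total` / `poor_wellbeing`
#' (from `who5_1`..`who5_5`), `hiv_knowledge` / `hiv_category` (from
#' `hiv_1`..`hiv_9`), `hunger_score` / `hunger_category` / `hunger_flag`
#' (from `hunger_1`..`hunger_3`). Columns already present are recomputed.
#'
#' @param profiles data frame of respondent records with the item columns
#'   above plus demographics (`age`, `registered`, `difficulty_350_bill`,
#'   `months_in_industry`, `months_per_year`, outcomes...).
#' @return the data frame with derived columns appended.
#' @export
score_profiles <- function(profiles) {
  profiles <- as.data.frame(profiles)
  who5_cols <- paste0("who5_", 1:5)
  hiv_cols <- paste0("hiv_", 1:9)
  hunger_cols <- paste0("hunger_", 1:3)
  if (all(who5_cols %in% names(profiles))) {
    sc <- apply(profiles[who5_cols], 1L, function(x) {
      s <- score_who5(x); c(s$total, s$low)
    })
    profiles$who5_total <- sc[1, ]
    profiles$poor_wellbeing <- sc[2, ] == 1
  }
  if (all(hiv_cols %in% names(profiles))) {
    sc <- apply(profiles[hiv_cols], 1L, function(x) score_hiv_knowledge(x)$count)
    profiles$hiv_knowledge <- sc
    profiles$hiv_category <- ifelse(sc == 9, "very_high",
                                    ifelse(sc < 6, "low", "mid"))
  }
  if (all(hunger_cols %in% names(profiles))) {
    sc <- lapply(seq_len(nrow(profiles)), function(i)
      score_household_hunger(as.numeric(profiles[i, hunger_cols])))
    profiles$hunger_score <- vapply(sc, `[[`, numeric(1), "score")
    profiles$hunger_category <- vapply(sc, function(s)
      if (is.na(s$category)) NA_character_ else s$category, character(1))
    profiles$hunger_flag <- vapply(sc, function(s)
      if (is.na(s$flag)) NA else s$flag, logical(1))
  }
  profiles
}

#' Read / write respondent survey records
#'
#' Delimited text, one row per respondent. `read_survey_data()` applies
#' [score_profiles()] on load when the item columns are present.
#'
#' @param path file path (`.csv` comma-separated, otherwise tab).
#' @param score derive scored covariates on load?
#' @return data frame of respondent records.
#' @export
read_survey_data <- function(path, score = TRUE) {
  if (!file.exists(path)) stop_dce("survey file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (score) df <- score_profiles(df)
  df
}

#' @rdname read_survey_data
#' @param profiles respondent data frame.
#' @export
write_survey_data <- function(profiles, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(profiles, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
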