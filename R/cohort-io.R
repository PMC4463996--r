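#' Cohort intake tables
#'
#' A cohort table has one row per participant: demographics (`sex`, `age`,
#' `weight_kg`, `height_m`), the single-item sugar-sweetened-beverage
#' response (`ssb_ml_per_week`, artificially sweetened drinks excluded), the
#' takeaway frequency category (`takeaway_per_week`, one of `0-1`, `2-3`,
#' `4-5`, `6+`), plain water (`water_ml_per_day`), a `complete` flag, and one
#' wide column per FFQ item prefixed `g_` holding grams/day (liquids are
#' stored as grams via their density).
#'
#' @name cohort
NULL

COHORT_FIXED_COLS <- c(
  "participant_id", "sex", "age", "weight_kg", "height_m",
  "ssb_ml_per_week", "takeaway_per_week", "water_ml_per_day", "complete"
)

#' Load a cohort intake table
#'
#' Reads a cohort CSV (see [cohort] for the schema) and validates it against
#' a composition table: every `g_<food_id>` column must reference a known
#' item and all amounts must be non-negative. A participant's `complete` flag
#' is FALSE when any required field (sex, age, weight, height, takeaway
#' category, SSB, water) is missing — such records are later excluded by
#' [apply_exclusions()], mirroring exclusion of participants who did not
#' complete the baseline survey. An explicit `complete` column, if present,
#' is combined (AND) with the missingness rule.
#'
#' @param path Path to a CSV file.
#' @param composition A composition tibble from [load_composition_table()].
#' @return A tibble with one record per participant; derived column `bmi`
#'   (kg/m^2) is added.
#' @export
load_cohort <- function(path, composition) {
  if (!file.exists(path)) {
    abort(paste0("Cohort file not found: ", path), class = "dietq_io_error")
  }
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(setdiff(COHORT_FIXED_COLS, "complete"), names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "dietq_schema_error")
  }
  amount_cols <- grep("^g_", names(cohort), value = TRUE)
  ids <- sub("^g_", "", amount_cols)
  unknown <- setdiff(ids, composition$food_id)
  if (length(unknown)) {
    abort(paste0("Cohort references food_id(s) absent from the composition ",
                 "table: ", paste(unknown, collapse = ", ")),
          class = "dietq_reference_error")
  }
  for (col in amount_cols) {
    if (any(cohort[[col]] < 0, na.rm = TRUE)) {
      bad <- cohort$participant_id[which(cohort[[col]] < 0)[1]]
      abort(sprintf("Negative amount in column %s (participant %s)", col, bad),
            class = "dietq_validation_error")
    }
  }
  if (any(cohort$ssb_ml_per_week < 0, na.rm = TRUE) ||
      any(cohort$water_ml_per_day < 0, na.rm = TRUE)) {
    abort("ssb_ml_per_week and water_ml_per_day must be non-negative",
          class = "dietq_validation_error")
  }
  bad_sex <- setdiff(unique(cohort$sex[!is.na(cohort$sex)]),
                     c("male", "female"))
  if (length(bad_sex)) {
    abort(paste0("Unknown sex value(s): ", paste(bad_sex, collapse = ", ")),
          class = "dietq_validation_error")
  }
  bad_ta <- setdiff(unique(cohort$takeaway_per_week[!is.na(cohort$takeaway_per_week)]),
                    TAKEAWAY_LEVELS)
  if (length(bad_ta)) {
    abort(paste0("Unknown takeaway category value(s): ",
                 paste(bad_ta, collapse = ", ")),
          class = "dietq_validation_error")
  }
  required <- setdiff(COHORT_FIXED_COLS, c("participant_id", "complete"))
  derived_complete <- complete.cases(cohort[required])
  if ("complete" %in% names(cohort)) {
    cohort$complete <- as.logical(cohort$complete) & derived_complete
  } else {
    cohort$complete <- derived_complete
  }
  cohort$bmi <- cohort$weight_kg / cohort$height_m^2
  cohort
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  amount_cols <- grep("^g_", names(cohort), value = TRUE)
  readr::write_csv(cohort[, c(COHORT_FIXED_COLS, amount_cols)], path,
                   progress = FALSE)
  invisible(path)
}

cohort_amounts <- function(cohort) {
  amount_cols <- grep("^g_", names(cohort), value = TRUE)
  m <- as.matrix(cohort[, amount_cols, drop = FALSE])
  m[is.na(m)] <- 0
  colnames(m) <- sub("^g_", "", amount_cols)
  rownames(m) <- cohort$participant_id
  m
}
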