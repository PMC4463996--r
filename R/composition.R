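#' Food composition tables
#'
#' A composition table has one row per FFQ food item with its food-group and
#' variety-subgroup assignment, wholegrain and low-fat flags, standard serve
#' size (g) and per-100 g energy and nutrients. It plays the role a national
#' food and nutrient database plays in FFQ analysis: the bridge from reported
#' grams to energy, nutrients and guideline serves.
#'
#' Required columns: `food_id`, `name`, `group`, `subgroup`,
#' `is_wholegrain`, `is_low_fat`, `serve_size_g`, `energy_kj`, `protein_g`,
#' `fat_g`, `sat_fat_g`, `mono_g`, `poly_g`, `carb_g`, `sugars_g`,
#' `starch_g`, `fiber_g`, `sodium_mg`, `alcohol_g`, `density_g_ml`.
#'
#' @name composition
NULL

COMPOSITION_COLS <- c(
  "food_id", "name", "group", "subgroup", "is_wholegrain", "is_low_fat",
  "serve_size_g", "energy_kj", "protein_g", "fat_g", "sat_fat_g", "mono_g",
  "poly_g", "carb_g", "sugars_g", "starch_g", "fiber_g", "sodium_mg",
  "alcohol_g", "density_g_ml"
)

#' Load a food composition table
#'
#' Reads a composition CSV (see [composition] for the schema) and validates
#' every row: unique `food_id`, known food group, positive serve size,
#' fat fractions not exceeding total fat, sugars + starch not exceeding
#' carbohydrate, and stated energy within 10% of the energy derived from the
#' macronutrient conversion factors (protein 17, fat 37, carbohydrate 16.7,
#' alcohol 29 kJ/g).
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header row,
#'   `.` decimal).
#' @param energy_factors Named list of kJ/g conversion factors used for the
#'   energy consistency check; defaults to those of
#'   [default_scoring_config()].
#' @return A tibble with one validated row per food item.
#' @export
#' @examples
#' comp <- load_composition_table(dietq_example("composition_demo.csv"))
#' dplyr::count(comp, group)
load_composition_table <- function(path,
                                   energy_factors = default_scoring_config()$energy_factors) {
  if (!file.exists(path)) {
    abort(paste0("Composition file not found: ", path),
          class = "dietq_io_error")
  }
  comp <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(COMPOSITION_COLS, names(comp))
  if (length(missing)) {
    abort(paste0("Composition table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "dietq_schema_error")
  }
  comp$is_wholegrain <- as.logical(comp$is_wholegrain)
  comp$is_low_fat <- as.logical(comp$is_low_fat)
  validate_composition(comp, energy_factors)
  comp
}

validate_composition <- function(comp, energy_factors = default_scoring_config()$energy_factors) {
  fail_row <- function(id, msg) {
    abort(sprintf("Composition row '%s': %s", id, msg),
          class = "dietq_validation_error")
  }
  if (anyDuplicated(comp$food_id)) {
    dup <- comp$food_id[duplicated(comp$food_id)][1]
    abort(sprintf("Duplicate food_id '%s' in composition table", dup),
          class = "dietq_validation_error")
  }
  bad_group <- setdiff(unique(comp$group), FOOD_GROUPS)
  if (length(bad_group)) {
    abort(paste0("Unknown food group(s): ", paste(bad_group, collapse = ", ")),
          class = "dietq_validation_error")
  }
  ef <- energy_factors
  for (i in seq_len(nrow(comp))) {
    r <- comp[i, ]
    if (is.na(r$serve_size_g) || r$serve_size_g <= 0) {
      fail_row(r$food_id, "serve_size_g must be > 0")
    }
    if (r$sat_fat_g + r$mono_g + r$poly_g > r$fat_g + 1e-6) {
      fail_row(r$food_id, sprintf(
        "saturated + mono + poly fat (%.3f g) exceeds total fat (%.3f g)",
        r$sat_fat_g + r$mono_g + r$poly_g, r$fat_g))
    }
    if (r$sugars_g + r$starch_g > r$carb_g + 1e-6) {
      fail_row(r$food_id, sprintf(
        "sugars + starch (%.3f g) exceeds carbohydrate (%.3f g)",
        r$sugars_g + r$starch_g, r$carb_g))
    }
    e_macro <- ef$protein * r$protein_g + ef$fat * r$fat_g +
      ef$carbohydrate * r$carb_g + ef$alcohol * r$alcohol_g
    if (abs(r$energy_kj - e_macro) > 0.10 * max(e_macro, 1)) {
      fail_row(r$food_id, sprintf(
        "energy_kj (%.1f) not within 10%% of macronutrient-derived energy (%.1f)",
        r$energy_kj, e_macro))
    }
    nonneg <- c("energy_kj", "protein_g", "fat_g", "sat_fat_g", "mono_g",
                "poly_g", "carb_g", "sugars_g", "starch_g", "fiber_g",
                "sodium_mg", "alcohol_g")
    vals <- unlist(r[nonneg])
    if (any(vals < 0, na.rm = TRUE)) {
      fail_row(r$food_id, "nutrient values must be non-negative")
    }
  }
  invisible(comp)
}

#' Write a composition table to CSV
#'
#' @param comp A composition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(comp, path) {
  readr::write_csv(comp[, COMPOSITION_COLS], path, progress = FALSE)
  invisible(path)
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' dietq_example()
dietq_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "dietq"))
  } else {
    path <- system.file("extdata", file, package = "dietq", mustWork = FALSE)
    if (!nzchar(path)) {
      abort(paste0("No bundled example file '", file, "'"),
            class = "dietq_io_error")
    }
    path
  }
}
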