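#' Default HEIFA scoring configuration
#'
#' Returns the full scoring rubric for the 11-component modified Healthy
#' Eating Index for Australians (HEIFA) used throughout the package. Nine
#' components (the five core food groups, discretionary foods, saturated fat,
#' sodium, total sugars) are scored out of 10 and two (water, alcohol) out of
#' 5, for a 0-100 total. Every element is overridable through
#' [load_scoring_config()]; the defaults encode:
#'
#' * **Quantity targets** (serves/day, by sex) from the 2013 Australian Guide
#'   to Healthy Eating adult recommendations: vegetables 6 (male) / 5
#'   (female); fruit 2; grain foods 6; meat and alternatives 3 / 2.5; dairy
#'   and alternatives 2.5. Intakes below target are prorated linearly; intakes
#'   above target are not penalised.
#' * **Variety sub-scores** for vegetables and fruit: 1 point per subgroup
#'   consumed at least once per week, capped at 5.
#' * **Wholegrain / low-fat sub-scores**: full credit when more than half of
#'   grain intake is wholegrain (resp. dairy intake low-fat), prorated below.
#' * **Moderation cut-offs** `(full_cut, zero_cut)`: saturated fat 10/15 %E,
#'   total sugars 15/30 %E, sodium 2300/4600 mg/day, discretionary energy
#'   20/60 %E, alcohol 20/40 g/day ethanol. Maximum points at or below
#'   `full_cut`, zero at or above `zero_cut`, linear in between.
#' * **Water**: full 5 points when water is at least half of total beverage
#'   volume, prorated below.
#' * **Energy conversion factors** (kJ/g): protein 17, fat 37, carbohydrate
#'   16.7, alcohol 29; 1 kcal = 4.184 kJ.
#'
#' @return A named list with elements `max_points`, `targets`,
#'   `quantity_points`, `variety`, `wholegrain`, `low_fat`, `moderation`,
#'   `water`, `energy_factors`, `kj_per_kcal`.
#' @seealso [load_scoring_config()], [score_record()]
#' @export
#' @examples
#' cfg <- default_scoring_config()
#' sum(unlist(cfg$max_points)) # 100
default_scoring_config <- function() {
  list(
    max_points = list(
      vegetables = 10, fruit = 10, grains = 10, meat_alt = 10,
      dairy_alt = 10, discretionary = 10, fat = 10, sodium = 10,
      sugars = 10, water = 5, alcohol = 5
    ),
    targets = list(
      vegetables = list(male = 6,   female = 5),
      fruit      = list(male = 2,   female = 2),
      grains     = list(male = 6,   female = 6),
      meat_alt   = list(male = 3,   female = 2.5),
      dairy_alt  = list(male = 2.5, female = 2.5)
    ),
    quantity_points = list(
      vegetables = 5, fruit = 5, grains = 5, meat_alt = 10, dairy_alt = 5
    ),
    variety = list(
      vegetables = list(
        points = list(green_veg = 1, orange_veg = 1, legumes = 1,
                      starchy_veg = 1, other_veg = 1),
        cap = 5
      ),
      fruit = list(
        points = list(pome_fruit = 1, citrus_fruit = 1, berry_fruit = 1,
                      stone_fruit = 1, tropical_fruit = 1),
        cap = 5
      ),
      min_serves_per_week = 1
    ),
    wholegrain = list(points = 5, full_credit_prop = 0.5),
    low_fat    = list(points = 5, full_credit_prop = 0.5),
    moderation = list(
      discretionary = list(full_cut = 20,   zero_cut = 60,   basis = "pct_energy"),
      fat           = list(full_cut = 10,   zero_cut = 15,   basis = "pct_energy"),
      sodium        = list(full_cut = 2300, zero_cut = 4600, basis = "mg_day"),
      sugars        = list(full_cut = 15,   zero_cut = 30,   basis = "pct_energy"),
      alcohol       = list(full_cut = 20,   zero_cut = 40,   basis = "g_day")
    ),
    water = list(full_credit_prop = 0.5),
    energy_factors = list(protein = 17, fat = 37, carbohydrate = 16.7,
                          alcohol = 29),
    kj_per_kcal = 4.184
  )
}

#' Load a scoring configuration from JSON
#'
#' Reads a (possibly partial) scoring configuration and merges it over
#' [default_scoring_config()]: any field absent from the file keeps its
#' default. The merged configuration is validated before return.
#'
#' @param path Path to a JSON file. An empty object `{}` yields the full
#'   default configuration.
#' @return A validated scoring configuration list.
#' @export
load_scoring_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Scoring config file not found: ", path),
          class = "dietq_io_error")
  }
  user <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- modifyList(default_scoring_config(), user)
  validate_scoring_config(cfg)
}

#' Validate a scoring configuration
#'
#' Checks structural invariants: the 11 component maxima sum to 100, every
#' moderation pair has `full_cut < zero_cut`, all quantity targets are
#' positive, and quantity points do not exceed their component maximum.
#'
#' @param cfg A scoring configuration list.
#' @return `cfg`, invisibly unchanged, if valid; otherwise an error of class
#'   `dietq_config_error`.
#' @export
validate_scoring_config <- function(cfg) {
  comps <- c("vegetables", "fruit", "grains", "meat_alt", "dairy_alt",
             "discretionary", "fat", "sodium", "sugars", "water", "alcohol")
  missing <- setdiff(comps, names(cfg$max_points))
  if (length(missing)) {
    abort(paste0("max_points missing component(s): ",
                 paste(missing, collapse = ", ")),
          class = "dietq_config_error")
  }
  total <- sum(unlist(cfg$max_points[comps]))
  if (abs(total - 100) > 1e-9) {
    abort(sprintf("Component maxima must sum to 100, got %g", total),
          class = "dietq_config_error")
  }
  for (nm in names(cfg$moderation)) {
    m <- cfg$moderation[[nm]]
    if (!(m$full_cut < m$zero_cut)) {
      abort(sprintf("moderation$%s: full_cut (%g) must be < zero_cut (%g)",
                    nm, m$full_cut, m$zero_cut),
            class = "dietq_config_error")
    }
  }
  for (g in names(cfg$targets)) {
    t <- unlist(cfg$targets[[g]])
    if (any(t <= 0)) {
      abort(sprintf("targets$%s must be > 0", g), class = "dietq_config_error")
    }
    q <- cfg$quantity_points[[g]]
    if (is.null(q) || q < 0 || q > cfg$max_points[[g]]) {
      abort(sprintf("quantity_points$%s must lie in [0, max_points$%s]", g, g),
            class = "dietq_config_error")
    }
  }
  if (!(cfg$water$full_credit_prop > 0 && cfg$water$full_credit_prop <= 1)) {
    abort("water$full_credit_prop must be in (0, 1]",
          class = "dietq_config_error")
  }
  invisible(cfg)
}

#' Reference population constants
#'
#' Named constants describing the comparison population used by
#' [compare_to_reference()]: national-survey mean intakes (g/day) of the core
#' food groups, mean percent-of-energy contributions of the macronutrients,
#' and fibre. Each value carries a `source` label; values are constants, never
#' recomputed.
#'
#' The defaults are the published survey means for Australian adults aged
#' 19-30 years (2011-13 national nutrition survey data cubes).
#'
#' @return A named list; each element is `list(value=, units=, source=)`.
#' @export
default_reference_values <- function() {
  src <- "National nutrition survey 2011-13, adults 19-30 y"
  ref <- function(value, units) list(value = value, units = units, source = src)
  list(
    vegetables_g        = ref(172.8, "g/day"),
    fruit_g             = ref(109.5, "g/day"),
    grains_g            = ref(171.5, "g/day"),
    meat_alt_g          = ref(221.5, "g/day"),
    dairy_alt_g         = ref(242.1, "g/day"),
    carb_pct_e          = ref(45.3, "%E"),
    sugars_pct_e        = ref(19.8, "%E"),
    starch_pct_e        = ref(24.7, "%E"),
    protein_pct_e       = ref(18.1, "%E"),
    fat_pct_e           = ref(31.2, "%E"),
    sat_fat_pct_e       = ref(11.7, "%E"),
    mono_pct_e          = ref(12.0, "%E"),
    poly_pct_e          = ref(4.9, "%E"),
    alcohol_pct_e       = ref(2.8, "%E"),
    fiber_g             = ref(23.7, "g/day")
  )
}

#' Load reference values from JSON
#'
#' @param path Path to a JSON file mapping names to
#'   `{"value": , "units": , "source": }` objects.
#' @return A named list of reference constants.
#' @export
load_reference_values <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Reference values file not found: ", path),
          class = "dietq_io_error")
  }
  ref <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (nm in names(ref)) {
    if (is.null(ref[[nm]]$value) || !is.numeric(ref[[nm]]$value)) {
      abort(sprintf("Reference entry '%s' has no numeric 'value'", nm),
            class = "dietq_config_error")
    }
    if (is.null(ref[[nm]]$source)) {
      abort(sprintf("Reference entry '%s' must carry a 'source' label", nm),
            class = "dietq_config_error")
    }
  }
  ref
}
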