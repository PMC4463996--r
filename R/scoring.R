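#' Prorated quantity score
#'
#' Awards full points when intake meets the recommended serves/day target,
#' linearly prorated below, never penalised above:
#' `max_points * min(serves / target, 1)`.
#'
#' @param serves Serves per day (>= 0).
#' @param target Recommended serves per day (> 0).
#' @param max_points Maximum points for the quantity sub-score.
#' @return Points in `[0, max_points]` (vectorised).
#' @export
#' @examples
#' prorated_quantity_score(1.5, 5, 5) # 1.5
prorated_quantity_score <- function(serves, target, max_points) {
  if (any(target <= 0)) {
    abort("target must be > 0", class = "dietq_domain_error")
  }
  if (any(serves < 0)) {
    abort("serves must be >= 0", class = "dietq_domain_error")
  }
  max_points * pmin(serves / target, 1)
}

#' Moderation score
#'
#' Scores a deleterious-nutrient level downward between two cut-offs: full
#' points at or below `full_cut`, zero at or above `zero_cut`, linear in
#' between: `max_points * (zero_cut - value) / (zero_cut - full_cut)`.
#'
#' @param value Nutrient level (%E, mg/day or g/day depending on component).
#' @param full_cut Level at or below which full points are awarded.
#' @param zero_cut Level at or above which zero points are awarded.
#' @param max_points Maximum points.
#' @return Points in `[0, max_points]` (vectorised).
#' @export
#' @examples
#' moderation_score(12.5, 10, 15, 10) # 5
moderation_score <- function(value, full_cut, zero_cut, max_points) {
  if (any(full_cut >= zero_cut)) {
    abort("full_cut must be < zero_cut", class = "dietq_domain_error")
  }
  pmin(pmax(max_points * (zero_cut - value) / (zero_cut - full_cut), 0),
       max_points)
}

#' Variety score
#'
#' Sums the points of the subgroups consumed, capped: `min(sum, cap)`.
#' Subgroups not listed in `subgroup_points` are ignored with a warning.
#'
#' @param consumed_subgroups Character vector of subgroups consumed (at
#'   least one serve per week).
#' @param subgroup_points Named list/vector of points per subgroup.
#' @param cap Maximum variety points.
#' @return Points in `[0, cap]`.
#' @export
variety_score <- function(consumed_subgroups, subgroup_points, cap) {
  consumed_subgroups <- unique(consumed_subgroups)
  unknown <- setdiff(consumed_subgroups, names(subgroup_points))
  if (length(unknown)) {
    warn(paste0("Ignoring unknown variety subgroup(s): ",
                paste(unknown, collapse = ", ")))
    consumed_subgroups <- intersect(consumed_subgroups, names(subgroup_points))
  }
  min(sum(unlist(subgroup_points[consumed_subgroups])), cap)
}

#' Score one intake summary with the HEIFA rubric
#'
#' Computes the 11 component scores and the 0-100 total for one participant:
#'
#' * vegetables, fruit: prorated quantity (sex-specific target) + variety;
#' * grain foods: prorated quantity + wholegrain proportion sub-score;
#' * meat and alternatives: prorated quantity only (no over-consumption
#'   penalty);
#' * dairy and alternatives: prorated quantity + low-fat proportion
#'   sub-score;
#' * discretionary %E, saturated fat %E, sodium mg/day, total sugars %E,
#'   alcohol g/day: moderation scoring between the configured cut-offs;
#' * water: prorated on the proportion of total beverage volume that is
#'   water.
#'
#' A record with zero FFQ energy is degenerate: all five moderation
#' components score 0 and `zero_energy` is flagged in the result.
#'
#' "Met guideline" flags: quantity components when serves reach the target;
#' moderation components when the value is at or below `full_cut` (and
#' energy is positive); water when the proportion reaches full credit.
#'
#' @param summary One row of [summarize_intake()] output (or an equivalent
#'   named list).
#' @param config A scoring configuration.
#' @return A named list with `components` (11 named scores), `subscores`,
#'   `met` (11 named flags), `total`, and `zero_energy`.
#' @export
score_record <- function(summary, config = default_scoring_config()) {
  s <- as_summary_list(summary)
  sex <- s$sex
  if (!sex %in% c("male", "female")) {
    abort("summary$sex must be 'male' or 'female'",
          class = "dietq_domain_error")
  }
  qp <- config$quantity_points
  mp <- config$max_points
  zero_energy <- isTRUE(s$zero_energy) || !(s$energy_kj > 0)

  target <- function(g) config$targets[[g]][[sex]]
  quantity <- lapply(CORE_GROUPS, function(g) {
    prorated_quantity_score(s[[paste0(g, "_serves")]], target(g), qp[[g]])
  })
  names(quantity) <- CORE_GROUPS

  veg_variety <- variety_score(s$veg_subgroups,
                               config$variety$vegetables$points,
                               config$variety$vegetables$cap)
  fruit_variety <- variety_score(s$fruit_subgroups,
                                 config$variety$fruit$points,
                                 config$variety$fruit$cap)
  wholegrain_sub <- config$wholegrain$points *
    min(s$wholegrain_prop / config$wholegrain$full_credit_prop, 1)
  lowfat_sub <- config$low_fat$points *
    min(s$lowfat_prop / config$low_fat$full_credit_prop, 1)

  mod_value <- list(
    discretionary = s$discretionary_pct_e,
    fat = s$sat_fat_pct_e,
    sodium = s$sodium_mg,
    sugars = s$sugars_pct_e,
    alcohol = s$alcohol_g
  )
  moderation <- lapply(names(mod_value), function(nm) {
    if (zero_energy) return(0)
    m <- config$moderation[[nm]]
    moderation_score(mod_value[[nm]], m$full_cut, m$zero_cut, mp[[nm]])
  })
  names(moderation) <- names(mod_value)

  water <- mp$water * min(s$water_prop / config$water$full_credit_prop, 1)

  components <- c(
    vegetables = quantity$vegetables + veg_variety,
    fruit = quantity$fruit + fruit_variety,
    grains = quantity$grains + wholegrain_sub,
    meat_alt = quantity$meat_alt,
    dairy_alt = quantity$dairy_alt + lowfat_sub,
    discretionary = moderation$discretionary,
    fat = moderation$fat,
    sodium = moderation$sodium,
    sugars = moderation$sugars,
    water = water,
    alcohol = moderation$alcohol
  )
  met_quantity <- vapply(CORE_GROUPS, function(g) {
    s[[paste0(g, "_serves")]] >= target(g)
  }, logical(1))
  met_moderation <- vapply(names(mod_value), function(nm) {
    !zero_energy && mod_value[[nm]] <= config$moderation[[nm]]$full_cut
  }, logical(1))
  met <- c(met_quantity, met_moderation,
           water = s$water_prop >= config$water$full_credit_prop)
  met <- met[names(components)]

  list(
    components = components,
    subscores = list(
      vegetables_quantity = quantity$vegetables,
      vegetables_variety = veg_variety,
      fruit_quantity = quantity$fruit,
      fruit_variety = fruit_variety,
      grains_quantity = quantity$grains,
      grains_wholegrain = wholegrain_sub,
      dairy_quantity = quantity$dairy_alt,
      dairy_lowfat = lowfat_sub
    ),
    met = met,
    total = sum(components),
    zero_energy = zero_energy
  )
}

as_summary_list <- function(summary) {
  if (is.data.frame(summary)) {
    if (nrow(summary) != 1) {
      abort("score_record() expects a single summary row",
            class = "dietq_domain_error")
    }
    s <- as.list(summary)
    for (nm in c("veg_subgroups", "fruit_subgroups")) {
      if (is.list(s[[nm]])) s[[nm]] <- s[[nm]][[1]]
    }
    s
  } else {
    summary
  }
}

#' Score a summarised cohort
#'
#' Applies [score_record()] to every row of an intake-summary table.
#'
#' @param summaries Output of [summarize_intake()].
#' @param config A scoring configuration.
#' @return A tibble with one row per participant: `participant_id`, `sex`,
#'   the 11 component scores, the eight sub-scores, `total`, `zero_energy`,
#'   and one `met_*` flag per component.
#' @export
score_cohort <- function(summaries, config = default_scoring_config()) {
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    sc <- score_record(summaries[i, ], config)
    c(list(participant_id = summaries$participant_id[i],
           sex = summaries$sex[i]),
      as.list(sc$components),
      sc$subscores,
      list(total = sc$total, zero_energy = sc$zero_energy),
      setNames(as.list(sc$met), paste0("met_", names(sc$met))))
  })
  dplyr::bind_rows(rows)
}

#' Names of the 11 HEIFA components
#'
#' @return Character vector, in reporting order.
#' @export
heifa_components <- function() {
  c("vegetables", "fruit", "grains", "meat_alt", "dairy_alt",
    "discretionary", "fat", "sodium", "sugars", "water", "alcohol")
}
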