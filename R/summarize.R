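#' Summarise FFQ intakes per participant
#'
#' Converts per-item gram amounts into the per-participant food-group and
#' nutrient summary the HEIFA rubric scores: grams/day, serves/day and
#' percent of energy per food group; the wholegrain proportion of grain
#' intake and low-fat proportion of dairy intake (gram basis); discretionary,
#' macronutrient and alcohol percent of energy; sodium (mg/day), alcohol
#' ethanol (g/day) and fibre (g/day); the proportion of total beverage volume
#' that is water; and the sets of vegetable and fruit subgroups consumed at
#' least once per week (the variety criterion).
#'
#' All quantities are linear in the reported amounts. For a record with zero
#' FFQ energy the percent-of-energy fields are `NA` and `zero_energy` is
#' `TRUE`; downstream scoring treats such degenerate records explicitly
#' rather than propagating `NaN`.
#'
#' The single-item weekly SSB response enters only the beverage-volume
#' denominator (as mL/day); it is not part of the FFQ nutrient model.
#'
#' @param cohort A cohort tibble ([load_cohort()] / [generate_cohort()]);
#'   one row per participant.
#' @param composition A composition tibble.
#' @param config A scoring configuration (for energy conversion factors and
#'   the variety threshold).
#' @return A tibble with one row per participant.
#' @export
summarize_intake <- function(cohort, composition,
                             config = default_scoring_config()) {
  amounts <- cohort_amounts(cohort)
  ids <- colnames(amounts)
  unknown <- setdiff(ids, composition$food_id)
  if (length(unknown)) {
    abort(paste0("Amount column(s) reference unknown food_id(s): ",
                 paste(unknown, collapse = ", ")),
          class = "dietq_reference_error")
  }
  comp <- composition[match(ids, composition$food_id), ]
  ef <- config$energy_factors
  n <- nrow(cohort)

  per_g <- function(col) as.numeric(amounts %*% (comp[[col]] / 100))
  energy_kj <- per_g("energy_kj")
  nutrients <- list(
    protein_g = per_g("protein_g"), fat_g = per_g("fat_g"),
    sat_fat_g = per_g("sat_fat_g"), mono_g = per_g("mono_g"),
    poly_g = per_g("poly_g"), carb_g = per_g("carb_g"),
    sugars_g = per_g("sugars_g"), starch_g = per_g("starch_g"),
    fiber_g = per_g("fiber_g"), sodium_mg = per_g("sodium_mg"),
    alcohol_g = per_g("alcohol_g")
  )

  group_mat <- function(values) {
    # items x groups indicator weighted by `values` (per-gram quantities)
    vapply(FOOD_GROUPS, function(g) {
      as.numeric(amounts %*% (values * (comp$group == g)))
    }, numeric(n))
  }
  gmat <- group_mat(rep(1, length(ids)))                # g/day
  smat <- group_mat(1 / comp$serve_size_g)              # serves/day
  emat <- group_mat(comp$energy_kj / 100)               # kJ/day
  if (n == 1) { gmat <- rbind(gmat); smat <- rbind(smat); emat <- rbind(emat) }

  pct_e <- function(kj) ifelse(energy_kj > 0, 100 * kj / energy_kj, NA_real_)
  macro_pct <- function(g, factor) pct_e(g * factor)

  wholegrain_g <- as.numeric(
    amounts %*% as.numeric(comp$group == "grains" & comp$is_wholegrain %in% TRUE))
  lowfat_g <- as.numeric(
    amounts %*% as.numeric(comp$group == "dairy_alt" & comp$is_low_fat %in% TRUE))
  grains_g <- gmat[, "grains"]
  dairy_g <- gmat[, "dairy_alt"]

  # beverage volumes (mL/day): survey water + FFQ beverages via density,
  # plus the single-item SSB response scaled to a day
  vol_of <- function(group) {
    dens <- ifelse(is.na(comp$density_g_ml), 1, comp$density_g_ml)
    as.numeric(amounts %*% ((comp$group == group) / dens))
  }
  water_ml <- ifelse(is.na(cohort$water_ml_per_day), 0,
                     cohort$water_ml_per_day) + vol_of("beverage_water")
  ssb_ml_day <- ifelse(is.na(cohort$ssb_ml_per_week), 0,
                       cohort$ssb_ml_per_week) / 7
  other_ml <- vol_of("beverage_ssb") + vol_of("beverage_other") +
    vol_of("alcohol_bev")
  beverage_ml <- water_ml + ssb_ml_day + other_ml
  water_prop <- ifelse(beverage_ml > 0, water_ml / beverage_ml, 0)

  # variety: subgroups consumed >= min_serves_per_week serves per week
  min_daily <- config$variety$min_serves_per_week / 7
  subgroup_sets <- function(group) {
    in_grp <- comp$group == group
    sgs <- unique(comp$subgroup[in_grp & !is.na(comp$subgroup)])
    lapply(seq_len(n), function(i) {
      serves_sg <- vapply(sgs, function(sg) {
        sel <- in_grp & comp$subgroup %in% sg
        sum(amounts[i, sel] / comp$serve_size_g[sel])
      }, numeric(1))
      sgs[serves_sg >= min_daily]
    })
  }

  out <- tibble::tibble(
    participant_id = cohort$participant_id,
    sex = cohort$sex,
    energy_kj = energy_kj,
    energy_kcal = energy_kj / config$kj_per_kcal,
    zero_energy = energy_kj <= 0
  )
  for (g in FOOD_GROUPS) {
    out[[paste0(g, "_g")]] <- gmat[, g]
    out[[paste0(g, "_serves")]] <- smat[, g]
    out[[paste0(g, "_pct_e")]] <- pct_e(emat[, g])
  }
  out$wholegrain_g <- wholegrain_g
  out$wholegrain_prop <- ifelse(grains_g > 0, wholegrain_g / grains_g, 0)
  out$lowfat_dairy_g <- lowfat_g
  out$lowfat_prop <- ifelse(dairy_g > 0, lowfat_g / dairy_g, 0)
  out$protein_pct_e <- macro_pct(nutrients$protein_g, ef$protein)
  out$fat_pct_e <- macro_pct(nutrients$fat_g, ef$fat)
  out$sat_fat_pct_e <- macro_pct(nutrients$sat_fat_g, ef$fat)
  out$mono_pct_e <- macro_pct(nutrients$mono_g, ef$fat)
  out$poly_pct_e <- macro_pct(nutrients$poly_g, ef$fat)
  out$carb_pct_e <- macro_pct(nutrients$carb_g, ef$carbohydrate)
  out$sugars_pct_e <- macro_pct(nutrients$sugars_g, ef$carbohydrate)
  out$starch_pct_e <- macro_pct(nutrients$starch_g, ef$carbohydrate)
  out$alcohol_g <- nutrients$alcohol_g
  out$alcohol_pct_e <- macro_pct(nutrients$alcohol_g, ef$alcohol)
  out$sodium_mg <- nutrients$sodium_mg
  out$fiber_g <- nutrients$fiber_g
  out$water_ml <- water_ml
  out$ssb_ml_day <- ssb_ml_day
  out$beverage_ml <- beverage_ml
  out$water_prop <- water_prop
  out$veg_subgroups <- subgroup_sets("vegetables")
  out$fruit_subgroups <- subgroup_sets("fruit")
  out
}
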