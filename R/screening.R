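#' Schofield basal metabolic rate
#'
#' Predicts basal metabolic rate (BMR, MJ/day) from body weight using the
#' weight-only Schofield (1985) equations for the adult age bands that cover
#' a young-adult cohort:
#'
#' | sex    | 18-29 y            | 30-59 y            |
#' |--------|--------------------|--------------------|
#' | male   | 0.063 w + 2.896    | 0.048 w + 3.653    |
#' | female | 0.062 w + 2.036    | 0.034 w + 3.538    |
#'
#' Age bands are half-open: age 30 falls in the 30-59 band. Ages below 18 or
#' at or above 60 are outside the supported bands and raise an error.
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @param age Age in completed years.
#' @param weight Body weight in kg (> 0).
#' @param coefficients Optional override: a list
#'   `list(male = list(young = c(slope, intercept), older = ...), female = ...)`.
#' @return BMR in MJ/day.
#' @export
#' @examples
#' schofield_bmr("male", 25, 80)    # 7.936
#' schofield_bmr("female", 32, 65)  # 5.748
schofield_bmr <- function(sex, age, weight, coefficients = NULL) {
  n <- max(length(sex), length(age), length(weight))
  sex <- rep_len(sex, n); age <- rep_len(age, n); weight <- rep_len(weight, n)
  if (any(!sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'", class = "dietq_domain_error")
  }
  if (any(weight <= 0)) {
    abort("weight must be > 0", class = "dietq_domain_error")
  }
  if (any(age < 18 | age >= 60)) {
    abort("age outside the supported Schofield bands [18, 60)",
          class = "dietq_domain_error")
  }
  co <- coefficients %||% list(
    male   = list(young = c(0.063, 2.896), older = c(0.048, 3.653)),
    female = list(young = c(0.062, 2.036), older = c(0.034, 3.538))
  )
  band <- ifelse(age < 30, "young", "older")
  vapply(seq_len(n), function(i) {
    cf <- co[[sex[i]]][[band[i]]]
    cf[1] * weight[i] + cf[2]
  }, numeric(1))
}

#' Classify a reporter by energy-intake to BMR ratio
#'
#' Implements the fixed Goldberg-type plausibility screen: reported energy
#' intake divided by predicted BMR, with exclusion below 0.5 or above 2.0.
#' The inequalities are strict, so ratios of exactly 0.5 or 2.0 are retained.
#'
#' @param energy_kcal Reported energy intake, kcal/day.
#' @param bmr BMR in MJ/day (> 0).
#' @param lower,upper Exclusion cut-offs on the ratio (defaults 0.5 and 2.0).
#' @param kj_per_kcal kJ per kcal (default 4.184).
#' @return A tibble with columns `energy_kcal`, `energy_kj`, `bmr`, `ei_bmr`
#'   and `status` (`included`, `excluded_under` or `excluded_over`).
#' @export
classify_reporter <- function(energy_kcal, bmr, lower = 0.5, upper = 2.0,
                              kj_per_kcal = 4.184) {
  if (any(bmr <= 0)) {
    abort("bmr must be > 0", class = "dietq_domain_error")
  }
  if (any(energy_kcal < 0)) {
    abort("energy intake must be >= 0", class = "dietq_domain_error")
  }
  energy_kj <- energy_kcal * kj_per_kcal
  ei_bmr <- (energy_kj / 1000) / bmr
  status <- ifelse(ei_bmr < lower, "excluded_under",
                   ifelse(ei_bmr > upper, "excluded_over", "included"))
  tibble::tibble(energy_kcal = energy_kcal, energy_kj = energy_kj,
                 bmr = bmr, ei_bmr = ei_bmr, status = status)
}

#' Apply the pre-scoring exclusion rules to a cohort
#'
#' Screens a cohort before diet-quality scoring, in order of precedence:
#' records flagged incomplete are excluded first; the remainder are screened
#' on the energy-intake/BMR ratio (exclusion when the ratio is strictly below
#' `lower` or strictly above `upper`). Energy intake is computed from the FFQ
#' amounts and the composition table; the single-item SSB response does not
#' contribute (it is not part of the FFQ nutrient model).
#'
#' @param cohort A cohort tibble from [load_cohort()] or [generate_cohort()].
#' @param composition A composition tibble.
#' @param lower,upper Ratio cut-offs (defaults 0.5, 2.0).
#' @param kj_per_kcal kJ per kcal.
#' @return A list with `included` (the retained cohort tibble) and `log`
#'   (one row per input participant: `participant_id`, `bmr`, `energy_kj`,
#'   `energy_kcal`, `ei_bmr`, `status`, `reason`).
#' @export
apply_exclusions <- function(cohort, composition, lower = 0.5, upper = 2.0,
                             kj_per_kcal = 4.184) {
  if (nrow(cohort) == 0) {
    log <- tibble::tibble(participant_id = character(), bmr = numeric(),
                          energy_kj = numeric(), energy_kcal = numeric(),
                          ei_bmr = numeric(), status = character(),
                          reason = character())
    return(list(included = cohort, log = log))
  }
  amounts <- cohort_amounts(cohort)
  e100 <- setNames(composition$energy_kj, composition$food_id)
  energy_kj <- as.numeric(amounts %*% (e100[colnames(amounts)] / 100))
  energy_kcal <- energy_kj / kj_per_kcal

  ok_profile <- !is.na(cohort$sex) & !is.na(cohort$age) &
    !is.na(cohort$weight_kg) & cohort$complete
  bmr <- rep(NA_real_, nrow(cohort))
  if (any(ok_profile)) {
    bmr[ok_profile] <- schofield_bmr(cohort$sex[ok_profile],
                                     cohort$age[ok_profile],
                                     cohort$weight_kg[ok_profile])
  }
  ei_bmr <- (energy_kj / 1000) / bmr

  status <- character(nrow(cohort))
  reason <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    if (!isTRUE(cohort$complete[i])) {
      status[i] <- "excluded_incomplete"
      reason[i] <- "incomplete baseline record"
    } else if (ei_bmr[i] < lower) {
      status[i] <- "excluded_under"
      reason[i] <- sprintf("EI/BMR %.3f < %.2f (underreporter)",
                           ei_bmr[i], lower)
    } else if (ei_bmr[i] > upper) {
      status[i] <- "excluded_over"
      reason[i] <- sprintf("EI/BMR %.3f > %.2f (overreporter)",
                           ei_bmr[i], upper)
    } else {
      status[i] <- "included"
      reason[i] <- ""
    }
  }
  log <- tibble::tibble(
    participant_id = cohort$participant_id,
    bmr = bmr, energy_kj = energy_kj, energy_kcal = energy_kcal,
    ei_bmr = ei_bmr, status = status, reason = reason
  )
  list(included = cohort[status == "included", , drop = FALSE], log = log)
}
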