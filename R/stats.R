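#' Assign diet-quality quartiles
#'
#' Rank-based split of a scored cohort into four ordered groups: Q1 holds
#' the lowest scores (diet least consistent with the guidelines), Q4 the
#' highest. Group sizes are as equal as `n` permits (they differ by at most
#' one; when `n` is not divisible by 4 the extra members go to Q2/Q4 by the
#' `floor(n * k / 4)` boundary rule). Ties are broken by stable input order.
#'
#' @param scores A tibble with columns `participant_id` and `total` (e.g.
#'   from [score_cohort()]).
#' @return A tibble `participant_id`, `total`, `quartile` (ordered factor
#'   `Q1` < ... < `Q4`).
#' @export
assign_quartiles <- function(scores) {
  n <- nrow(scores)
  if (n < 4) {
    abort("At least 4 participants are required for quartiles",
          class = "dietq_domain_error")
  }
  ord <- order(scores$total)  # stable: ties keep input order
  boundaries <- floor(n * (0:4) / 4)
  sizes <- diff(boundaries)
  q <- rep(paste0("Q", 1:4), times = sizes)
  out <- tibble::tibble(
    participant_id = scores$participant_id,
    total = scores$total,
    quartile = factor(NA, levels = paste0("Q", 1:4), ordered = TRUE)
  )
  out$quartile[ord] <- q
  out
}

#' Linear trend across quartiles
#'
#' Tests for a linear trend in a per-participant quantity across the four
#' ordered diet-quality groups, as a polynomial one-way ANOVA linear
#' contrast. Two routes are provided:
#'
#' * `"ols"` (default): least-squares regression of the value on the
#'   quartile index 1-4; the slope t-test. Handles unequal group sizes.
#' * `"contrast"`: the orthogonal linear contrast `(-3, -1, 1, 3)` on the
#'   group means, computed entirely from closed forms (no model fit), with
#'   the error mean square taken around the fitted trend line on `N - 2`
#'   degrees of freedom. With equal group sizes this route gives t
#'   statistics and p-values identical to the OLS slope test; under
#'   imbalance it weights the group means equally, whereas OLS weights by
#'   group size.
#'
#' @param values Numeric vector, one value per participant.
#' @param quartiles Factor/character of quartile labels `Q1`-`Q4`, aligned
#'   with `values`.
#' @param method `"ols"` or `"contrast"`.
#' @return A tibble: `estimate` (slope per quartile step, or the contrast
#'   value), `se`, `statistic`, `df`, `p`, `method`.
#' @export
trend_by_quartile <- function(values, quartiles, method = c("ols", "contrast")) {
  method <- match.arg(method)
  quartiles <- factor(as.character(quartiles), levels = paste0("Q", 1:4))
  if (anyNA(quartiles)) {
    abort("quartiles must be labelled Q1..Q4", class = "dietq_domain_error")
  }
  counts <- table(quartiles)
  if (any(counts == 0)) {
    abort("Every quartile must be non-empty", class = "dietq_domain_error")
  }
  if (method == "ols") {
    idx <- as.integer(quartiles)
    fit <- summary(lm(values ~ idx))
    co <- fit$coefficients["idx", ]
    tibble::tibble(estimate = co[["Estimate"]], se = co[["Std. Error"]],
                   statistic = co[["t value"]], df = fit$df[2],
                   p = co[["Pr(>|t|)"]], method = "ols")
  } else {
    coefs <- c(-3, -1, 1, 3)
    means <- tapply(values, quartiles, mean)
    ns <- as.numeric(counts)
    n_tot <- sum(ns)
    est <- sum(coefs * means)
    ss_trend <- est^2 / sum(coefs^2 / ns)
    ss_total <- sum((values - mean(values))^2)
    df <- n_tot - 2
    mse <- (ss_total - ss_trend) / df  # error around the fitted trend line
    se <- sqrt(mse * sum(coefs^2 / ns))
    stat <- est / se
    tibble::tibble(estimate = est, se = se, statistic = stat, df = df,
                   p = 2 * pt(abs(stat), df, lower.tail = FALSE),
                   method = "contrast")
  }
}

#' Gender comparison table
#'
#' For the HEIFA total and each of the 11 components: mean (SD) by sex, the
#' number and percentage meeting the guideline by sex, a two-sample t test
#' on the component score (Welch by default; set `var_equal = TRUE` for the
#' pooled-variance variant) and a Pearson chi-square test (no continuity
#' correction by default) on the met-guideline proportions.
#'
#' @param scores Output of [score_cohort()]; must contain both sexes.
#' @param var_equal Pooled-variance t test instead of Welch.
#' @param correct Apply the Yates continuity correction to the chi-square.
#' @return A tibble, one row per component plus a `total` row (no met-flag
#'   test for the total).
#' @export
compare_genders <- function(scores, var_equal = FALSE, correct = FALSE) {
  sexes <- unique(scores$sex)
  if (!all(c("male", "female") %in% sexes)) {
    abort("Both sexes must be present for a gender comparison",
          class = "dietq_domain_error")
  }
  male <- scores[scores$sex == "male", ]
  female <- scores[scores$sex == "female", ]
  row_for <- function(comp) {
    xm <- male[[comp]]; xf <- female[[comp]]
    tt <- stats::t.test(xm, xf, var.equal = var_equal)
    met_col <- paste0("met_", comp)
    if (comp != "total" && met_col %in% names(scores)) {
      mm <- sum(male[[met_col]]); mf <- sum(female[[met_col]])
      tab <- rbind(c(mm, nrow(male) - mm), c(mf, nrow(female) - mf))
      cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      chisq <- unname(cs$statistic); chisq_p <- cs$p.value
    } else {
      mm <- NA_integer_; mf <- NA_integer_
      chisq <- NA_real_; chisq_p <- NA_real_
    }
    tibble::tibble(
      component = comp,
      male_mean = mean(xm), male_sd = sd(xm),
      female_mean = mean(xf), female_sd = sd(xf),
      male_met_n = mm, male_met_pct = 100 * mm / nrow(male),
      female_met_n = mf, female_met_pct = 100 * mf / nrow(female),
      t_statistic = unname(tt$statistic), t_p = tt$p.value,
      chisq_statistic = chisq, chisq_p = chisq_p
    )
  }
  dplyr::bind_rows(lapply(c(heifa_components(), "total"), row_for))
}

#' Tally guideline attainment
#'
#' Counts (and percentages, to one decimal) of participants attaining the
#' maximum-score criterion on each of the 11 components.
#'
#' @param scores Output of [score_cohort()].
#' @return A tibble `component`, `met_n`, `met_pct`.
#' @export
tally_guidelines <- function(scores) {
  n <- nrow(scores)
  rows <- lapply(heifa_components(), function(comp) {
    met <- sum(scores[[paste0("met_", comp)]])
    tibble::tibble(component = comp, met_n = met,
                   met_pct = if (n > 0) round(100 * met / n, 1) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Regress diet quality on reported behaviours
#'
#' Simple (one predictor at a time) ordinary least-squares regressions of
#' the HEIFA total on weekly sugar-sweetened-beverage volume (mL/week) and
#' on the takeaway frequency category coded ordinally 0-3
#' (`0-1` -> 0, ..., `6+` -> 3). Records with a missing predictor are
#' dropped from that regression.
#'
#' @param scores Output of [score_cohort()].
#' @param cohort The matching cohort tibble (for the behaviour variables).
#' @return A tibble, one row per predictor: `predictor`, `slope`, `se`,
#'   `statistic`, `p`, `n`.
#' @export
regress_behavior <- function(scores, cohort) {
  merged <- dplyr::inner_join(
    scores[, c("participant_id", "total")],
    cohort[, c("participant_id", "ssb_ml_per_week", "takeaway_per_week")],
    by = "participant_id"
  )
  merged$takeaway_ordinal <-
    as.numeric(factor(merged$takeaway_per_week, levels = TAKEAWAY_LEVELS)) - 1
  one <- function(predictor, x) {
    keep <- !is.na(x) & !is.na(merged$total)
    x <- x[keep]; y <- merged$total[keep]
    if (length(unique(x)) < 2) {
      abort(sprintf("Predictor '%s' has no variance", predictor),
            class = "dietq_domain_error")
    }
    fit <- summary(lm(y ~ x))
    co <- fit$coefficients["x", ]
    tibble::tibble(predictor = predictor, slope = co[["Estimate"]],
                   se = co[["Std. Error"]], statistic = co[["t value"]],
                   p = co[["Pr(>|t|)"]], n = length(x))
  }
  dplyr::bind_rows(
    one("ssb_ml_per_week", merged$ssb_ml_per_week),
    one("takeaway_ordinal", merged$takeaway_ordinal)
  )
}

#' Compare cohort means with reference-population constants
#'
#' Side-by-side cohort mean (SD) versus the reference constant for every
#' reference key that matches a numeric column of the intake-summary table
#' (e.g. `vegetables_g`, `sugars_pct_e`, `fiber_g`). No inferential test is
#' performed — the reference values are population constants without
#' dispersion. Keys with no matching column are dropped with a warning.
#'
#' @param summaries Output of [summarize_intake()].
#' @param reference A reference list ([default_reference_values()] /
#'   [load_reference_values()]).
#' @return A tibble `key`, `cohort_mean`, `cohort_sd`, `reference_value`,
#'   `difference`, `units`, `source`.
#' @export
compare_to_reference <- function(summaries, reference = default_reference_values()) {
  if (length(reference) == 0) {
    warn("Empty reference set; returning an empty comparison table")
    return(tibble::tibble(key = character(), cohort_mean = numeric(),
                          cohort_sd = numeric(), reference_value = numeric(),
                          difference = numeric(), units = character(),
                          source = character()))
  }
  rows <- list()
  for (key in names(reference)) {
    if (!key %in% names(summaries)) {
      warn(paste0("Reference key '", key,
                  "' has no matching cohort column; row omitted"))
      next
    }
    x <- summaries[[key]]
    m <- mean(x, na.rm = TRUE)
    rows[[key]] <- tibble::tibble(
      key = key, cohort_mean = m, cohort_sd = sd(x, na.rm = TRUE),
      reference_value = reference[[key]]$value,
      difference = m - reference[[key]]$value,
      units = reference[[key]]$units %||% NA_character_,
      source = reference[[key]]$source %||% NA_character_
    )
  }
  dplyr::bind_rows(rows)
}

#' Quartile profile table
#'
#' Per-quartile mean (SD) of the HEIFA total, energy and the main food-group
#' and behaviour quantities, with the linear-trend p-value for each row
#' (the total itself defines the ordering and is reported without a test).
#'
#' @param scores Output of [score_cohort()].
#' @param summaries Output of [summarize_intake()].
#' @param cohort The cohort tibble (for SSB volume).
#' @return A tibble, one row per quantity, with `Q1_mean` .. `Q4_sd` and
#'   `trend_p` columns.
#' @export
quartile_profile <- function(scores, summaries, cohort) {
  qt <- assign_quartiles(scores)
  merged <- dplyr::inner_join(qt, summaries, by = "participant_id")
  merged <- dplyr::inner_join(
    merged, cohort[, c("participant_id", "ssb_ml_per_week")],
    by = "participant_id")
  vars <- c(
    heifa_total = "total", energy_kcal = "energy_kcal",
    vegetables_g = "vegetables_g", fruit_g = "fruit_g",
    grains_g = "grains_g", wholegrain_g = "wholegrain_g",
    meat_alt_g = "meat_alt_g", dairy_alt_g = "dairy_alt_g",
    lowfat_dairy_g = "lowfat_dairy_g", discretionary_g = "discretionary_g",
    ssb_ml_per_week = "ssb_ml_per_week", sodium_mg = "sodium_mg",
    fiber_g = "fiber_g"
  )
  rows <- lapply(names(vars), function(nm) {
    x <- merged[[vars[[nm]]]]
    row <- tibble::tibble(quantity = nm)
    for (q in paste0("Q", 1:4)) {
      sel <- merged$quartile == q
      row[[paste0(q, "_mean")]] <- mean(x[sel])
      row[[paste0(q, "_sd")]] <- sd(x[sel])
    }
    row$trend_p <- if (nm == "heifa_total") NA_real_ else
      trend_by_quartile(x, merged$quartile)$p
    row
  })
  dplyr::bind_rows(rows)
}
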