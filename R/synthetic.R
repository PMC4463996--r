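#' Simulation parameters for a synthetic FFQ cohort
#'
#' Builds the parameter set for [generate_cohort()]. The defaults emulate an
#' overweight young-adult cohort enrolling in a lifestyle program: n = 230
#' with 141 females and 89 males; ages 18-35; BMI lognormal with arithmetic
#' mean 27.2 and SD 2.5 kg/m^2; right-skewed (lognormal) sex-specific
#' food-group intakes with means seeded from the observed group means of
#' such cohorts (e.g. vegetables ~117 g/day, fruit ~210 g/day); a latent
#' diet-quality propensity that raises core-food and lowers discretionary
#' and alcohol intake; a configurable fraction of energy misreporters whose
#' amounts are rescaled to land the EI/BMR ratio in the exclusion tails; and
#' negative associations between the propensity and both weekly
#' sugar-sweetened-beverage volume and the ordinal takeaway category
#' (ordered-logit sampling).
#'
#' Group intakes are parameterised by their *arithmetic mean* (g/day) and a
#' geometric SD, so configured means are recovered by sample means.
#'
#' @param n Number of participants.
#' @param seed Integer seed; fixed seed implies identical output
#'   (R's default Mersenne-Twister generator).
#' @param female_fraction Proportion female (default 141/230).
#' @param age_range Inclusive integer age range.
#' @param bmi_mean,bmi_sd Arithmetic mean and SD of the BMI lognormal.
#' @param group_intake Named list per food group:
#'   `list(mean_g = list(male=, female=), gsd = )`. A group with zero mean is
#'   generated as zero intake. Within each participant, group totals also
#'   scale with relative BMR (heavier people eat more) and with a shared
#'   "appetite" factor, both mean-preserving, so reported energy tracks
#'   energy requirement and the plausibility screen excludes few natural
#'   reporters.
#' @param appetite_gsd Geometric SD of the shared per-person intake factor.
#' @param quality_effect Named vector: per-group multiplicative tilt
#'   (per SD of the latent propensity, mean-preserving).
#' @param wholegrain_share,lowfat_share Baseline within-group share routed to
#'   wholegrain grain items / low-fat dairy items, with a logit tilt on the
#'   propensity.
#' @param water Water intake model: mean mL/day, geometric SD, tilt.
#' @param ssb SSB model: `zero_prob` (never-consumers), sex-specific mean
#'   mL/week among consumers scaled from the overall mean, geometric SD, and
#'   `effect` — the slope of log-SSB on the latent propensity (negative
#'   default).
#' @param takeaway Takeaway model: baseline category probabilities for
#'   `0-1`, `2-3`, `4-5`, `6+` and `effect`, the ordered-logit slope on the
#'   propensity (negative default).
#' @param misreport_fraction Fraction with EI/BMR forced outside the
#'   plausibility window (default 15/230).
#' @param incomplete_fraction Fraction with an incomplete baseline record
#'   (default 2/230).
#' @return A validated parameter list of class `dietq_sim_params`.
#' @export
simulation_params <- function(
    n = 230,
    seed = 1L,
    female_fraction = 141 / 230,
    age_range = c(18L, 35L),
    bmi_mean = 27.2,
    bmi_sd = 2.5,
    group_intake = list(
      vegetables     = list(mean_g = list(male = 119.8, female = 115.0), gsd = 1.6),
      fruit          = list(mean_g = list(male = 228.3, female = 197.0), gsd = 1.7),
      grains         = list(mean_g = list(male = 272.6, female = 223.5), gsd = 1.5),
      meat_alt       = list(mean_g = list(male = 233.7, female = 162.5), gsd = 1.5),
      dairy_alt      = list(mean_g = list(male = 335.8, female = 338.2), gsd = 1.5),
      discretionary  = list(mean_g = list(male = 70,    female = 62),    gsd = 1.7),
      beverage_water = list(mean_g = list(male = 250,   female = 250),   gsd = 1.8),
      beverage_ssb   = list(mean_g = list(male = 0,     female = 0),     gsd = 1.8),
      beverage_other = list(mean_g = list(male = 150,   female = 100),   gsd = 2.0),
      alcohol_bev    = list(mean_g = list(male = 420,   female = 240),   gsd = 2.0)
    ),
    appetite_gsd = 1.15,
    quality_effect = c(
      vegetables = 0.4, fruit = 0.4, grains = 0.3, meat_alt = 0.1,
      dairy_alt = 0.1, discretionary = -0.4, beverage_water = 0.2,
      beverage_ssb = 0, beverage_other = 0, alcohol_bev = -0.3
    ),
    wholegrain_share = list(base = 0.37, tilt = 0.8),
    lowfat_share = list(base = 0.5, tilt = 0.5),
    water = list(mean_ml = 1200, gsd = 1.6, tilt = 0.3),
    ssb = list(zero_prob = 0.235,
               mean_ml_per_week = list(male = 500, female = 475),
               gsd = 2.2, effect = -0.6),
    takeaway = list(base_probs = c(0.41, 0.46, 0.12, 0.01), effect = -0.8),
    misreport_fraction = 15 / 230,
    incomplete_fraction = 2 / 230) {
  params <- list(
    n = as.integer(n), seed = as.integer(seed),
    female_fraction = female_fraction, age_range = as.integer(age_range),
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, group_intake = group_intake,
    appetite_gsd = appetite_gsd, quality_effect = quality_effect,
    wholegrain_share = wholegrain_share, lowfat_share = lowfat_share,
    water = water, ssb = ssb, takeaway = takeaway,
    misreport_fraction = misreport_fraction,
    incomplete_fraction = incomplete_fraction
  )
  props <- c(female_fraction, misreport_fraction, incomplete_fraction,
             ssb$zero_prob)
  if (any(props < 0 | props > 1)) {
    abort("Proportions must lie in [0, 1]", class = "dietq_config_error")
  }
  if (params$n < 0) abort("n must be >= 0", class = "dietq_config_error")
  if (bmi_mean <= 0 || bmi_sd <= 0 || water$mean_ml < 0) {
    abort("Scale parameters must be > 0", class = "dietq_config_error")
  }
  for (g in names(group_intake)) {
    gi <- group_intake[[g]]
    if (any(unlist(gi$mean_g) < 0) || gi$gsd <= 1) {
      abort(sprintf("group_intake$%s: means must be >= 0 and gsd > 1", g),
            class = "dietq_config_error")
    }
  }
  if (appetite_gsd < 1) {
    abort("appetite_gsd must be >= 1", class = "dietq_config_error")
  }
  if (abs(sum(params$takeaway$base_probs) - 1) > 1e-9) {
    abort("takeaway$base_probs must sum to 1", class = "dietq_config_error")
  }
  structure(params, class = "dietq_sim_params")
}

# lognormal parameterised by arithmetic mean and geometric SD, with a
# mean-preserving multiplicative tilt on the latent propensity z
rlnorm_mean <- function(n, mean, gsd, tilt = 0, z = 0) {
  sdlog <- log(gsd)
  meanlog <- log(mean) - sdlog^2 / 2 + tilt * z - tilt^2 / 2
  rlnorm(n, meanlog, sdlog)
}

# one Dirichlet weight vector per row; expected weights follow `shares`
# (serve sizes, so bigger-serve items carry more grams), with concentration
# `conc` per item controlling person-to-person sparsity
dirichlet_weights <- function(n, shares, conc = 0.8) {
  k <- length(shares)
  alpha <- conc * k * shares / sum(shares)
  w <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  w / rowSums(w)
}

#' Generate a synthetic FFQ cohort
#'
#' Simulates `params$n` participant records against a composition table.
#' Group totals are drawn from sex-specific lognormals tilted by a latent
#' diet-quality propensity, split across the group's items with Dirichlet
#' weights (grain and dairy totals are first routed to wholegrain / low-fat
#' items according to a logit-tilted share). Misreporters are created by
#' rescaling all FFQ amounts so the EI/BMR ratio lands in (0, 0.4] or
#' [2.1, 3]; incomplete records lack the takeaway response.
#'
#' The latent propensity is returned as attribute `"latent_propensity"`.
#'
#' @param params A [simulation_params()] object.
#' @param composition A composition tibble; every group with a positive
#'   configured mean must have at least one item.
#' @return A cohort tibble (see [cohort]) with one `g_<food_id>` column per
#'   composition item.
#' @export
generate_cohort <- function(params, composition) {
  stopifnot(inherits(params, "dietq_sim_params"))
  used <- names(params$group_intake)[vapply(params$group_intake, function(gi) {
    any(unlist(gi$mean_g) > 0)
  }, logical(1))]
  missing <- setdiff(used, unique(composition$group))
  if (length(missing)) {
    abort(paste0("Composition table has no items for configured group(s): ",
                 paste(missing, collapse = ", ")),
          class = "dietq_config_error")
  }
  n <- params$n
  ids <- composition$food_id
  empty <- tibble::tibble(
    participant_id = character(), sex = character(), age = integer(),
    weight_kg = numeric(), height_m = numeric(), ssb_ml_per_week = numeric(),
    takeaway_per_week = character(), water_ml_per_day = numeric(),
    complete = logical()
  )
  for (id in ids) empty[[paste0("g_", id)]] <- numeric()
  if (n == 0) {
    return(structure(empty, latent_propensity = numeric()))
  }

  withr::with_seed(params$seed, {
    sex <- ifelse(runif(n) < params$female_fraction, "female", "male")
    age <- sample(seq(params$age_range[1], params$age_range[2]), n,
                  replace = TRUE)
    cv <- params$bmi_sd / params$bmi_mean
    sdlog <- sqrt(log(1 + cv^2))
    bmi <- rlnorm(n, log(params$bmi_mean) - sdlog^2 / 2, sdlog)
    height <- ifelse(sex == "female", rnorm(n, 1.64, 0.065),
                     rnorm(n, 1.78, 0.07))
    weight <- bmi * height^2
    z <- rnorm(n)

    # mean-preserving per-person scale: relative BMR x shared appetite factor
    bmr <- schofield_bmr(sex, age, weight)
    rel_bmr <- bmr / stats::ave(bmr, sex)
    a_sd <- log(params$appetite_gsd)
    appetite <- exp(rnorm(n, -a_sd^2 / 2, a_sd))
    person_scale <- rel_bmr * appetite

    amounts <- matrix(0, nrow = n, ncol = length(ids),
                      dimnames = list(NULL, ids))
    for (g in names(params$group_intake)) {
      gi <- params$group_intake[[g]]
      m <- ifelse(sex == "female", gi$mean_g$female, gi$mean_g$male)
      if (all(m == 0)) next
      eff <- params$quality_effect[[g]] %||% 0
      total <- person_scale *
        ifelse(m > 0, rlnorm_mean(n, pmax(m, 1e-12), gi$gsd, eff, z), 0)
      items <- which(composition$group == g)
      if (g %in% c("grains", "dairy_alt")) {
        flag <- if (g == "grains") composition$is_wholegrain else composition$is_low_fat
        share_cfg <- if (g == "grains") params$wholegrain_share else params$lowfat_share
        special <- items[flag[items] %in% TRUE]
        plain <- setdiff(items, special)
        share <- plogis(qlogis(share_cfg$base) + share_cfg$tilt * z)
        if (length(special) == 0) share <- rep(0, n)
        if (length(plain) == 0) share <- rep(1, n)
        for (set in list(list(idx = special, amt = total * share),
                         list(idx = plain, amt = total * (1 - share)))) {
          if (length(set$idx) == 0) next
          w <- dirichlet_weights(n, composition$serve_size_g[set$idx])
          amounts[, set$idx] <- amounts[, set$idx] + w * set$amt
        }
      } else {
        w <- dirichlet_weights(n, composition$serve_size_g[items])
        amounts[, items] <- w * total
      }
    }

    water_ml <- rlnorm_mean(n, params$water$mean_ml, params$water$gsd,
                            params$water$tilt, z)
    ssb_mean <- ifelse(sex == "female", params$ssb$mean_ml_per_week$female,
                       params$ssb$mean_ml_per_week$male)
    ssb_consumer <- runif(n) >= params$ssb$zero_prob
    ssb <- ifelse(ssb_consumer,
                  rlnorm_mean(n, ssb_mean / (1 - params$ssb$zero_prob),
                              params$ssb$gsd, params$ssb$effect, z),
                  0)
    cuts <- qlogis(cumsum(params$takeaway$base_probs)[1:3])
    u <- params$takeaway$effect * z + rlogis(n)
    ta_idx <- 1L + (u > cuts[1]) + (u > cuts[2]) + (u > cuts[3])
    takeaway <- TAKEAWAY_LEVELS[ta_idx]

    # misreporters: rescale all FFQ amounts to force EI/BMR into a tail
    mis <- runif(n) < params$misreport_fraction
    if (any(mis)) {
      e100 <- setNames(composition$energy_kj, composition$food_id)
      energy_kj <- as.numeric(amounts %*% (e100[ids] / 100))
      ratio <- (energy_kj / 1000) / bmr
      for (i in which(mis)) {
        if (ratio[i] <= 0) next
        target <- if (runif(1) < 0.5) runif(1, 0.05, 0.4) else runif(1, 2.1, 3.0)
        amounts[i, ] <- amounts[i, ] * target / ratio[i]
      }
    }

    incomplete <- runif(n) < params$incomplete_fraction
    takeaway[incomplete] <- NA_character_

    cohort <- tibble::tibble(
      participant_id = sprintf("P%04d", seq_len(n)),
      sex = sex, age = age, weight_kg = weight, height_m = height,
      ssb_ml_per_week = ssb, takeaway_per_week = takeaway,
      water_ml_per_day = water_ml, complete = !incomplete
    )
    for (id in ids) cohort[[paste0("g_", id)]] <- amounts[, id]
    structure(cohort, latent_propensity = z)
  })
}

#' Deterministic archetype diets
#'
#' Constructs single-participant records at the two endpoints of the scoring
#' scale, for use as fixtures and end-to-end checks:
#'
#' * `"perfect"` meets every component criterion — all quantity targets
#'   (with a 2% margin so floating-point never undercuts a target), at least
#'   one weekly serve of every configured vegetable and fruit subgroup, 100%
#'   wholegrain grains and low-fat dairy, all moderation nutrients at or
#'   below their full-score cuts, zero discretionary energy, zero alcohol,
#'   and water as the only beverage — and therefore scores exactly 100.
#'   Remaining quantity beyond the variety minima is allocated to the item
#'   in each group with the lowest sugar + saturated-fat + sodium energy
#'   burden.
#' * `"null"` has zero core-food intake, zero water, and discretionary +
#'   spirits amounts pushing every moderation value at or beyond its
#'   zero-score cut, and therefore scores exactly 0.
#'
#' The constructed record is verified by scoring it; if the provided
#' composition items cannot realise the requested endpoint the function
#' fails with an explicit error rather than silently truncating.
#'
#' @param kind `"perfect"` or `"null"`.
#' @param composition A composition tibble covering all variety subgroups in
#'   `config` (for `"perfect"`).
#' @param config A scoring configuration.
#' @param sex Sex of the archetype profile (targets are sex-specific).
#' @return A one-row cohort tibble.
#' @export
#' @examples
#' comp <- load_composition_table(dietq_example("composition_demo.csv"))
#' rec <- generate_archetype("perfect", comp)
#' score_cohort(summarize_intake(rec, comp))$total # 100
generate_archetype <- function(kind = c("perfect", "null"), composition,
                               config = default_scoring_config(),
                               sex = "female") {
  kind <- match.arg(kind)
  ids <- composition$food_id
  amounts <- setNames(numeric(length(ids)), ids)
  ef <- config$energy_factors

  # moderation burden of an item, per kJ: energy share of sugars and
  # saturated fat plus a sodium-density term
  burden <- function(rows) {
    e <- pmax(composition$energy_kj[rows], 1)
    (composition$sugars_g[rows] * ef$carbohydrate +
       composition$sat_fat_g[rows] * ef$fat) / e +
      composition$sodium_mg[rows] / e
  }
  pick_min_burden <- function(rows, what) {
    if (length(rows) == 0) {
      abort(paste0("Composition has no item usable for ", what),
            class = "dietq_config_error")
    }
    rows[which.min(burden(rows))]
  }

  if (kind == "perfect") {
    margin <- 1.02
    # comfortably above the weekly variety threshold, so moderate
    # proportional perturbations of the diet keep every subgroup counted
    min_serves <- 2.2 * config$variety$min_serves_per_week / 7
    for (g in CORE_GROUPS) {
      target <- config$targets[[g]][[sex]] * margin
      rows <- which(composition$group == g)
      if (g == "grains") rows <- rows[composition$is_wholegrain[rows] %in% TRUE]
      if (g == "dairy_alt") rows <- rows[composition$is_low_fat[rows] %in% TRUE]
      variety_cfg <- switch(g, vegetables = config$variety$vegetables,
                            fruit = config$variety$fruit, NULL)
      allocated <- 0
      if (!is.null(variety_cfg)) {
        for (sg in names(variety_cfg$points)) {
          sg_rows <- rows[composition$subgroup[rows] %in% sg]
          if (length(sg_rows) == 0) {
            abort(sprintf(
              "Composition lacks a '%s' item in subgroup '%s' needed for the perfect archetype",
              g, sg), class = "dietq_config_error")
          }
          r <- pick_min_burden(sg_rows, sg)
          amounts[ids[r]] <- amounts[ids[r]] +
            min_serves * composition$serve_size_g[r]
          allocated <- allocated + min_serves
        }
      }
      if (target > allocated) {
        r <- pick_min_burden(rows, paste0(g, " (", sex, " target)"))
        amounts[ids[r]] <- amounts[ids[r]] +
          (target - allocated) * composition$serve_size_g[r]
      }
    }
    water_ml <- 2000; ssb <- 0; takeaway <- "0-1"
  } else {
    disc <- which(composition$group == "discretionary" &
                    composition$sodium_mg > 0)
    alc <- which(composition$group == "alcohol_bev" &
                   composition$alcohol_g > 0)
    if (length(disc) == 0 || length(alc) == 0) {
      abort(paste0("Null archetype needs a sodium-bearing discretionary item ",
                   "and an alcoholic beverage item"),
            class = "dietq_config_error")
    }
    disc <- disc[which.max(composition$sodium_mg[disc])]
    alc <- alc[which.max(composition$alcohol_g[alc])]
    amounts[ids[disc]] <- 1.1 * config$moderation$sodium$zero_cut /
      (composition$sodium_mg[disc] / 100)
    amounts[ids[alc]] <- 1.05 * config$moderation$alcohol$zero_cut /
      (composition$alcohol_g[alc] / 100)
    water_ml <- 0; ssb <- 2000; takeaway <- "6+"
  }

  height <- if (sex == "female") 1.65 else 1.78
  rec <- tibble::tibble(
    participant_id = kind, sex = sex, age = 25L,
    weight_kg = 23 * height^2, height_m = height,
    ssb_ml_per_week = ssb, takeaway_per_week = takeaway,
    water_ml_per_day = water_ml, complete = TRUE
  )
  for (id in ids) rec[[paste0("g_", id)]] <- amounts[[id]]

  sc <- score_record(summarize_intake(rec, composition, config)[1, ], config)
  expected <- if (kind == "perfect") sum(unlist(config$max_points)) else 0
  if (abs(sc$total - expected) > 1e-9) {
    off <- sc$components[abs(sc$components - (if (kind == "perfect")
      unlist(config$max_points)[names(sc$components)] else 0)) > 1e-9]
    abort(sprintf(
      "Cannot realise the %s archetype with the provided items (total %.3f, off-target: %s)",
      kind, sc$total, paste(names(off), collapse = ", ")),
      class = "dietq_config_error")
  }
  rec
}
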