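test_that("quartile assignment splits rank order into near-equal groups", {
  sc <- tibble::tibble(participant_id = paste0("P", 1:8), total = 1:8)
  q <- assign_quartiles(sc)
  expect_equal(as.character(q$quartile[q$total %in% 1:2]), c("Q1", "Q1"))
  expect_equal(as.character(q$quartile[q$total %in% 7:8]), c("Q4", "Q4"))
  # Q1 always holds the minimum score
  expect_equal(min(sc$total),
               min(q$total[q$quartile == "Q1"]))

  # all scores equal: stable input order decides, sizes as equal as possible
  tied <- tibble::tibble(participant_id = paste0("T", 1:10),
                         total = rep(50, 10))
  qt <- assign_quartiles(tied)
  expect_equal(as.integer(table(qt$quartile)), c(2, 3, 2, 3))
  expect_equal(as.character(qt$quartile[1:2]), c("Q1", "Q1"))
  # partition: exhaustive and disjoint
  expect_false(anyNA(qt$quartile))
  expect_equal(sum(table(qt$quartile)), 10)

  expect_error(assign_quartiles(tied[1:3, ]), class = "dietq_domain_error")
})

test_that("the linear trend contrast matches the regression-on-index oracle", {
  withr::with_seed(57, {
    for (i in 1:50) {
      n_per <- sample(5:30, 1)
      vals <- rnorm(4 * n_per, mean = rep(runif(4, 0, 10), each = n_per))
      q <- rep(paste0("Q", 1:4), each = n_per)
      ols <- trend_by_quartile(vals, q, method = "ols")
      con <- trend_by_quartile(vals, q, method = "contrast")
      expect_equal(ols$statistic, con$statistic, tolerance = 1e-6)
      expect_equal(ols$p, con$p, tolerance = 1e-6)
    }
  })
})

test_that("trend inference behaves at the null and under affine maps", {
  # exactly equal group means: estimate 0, p = 1
  vals <- rep(c(1, 9), 20) # every quartile holds five 1s and five 9s
  q <- rep(paste0("Q", 1:4), each = 10)
  res <- trend_by_quartile(vals, q)
  expect_equal(res$estimate, 0)
  expect_equal(res$p, 1, tolerance = 1e-9)

  withr::with_seed(8, vals <- rnorm(40, rep(1:4, each = 10)))
  base <- trend_by_quartile(vals, q)
  shifted <- trend_by_quartile(vals + 100, q)
  expect_equal(shifted$estimate, base$estimate, tolerance = 1e-9)
  expect_equal(shifted$p, base$p, tolerance = 1e-9)
  scaled <- trend_by_quartile(3 * vals, q)
  expect_equal(scaled$estimate, 3 * base$estimate, tolerance = 1e-9)
  expect_equal(scaled$statistic, base$statistic, tolerance = 1e-9)
})

test_that("a quartile pattern like the published score gradient gives p < .001", {
  # group means 34.0 / 42.4 / 48.1 / 56.4 with the printed SDs, 57 per group
  withr::with_seed(12, {
    vals <- c(rnorm(57, 34.0, 4.1), rnorm(57, 42.4, 1.6),
              rnorm(57, 48.1, 2.0), rnorm(57, 56.4, 4.9))
  })
  q <- rep(paste0("Q", 1:4), each = 57)
  res <- trend_by_quartile(vals, q)
  expect_gt(res$estimate, 0)
  expect_lt(res$p, 0.001)
})

test_that("gender comparison reduces to textbook statistics", {
  # identical samples for both sexes: t = 0, chi-square = 0
  base <- tibble::tibble(
    participant_id = paste0("P", 1:40),
    sex = rep(c("male", "female"), each = 20)
  )
  for (comp in heifa_components()) {
    base[[comp]] <- rep(seq(0, 9.5, 0.5), 2)
    base[[paste0("met_", comp)]] <- rep(c(TRUE, FALSE), 20)
  }
  base$total <- rowSums(base[heifa_components()])
  tab <- compare_genders(base)
  expect_equal(tab$t_statistic, rep(0, nrow(tab)))
  sodium_row <- tab[tab$component == "sodium", ]
  expect_equal(sodium_row$chisq_statistic, 0)

  # Pearson chi-square equals the closed form n(ad-bc)^2 / row.col products
  withr::with_seed(44, {
    met <- c(runif(20) < 0.3, runif(20) < 0.6)
  })
  base$met_sodium <- met
  tab <- compare_genders(base)
  a <- sum(met[1:20]); b <- 20 - a; c_ <- sum(met[21:40]); d <- 20 - c_
  hand <- 40 * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(tab$chisq_statistic[tab$component == "sodium"], hand,
               tolerance = 1e-9)

  expect_error(compare_genders(base[base$sex == "male", ]),
               class = "dietq_domain_error")
})

test_that("guideline tallies equal direct counts of the met flags", {
  comp <- demo_comp()
  cfg <- default_scoring_config()
  perfect <- generate_archetype("perfect", comp, cfg)
  null <- generate_archetype("null", comp, cfg)
  cohort <- dplyr::bind_rows(perfect, perfect, null)
  cohort$participant_id <- paste0("P", 1:3)
  scores <- score_cohort(summarize_intake(cohort, comp, cfg), cfg)
  tally <- tally_guidelines(scores)
  expect_equal(tally$met_n, rep(2L, 11))
  expect_equal(tally$met_pct, rep(66.7, 11))

  # recount independently from the flags
  for (nm in heifa_components()) {
    expect_equal(tally$met_n[tally$component == nm],
                 sum(scores[[paste0("met_", nm)]]))
  }
})

test_that("behaviour regression slopes match the covariance formula", {
  scores <- tibble::tibble(participant_id = paste0("P", 1:5),
                           total = c(40, 45, 50, 55, 62))
  cohort <- tibble::tibble(
    participant_id = paste0("P", 1:5),
    ssb_ml_per_week = c(2000, 1500, 900, 500, 100),
    takeaway_per_week = c("6+", "4-5", "2-3", "2-3", "0-1")
  )
  res <- regress_behavior(scores, cohort)
  ssb <- cohort$ssb_ml_per_week
  hand_slope <- cov(ssb, scores$total) / var(ssb)
  expect_equal(res$slope[res$predictor == "ssb_ml_per_week"], hand_slope,
               tolerance = 1e-12)
  expect_lt(res$slope[res$predictor == "takeaway_ordinal"], 0)

  const <- cohort
  const$takeaway_per_week <- "2-3"
  expect_error(regress_behavior(scores, const), class = "dietq_domain_error")
})

test_that("a permuted predictor gives a near-zero slope", {
  comp <- demo_comp()
  coh <- generate_cohort(simulation_params(n = 200, seed = 61,
                                           misreport_fraction = 0,
                                           incomplete_fraction = 0), comp)
  scores <- score_cohort(summarize_intake(coh, comp))
  withr::with_seed(62, {
    coh$ssb_ml_per_week <- sample(coh$ssb_ml_per_week)
  })
  res <- regress_behavior(scores, coh)
  ssb_row <- res[res$predictor == "ssb_ml_per_week", ]
  expect_gt(ssb_row$p, 0.001) # no fabricated association
  expect_lt(abs(ssb_row$statistic), 3.5)
})

test_that("reference comparison reports differences against constants", {
  comp <- demo_comp()
  coh <- generate_cohort(simulation_params(n = 30, seed = 71), comp)
  summ <- summarize_intake(coh, comp)

  # cohort equal to the reference: all differences zero
  ref <- list(vegetables_g = list(value = mean(summ$vegetables_g),
                                  units = "g/day", source = "test"))
  tab <- compare_to_reference(summ, ref)
  expect_equal(tab$difference, 0)

  expect_warning(empty <- compare_to_reference(summ, list()), "Empty")
  expect_equal(nrow(empty), 0)

  ref$unknown_key <- list(value = 1, units = "g", source = "test")
  expect_warning(tab2 <- compare_to_reference(summ, ref), "unknown_key")
  expect_equal(nrow(tab2), 1)
})

test_that("cohorts seeded from survey-like group means land near the reference", {
  comp <- demo_comp()
  params <- simulation_params(
    n = 1500, seed = 81, misreport_fraction = 0, incomplete_fraction = 0,
    group_intake = modifyList(
      simulation_params()$group_intake,
      list(vegetables = list(mean_g = list(male = 172.8, female = 172.8),
                             gsd = 1.6))
    )
  )
  coh <- generate_cohort(params, comp)
  summ <- summarize_intake(coh, comp)
  tab <- compare_to_reference(summ, default_reference_values())
  row <- tab[tab$key == "vegetables_g", ]
  se <- sd(summ$vegetables_g) / sqrt(nrow(summ))
  expect_lt(abs(row$difference), 3 * se)
})
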