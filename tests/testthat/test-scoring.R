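test_that("prorated quantity scoring is linear below target, flat above", {
  expect_equal(prorated_quantity_score(5, 5, 10), 10)
  expect_equal(prorated_quantity_score(0, 5, 10), 0)
  expect_equal(prorated_quantity_score(1.5, 5, 5), 1.5)
  expect_equal(prorated_quantity_score(8, 5, 10), 10) # no over-intake penalty
  expect_error(prorated_quantity_score(-1, 5, 10), class = "dietq_domain_error")
  expect_error(prorated_quantity_score(1, 0, 10), class = "dietq_domain_error")
})

test_that("moderation scoring interpolates between full and zero cuts", {
  expect_equal(moderation_score(10, 10, 15, 10), 10) # at the full cut
  expect_equal(moderation_score(15, 10, 15, 10), 0)  # at the zero cut
  expect_equal(moderation_score(12.5, 10, 15, 10), 5) # midway
  expect_equal(moderation_score(0, 10, 15, 10), 10)
  expect_equal(moderation_score(50, 10, 15, 10), 0)
  # linearity across random interior points
  withr::with_seed(3, {
    v <- runif(20, 10, 15)
    expect_equal(moderation_score(v, 10, 15, 10), 10 * (15 - v) / 5)
  })
  expect_error(moderation_score(1, 15, 10, 10), class = "dietq_domain_error")
})

test_that("variety scoring sums subgroup points under the cap", {
  pts <- list(a = 1, b = 1, c = 1, d = 1, e = 1)
  expect_equal(variety_score(names(pts), pts, 5), 5)
  expect_equal(variety_score(character(), pts, 5), 0)
  expect_equal(variety_score(c("a", "b"), pts, 5), 2)
  expect_equal(variety_score(names(pts), pts, 3), 3) # cap binds
  expect_warning(sc <- variety_score(c("a", "zzz"), pts, 5), "zzz")
  expect_equal(sc, 1)
})

test_that("intake summaries convert grams to serves, proportions and %E", {
  comp <- tiny_composition()
  rec <- tiny_cohort_row(amounts = c(veg1 = 100, grain1 = 0, milk1 = 0))
  s <- summarize_intake(rec, comp)
  expect_equal(s$vegetables_serves, 100 / 75) # 1.333 serves
  expect_equal(s$vegetables_pct_e, 100)       # sole energy source

  # 50 g wholegrain of 100 g total grains -> proportion 0.5
  comp2 <- dplyr::bind_rows(
    tiny_composition(),
    within(tiny_composition()[2, ], {
      food_id <- "grain2"; is_wholegrain <- FALSE
    })
  )
  rec2 <- tiny_cohort_row(amounts = c(grain1 = 50, grain2 = 50))
  s2 <- summarize_intake(rec2, comp2)
  expect_equal(s2$wholegrain_prop, 0.5)
  expect_equal(s2$grains_g, 100)

  # empty record: zero summary, flagged rather than NaN
  rec0 <- tiny_cohort_row(amounts = c(veg1 = 0, grain1 = 0, milk1 = 0),
                          water = 0, ssb = 0)
  s0 <- summarize_intake(rec0, comp)
  expect_true(s0$zero_energy)
  expect_true(is.na(s0$sat_fat_pct_e))
  expect_equal(s0$vegetables_g, 0)
  expect_equal(s0$water_prop, 0)

  # macronutrient %E closes to ~100 when energy is exactly macro-derived
  s1 <- summarize_intake(tiny_cohort_row(), comp)
  closure <- s1$protein_pct_e + s1$fat_pct_e + s1$carb_pct_e + s1$alcohol_pct_e
  expect_equal(closure, 100, tolerance = 2e-2)
})

test_that("water proportion uses total beverage volume including SSB", {
  comp <- tiny_composition()
  rec <- tiny_cohort_row(water = 1000, ssb = 7000,
                         amounts = c(veg1 = 100, grain1 = 0, milk1 = 0))
  s <- summarize_intake(rec, comp)
  expect_equal(s$ssb_ml_day, 1000)
  expect_equal(s$water_prop, 1000 / 2000)
})

test_that("the perfect archetype scores exactly 100 and the null exactly 0", {
  comp <- demo_comp()
  cfg <- default_scoring_config()
  for (sex in c("female", "male")) {
    p <- generate_archetype("perfect", comp, cfg, sex = sex)
    sp <- score_record(summarize_intake(p, comp, cfg)[1, ], cfg)
    expect_identical(sp$total, 100)
    expect_true(all(sp$met))
  }
  nl <- generate_archetype("null", comp, cfg)
  sn <- score_record(summarize_intake(nl, comp, cfg)[1, ], cfg)
  expect_identical(sn$total, 0)
  expect_false(any(sn$met))
})

test_that("halving the perfect archetype's vegetables halves only that quantity sub-score", {
  comp <- demo_comp()
  cfg <- default_scoring_config()
  p <- generate_archetype("perfect", comp, cfg)
  base <- score_record(summarize_intake(p, comp, cfg)[1, ], cfg)

  veg_ids <- comp$food_id[comp$group == "vegetables"]
  halved <- p
  for (id in veg_ids) halved[[paste0("g_", id)]] <- p[[paste0("g_", id)]] / 2
  sh <- summarize_intake(halved, comp, cfg)
  sc <- score_record(sh[1, ], cfg)

  target <- cfg$targets$vegetables$female
  expected_q <- prorated_quantity_score(sh$vegetables_serves, target,
                                        cfg$quantity_points$vegetables)
  expect_equal(sc$subscores$vegetables_quantity, expected_q)
  expect_lt(sc$subscores$vegetables_quantity, 5)
  expect_equal(sc$subscores$vegetables_variety, 5) # weekly serves still met
  for (comp_nm in setdiff(heifa_components(), "vegetables")) {
    expect_equal(sc$components[[comp_nm]], base$components[[comp_nm]],
                 info = comp_nm)
  }
})

test_that("score_record agrees with an independent brute-force rubric evaluator", {
  cfg <- default_scoring_config()
  withr::with_seed(17, {
    for (i in 1:100) {
      s <- random_summary(cfg)
      got <- score_record(s, cfg)
      expect_equal(got$total, oracle_score(s, cfg), tolerance = 1e-9)
      expect_equal(got$total, sum(got$components), tolerance = 1e-9)
    }
  })
})

test_that("component scores respect bounds and the total is their sum", {
  cfg <- default_scoring_config()
  maxes <- unlist(cfg$max_points)
  withr::with_seed(23, {
    for (i in 1:500) {
      sc <- score_record(random_summary(cfg), cfg)
      expect_true(all(sc$components >= -1e-12))
      expect_true(all(sc$components <= maxes[names(sc$components)] + 1e-12))
      expect_gte(sc$total, 0)
      expect_lte(sc$total, 100)
    }
  })
})

test_that("raising a below-target core food never lowers the total; raising sodium never raises it", {
  cfg <- default_scoring_config()
  withr::with_seed(31, {
    for (i in 1:50) {
      s <- random_summary(cfg)
      t0 <- score_record(s, cfg)$total
      s_up <- s
      s_up$vegetables_serves <- s$vegetables_serves + runif(1, 0, 2)
      expect_gte(score_record(s_up, cfg)$total, t0 - 1e-12)
      if (!s$zero_energy) {
        s_na <- s
        s_na$sodium_mg <- s$sodium_mg + runif(1, 0, 1000)
        expect_lte(score_record(s_na, cfg)$total, t0 + 1e-12)
      }
    }
  })
})

test_that("permuting composition rows leaves every score unchanged", {
  comp <- demo_comp()
  coh <- generate_cohort(simulation_params(n = 12, seed = 8), comp)
  sc1 <- score_cohort(summarize_intake(coh, comp))
  withr::with_seed(4, perm <- sample(nrow(comp)))
  sc2 <- score_cohort(summarize_intake(coh, comp[perm, ]))
  expect_equal(sc1$total, sc2$total, tolerance = 1e-12)
  expect_equal(sc1$vegetables, sc2$vegetables, tolerance = 1e-12)
})

test_that("a zero-energy record scores zero on all moderation components", {
  comp <- tiny_composition()
  rec <- tiny_cohort_row(amounts = c(veg1 = 0, grain1 = 0, milk1 = 0),
                         water = 500)
  sc <- score_record(summarize_intake(rec, comp)[1, ])
  expect_true(sc$zero_energy)
  for (nm in c("discretionary", "fat", "sodium", "sugars", "alcohol")) {
    expect_equal(sc$components[[nm]], 0, info = nm)
  }
  expect_false(any(sc$met[c("discretionary", "fat", "sodium", "sugars",
                            "alcohol")]))
})
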