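# Shared fixtures and the independent scoring oracle.

demo_comp <- function() {
  load_composition_table(dietq_example("composition_demo.csv"))
}

# minimal composition rows built in code, for data-model tests
tiny_composition <- function() {
  tibble::tibble(
    food_id = c("veg1", "grain1", "milk1"),
    name = c("Test vegetable", "Test wholegrain", "Test skim milk"),
    group = c("vegetables", "grains", "dairy_alt"),
    subgroup = c("green_veg", "bread", "milk"),
    is_wholegrain = c(FALSE, TRUE, FALSE),
    is_low_fat = c(FALSE, FALSE, TRUE),
    serve_size_g = c(75, 40, 250),
    protein_g = c(2, 10, 3.5),
    fat_g = c(0.5, 3, 0.1),
    sat_fat_g = c(0.1, 0.5, 0.05),
    mono_g = c(0.2, 1, 0.02),
    poly_g = c(0.1, 1.2, 0.01),
    carb_g = c(5, 40, 5),
    sugars_g = c(3, 3, 5),
    starch_g = c(2, 37, 0),
    fiber_g = c(2.5, 7, 0),
    sodium_mg = c(20, 380, 45),
    alcohol_g = c(0, 0, 0),
    density_g_ml = c(NA, NA, 1.03)
  ) |>
    (\(d) { d$energy_kj <- 17 * d$protein_g + 37 * d$fat_g +
              16.7 * d$carb_g + 29 * d$alcohol_g; d })()
}

write_tmp_composition <- function(comp, file = tempfile(fileext = ".csv")) {
  write_composition_table(comp, file)
  file
}

# one-participant cohort row around the tiny composition
tiny_cohort_row <- function(id = "T01", sex = "female", age = 25,
                            weight = 65, height = 1.65, ssb = 700,
                            takeaway = "2-3", water = 1000,
                            amounts = c(veg1 = 150, grain1 = 120, milk1 = 300)) {
  row <- tibble::tibble(
    participant_id = id, sex = sex, age = age, weight_kg = weight,
    height_m = height, ssb_ml_per_week = ssb, takeaway_per_week = takeaway,
    water_ml_per_day = water, complete = TRUE
  )
  for (nm in names(amounts)) row[[paste0("g_", nm)]] <- amounts[[nm]]
  row
}

# A brute-force re-statement of the HEIFA rubric, written independently of
# score_record(): explicit branch-by-branch evaluation, no shared helpers.
oracle_score <- function(s, cfg = default_scoring_config()) {
  pick <- function(x, nm) x[[nm]]
  target <- function(g) cfg$targets[[g]][[s$sex]]
  below <- function(x, t, pts) {
    if (x >= t) pts else pts * x / t
  }
  prop_sub <- function(p, full, pts) {
    if (p >= full) pts else pts * p / full
  }
  mod <- function(x, fc, zc, pts) {
    if (x <= fc) return(pts)
    if (x >= zc) return(0)
    pts * (zc - x) / (zc - fc)
  }
  dead <- !(s$energy_kj > 0)

  veg <- below(s$vegetables_serves, target("vegetables"),
               cfg$quantity_points$vegetables)
  for (sg in s$veg_subgroups) {
    veg <- veg + pick(cfg$variety$vegetables$points, sg)
  }
  veg <- min(veg, cfg$quantity_points$vegetables + cfg$variety$vegetables$cap)

  fr <- below(s$fruit_serves, target("fruit"), cfg$quantity_points$fruit)
  fv <- 0
  for (sg in s$fruit_subgroups) fv <- fv + pick(cfg$variety$fruit$points, sg)
  fr <- fr + min(fv, cfg$variety$fruit$cap)

  gr <- below(s$grains_serves, target("grains"), cfg$quantity_points$grains) +
    prop_sub(s$wholegrain_prop, cfg$wholegrain$full_credit_prop,
             cfg$wholegrain$points)
  meat <- below(s$meat_alt_serves, target("meat_alt"),
                cfg$quantity_points$meat_alt)
  dairy <- below(s$dairy_alt_serves, target("dairy_alt"),
                 cfg$quantity_points$dairy_alt) +
    prop_sub(s$lowfat_prop, cfg$low_fat$full_credit_prop, cfg$low_fat$points)

  m <- cfg$moderation
  disc <- if (dead) 0 else mod(s$discretionary_pct_e, m$discretionary$full_cut,
                               m$discretionary$zero_cut, cfg$max_points$discretionary)
  fat <- if (dead) 0 else mod(s$sat_fat_pct_e, m$fat$full_cut, m$fat$zero_cut,
                              cfg$max_points$fat)
  sodium <- if (dead) 0 else mod(s$sodium_mg, m$sodium$full_cut,
                                 m$sodium$zero_cut, cfg$max_points$sodium)
  sugars <- if (dead) 0 else mod(s$sugars_pct_e, m$sugars$full_cut,
                                 m$sugars$zero_cut, cfg$max_points$sugars)
  alcohol <- if (dead) 0 else mod(s$alcohol_g, m$alcohol$full_cut,
                                  m$alcohol$zero_cut, cfg$max_points$alcohol)
  water <- prop_sub(s$water_prop, cfg$water$full_credit_prop,
                    cfg$max_points$water)

  veg + fr + gr + meat + dairy + disc + fat + sodium + sugars + water + alcohol
}

# random valid intake summaries (call under withr::with_seed)
random_summary <- function(cfg = default_scoring_config()) {
  zero <- stats::runif(1) < 0.05
  pe <- function(lo, hi) if (zero) NA_real_ else stats::runif(1, lo, hi)
  list(
    sex = sample(c("male", "female"), 1),
    energy_kj = if (zero) 0 else stats::runif(1, 2000, 15000),
    zero_energy = zero,
    vegetables_serves = stats::runif(1, 0, 9),
    fruit_serves = stats::runif(1, 0, 5),
    grains_serves = stats::runif(1, 0, 9),
    meat_alt_serves = stats::runif(1, 0, 5),
    dairy_alt_serves = stats::runif(1, 0, 5),
    veg_subgroups = sample(names(cfg$variety$vegetables$points),
                           sample(0:5, 1)),
    fruit_subgroups = sample(names(cfg$variety$fruit$points), sample(0:5, 1)),
    wholegrain_prop = stats::runif(1),
    lowfat_prop = stats::runif(1),
    discretionary_pct_e = pe(0, 90),
    sat_fat_pct_e = pe(0, 25),
    sugars_pct_e = pe(0, 45),
    sodium_mg = if (zero) NA_real_ else stats::runif(1, 0, 6500),
    alcohol_g = if (zero) NA_real_ else stats::runif(1, 0, 60),
    water_prop = stats::runif(1)
  )
}
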