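# Sowing rule, phenology, light interception, RUE growth and harvest.

test_that("the sowing rule triggers on the trailing 5-day 20 mm sum", {
  win <- sowing_window(150, 200)
  p <- numeric(366)
  p[160:162] <- 8      # trailing sums reach 24 >= 20 only on day 162
  expect_equal(determine_sowing_date(p, win), 162)
  expect_equal(determine_sowing_date(numeric(366), win), 200)  # fallback
  p2 <- numeric(366); p2[150] <- 25
  expect_equal(determine_sowing_date(p2, win), 150)
  expect_error(determine_sowing_date(numeric(100), win), "shorter")
})

test_that("the sowing rule agrees with a brute-force scan on random series", {
  brute <- function(p, win) {
    hits <- Filter(function(d)
      sum(p[max(1, d - win$accum_days + 1):d]) >= win$rain_threshold,
      win$start_doy:win$end_doy)
    if (length(hits) > 0) hits[[1]] else win$end_doy
  }
  withr::with_seed(99, {
    ok <- TRUE
    for (i in 1:500) {
      p <- ifelse(runif(366) < 0.25, rexp(366, rate = 1 / 8), 0)
      win <- sowing_window(sample(100:180, 1), sample(190:260, 1))
      ok <- ok && determine_sowing_date(p, win) == brute(p, win)
    }
    expect_true(ok)
  })
})

test_that("phenology accumulates thermal time above base and promotes stages", {
  params <- crop_params("millet")      # t_base 10
  s <- sow_crop(crop_state(), 150)
  s1 <- step_phenology(s, tmean = params$t_base, params)
  expect_equal(s1$tt_sum, 0)
  s2 <- step_phenology(s, tmean = params$t_base + 10, params)
  expect_equal(s2$tt_sum, 10)
  # constant tmean = t_base + 20, maturity 1400 degC day -> mature on day 70
  p1400 <- crop_params("millet", tt_maturity = 1400)
  s <- sow_crop(crop_state(), 150)
  days <- 0
  while (s$stage != "mature") {
    s <- step_phenology(s, p1400$t_base + 20, p1400)
    days <- days + 1
  }
  expect_equal(days, 70)
  expect_error(step_phenology(crop_state(), 25, params), "unsown")
})

test_that("light interception follows Beer's law", {
  expect_equal(light_interception(0, 0.6), 0)
  expect_equal(light_interception(3, 0.6), 1 - exp(-1.8))
  lais <- seq(0, 10, by = 0.5)
  f <- light_interception(lais, 0.6)
  expect_true(all(diff(f) > 0))
  expect_true(all(f < 1))
  expect_error(light_interception(-1, 0.6))
})

test_that("daily growth is RUE times intercepted PAR times the stress minimum", {
  params <- crop_params("maize", rue = 3, k_ext = 0.6)
  s <- sow_crop(crop_state(), 150)
  s$stage <- "emerged"
  s$lai <- -log(0.5) / 0.6          # f_int = 0.5 exactly
  day <- make_day(srad = 20)
  out <- step_crop_growth(s, day, water_factor = 1, n_factor = 1, params,
                          et0 = 6)
  expect_equal(sum(out$state$biomass) - sum(s$biomass), 3 * 0.5 * 10)  # 15 g m-2
  # full stress: no dry-matter gain
  out0 <- step_crop_growth(s, day, water_factor = 0, n_factor = 1, params,
                           et0 = 6)
  expect_equal(out0$state$biomass, s$biomass)
  # transpiration demand scales with cover
  expect_equal(out$transp_demand, 6 * 0.5)
  expect_error(step_crop_growth(crop_state(), day, 1, 1, params, 6))
})

test_that("dry matter is conserved into the organ pools", {
  params <- crop_params("sorghum")
  s <- sow_crop(crop_state(), 150)
  s$stage <- "emerged"
  total_ddm <- 0
  withr::with_seed(5, {
    for (i in 1:120) {
      before <- sum(s$biomass)
      out <- step_crop_growth(s, make_day(srad = runif(1, 10, 25)),
                              runif(1), runif(1), params, et0 = 5)
      s <- out$state
      s$tt_sum <- s$tt_sum + 15   # advance dvs so all table rows are visited
      total_ddm <- total_ddm + (sum(s$biomass) - before)
    }
  })
  expect_equal(sum(s$biomass), total_ddm, tolerance = 1e-12)
  expect_true(all(s$biomass >= 0))
})

test_that("harvest caps yield at hi_max and exports residue", {
  params <- crop_params("maize", hi_max = 0.5, residue_feed_fraction = 0.5)
  s <- crop_state()
  s$stage <- "mature"
  s$biomass <- c(leaf = 150, stem = 200, root = 100, storage = 150) # AGB 500
  h <- harvest(s, params)
  expect_equal(h$yield_dm, 1500)          # g m-2 -> kg ha-1
  expect_equal(h$residue_total, 3500)
  expect_equal(h$residue_feed, 1750)
  expect_equal(h$state$stage, "unsown")
  # storage above the cap: yield limited to hi_max * AGB
  s$biomass <- c(leaf = 100, stem = 100, root = 50, storage = 300)
  h2 <- harvest(s, params)
  expect_equal(h2$yield_dm, 2500)
  expect_equal(h2$residue_total, 2500)
  # zero biomass
  s$biomass[] <- 0
  h3 <- harvest(s, params)
  expect_equal(c(h3$yield_dm, h3$residue_total, h3$residue_feed), c(0, 0, 0))
  s$stage <- "emerged"
  expect_error(harvest(s, params), "maturity")
})

test_that("production levels are ordered: potential >= water >= water+N", {
  win <- sowing_window(150, 220)
  soil_cfg <- default_config()$soil
  soil_cfg$mineral_n_kgha <- 8        # make nitrogen genuinely limiting
  for (seed in 1:6) {
    w <- generate_weather(zone_climate_spec("sahelian", seed = seed),
                          n_years = 1)
    pot <- simulate_crop_season(w, crop_params("millet"), win, soil_cfg,
                                level = "potential")
    wl <- simulate_crop_season(w, crop_params("millet"), win, soil_cfg,
                               level = "water")
    wn <- simulate_crop_season(w, crop_params("millet"), win, soil_cfg,
                               level = "water_nitrogen")
    expect_gte(pot$yield_dm, wl$yield_dm)
    expect_gte(wl$yield_dm, wn$yield_dm)
    # harvest index bounded by hi_max throughout
    expect_lte(wn$yield_dm / wn$agb, crop_params("millet")$hi_max + 1e-9)
  }
})

test_that("uniform warming shortens the crop duration", {
  win <- sowing_window(150, 220)
  for (seed in 1:5) {
    w <- generate_weather(zone_climate_spec("sudanian", seed = seed),
                          n_years = 1)
    warm <- apply_climate_delta(w, climate_delta(1.5, 1.5, 1))
    for (crop in c("maize", "sorghum")) {
      base <- simulate_crop_season(w, crop_params(crop), win)
      shifted <- simulate_crop_season(warm, crop_params(crop), win)
      expect_lt(shifted$days_to_maturity, base$days_to_maturity)
    }
  }
})
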