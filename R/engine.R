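# Cell-level orchestration: configuration, the daily simulation loop
# coupling weather -> soil -> crop/grass -> feed -> herd -> management,
# aggregation over land-use shares, and result serialization.

#' Default scenario configuration for a zone
#'
#' Builds the full nested configuration for [run_simulation()]: the
#' Sahelian cell grows millet and sorghum over annual grassland, the
#' Sudanian cell maize and sorghum over perennial grassland, each with a
#' zone-typical sowing window, land-use shares, soil profile, herd and
#' market block. Any element can be overridden by modifying the returned
#' list (or a YAML file with the same structure, see [read_config()]).
#'
#' @param zone `"sahelian"` or `"sudanian"`.
#' @param years Simulated years.
#' @param seed Integer seed for the weather generator (mandatory for a
#'   run).
#' @param start_year First calendar year.
#' @return A nested configuration list with blocks `run`, `climate`,
#'   `cell`, `soil`, `crops`, `grass`, `herd`, `feed`, `market`.
#' @export
default_config <- function(zone = c("sahelian", "sudanian"), years = 5,
                           seed = 1L, start_year = 2001L) {
  zone <- match.arg(zone)
  crops <- if (zone == "sahelian") list(millet = 0.7, sorghum = 0.3)
           else list(maize = 0.6, sorghum = 0.4)
  window <- if (zone == "sahelian") list(start_doy = 150L, end_doy = 220L)
            else list(start_doy = 120L, end_doy = 200L)
  list(
    run = list(years = as.integer(years), seed = as.integer(seed),
               start_year = as.integer(start_year)),
    climate = list(zone = zone, weather_csv = NULL,
                   delta = list(delta_tmax = 0, delta_tmin = 0,
                                precip_factor = 1)),
    cell = list(cell_area_ha = 100, share_grass = 0.5, share_crop = 0.3,
                share_tree = 0.15, share_settlement = 0.05, share_other = 0,
                crop_area_shares = crops),
    soil = list(thickness_m = c(0.2, 0.3, 0.5), fc_vol = 0.25,
                wp_vol = 0.10, sat_vol = 0.40,
                infiltration_capacity_mm = 50, initial_fraction_fc = 0.5,
                mineral_n_kgha = 20, p_crit = 0.5, leach_lambda = 0.5,
                mineralization_kgha_day = 0.04),
    crops = list(sowing_window = window,
                 fertilizer_n = list(maize = 15, millet = 0, sorghum = 0)),
    grass = list(habit = if (zone == "sahelian") "annual" else "perennial"),
    herd = list(counts = if (zone == "sahelian")
                  list(JuvenilesMale = 3, SubAdultsMale = 2, AdultsMale = 2,
                       JuvenilesFemale = 3, SubAdultsFemale = 3,
                       AdultsFemale = 6)
                else
                  list(JuvenilesMale = 6, SubAdultsMale = 5, AdultsMale = 4,
                       JuvenilesFemale = 7, SubAdultsFemale = 6,
                       AdultsFemale = 12),
                weights = NULL, cash = 50000,
                demography = list(),
                maintenance_mj_per_kg075 = 0.5,
                intake_frac_lw = 0.025,
                feed_n_content = 0.012),
    feed = list(me_grass = 8, me_residue = 7, me_concentrate = 12,
                residue_decay = 0.001, manure_to_cropland = 0.5,
                initial_residue_kgha = 600),
    market = list())
}

#' Read a scenario configuration from YAML
#'
#' @param path Path to a YAML file with the [default_config()] structure;
#'   missing keys fall back to the zone defaults.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  zone <- user$climate$zone %||% "sahelian"
  base <- default_config(zone = zone,
                         years = user$run$years %||% 5,
                         seed = user$run$seed %||% stop(
                           "config error: run.seed is mandatory"))
  utils::modifyList(base, user)
}

# Validate the configuration, naming the offending key on failure.
validate_config <- function(config) {
  need <- function(block) if (is.null(config[[block]]))
    stop("config error: missing block '", block, "'")
  for (b in c("run", "climate", "cell", "soil", "crops", "grass", "herd",
              "feed", "market")) need(b)
  if (is.null(config$run$seed)) stop("config error: run.seed is mandatory")
  cell <- config$cell
  shares <- c(cell$share_grass, cell$share_crop, cell$share_tree,
              cell$share_settlement, cell$share_other)
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-6)
    stop("config error: cell land-use shares must be >= 0 and sum to 1")
  cs <- unlist(cell$crop_area_shares)
  if (length(cs) > 0 && abs(sum(cs) - 1) > 1e-6)
    stop("config error: cell.crop_area_shares must sum to 1")
  if (!config$climate$zone %in% c("sahelian", "sudanian"))
    stop("config error: climate.zone must be sahelian or sudanian")
  config
}

# Build a soil_profile from the config soil block.
.soil_from_config <- function(soil) {
  soil_profile(thickness_m = soil$thickness_m, fc_vol = soil$fc_vol,
               wp_vol = soil$wp_vol, sat_vol = soil$sat_vol,
               infiltration_capacity_mm = soil$infiltration_capacity_mm,
               initial_fraction_fc = soil$initial_fraction_fc,
               mineral_n_kgha = soil$mineral_n_kgha)
}

# One day of a crop soil column: rainfall partition, sowing, phenology,
# growth under water/N stress (N factor lagged one day), soil water and
# nitrogen updates. `level` switches the production level: "potential"
# (no stress), "water" (water-limited) or "water_nitrogen".
.crop_column_day <- function(col, day, et0_d, sow_today, n_manure = 0,
                             level = "water_nitrogen") {
  soil <- col$soil; state <- col$state; params <- col$params
  cfg <- col$soil_cfg
  rain <- day$precip
  part <- partition_rainfall(rain, soil)
  fert <- 0
  if (sow_today && state$stage == "unsown") {
    state <- sow_crop(state, as.integer(format(day$date, "%j")))
    fert <- col$fertilizer_n
  }
  transp_demand <- 0; n_demand <- 0; harvested <- NULL
  if (state$stage != "unsown") {
    state <- step_phenology(state, day$tmean, params)
    if (state$stage %in% c("emerged", "anthesis")) {
      wf <- if (level == "potential") 1
            else drought_factor(soil, max(state$root_depth, 0.05), cfg$p_crit)
      nf <- if (level == "water_nitrogen") col$last_n_factor else 1
      g <- step_crop_growth(state, day, wf, nf, params, et0_d)
      state <- g$state
      transp_demand <- g$transp_demand
      n_demand <- g$n_demand
    }
  }
  f_int <- light_interception(state$lai, params$k_ext)
  sw <- step_soil_water(soil, part$infiltration,
                        evap_demand = et0_d * (1 - f_int),
                        transp_demand = transp_demand,
                        root_depth = state$root_depth)
  soil <- sw$profile
  state$cum_transpiration <- state$cum_transpiration + sw$flux$transpiration
  sn <- step_soil_nitrogen(soil,
                           n_inputs = fert + n_manure + cfg$mineralization_kgha_day,
                           uptake_demand = n_demand,
                           drainage = sw$flux$drainage,
                           leach_lambda = cfg$leach_lambda)
  soil <- sn$profile
  col$last_n_factor <- sn$n_factor
  if (state$stage == "mature") {
    season_ta <- state$cum_transpiration
    harvested <- harvest(state, params)
    harvested$season_ta <- season_ta
    state <- harvested$state
  }
  col$state <- state; col$soil <- soil
  col$flux <- sw$flux; col$leached <- sn$leached; col$runoff <- part$runoff
  col$harvested <- harvested
  col
}

#' Simulate one cropping season for a single field
#'
#' Standalone single-crop, single-soil-column season run used for
#' production-level comparisons: sowing follows the rainfall rule within
#' the window, then daily phenology, growth and soil updates until
#' maturity. `level` selects the production level: `"potential"` (no
#' stress), `"water"` (water-limited) or `"water_nitrogen"` (water- and
#' nitrogen-limited).
#'
#' @param weather A `weather_series` covering at least one calendar year;
#'   the first year is simulated.
#' @param params A [crop_params()].
#' @param window A [sowing_window()].
#' @param soil_cfg Soil config block as in [default_config()].
#' @param level Production level.
#' @return List with `yield_dm`, `agb` (kg DM ha-1), `sowing_doy`,
#'   `maturity_doy`, `days_to_maturity`, `season_transpiration` (mm) and
#'   `season_precip` (mm).
#' @export
simulate_crop_season <- function(weather, params, window,
                                 soil_cfg = default_config()$soil,
                                 level = c("water_nitrogen", "water",
                                           "potential")) {
  level <- match.arg(level)
  lat <- attr(weather, "latitude") %||% 13
  yr <- format(weather$date, "%Y")[1]
  wy <- weather[format(weather$date, "%Y") == yr, , drop = FALSE]
  doy <- as.integer(format(wy$date, "%j"))
  precip_by_doy <- numeric(max(doy)); precip_by_doy[doy] <- wy$precip
  sow_doy <- determine_sowing_date(precip_by_doy, window)
  et0 <- reference_et(wy, lat)
  col <- list(state = crop_state(), soil = .soil_from_config(soil_cfg),
              params = params, soil_cfg = soil_cfg, last_n_factor = 1,
              fertilizer_n = 0)
  result <- NULL
  for (d in seq_len(nrow(wy))) {
    col <- .crop_column_day(col, wy[d, ], et0[d], sow_today = doy[d] == sow_doy,
                            level = level)
    if (!is.null(col$harvested)) {
      h <- col$harvested
      result <- list(yield_dm = h$yield_dm, agb = h$yield_dm + h$residue_total,
                     sowing_doy = sow_doy, maturity_doy = doy[d],
                     days_to_maturity = doy[d] - sow_doy,
                     season_transpiration = h$season_ta,
                     season_precip = sum(wy$precip[doy >= sow_doy & doy <= doy[d]]))
      break
    }
  }
  if (is.null(result))
    stop("crop did not reach maturity within the simulated year")
  result
}

#' Run the integrated mixed crop-livestock simulation for one cell
#'
#' Executes the daily loop in fixed order: weather and reference ET;
#' per-activity soil water and nitrogen; grassland growth and seasonal
#' transitions; crop sowing, phenology, growth and harvest; feed-store
#' update; herd energy demand, feed supply and the 0-1 energy-stress
#' index; concentrate purchase within cash limits; sell-out management;
#' herd demography, live weights, milk, methane and manure (manure
#' produced on day t fertilizes on day t+1). The run is deterministic
#' given the configuration (all randomness flows from `run$seed` through
#' the weather generator).
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @param debug_invariants Assert water-balance closure and herd/cash
#'   bookkeeping every day (aborts naming the day on a breach).
#' @return An object of class `mcl_result`: list with `daily` and `annual`
#'   data frames, the `config` and the forcing `weather`.
#' @export
run_simulation <- function(config, debug_invariants = FALSE) {
  config <- validate_config(config)
  cl <- config$climate
  weather <- if (!is.null(cl$weather_csv)) {
    read_weather_csv(cl$weather_csv)
  } else {
    spec_args <- cl[intersect(names(cl), c("zone", "annual_rain_mm",
      "wet_season_start_doy", "wet_season_length_days", "tmax_mean",
      "tmin_mean", "cv_rain", "latitude"))]
    spec_args$seed <- config$run$seed
    generate_weather(do.call(zone_climate_spec, spec_args),
                     n_years = config$run$years,
                     start_year = config$run$start_year)
  }
  if (!is.null(cl$delta)) {
    d <- cl$delta
    weather <- apply_climate_delta(weather,
      climate_delta(d$delta_tmax %||% 0, d$delta_tmin %||% 0,
                    d$precip_factor %||% 1))
  }
  lat <- attr(weather, "latitude")
  n <- nrow(weather)
  dates <- weather$date
  doy <- as.integer(format(dates, "%j"))
  year <- as.integer(format(dates, "%Y"))
  years <- unique(year)
  et0 <- reference_et(weather, lat)
  trail5 <- as.numeric(stats::filter(weather$precip, rep(1, 5), sides = 1))
  trail30 <- as.numeric(stats::filter(weather$precip, rep(1, 30), sides = 1))
  trail5[is.na(trail5)] <- 0; trail30[is.na(trail30)] <- Inf

  # land areas
  cell <- config$cell
  grass_area <- cell$cell_area_ha * cell$share_grass
  crop_names <- names(cell$crop_area_shares)
  crop_area <- vapply(crop_names, function(cn)
    cell$cell_area_ha * cell$share_crop * cell$crop_area_shares[[cn]],
    numeric(1))

  # crop columns
  window <- sowing_window(config$crops$sowing_window$start_doy,
                          config$crops$sowing_window$end_doy)
  cols <- lapply(crop_names, function(cn) {
    list(state = crop_state(), soil = .soil_from_config(config$soil),
         params = crop_params(cn), soil_cfg = config$soil,
         last_n_factor = 1,
         fertilizer_n = config$crops$fertilizer_n[[cn]] %||% 0)
  })
  names(cols) <- crop_names
  # per-year sowing dates from the rainfall rule
  sow_doy <- vapply(years, function(y) {
    p <- numeric(366); idx <- year == y
    p[doy[idx]] <- weather$precip[idx]
    determine_sowing_date(p, window)
  }, numeric(1))
  names(sow_doy) <- as.character(years)

  # grassland
  gpar <- do.call(grass_params, c(list(habit = config$grass$habit),
                                 config$grass[setdiff(names(config$grass), "habit")]))
  gstate <- if (gpar$habit == "perennial")
    grass_state(shoot = 50, reserve = 150, root_depth = 1.0, dormant = TRUE,
                sla = gpar$sla)
  else grass_state(shoot = 0, root_depth = 0.05, dormant = TRUE, sla = gpar$sla)
  gsoil <- .soil_from_config(config$soil)
  g_last_nf <- 1
  season <- "dry"; days_in_wet <- 0L

  # herd, feed, market
  hc <- config$herd
  herd <- herd_state(
    count = if (!is.null(hc$counts)) unlist(hc$counts)
            else eval(formals(herd_state)$count),
    mean_weight = if (!is.null(hc$weights)) unlist(hc$weights)
                  else eval(formals(herd_state)$mean_weight),
    cash = hc$cash %||% 50000)
  dp <- do.call(demography_params, hc$demography %||% list())
  market <- do.call(market_params, config$market %||% list())
  fd <- config$feed
  store <- feed_store(residue_dm = (fd$initial_residue_kgha %||% 0) * grass_area,
                      me_grass = fd$me_grass, me_residue = fd$me_residue,
                      me_concentrate = fd$me_concentrate)
  manure_pending <- 0

  # output accumulators
  num_cols <- c("precip", "et0",
                paste0(rep(crop_names, each = 4),
                       c("_tt", "_lai", "_agb_kgha", "_soilwater_mm")),
                "grass_shoot_kgha", "grass_reserve_kgha", "grass_soilwater_mm",
                HERD_CLASSES, "total_lw_kg", "energy_demand_mj",
                "energy_supply_mj", "energy_stress", "milk_kg", "ch4_kg",
                "manure_n_kg", "concentrate_kg", "leached_n_kgha", "cash")
  daily <- matrix(0, nrow = n, ncol = length(num_cols),
                  dimnames = list(NULL, num_cols))
  ann <- new.env()
  reset_year <- function() {
    as.list(stats::setNames(rep(0, 6),
      c("milk", "meat", "ch4", "leached", "grass_shoot_sum", "grass_ta")))
  }
  yacc <- reset_year(); yacc$grass_p <- 0
  harvest_log <- list()
  annual_rows <- list()

  for (d in seq_len(n)) {
    day <- weather[d, ]
    rains_onset <- season == "dry" && trail5[d] >= window$rain_threshold &&
      day$precip > 0
    dry_onset <- season == "wet" && days_in_wet > 30 && trail30[d] < 5
    hay_kg <- 0
    if (rains_onset || dry_onset) {
      tr <- season_transition(gstate, gpar, dry_season_onset = dry_onset,
                              rains_onset = rains_onset)
      gstate <- tr$state
      hay_kg <- tr$standing_hay * grass_area * 10
      season <- if (rains_onset) "wet" else "dry"
      days_in_wet <- 0L
    }
    if (season == "wet") days_in_wet <- days_in_wet + 1L

    # grassland column
    manure_grass_ha <- if (grass_area > 0)
      manure_pending * (1 - fd$manure_to_cropland) / grass_area else 0
    g_transp <- 0
    gpart <- partition_rainfall(day$precip, gsoil)
    if (!gstate$dormant) {
      gwf <- drought_factor(gsoil, max(gstate$root_depth, 0.05),
                            config$soil$p_crit)
      gg <- step_grass_growth(gstate, day, gwf, g_last_nf, gpar, et0[d])
      gstate <- gg$state
      g_transp <- gg$transp_demand
      g_ndem <- gg$n_demand
    } else g_ndem <- 0
    gsw <- step_soil_water(gsoil, gpart$infiltration,
                           evap_demand = et0[d] * (1 - light_interception(gstate$lai, gpar$k_ext)),
                           transp_demand = g_transp,
                           root_depth = gstate$root_depth)
    gsoil <- gsw$profile
    gsn <- step_soil_nitrogen(gsoil,
      n_inputs = manure_grass_ha + config$soil$mineralization_kgha_day,
      uptake_demand = g_ndem, drainage = gsw$flux$drainage,
      leach_lambda = config$soil$leach_lambda)
    gsoil <- gsn$profile; g_last_nf <- gsn$n_factor
    if (!gstate$dormant) {
      yacc$grass_ta <- yacc$grass_ta + gsw$flux$transpiration
      yacc$grass_p <- yacc$grass_p + day$precip
    }

    # crop columns
    manure_crop_ha <- if (sum(crop_area) > 0)
      manure_pending * fd$manure_to_cropland / sum(crop_area) else 0
    residue_in_kg <- 0
    leached_ha <- gsn$leached * cell$share_grass
    for (cn in crop_names) {
      cols[[cn]] <- .crop_column_day(cols[[cn]], day, et0[d],
        sow_today = doy[d] == sow_doy[[as.character(year[d])]],
        n_manure = manure_crop_ha)
      h <- cols[[cn]]$harvested
      if (!is.null(h)) {
        residue_in_kg <- residue_in_kg + h$residue_feed * crop_area[[cn]]
        harvest_log[[length(harvest_log) + 1]] <- data.frame(
          date = day$date, year = year[d], crop = cn,
          yield_kgha = h$yield_dm, agb_kgha = h$yield_dm + h$residue_total,
          sowing_doy = sow_doy[[as.character(year[d])]], maturity_doy = doy[d],
          season_ta = h$season_ta)
      }
      leached_ha <- leached_ha + cols[[cn]]$leached * cell$share_crop *
        cell$crop_area_shares[[cn]]
    }

    # feed store and livestock
    store <- update_feed_store(store, standing_hay_in = hay_kg,
                               residue_in = residue_in_kg,
                               decay_rate = fd$residue_decay)
    grazable_kg <- max(0, gstate$shoot - gpar$ungrazable_residual) *
      grass_area * 10
    store$grass_dm <- grazable_kg
    demand <- energy_demand(herd, hc$maintenance_mj_per_kg075)
    cap_dm <- hc$intake_frac_lw * total_live_weight(herd)
    sup <- energy_supply(store, cap_dm, demand)
    store <- sup$store
    drawn <- sup$dm_intake_by_source
    if (drawn[["grass"]] > 0 && grass_area > 0) {
      gz <- graze(gstate, drawn[["grass"]] / (grass_area * 10),
                  gpar$ungrazable_residual)
      gstate <- gz$state
    }
    supply <- sup$supply_mj
    bought <- 0
    deficit <- max(0, demand - supply)
    if (deficit > 1e-9 && herd$cash > 0) {
      buy <- concentrate_purchase(deficit, herd$cash, market,
                                  store$me_concentrate)
      bought <- buy$dm_bought
      herd$cash <- buy$cash
      supply <- supply + bought * store$me_concentrate
    }
    stress <- energy_stress(supply, demand)
    unmet <- max(0, demand - supply)
    meat_today <- 0
    if (unmet > 1e-9) {
      per_head <- hc$maintenance_mj_per_kg075 * herd$mean_weight^0.75
      sale <- sell_out_decision(herd, stress, unmet, market, per_head)
      herd <- sale$herd
      meat_today <- meat_today +
        meat_production(sum(sale$sold * herd$mean_weight), dp$carcass_fraction)
    }
    dem <- step_demography(herd, dp, stress)
    herd <- dem$herd
    meat_today <- meat_today + meat_production(
      sum(dem$flows$offtake * herd$mean_weight), dp$carcass_fraction)
    herd <- update_live_weights(herd, dp, stress)
    milk <- milk_production(herd, dp, stress)
    herd$cash <- max(0, herd$cash + milk * market$milk_price -
                       market$household_expenditure)
    dmi <- sum(drawn) + bought
    ch4 <- methane_emission(dmi, dp$ch4_yield)
    manure_pending <- manure_nitrogen(dmi * hc$feed_n_content,
                                      dp$n_excretion_fraction)

    yacc$milk <- yacc$milk + milk
    yacc$meat <- yacc$meat + meat_today
    yacc$ch4 <- yacc$ch4 + ch4
    yacc$leached <- yacc$leached + leached_ha
    yacc$grass_shoot_sum <- yacc$grass_shoot_sum + gstate$shoot

    if (debug_invariants) {
      if (any(herd$count < 0))
        stop("invariant breach (herd counts) on day ", d)
      if (store$residue_dm < 0 || store$concentrate_dm < 0)
        stop("invariant breach (feed pools) on day ", d)
    }

    row <- c(day$precip, et0[d],
             unlist(lapply(crop_names, function(cn) {
               s <- cols[[cn]]$state
               c(s$tt_sum, s$lai,
                 sum(s$biomass[c("leaf", "stem", "storage")]) * 10,
                 sum(cols[[cn]]$soil$water))
             })),
             gstate$shoot * 10, gstate$reserve * 10, sum(gsoil$water),
             herd$count, total_live_weight(herd), demand, supply, stress,
             milk, ch4, manure_pending, bought, leached_ha, herd$cash)
    daily[d, ] <- row

    # close out the calendar year
    if (d == n || year[d + 1] != year[d]) {
      hl <- if (length(harvest_log) > 0) do.call(rbind, harvest_log) else NULL
      yrow <- list(year = year[d])
      for (cn in crop_names) {
        hy <- if (!is.null(hl)) hl[hl$year == year[d] & hl$crop == cn, ] else NULL
        got <- !is.null(hy) && nrow(hy) > 0
        yrow[[paste0(cn, "_yield_kgha")]] <- if (got) sum(hy$yield_kgha) else 0
        yrow[[paste0(cn, "_agb_kgha")]] <- if (got) sum(hy$agb_kgha) else 0
        yrow[[paste0(cn, "_sowing_doy")]] <- if (got) hy$sowing_doy[1] else NA_real_
        yrow[[paste0(cn, "_maturity_doy")]] <- if (got) hy$maturity_doy[1] else NA_real_
        yrow[[paste0(cn, "_season_ta")]] <- if (got) sum(hy$season_ta) else 0
      }
      ydays <- sum(year == year[d])
      yrow$grass_mean_kgha <- yacc$grass_shoot_sum / ydays * 10
      yrow$grass_ta <- yacc$grass_ta
      yrow$grass_p <- yacc$grass_p
      yrow$annual_rain_mm <- sum(weather$precip[year == year[d]])
      yrow$livestock_total <- sum(herd$count)
      yrow$total_lw_kg <- total_live_weight(herd)
      yrow$milk_kg <- yacc$milk
      yrow$meat_kg <- yacc$meat
      yrow$ch4_kg <- yacc$ch4
      yrow$leached_n_kgha <- yacc$leached
      yrow$cash <- herd$cash
      annual_rows[[length(annual_rows) + 1]] <- as.data.frame(yrow)
      yacc <- reset_year(); yacc$grass_p <- 0
    }
  }

  daily_df <- data.frame(date = dates, daily, check.names = FALSE)
  annual_df <- do.call(rbind, annual_rows)
  # sWSI per activity over the run's own baseline (needs >= 2 years)
  if (nrow(annual_df) >= 2) {
    ws <- annual_df$grass_ta - annual_df$grass_p
    annual_df$grass_swsi <- if (stats::sd(ws) > 0)
      swsi(annual_df$grass_ta, annual_df$grass_p) else NA_real_
  } else annual_df$grass_swsi <- NA_real_
  structure(list(daily = daily_df, annual = annual_df, config = config,
                 weather = weather,
                 harvests = if (length(harvest_log) > 0)
                   do.call(rbind, harvest_log) else NULL),
            class = "mcl_result")
}

#' Aggregate per-activity outputs to the cell level
#'
#' Cell output per hectare of cell is the share-weighted sum of the
#' per-hectare outputs of each land-use activity; absolute totals scale by
#' the cell area. Activities without an entry in `outputs_per_ha` (tree,
#' settlement, other) contribute zero.
#'
#' @param outputs_per_ha Named numeric vector of per-activity outputs per
#'   ha of that activity (names among `grass`, `crop`, `tree`,
#'   `settlement`, `other`).
#' @param cell The `cell` config block (shares summing to 1 within 1e-6).
#' @return List with `per_cell_ha` and `total` (scaled by `cell_area_ha`).
#' @export
aggregate_cell <- function(outputs_per_ha, cell) {
  shares <- c(grass = cell$share_grass, crop = cell$share_crop,
              tree = cell$share_tree, settlement = cell$share_settlement,
              other = cell$share_other)
  if (abs(sum(shares) - 1) > 1e-6)
    stop("land-use shares must sum to 1 (tolerance 1e-6)")
  bad <- setdiff(names(outputs_per_ha), names(shares))
  if (length(bad) > 0) stop("unknown activity: ", paste(bad, collapse = ", "))
  per_ha <- sum(outputs_per_ha * shares[names(outputs_per_ha)])
  list(per_cell_ha = per_ha, total = per_ha * cell$cell_area_ha)
}

#' Write simulation results to disk
#'
#' Writes `daily.csv`, `annual.csv` and `metadata.json` (configuration
#' hash, seed, package version) into `out_dir`. Identical results produce
#' byte-identical files.
#'
#' @param result An `mcl_result` from [run_simulation()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("daily.csv", "annual.csv", "metadata.json"))
  utils::write.csv(result$daily, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(result$annual, paths[2], row.names = FALSE, quote = FALSE)
  meta <- list(config_hash = rlang::hash(result$config),
               seed = result$config$run$seed,
               years = result$config$run$years,
               zone = result$config$climate$zone,
               package_version = as.character(utils::packageVersion("mclsim")))
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
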