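# Radiation-use-efficiency crop growth with thermal-time phenology for the
# three staple cereals, plus the rainfall-triggered sowing rule.
#
# Biomass pools are carried in g DM m-2; harvest results are reported in
# kg DM ha-1 (factor 10).

CROP_STAGES <- c("unsown", "sown", "emerged", "anthesis", "mature")

#' Default cultivar parameter sets
#'
#' Parameters for millet (cv. CIVT, Sahelian), maize (cv. EVDT97, Sudanian)
#' and sorghum (cv. Kadaga). The values are illustrative, non-calibrated
#' defaults in the typical range for West African cultivars of these crops;
#' they are meant to be edited per study. Partitioning fractions are defined
#' at development-stage breakpoints (dvs = thermal time / thermal time to
#' maturity) and interpolated linearly; each row sums to 1, so interpolated
#' fractions do too.
#'
#' @param name One of `"maize"`, `"millet"`, `"sorghum"`.
#' @param ... Named overrides of any parameter field.
#' @return An object of class `crop_params` with fields `name`, `t_base`
#'   (degC), `tt_emergence`, `tt_anthesis`, `tt_maturity` (degC day), `rue`
#'   (g DM MJ-1 PAR), `k_ext`, `sla` (m2 g-1), `partition_table`,
#'   `max_root_depth` (m), `root_growth_rate` (m per degC day), `hi_max`,
#'   `n_demand_per_dm` (kg N per kg DM), `residue_feed_fraction`.
#' @export
crop_params <- function(name = c("maize", "millet", "sorghum"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    maize = list(t_base = 8, tt_emergence = 60, tt_anthesis = 700,
                 tt_maturity = 1300, rue = 3.0, k_ext = 0.60, sla = 0.022,
                 max_root_depth = 1.2, root_growth_rate = 0.0012,
                 hi_max = 0.50, n_demand_per_dm = 0.015,
                 residue_feed_fraction = 0.5),
    millet = list(t_base = 10, tt_emergence = 50, tt_anthesis = 600,
                  tt_maturity = 1100, rue = 2.4, k_ext = 0.55, sla = 0.024,
                  max_root_depth = 1.4, root_growth_rate = 0.0014,
                  hi_max = 0.35, n_demand_per_dm = 0.012,
                  residue_feed_fraction = 0.5),
    sorghum = list(t_base = 9, tt_emergence = 55, tt_anthesis = 650,
                   tt_maturity = 1200, rue = 2.6, k_ext = 0.55, sla = 0.022,
                   max_root_depth = 1.5, root_growth_rate = 0.0013,
                   hi_max = 0.40, n_demand_per_dm = 0.013,
                   residue_feed_fraction = 0.5))
  base$name <- name
  # juvenile canopy expansion: relative LAI growth per unit thermal time,
  # active until lai_exp_max (source-limited expansion takes over after)
  base$rgrl <- 0.009
  base$lai_exp_max <- 0.75
  # leaf/stem/root before anthesis, storage after; rows sum to 1
  base$partition_table <- data.frame(
    dvs     = c(0.00, 0.30, 0.55, 0.80, 1.00),
    leaf    = c(0.40, 0.35, 0.15, 0.00, 0.00),
    stem    = c(0.25, 0.35, 0.35, 0.15, 0.05),
    root    = c(0.35, 0.30, 0.20, 0.05, 0.00),
    storage = c(0.00, 0.00, 0.30, 0.80, 0.95))
  params <- utils::modifyList(base, list(...))
  stopifnot(params$tt_emergence < params$tt_anthesis,
            params$tt_anthesis < params$tt_maturity,
            params$hi_max >= 0, params$hi_max <= 1)
  sums <- rowSums(params$partition_table[, c("leaf", "stem", "root", "storage")])
  if (any(abs(sums - 1) > 1e-9)) stop("partition fractions must sum to 1 at every stage")
  class(params) <- "crop_params"
  params
}

#' Empty crop state
#'
#' @param sowing_doy Day of year of sowing (NA until sown).
#' @return An object of class `crop_state` with stage `"unsown"`, zero
#'   thermal time, LAI and biomass pools (`leaf`, `stem`, `root`,
#'   `storage`, g DM m-2), zero root depth and cumulative transpiration.
#' @export
crop_state <- function(sowing_doy = NA_integer_) {
  structure(list(stage = "unsown", tt_sum = 0, lai = 0,
                 biomass = c(leaf = 0, stem = 0, root = 0, storage = 0),
                 root_depth = 0, cum_transpiration = 0,
                 sowing_doy = sowing_doy),
            class = "crop_state")
}

#' Sowing window and rainfall trigger rule
#'
#' Sowing occurs on the first day of the window whose cumulative
#' precipitation over the trailing `accum_days` days reaches
#' `rain_threshold`; if no day in the window qualifies, sowing falls back to
#' the window's last day.
#'
#' @param start_doy,end_doy Window bounds (day of year, start < end).
#' @param rain_threshold Trigger threshold (mm), default 20.
#' @param accum_days Accumulation period (days), default 5.
#' @return An object of class `sowing_window`.
#' @export
sowing_window <- function(start_doy, end_doy, rain_threshold = 20,
                          accum_days = 5) {
  stopifnot(start_doy < end_doy, rain_threshold > 0, accum_days >= 1)
  structure(list(start_doy = as.integer(start_doy),
                 end_doy = as.integer(end_doy),
                 rain_threshold = rain_threshold,
                 accum_days = as.integer(accum_days)),
            class = "sowing_window")
}

#' Determine the sowing date from daily rainfall
#'
#' @param precip Daily precipitation for one year, indexed by day of year
#'   (so `precip[d]` is the rain on day `d`).
#' @param window A [sowing_window()].
#' @return The sowing day of year: the first window day whose trailing
#'   accumulation meets the threshold, else the window's last day.
#' @export
determine_sowing_date <- function(precip, window) {
  if (length(precip) < window$end_doy)
    stop("precipitation series shorter than the sowing window")
  for (d in window$start_doy:window$end_doy) {
    lo <- max(1, d - window$accum_days + 1)
    if (sum(precip[lo:d]) >= window$rain_threshold) return(d)
  }
  window$end_doy
}

#' Advance crop phenology by one day
#'
#' Accumulates thermal time `max(0, tmean - t_base)` and promotes the stage
#' when the accumulated sum crosses the emergence, anthesis and maturity
#' thresholds; stages are never demoted.
#'
#' @param state A sown [crop_state()].
#' @param tmean Daily mean temperature (degC).
#' @param params A [crop_params()].
#' @return The updated `crop_state`.
#' @export
step_phenology <- function(state, tmean, params) {
  if (state$stage == "unsown") stop("cannot advance phenology of an unsown crop")
  if (state$stage == "mature") return(state)
  state$tt_sum <- state$tt_sum + max(0, tmean - params$t_base)
  state$stage <- if (state$tt_sum >= params$tt_maturity) "mature"
    else if (state$tt_sum >= params$tt_anthesis) "anthesis"
    else if (state$tt_sum >= params$tt_emergence) "emerged"
    else state$stage
  state
}

#' Fraction of radiation intercepted by the canopy
#'
#' Beer's law: `1 - exp(-k_ext * lai)`.
#'
#' @param lai Leaf area index (m2 m-2, >= 0).
#' @param k_ext Extinction coefficient (> 0).
#' @return Intercepted fraction in `[0, 1)`.
#' @export
light_interception <- function(lai, k_ext) {
  if (any(lai < 0)) stop("lai must be >= 0")
  stopifnot(k_ext > 0)
  1 - exp(-k_ext * lai)
}

# Organ partition fractions at a development stage (linear interpolation).
.partition_at <- function(table, dvs) {
  dvs <- min(max(dvs, 0), 1)
  vapply(c("leaf", "stem", "root", "storage"), function(organ)
    stats::approx(table$dvs, table[[organ]], xout = dvs, rule = 2)$y,
    numeric(1))
}

#' Grow the crop by one day
#'
#' Daily dry-matter increment `rue * f_int * 0.5 * srad * min(water_factor,
#' n_factor)` (PAR taken as half of global radiation; Liebig-style combined
#' stress), allocated to leaf, stem, root and storage by the stage-dependent
#' partition table. During the juvenile phase (LAI below `lai_exp_max`)
#' the canopy expands exponentially with thermal time at relative rate
#' `rgrl`, slowed by the stress factor; afterwards LAI grows with specific
#' leaf area times the leaf increment. Root depth advances with thermal
#' time up to the maximum.
#' Returns the potential transpiration (`et0 * f_int`) and the nitrogen
#' demand of the new growth for the soil modules.
#'
#' @param state An emerged, non-mature [crop_state()].
#' @param day One row of a `weather_series`.
#' @param water_factor,n_factor Stress factors in `[0, 1]`.
#' @param params A [crop_params()].
#' @param et0 Reference evapotranspiration for the day (mm).
#' @return List with the updated `state`, `transp_demand` (mm) and
#'   `n_demand` (kg N ha-1).
#' @export
step_crop_growth <- function(state, day, water_factor, n_factor, params, et0) {
  if (!state$stage %in% c("emerged", "anthesis"))
    stop("step_crop_growth requires an emerged, non-mature crop")
  stopifnot(water_factor >= 0, water_factor <= 1, n_factor >= 0, n_factor <= 1)
  f_int <- light_interception(state$lai, params$k_ext)
  ddm <- params$rue * f_int * 0.5 * day$srad * min(water_factor, n_factor)
  alloc <- .partition_at(params$partition_table, state$tt_sum / params$tt_maturity)
  state$biomass <- state$biomass + ddm * alloc
  dtt <- max(0, day$tmean - params$t_base)
  if (state$lai < params$lai_exp_max) {
    # juvenile phase: thermal-time-driven exponential canopy expansion,
    # slowed by the same stress factor as assimilation
    state$lai <- state$lai *
      exp(params$rgrl * dtt * min(water_factor, n_factor))
  } else {
    state$lai <- state$lai + params$sla * ddm * alloc[["leaf"]]
  }
  state$root_depth <- min(params$max_root_depth,
                          state$root_depth + params$root_growth_rate * dtt)
  list(state = state,
       transp_demand = et0 * f_int,
       n_demand = ddm * 10 * params$n_demand_per_dm)  # g m-2 -> kg ha-1
}

#' Harvest a mature crop
#'
#' Yield is the storage-organ pool capped at `hi_max` times above-ground
#' biomass (leaf + stem + storage); the remaining above-ground biomass is
#' residue, of which `residue_feed_fraction` is usable as livestock feed.
#' The state is reset to unsown.
#'
#' @param state A mature [crop_state()].
#' @param params A [crop_params()].
#' @return List with `yield_dm`, `residue_total`, `residue_feed`
#'   (kg DM ha-1) and the reset `state`.
#' @export
harvest <- function(state, params) {
  if (state$stage != "mature") stop("cannot harvest before maturity")
  agb <- sum(state$biomass[c("leaf", "stem", "storage")])
  yield <- min(state$biomass[["storage"]], params$hi_max * agb)
  residue <- agb - yield
  list(yield_dm = yield * 10, residue_total = residue * 10,
       residue_feed = residue * 10 * params$residue_feed_fraction,
       state = crop_state())
}

#' Seed a sown crop state
#'
#' Marks the crop as sown on `doy` and gives it the small initial leaf area
#' used at emergence.
#'
#' @param state A [crop_state()].
#' @param doy Sowing day of year.
#' @param initial_lai LAI present at emergence (default 0.02).
#' @return The sown `crop_state`.
#' @export
sow_crop <- function(state, doy, initial_lai = 0.02) {
  state$stage <- "sown"
  state$tt_sum <- 0
  state$lai <- initial_lai
  state$biomass <- c(leaf = 0, stem = 0, root = 0, storage = 0)
  state$root_depth <- 0.05
  state$cum_transpiration <- 0
  state$sowing_doy <- as.integer(doy)
  state
}
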