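# Grassland dynamics with the zone distinction: annual grass (Sahelian) dies
# back each dry season and re-establishes with the rains; perennial grass
# (Sudanian) survives dormancy on a reserve pool, roots deeper, and regrows
# from the reserve. Pools in g DM m-2.

#' Grass parameter set for a habit
#'
#' @param habit `"annual"` (Sahelian zone) or `"perennial"` (Sudanian zone).
#' @param ... Named overrides.
#' @return An object of class `grass_params`: `rue` (g DM MJ-1 PAR),
#'   `k_ext`, `t_base` (degC), `sla` (m2 g-1), `shoot_fraction` (allocation
#'   to shoot vs root), `max_root_depth` (m; deeper for perennials),
#'   `reserve_fraction` (shoot moved to reserve at dormancy, perennial
#'   only), `regrowth_rate` (g m-2 day-1 from reserve), `senescence_rate`
#'   (day-1), `ungrazable_residual` (g DM m-2), `n_demand_per_dm`
#'   (kg N per kg DM), `me_content` (MJ ME kg-1 DM).
#' @export
grass_params <- function(habit = c("annual", "perennial"), ...) {
  habit <- match.arg(habit)
  base <- list(habit = habit, rue = 2.0, k_ext = 0.50, t_base = 10,
               sla = 0.025, shoot_fraction = 0.7,
               max_root_depth = if (habit == "perennial") 1.5 else 0.6,
               reserve_fraction = if (habit == "perennial") 0.3 else 0,
               regrowth_rate = if (habit == "perennial") 5 else 0,
               senescence_rate = 0.01, ungrazable_residual = 15,
               n_demand_per_dm = 0.010, me_content = 8)
  params <- utils::modifyList(base, list(...))
  stopifnot(params$rue > 0, params$reserve_fraction >= 0,
            params$reserve_fraction <= 1)
  if (habit == "annual" && params$reserve_fraction != 0)
    stop("annual grass cannot carry a reserve")
  class(params) <- "grass_params"
  params
}

#' Grass state
#'
#' @param shoot,reserve Pools in g DM m-2 (reserve is perennial only).
#' @param root_depth Rooting depth (m).
#' @param dormant Dormancy flag.
#' @param sla Specific leaf area used to derive LAI from shoot mass.
#' @return An object of class `grass_state` with `shoot`, `reserve`, `lai`,
#'   `root_depth`, `dormant`.
#' @export
grass_state <- function(shoot = 30, reserve = 0, root_depth = 0.3,
                        dormant = FALSE, sla = 0.025) {
  stopifnot(shoot >= 0, reserve >= 0)
  structure(list(shoot = shoot, reserve = reserve, lai = sla * shoot,
                 root_depth = root_depth, dormant = dormant),
            class = "grass_state")
}

#' Grow grass by one day
#'
#' Radiation-use-efficiency growth as for crops, allocated between shoot and
#' root (no storage organ); LAI tracks shoot mass through the specific leaf
#' area. Perennials additionally transfer up to `regrowth_rate` per day from
#' the reserve to the shoot while reserve remains and water is available.
#' A fixed relative senescence rate acts on the shoot. No-op while dormant.
#'
#' @param state A [grass_state()].
#' @param day One row of a `weather_series`.
#' @param water_factor,n_factor Stress factors in `[0, 1]`.
#' @param params A [grass_params()].
#' @param et0 Reference evapotranspiration (mm).
#' @return List with the updated `state` and `transp_demand` (mm).
#' @export
step_grass_growth <- function(state, day, water_factor, n_factor, params, et0) {
  if (state$dormant) return(list(state = state, transp_demand = 0, n_demand = 0))
  stopifnot(water_factor >= 0, water_factor <= 1)
  f_int <- light_interception(state$lai, params$k_ext)
  growth <- params$rue * f_int * 0.5 * day$srad * min(water_factor, n_factor)
  regrowth <- 0
  if (params$habit == "perennial" && state$reserve > 0 && water_factor > 0) {
    regrowth <- min(state$reserve, params$regrowth_rate)
    state$reserve <- state$reserve - regrowth
  }
  senesced <- state$shoot * params$senescence_rate
  state$shoot <- state$shoot + growth * params$shoot_fraction + regrowth - senesced
  dtt <- max(0, day$tmean - params$t_base)
  state$root_depth <- min(params$max_root_depth,
                          state$root_depth + 0.001 * dtt)
  state$lai <- params$sla * state$shoot
  list(state = state, transp_demand = et0 * f_int,
       n_demand = growth * 10 * params$n_demand_per_dm)
}

#' Seasonal transition of the grass sward
#'
#' At dry-season onset annual grass dies back completely; its shoot becomes
#' standing hay credited to the feed store. Perennial grass moves
#' `reserve_fraction` of the shoot into the reserve, keeps the remainder as
#' standing (grazable) dry matter, and goes dormant. At the onset of rains
#' perennials wake from dormancy; annuals re-establish when the
#' establishment rule (same rainfall trigger as sowing) fires.
#'
#' @param state A [grass_state()].
#' @param params A [grass_params()].
#' @param dry_season_onset,rains_onset Logical event flags (at most one
#'   true).
#' @return List with the updated `state` and `standing_hay` (g DM m-2)
#'   released to the feed store (annuals at dry-season onset only).
#' @export
season_transition <- function(state, params, dry_season_onset = FALSE,
                              rains_onset = FALSE) {
  if (dry_season_onset && rains_onset)
    stop("contradictory season flags: dry-season onset and rains onset")
  hay <- 0
  if (dry_season_onset) {
    if (params$habit == "annual") {
      hay <- state$shoot
      state$shoot <- 0
      state$lai <- 0
    } else {
      state$reserve <- state$reserve + state$shoot * params$reserve_fraction
      state$shoot <- state$shoot * (1 - params$reserve_fraction)
      state$lai <- params$sla * state$shoot
    }
    state$dormant <- TRUE
  }
  if (rains_onset) {
    state$dormant <- FALSE
    if (params$habit == "annual" && state$shoot <= 0) {
      state$shoot <- 5            # establishment flush from the seed bank
      state$lai <- params$sla * state$shoot
      state$root_depth <- 0.05
    }
  }
  list(state = state, standing_hay = hay)
}

#' Remove grazed dry matter from the sward
#'
#' Removes `min(demand, shoot - ungrazable_residual)` (never below the
#' residual, never negative) and rescales LAI in proportion to the shoot.
#'
#' @param state A [grass_state()].
#' @param demand_dm Grazing demand (g DM m-2, >= 0).
#' @param ungrazable_residual Shoot mass inaccessible to grazing
#'   (g DM m-2).
#' @return List with the updated `state` and `removed_dm` (g DM m-2).
#' @export
graze <- function(state, demand_dm, ungrazable_residual = 15) {
  stopifnot(demand_dm >= 0)
  removed <- min(demand_dm, max(0, state$shoot - ungrazable_residual))
  if (removed > 0) {
    scale <- (state$shoot - removed) / state$shoot
    state$shoot <- state$shoot - removed
    state$lai <- state$lai * scale
  }
  list(state = state, removed_dm = removed)
}
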