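# Multi-layer tipping-bucket soil water balance with a single mineral-N pool.
# Layer storages are held in mm; volumetric config values are converted at
# construction time.

#' Construct a layered soil profile
#'
#' Layers are ordered top to bottom. Water-holding limits are supplied as
#' volumetric fractions and stored internally as mm per layer
#' (`fraction * thickness_m * 1000`).
#'
#' @param thickness_m Numeric vector of layer thicknesses (m).
#' @param fc_vol,wp_vol,sat_vol Volumetric water content at field capacity,
#'   wilting point and saturation (m3 m-3); recycled over layers.
#' @param infiltration_capacity_mm Maximum daily infiltration (mm day-1);
#'   rain in excess runs off.
#' @param initial_fraction_fc Initial water as a fraction of the
#'   wilting-point-to-field-capacity range.
#' @param mineral_n_kgha Initial mineral nitrogen pool (kg N ha-1).
#' @return An object of class `soil_profile` with per-layer vectors
#'   `thickness`, `fc`, `wp`, `sat`, `water` (all storages in mm) plus
#'   `mineral_n` and `infiltration_capacity`.
#' @export
soil_profile <- function(thickness_m = c(0.2, 0.3, 0.5),
                         fc_vol = 0.25, wp_vol = 0.10, sat_vol = 0.40,
                         infiltration_capacity_mm = 50,
                         initial_fraction_fc = 0.5,
                         mineral_n_kgha = 20) {
  nl <- length(thickness_m)
  if (nl < 1) stop("soil profile needs at least one layer")
  fc_vol <- rep_len(fc_vol, nl); wp_vol <- rep_len(wp_vol, nl)
  sat_vol <- rep_len(sat_vol, nl)
  if (any(wp_vol < 0) || any(wp_vol >= fc_vol) || any(fc_vol > sat_vol))
    stop("soil layers must satisfy 0 <= wp < fc <= sat")
  if (mineral_n_kgha < 0) stop("mineral_n_kgha must be >= 0")
  mm <- thickness_m * 1000
  fc <- fc_vol * mm; wp <- wp_vol * mm; sat <- sat_vol * mm
  water <- wp + initial_fraction_fc * (fc - wp)
  structure(list(thickness = thickness_m, fc = fc, wp = wp, sat = sat,
                 water = water, mineral_n = mineral_n_kgha,
                 infiltration_capacity = infiltration_capacity_mm),
            class = "soil_profile")
}

#' Split daily rainfall into infiltration and runoff
#'
#' Threshold-excess rule: water infiltrates up to the profile's daily
#' infiltration capacity and the remainder runs off, so
#' `infiltration + runoff == rain` exactly.
#'
#' @param rain Daily rainfall (mm, >= 0).
#' @param profile A [soil_profile()].
#' @return List with `infiltration` and `runoff` (mm).
#' @export
partition_rainfall <- function(rain, profile) {
  if (rain < 0) stop("rain must be >= 0")
  infiltration <- min(rain, profile$infiltration_capacity)
  list(infiltration = infiltration, runoff = rain - infiltration)
}

#' Extraterrestrial radiation
#'
#' Daily extraterrestrial (top-of-atmosphere) solar radiation from latitude
#' and day of year, from the standard solar-geometry relations (solar
#' constant 0.0820 MJ m-2 min-1).
#'
#' @param latitude Latitude in decimal degrees.
#' @param doy Day of year (1-366); vectorised.
#' @return Radiation in MJ m-2 day-1.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  ws <- acos(x)
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Hargreaves-Samani reference evapotranspiration
#'
#' `ET0 = 0.0023 * Ra_mm * (tmean + 17.8) * sqrt(tmax - tmin)` with `Ra`
#' expressed in mm of evaporation equivalent. Needs only temperatures, which
#' suits daily simulation where humidity and wind data may be synthetic.
#'
#' @param tmean,tmax,tmin Daily temperatures (degC); `tmax >= tmin` required.
#' @param ra_mm Extraterrestrial radiation in mm day-1 equivalent
#'   (MJ m-2 day-1 times 0.408).
#' @return Reference evapotranspiration (mm day-1, >= 0).
#' @export
hargreaves_et0 <- function(tmean, tmax, tmin, ra_mm) {
  if (any(tmax < tmin)) stop("tmax < tmin in ET0 input")
  pmax(0, 0.0023 * ra_mm * (tmean + 17.8) * sqrt(tmax - tmin))
}

#' Reference evapotranspiration for one weather day
#'
#' Convenience wrapper computing extraterrestrial radiation from latitude
#' and day of year and applying [hargreaves_et0()]. Vectorised over days.
#'
#' @param day One or more rows of a `weather_series` (needs `date`, `tmean`,
#'   `tmax`, `tmin`).
#' @param latitude Latitude in decimal degrees.
#' @return ET0 in mm day-1.
#' @export
reference_et <- function(day, latitude) {
  doy <- as.integer(format(as.Date(day$date), "%j"))
  ra_mm <- extraterrestrial_radiation(latitude, doy) * 0.408
  hargreaves_et0(day$tmean, day$tmax, day$tmin, ra_mm)
}

#' Advance the soil water balance by one day
#'
#' Tipping-bucket cascade: infiltration enters the top layer; each layer
#' spills its surplus above field capacity downward and the bottom layer's
#' surplus leaves as drainage. Soil evaporation is then extracted from the
#' top layer and transpiration from the rooted layers, both limited to the
#' water held above wilting point (transpiration weighted by each rooted
#' layer's available water). The daily water balance closes exactly:
#' `sum(water') - sum(water) = infiltration - E - T - drainage`.
#'
#' @param profile A [soil_profile()].
#' @param infiltration Water entering the profile (mm, from
#'   [partition_rainfall()]).
#' @param evap_demand Potential soil evaporation (mm).
#' @param transp_demand Potential transpiration (mm).
#' @param root_depth Current rooting depth (m); transpiration is taken from
#'   layers (partially) within it.
#' @return List with the updated `profile` and a `flux` list
#'   (`infiltration`, `runoff` (always 0 here), `evaporation`,
#'   `transpiration`, `drainage`, all mm day-1).
#' @export
step_soil_water <- function(profile, infiltration, evap_demand, transp_demand,
                            root_depth) {
  stopifnot(infiltration >= 0, evap_demand >= 0, transp_demand >= 0,
            root_depth >= 0)
  w <- profile$water
  # downward cascade, spilling above field capacity
  carry <- infiltration
  for (i in seq_along(w)) {
    w[i] <- w[i] + carry
    carry <- max(0, w[i] - profile$fc[i])
    w[i] <- min(w[i], profile$fc[i])
  }
  drainage <- carry
  # soil evaporation from the top layer; the demand is reduced linearly
  # with the layer's relative wetness (stage-2 drying) and capped at the
  # water held above wilting point
  rel <- min(1, max(0, (w[1] - profile$wp[1]) / (profile$fc[1] - profile$wp[1])))
  e_act <- min(evap_demand * rel, max(0, w[1] - profile$wp[1]))
  w[1] <- w[1] - e_act
  # transpiration from rooted layers, weighted by available water
  rooted <- .rooted_fractions(profile$thickness, root_depth)
  avail <- pmax(0, w - profile$wp) * rooted
  t_act <- min(transp_demand, sum(avail))
  if (t_act > 0) w <- w - t_act * avail / sum(avail)
  profile$water <- w
  list(profile = profile,
       flux = list(infiltration = infiltration, runoff = 0,
                   evaporation = e_act, transpiration = t_act,
                   drainage = drainage))
}

# Fraction of each layer lying within the root zone.
.rooted_fractions <- function(thickness, root_depth) {
  bottoms <- cumsum(thickness)
  tops <- bottoms - thickness
  pmin(pmax((root_depth - tops) / thickness, 0), 1)
}

#' Plant-available water stress factor over the root zone
#'
#' `f = clamp((W - WP) / (p_crit * (FC - WP)), 0, 1)` computed over the
#' rooted part of the profile (partial layers weighted by the rooted
#' fraction). Equals 1 at or above `p_crit` of the available range and 0 at
#' wilting point.
#'
#' @param profile A [soil_profile()].
#' @param root_depth Rooting depth (m).
#' @param p_crit Critical depletion fraction in (0, 1]; default 0.5.
#' @return Stress factor in `[0, 1]` (1 = no water limitation).
#' @export
drought_factor <- function(profile, root_depth, p_crit = 0.5) {
  stopifnot(root_depth >= 0, p_crit > 0, p_crit <= 1)
  rooted <- .rooted_fractions(profile$thickness, root_depth)
  if (sum(rooted) == 0) rooted <- c(1, rep(0, length(rooted) - 1))
  w <- sum(profile$water * rooted)
  fc <- sum(profile$fc * rooted)
  wp <- sum(profile$wp * rooted)
  if (fc - wp <= 0) stop("degenerate profile: field capacity equals wilting point")
  min(max((w - wp) / (p_crit * (fc - wp)), 0), 1)
}

#' Advance the mineral nitrogen pool by one day
#'
#' Inputs (fertilizer, manure, mineralization) enter a single pool; plant
#' uptake is the demand capped at the pool; a fraction of the remainder
#' leaches in proportion to drainage relative to the profile's total
#' field-capacity storage. The nitrogen limitation factor returned is
#' `uptake / demand` (1 when demand is zero).
#'
#' @param profile A [soil_profile()].
#' @param n_inputs Nitrogen inputs for the day (kg N ha-1).
#' @param uptake_demand Crop/grass nitrogen demand (kg N ha-1).
#' @param drainage Same-day drainage below the root zone (mm).
#' @param leach_lambda Proportional leaching coefficient (default 0.5).
#' @return List with the updated `profile`, `uptake`, `leached` (kg N ha-1)
#'   and `n_factor` in `[0, 1]`.
#' @export
step_soil_nitrogen <- function(profile, n_inputs, uptake_demand, drainage,
                               leach_lambda = 0.5) {
  stopifnot(n_inputs >= 0, uptake_demand >= 0, drainage >= 0)
  pool <- profile$mineral_n + n_inputs
  uptake <- min(uptake_demand, pool)
  pool <- pool - uptake
  capacity <- sum(profile$fc)
  leached <- pool * leach_lambda * min(1, drainage / capacity)
  pool <- pool - leached
  profile$mineral_n <- pool
  n_factor <- if (uptake_demand == 0) 1 else uptake / uptake_demand
  list(profile = profile, uptake = uptake, leached = leached,
       n_factor = n_factor)
}
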