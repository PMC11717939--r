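# Daily weather forcing: zone-specific stochastic generator, climate-change
# deltas, and the CSV dialect used by the rest of the package.

WEATHER_COLUMNS <- c("date", "tmin", "tmax", "tmean", "precip", "srad", "rh", "wind")

#' Climate specification for one agro-ecological zone
#'
#' Bundles the parameters of the stochastic daily weather generator for the
#' Sahelian or Sudanian savanna zone. Defaults place the Sahelian zone at
#' roughly 400 mm of annual rainfall falling in a short unimodal wet season
#' (about 100 days from mid-June) and the Sudanian zone at roughly 900 mm
#' over a longer season, with interannual rainfall variability typical of
#' each zone.
#'
#' @param zone `"sahelian"` or `"sudanian"`.
#' @param annual_rain_mm Target long-run mean annual rainfall (mm).
#' @param wet_season_start_doy Day of year on which the wet-season window opens.
#' @param wet_season_length_days Length of the wet-season window (days, < 366).
#' @param tmax_mean,tmin_mean Annual mean daily maximum/minimum temperature (degC).
#' @param cv_rain Interannual coefficient of variation of annual rainfall (%).
#' @param latitude Site latitude (decimal degrees), used for radiation.
#' @param seed Integer seed making the generated series reproducible.
#' @return An object of class `zone_climate_spec`.
#' @seealso [generate_weather()]
#' @export
zone_climate_spec <- function(zone = c("sahelian", "sudanian"),
                              annual_rain_mm = NULL,
                              wet_season_start_doy = NULL,
                              wet_season_length_days = NULL,
                              tmax_mean = NULL,
                              tmin_mean = NULL,
                              cv_rain = NULL,
                              latitude = NULL,
                              seed = 1L) {
  zone <- match.arg(zone)
  defaults <- switch(zone,
    sahelian = list(annual_rain_mm = 400, wet_season_start_doy = 166L,
                    wet_season_length_days = 100L, tmax_mean = 36,
                    tmin_mean = 22, cv_rain = 30, latitude = 14),
    sudanian = list(annual_rain_mm = 900, wet_season_start_doy = 135L,
                    wet_season_length_days = 160L, tmax_mean = 33,
                    tmin_mean = 20, cv_rain = 25, latitude = 11))
  spec <- list(
    zone = zone,
    annual_rain_mm = annual_rain_mm %||% defaults$annual_rain_mm,
    wet_season_start_doy = as.integer(wet_season_start_doy %||% defaults$wet_season_start_doy),
    wet_season_length_days = as.integer(wet_season_length_days %||% defaults$wet_season_length_days),
    tmax_mean = tmax_mean %||% defaults$tmax_mean,
    tmin_mean = tmin_mean %||% defaults$tmin_mean,
    cv_rain = cv_rain %||% defaults$cv_rain,
    latitude = latitude %||% defaults$latitude,
    seed = as.integer(seed))
  stopifnot(spec$annual_rain_mm > 0,
            spec$wet_season_length_days > 0, spec$wet_season_length_days < 366,
            spec$cv_rain >= 0)
  class(spec) <- "zone_climate_spec"
  spec
}

#' Climate-change delta for scenario runs
#'
#' Additive temperature shifts and a multiplicative precipitation factor,
#' applied uniformly to a weather series. Ensemble projections for the study
#' region put near-future warming around +1.2 to +1.6 degC with rainfall
#' changes of roughly +5 to +22 %.
#'
#' @param delta_tmax,delta_tmin Temperature shifts (degC).
#' @param precip_factor Multiplicative precipitation factor (1 = unchanged).
#' @return An object of class `climate_delta`.
#' @export
climate_delta <- function(delta_tmax = 0, delta_tmin = 0, precip_factor = 1) {
  if (precip_factor < 0) stop("precip_factor must be >= 0")
  structure(list(delta_tmax = delta_tmax, delta_tmin = delta_tmin,
                 precip_factor = precip_factor),
            class = "climate_delta")
}

#' Generate a synthetic daily weather series for a zone
#'
#' Stochastic daily weather emulating the Sahelian / Sudanian regimes.
#' Rainfall occurrence inside the wet-season window follows a two-state
#' (wet/dry) Markov chain; wet-day amounts are exponential and rescaled so
#' that each year's total equals the zone target times a lognormal year
#' factor with mean 1 and coefficient of variation `cv_rain`. No rain falls
#' outside the window. Temperatures follow a seasonal sine around the zone
#' means with Gaussian noise; solar radiation follows a clear-sky seasonal
#' curve damped 25 % on wet days; humidity is higher in the wet season.
#'
#' The series is deterministic given the spec (including its `seed`), uses a
#' real calendar with leap days, and satisfies the per-day invariants
#' (tmin <= tmean <= tmax, non-negative rain/radiation/wind, humidity in
#' 0-100).
#'
#' @param spec A [zone_climate_spec()].
#' @param n_years Number of calendar years to generate (>= 1).
#' @param start_year First calendar year.
#' @param site_id Identifier stored on the series.
#' @return A `weather_series`: a data frame with columns
#'   `date, tmin, tmax, tmean, precip, srad, rh, wind` and attributes
#'   `site_id` and `latitude`.
#' @examples
#' w <- generate_weather(zone_climate_spec("sahelian", seed = 1), n_years = 2)
#' sum(w$precip) / 2  # close to the 400 mm zone target
#' @export
generate_weather <- function(spec, n_years, start_year = 2001L, site_id = NULL) {
  if (!inherits(spec, "zone_climate_spec")) stop("spec must be a zone_climate_spec")
  if (length(n_years) != 1 || n_years < 1) stop("n_years must be >= 1")
  n_years <- as.integer(n_years)
  withr::with_seed(spec$seed, {
    years <- seq(start_year, length.out = n_years)
    per_year <- lapply(years, function(y) .generate_weather_year(spec, y))
    out <- do.call(rbind, per_year)
  })
  rownames(out) <- NULL
  weather_series(out, site_id = site_id %||% spec$zone, latitude = spec$latitude)
}

# One calendar year of daily weather; relies on the caller's RNG state.
.generate_weather_year <- function(spec, year) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  win <- doy >= spec$wet_season_start_doy &
    doy < spec$wet_season_start_doy + spec$wet_season_length_days

  # rainfall: Markov-chain occurrence inside the window, exponential amounts
  # rescaled to the (lognormal-perturbed) annual target
  cv <- spec$cv_rain / 100
  year_factor <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else 1
  target <- spec$annual_rain_mm * year_factor
  p01 <- 0.35; p11 <- 0.75     # dry->wet, wet->wet transition probabilities
  wet <- logical(n)
  u <- stats::runif(n)
  prev <- FALSE
  for (i in which(win)) {
    wet[i] <- u[i] < (if (prev) p11 else p01)
    prev <- wet[i]
  }
  if (!any(wet) && any(win)) wet[which(win)[spec$wet_season_length_days %/% 2 + 1]] <- TRUE
  precip <- numeric(n)
  if (any(wet)) {
    amounts <- stats::rexp(sum(wet))
    precip[wet] <- amounts / sum(amounts) * target
  }

  # temperatures: seasonal sine peaking just before the rains, cooler wet days
  peak <- spec$wet_season_start_doy - 45
  seas <- cos(2 * pi * (doy - peak) / 365.25)
  tmax <- spec$tmax_mean + 3.5 * seas - 1.5 * wet + stats::rnorm(n, sd = 1.0)
  tmin <- spec$tmin_mean + 3.0 * seas + stats::rnorm(n, sd = 0.8)
  tmax <- pmax(tmax, tmin + 0.5)
  tmean <- (tmin + tmax) / 2

  srad <- 22 + 2 * seas + stats::rnorm(n, sd = 0.5)
  srad <- pmax(srad, 1)
  srad[wet] <- srad[wet] * 0.75

  rh <- 35 + 35 * win + 10 * wet + stats::rnorm(n, sd = 3)
  rh <- pmin(pmax(rh, 5), 100)
  wind <- pmax(stats::rnorm(n, mean = 2.5, sd = 0.6), 0.1)

  data.frame(date = dates, tmin = tmin, tmax = tmax, tmean = tmean,
             precip = precip, srad = srad, rh = rh, wind = wind)
}

#' Construct and validate a weather series
#'
#' @param df Data frame with columns `date, tmin, tmax, precip, srad, rh,
#'   wind` (and optionally `tmean`, filled as `(tmin + tmax) / 2` when
#'   absent).
#' @param site_id Site identifier.
#' @param latitude Latitude in decimal degrees.
#' @return A validated `weather_series`.
#' @export
weather_series <- function(df, site_id = "site", latitude = 13) {
  required <- setdiff(WEATHER_COLUMNS, "tmean")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("weather series is missing column(s): ", paste(missing, collapse = ", "))
  if (!inherits(df$date, "Date")) df$date <- as.Date(df$date)
  if (is.null(df$tmean)) df$tmean <- (df$tmin + df$tmax) / 2
  df <- df[, WEATHER_COLUMNS]
  validate_weather_series(df)
  structure(df, site_id = site_id, latitude = latitude,
            class = c("weather_series", "data.frame"))
}

#' Check the per-day invariants of a weather series
#'
#' Errors (citing the first offending row) if dates are non-increasing or
#' gapped, `tmin <= tmean <= tmax` is violated, or rain, radiation, humidity
#' or wind fall outside their physical ranges.
#'
#' @param df A weather series (or plain data frame with the same columns).
#' @return Invisibly `TRUE`.
#' @export
validate_weather_series <- function(df) {
  fail <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      stop(sprintf("weather validation failed at row %d: %s",
                   which(rows)[1], what), call. = FALSE)
  }
  if (nrow(df) > 1) {
    d <- diff(as.integer(df$date))
    if (any(d <= 0)) stop(sprintf(
      "weather dates not strictly increasing at row %d", which(d <= 0)[1] + 1),
      call. = FALSE)
    if (any(d != 1)) stop(sprintf(
      "gap in weather dates at row %d", which(d != 1)[1] + 1), call. = FALSE)
  }
  fail(df$tmin > df$tmax, "tmin > tmax")
  fail(df$tmean < df$tmin - 1e-9 | df$tmean > df$tmax + 1e-9,
       "tmean outside [tmin, tmax]")
  fail(df$precip < 0, "negative precipitation")
  fail(df$srad < 0, "negative solar radiation")
  fail(df$rh < 0 | df$rh > 100, "relative humidity outside [0, 100]")
  fail(df$wind < 0, "negative wind speed")
  invisible(TRUE)
}

#' Apply a climate-change delta to a weather series
#'
#' Shifts each day's `tmax` and `tmin` additively, recomputes `tmean` as
#' their midpoint, and multiplies precipitation by `precip_factor`; all
#' other fields are unchanged. Deltas compose: applying two deltas equals
#' one delta with summed temperature shifts and multiplied precipitation
#' factors.
#'
#' @param series A `weather_series`.
#' @param delta A [climate_delta()].
#' @return The shifted `weather_series`.
#' @export
apply_climate_delta <- function(series, delta) {
  if (!inherits(delta, "climate_delta")) stop("delta must be a climate_delta")
  series$tmax <- series$tmax + delta$delta_tmax
  series$tmin <- series$tmin + delta$delta_tmin
  series$tmean <- (series$tmin + series$tmax) / 2
  series$precip <- series$precip * delta$precip_factor
  series
}

#' Read a weather series from CSV
#'
#' Expects the dialect `date,tmin,tmax,precip,srad,rh,wind` (comma-separated,
#' ISO dates, '.' decimal); `tmean` is filled as `(tmin + tmax) / 2` when the
#' column is absent. Validation errors cite the offending row.
#'
#' @param path Path to the CSV file.
#' @param site_id,latitude Metadata attached to the series.
#' @return A `weather_series`.
#' @export
read_weather_csv <- function(path, site_id = "site", latitude = 13) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(WEATHER_COLUMNS, "tmean")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("weather CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  weather_series(df, site_id = site_id, latitude = latitude)
}

#' Write a weather series to CSV
#'
#' Writes the canonical column set (without the derived `tmean`);
#' [read_weather_csv()] round-trips the series.
#'
#' @param series A `weather_series`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_weather_csv <- function(series, path) {
  out <- as.data.frame(series)[, setdiff(WEATHER_COLUMNS, "tmean")]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
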