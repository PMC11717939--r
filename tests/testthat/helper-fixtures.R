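# Shared fixtures: small soil profiles, constant weather days and compact
# scenario configs, all built in code.

make_day <- function(tmin = 22, tmax = 34, precip = 0, srad = 20, rh = 50,
                     wind = 2, date = as.Date("2001-07-15")) {
  data.frame(date = date, tmin = tmin, tmax = tmax, tmean = (tmin + tmax) / 2,
             precip = precip, srad = srad, rh = rh, wind = wind)
}

# two-layer toy profile: per-layer fc 50/75 mm, wp 20/30 mm
make_profile <- function(initial_fraction_fc = 0.5, capacity = 50) {
  soil_profile(thickness_m = c(0.2, 0.3), fc_vol = 0.25, wp_vol = 0.10,
               sat_vol = 0.40, infiltration_capacity_mm = capacity,
               initial_fraction_fc = initial_fraction_fc)
}

make_herd <- function(counts = c(10, 8, 5, 11, 9, 20), weights = NULL) {
  herd_state(count = stats::setNames(counts, mclsim::HERD_CLASSES),
             mean_weight = if (is.null(weights))
               stats::setNames(c(50, 150, 250, 45, 140, 220),
                               mclsim::HERD_CLASSES)
             else stats::setNames(weights, mclsim::HERD_CLASSES))
}

# single-class herd: all animals in AdultsMale, every other class empty
single_class_herd <- function(n = 100, weight = 250) {
  counts <- stats::setNames(rep(0, 6), mclsim::HERD_CLASSES)
  counts[["AdultsMale"]] <- n
  weights <- stats::setNames(rep(weight, 6), mclsim::HERD_CLASSES)
  herd_state(count = counts, mean_weight = weights)
}

# demography with every rate zeroed; override what the test needs
null_demography <- function(...) {
  zero6 <- stats::setNames(rep(0, 6), mclsim::HERD_CLASSES)
  args <- utils::modifyList(list(
    parturition_annual = 0, prolification = 0,
    base_mortality_annual = zero6,
    starvation_mortality_max_annual = zero6,
    survival_for_gamma = c(JuvenilesMale = 1e-12, SubAdultsMale = 1e-12,
                           JuvenilesFemale = 1e-12, SubAdultsFemale = 1e-12),
    offtake_annual = zero6, weight_gain_max = zero6, weight_loss_max = zero6),
    list(...))
  do.call(demography_params, args)
}

small_config <- function(zone = "sahelian", years = 2, seed = 1, ...) {
  cfg <- default_config(zone = zone, years = years, seed = seed)
  utils::modifyList(cfg, list(...))
}
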