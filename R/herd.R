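# Six-class livestock demographic projection (DynMod lineage): daily births,
# mortality with a starvation component, gamma class transitions, fractional
# offtake, live-weight tracking, and meat / milk / methane / manure outputs.
# Animal counts are non-negative reals: the daily time step makes fractional
# flows (including decimal sales) the natural representation.

#' The six age-by-sex herd classes
#'
#' @format Character vector of length six, in the fixed order used by all
#'   herd functions.
#' @export
HERD_CLASSES <- c("JuvenilesMale", "SubAdultsMale", "AdultsMale",
                  "JuvenilesFemale", "SubAdultsFemale", "AdultsFemale")

#' Herd state: counts, mean live weights and the cash ledger
#'
#' @param count Named numeric vector of animals per class (fractions
#'   allowed); names must be the six [HERD_CLASSES].
#' @param mean_weight Named numeric vector of mean live weight per class
#'   (kg, > 0).
#' @param cash Household cash (currency units).
#' @return An object of class `herd_state`. Total herd live weight is
#'   always `sum(count * mean_weight)`.
#' @export
herd_state <- function(count = c(JuvenilesMale = 6, SubAdultsMale = 5,
                                 AdultsMale = 4, JuvenilesFemale = 7,
                                 SubAdultsFemale = 6, AdultsFemale = 12),
                       mean_weight = c(JuvenilesMale = 50, SubAdultsMale = 150,
                                       AdultsMale = 250, JuvenilesFemale = 45,
                                       SubAdultsFemale = 140, AdultsFemale = 220),
                       cash = 50000) {
  count <- count[HERD_CLASSES]; mean_weight <- mean_weight[HERD_CLASSES]
  if (anyNA(count) || anyNA(mean_weight))
    stop("count and mean_weight must be named over the six herd classes")
  stopifnot(all(count >= 0), all(mean_weight > 0))
  structure(list(count = count, mean_weight = mean_weight, cash = cash),
            class = "herd_state")
}

#' Total herd live weight
#'
#' @param herd A [herd_state()].
#' @return Sum over classes of count times mean weight (kg).
#' @export
total_live_weight <- function(herd) sum(herd$count * herd$mean_weight)

#' Demographic and production rate parameters
#'
#' All annual rates are converted to daily rates by division by 365 (the
#' model runs on a daily step). Defaults describe an extensive Sahelian
#' cattle herd and are per-class where relevant.
#'
#' @param ... Named overrides of any field.
#' @return An object of class `demography_params` with fields
#'   `parturition_annual` (parturitions per adult female per year),
#'   `prolification` (offspring per parturition), `sex_ratio_male`,
#'   `base_mortality_annual` (per class),
#'   `starvation_mortality_max_annual` (per class, scaled by
#'   `1 - energy stress`), `class_duration_days` and `survival_for_gamma`
#'   (per promoting class), `offtake_annual` and `intake_annual` (per
#'   class), `carcass_fraction`, `milk_yield_potential` (kg head-1 day-1),
#'   `lactating_fraction`, `weight_gain_max` / `weight_loss_max`
#'   (kg day-1, per class), `min_viable_weight` (kg floor), `ch4_yield`
#'   (kg CH4 per kg DM intake), `n_excretion_fraction`.
#' @export
demography_params <- function(...) {
  per_class <- function(j, s, a) {
    stats::setNames(c(j, s, a, j, s, a), HERD_CLASSES)
  }
  base <- list(
    parturition_annual = 0.6,
    prolification = 1.0,
    sex_ratio_male = 0.5,
    base_mortality_annual = per_class(0.15, 0.08, 0.05),
    starvation_mortality_max_annual = per_class(0.40, 0.30, 0.25),
    class_duration_days = c(JuvenilesMale = 365, SubAdultsMale = 730,
                            JuvenilesFemale = 365, SubAdultsFemale = 730),
    survival_for_gamma = c(JuvenilesMale = 0.85, SubAdultsMale = 0.92,
                           JuvenilesFemale = 0.85, SubAdultsFemale = 0.92),
    offtake_annual = stats::setNames(c(0.02, 0.05, 0.25, 0.02, 0.03, 0.08),
                                     HERD_CLASSES),
    intake_annual = stats::setNames(numeric(6), HERD_CLASSES),
    carcass_fraction = 0.5,
    milk_yield_potential = 2.0,
    lactating_fraction = 0.5,
    weight_gain_max = per_class(0.25, 0.20, 0.15),
    weight_loss_max = per_class(0.30, 0.35, 0.40),
    min_viable_weight = 10,
    ch4_yield = 0.021,
    n_excretion_fraction = 0.8)
  params <- utils::modifyList(base, list(...))
  class(params) <- "demography_params"
  params
}

#' Daily class-promotion rate (the gamma factor)
#'
#' Combines the survival probability over a class with the expected
#' residence duration: `gamma = survival / duration_days`, the daily
#' fraction of the class promoted to the next one.
#'
#' @param duration_days Residence duration in the class (days, >= 1).
#' @param survival Probability of surviving the class (0 < survival <= 1).
#' @return Daily promotion rate.
#' @export
class_transition_rate <- function(duration_days, survival) {
  if (any(duration_days < 1)) stop("class duration must be >= 1 day")
  stopifnot(all(survival > 0), all(survival <= 1))
  survival / duration_days
}

#' Advance herd demography by one day
#'
#' All flows are computed from start-of-day counts, making the update linear
#' in the counts when no class is emptied:
#' births = adult females x (parturition/365) x prolification, split between
#' the two juvenile classes by the birth sex ratio; deaths combine the base
#' mortality with a starvation component scaled by `1 - energy_stress`;
#' promotions move `count x gamma` animals juveniles -> subadults -> adults
#' within each sex; offtake and intake apply their daily rates. If removals
#' (deaths + promotions out + offtake) would exceed what is available, they
#' are scaled down so the class empties exactly to zero.
#'
#' @param herd A [herd_state()].
#' @param params A [demography_params()].
#' @param energy_stress Feed-energy stress index in `[0, 1]` (1 = no
#'   stress).
#' @return List with the updated `herd` and a `flows` data frame (per-class
#'   `births`, `deaths`, `promotions_in`, `promotions_out`, `offtake`,
#'   `intake`, animals day-1).
#' @export
step_demography <- function(herd, params, energy_stress) {
  stopifnot(energy_stress >= 0, energy_stress <= 1)
  n <- herd$count
  zero <- stats::setNames(numeric(6), HERD_CLASSES)

  births_total <- n[["AdultsFemale"]] * params$parturition_annual / 365 *
    params$prolification
  births <- zero
  births[["JuvenilesMale"]] <- births_total * params$sex_ratio_male
  births[["JuvenilesFemale"]] <- births_total * (1 - params$sex_ratio_male)

  mort_daily <- params$base_mortality_annual / 365 +
    params$starvation_mortality_max_annual / 365 * (1 - energy_stress)
  deaths <- n * mort_daily[HERD_CLASSES]

  gamma <- class_transition_rate(params$class_duration_days,
                                 params$survival_for_gamma[names(params$class_duration_days)])
  promotions_out <- zero
  promotions_out[names(gamma)] <- n[names(gamma)] * gamma
  promotions_in <- zero
  promotions_in[["SubAdultsMale"]] <- promotions_out[["JuvenilesMale"]]
  promotions_in[["AdultsMale"]] <- promotions_out[["SubAdultsMale"]]
  promotions_in[["SubAdultsFemale"]] <- promotions_out[["JuvenilesFemale"]]
  promotions_in[["AdultsFemale"]] <- promotions_out[["SubAdultsFemale"]]

  offtake <- n * params$offtake_annual[HERD_CLASSES] / 365
  intake <- params$intake_annual[HERD_CLASSES]
  intake <- if (all(intake == 0)) zero else intake / 365

  # cap removals so no class goes negative (empties exactly to zero)
  removals <- deaths + promotions_out + offtake
  additions <- births + promotions_in + intake
  over <- removals > n + additions
  if (any(over)) {
    scale <- (n[over] + additions[over]) / removals[over]
    deaths[over] <- deaths[over] * scale
    offtake[over] <- offtake[over] * scale
    po_scaled <- promotions_out[over] * scale
    # keep promotion bookkeeping consistent downstream
    for (cls in names(promotions_out)[over]) {
      dest <- switch(cls, JuvenilesMale = "SubAdultsMale",
                     SubAdultsMale = "AdultsMale",
                     JuvenilesFemale = "SubAdultsFemale",
                     SubAdultsFemale = "AdultsFemale", NA_character_)
      if (!is.na(dest))
        promotions_in[[dest]] <- promotions_in[[dest]] -
          (promotions_out[[cls]] - po_scaled[[cls]])
    }
    promotions_out[over] <- po_scaled
  }

  herd$count <- pmax(n + births + promotions_in + intake -
                       deaths - promotions_out - offtake, 0)
  flows <- data.frame(class = HERD_CLASSES, births = births, deaths = deaths,
                      promotions_in = promotions_in,
                      promotions_out = promotions_out,
                      offtake = offtake, intake = intake,
                      row.names = NULL)
  list(herd = herd, flows = flows)
}

#' Update mean live weights under energy stress
#'
#' `mean_weight += weight_gain_max * stress - weight_loss_max * (1 -
#' stress)` per class, floored at the minimum viable weight.
#'
#' @param herd A [herd_state()].
#' @param params A [demography_params()].
#' @param energy_stress Stress index in `[0, 1]`.
#' @return The updated `herd_state`.
#' @export
update_live_weights <- function(herd, params, energy_stress) {
  stopifnot(energy_stress >= 0, energy_stress <= 1)
  delta <- params$weight_gain_max[HERD_CLASSES] * energy_stress -
    params$weight_loss_max[HERD_CLASSES] * (1 - energy_stress)
  herd$mean_weight <- pmax(herd$mean_weight + delta, params$min_viable_weight)
  herd
}

#' Carcass (meat) mass from live weight
#'
#' @param live_weight_kg Live weight sold or slaughtered (kg, >= 0).
#' @param carcass_fraction Dressed carcass fraction of live weight.
#' @return Carcass mass (kg).
#' @export
meat_production <- function(live_weight_kg, carcass_fraction) {
  if (carcass_fraction < 0 || carcass_fraction > 1)
    stop("carcass_fraction must be in [0, 1]")
  stopifnot(all(live_weight_kg >= 0))
  live_weight_kg * carcass_fraction
}

#' Daily milk production
#'
#' Adult females times the lactating fraction times the potential yield,
#' scaled linearly by the energy-stress index (no feed, no milk).
#'
#' @param herd A [herd_state()].
#' @param params A [demography_params()].
#' @param energy_stress Stress index in `[0, 1]`.
#' @return Milk (kg day-1).
#' @export
milk_production <- function(herd, params, energy_stress) {
  stopifnot(energy_stress >= 0, energy_stress <= 1)
  herd$count[["AdultsFemale"]] * params$lactating_fraction *
    params$milk_yield_potential * energy_stress
}

#' Enteric methane from dry-matter intake
#'
#' Linear emission factor (default 0.021 kg CH4 per kg DM intake, a typical
#' tier-2 value for tropical cattle diets).
#'
#' @param dm_intake_kg Dry-matter intake (kg DM day-1).
#' @param ch4_yield Emission factor (kg CH4 per kg DM).
#' @return Methane emission (kg CH4 day-1).
#' @export
methane_emission <- function(dm_intake_kg, ch4_yield) {
  stopifnot(all(dm_intake_kg >= 0), ch4_yield >= 0)
  dm_intake_kg * ch4_yield
}

#' Manure nitrogen excretion
#'
#' @param n_intake_kg Nitrogen ingested with feed (kg N day-1).
#' @param excretion_fraction Fraction of intake excreted (0-1); the engine
#'   routes the excreted N to cropland and grassland pools by a config
#'   share.
#' @return Excreted nitrogen (kg N day-1).
#' @export
manure_nitrogen <- function(n_intake_kg, excretion_fraction) {
  if (excretion_fraction < 0 || excretion_fraction > 1)
    stop("excretion_fraction must be in [0, 1]")
  stopifnot(all(n_intake_kg >= 0))
  n_intake_kg * excretion_fraction
}
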