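# Feed-energy supply, the 0-1 energy-stress index, concentrate purchase and
# sell-out management. Feed pools are kept at herd (cell) scale in kg DM;
# energy in MJ of metabolizable energy (ME).

#' Feed store
#'
#' Standing grass is owned by the grassland module and exposed here through
#' `grass_dm` (the engine refreshes it daily from the sward and removes what
#' is eaten via [graze()]); residues and concentrates are true pools.
#'
#' @param grass_dm Standing grazable grass (kg DM).
#' @param residue_dm Crop-residue pool (kg DM).
#' @param concentrate_dm Concentrate pool (kg DM).
#' @param me_grass,me_residue,me_concentrate Metabolizable-energy contents
#'   (MJ ME kg-1 DM).
#' @return An object of class `feed_store`.
#' @export
feed_store <- function(grass_dm = 0, residue_dm = 0, concentrate_dm = 0,
                       me_grass = 8, me_residue = 7, me_concentrate = 12) {
  stopifnot(grass_dm >= 0, residue_dm >= 0, concentrate_dm >= 0,
            me_grass > 0, me_residue > 0, me_concentrate > 0)
  structure(list(grass_dm = grass_dm, residue_dm = residue_dm,
                 concentrate_dm = concentrate_dm, me_grass = me_grass,
                 me_residue = me_residue, me_concentrate = me_concentrate),
            class = "feed_store")
}

#' Market and sell-out management parameters
#'
#' @param concentrate_price Price per kg DM of concentrate.
#' @param animal_price Price per kg live weight.
#' @param milk_price Price per kg milk.
#' @param stress_sell_threshold Stress level below which (with an unmet
#'   feed deficit and no purchasing power left) animals are sold.
#' @param household_expenditure Daily cash drawn from the store for
#'   household needs (floored at zero); the cash box finances both the
#'   household and feed purchases, so livestock revenue does not accumulate
#'   into an unbounded concentrate buffer.
#' @param sell_priority Order in which classes are sold; the default sells
#'   males first and withholds adult (breeding) females entirely, so a
#'   total feed failure cannot liquidate the reproductive core — those
#'   animals face starvation mortality instead.
#' @return An object of class `market_params`.
#' @export
market_params <- function(concentrate_price = 250, animal_price = 700,
                          milk_price = 150, stress_sell_threshold = 0.6,
                          household_expenditure = 2500,
                          sell_priority = c("AdultsMale", "SubAdultsMale",
                                            "JuvenilesMale", "SubAdultsFemale",
                                            "JuvenilesFemale")) {
  sell_priority <- unlist(sell_priority)
  stopifnot(concentrate_price >= 0, animal_price >= 0, milk_price >= 0,
            stress_sell_threshold >= 0, stress_sell_threshold <= 1,
            all(sell_priority %in% HERD_CLASSES))
  structure(list(concentrate_price = concentrate_price,
                 animal_price = animal_price, milk_price = milk_price,
                 stress_sell_threshold = stress_sell_threshold,
                 household_expenditure = household_expenditure,
                 sell_priority = sell_priority),
            class = "market_params")
}

#' Daily herd feed-energy demand
#'
#' Metabolic-weight scaling: `sum over classes of count * coefficient *
#' weight^0.75`. The single coefficient folds maintenance and production
#' requirements together.
#'
#' @param herd A [herd_state()].
#' @param maintenance_mj_per_kg075 ME requirement per kg of metabolic
#'   weight (MJ kg^-0.75 day-1), default 0.5.
#' @return Demand (MJ day-1).
#' @export
energy_demand <- function(herd, maintenance_mj_per_kg075 = 0.5) {
  sum(herd$count * maintenance_mj_per_kg075 * herd$mean_weight^0.75)
}

#' Draw feed to meet the day's energy demand
#'
#' Feed is drawn in the order grass, then residue, then stored concentrate,
#' until the demand is met, the dry-matter intake capacity is reached, or
#' the pools are empty. Each source contributes its DM times its ME
#' content.
#'
#' @param store A [feed_store()] (with `grass_dm` set to today's grazable
#'   grass).
#' @param max_intake_dm Intake capacity (kg DM day-1).
#' @param demand_mj Energy demand (MJ).
#' @return List with `supply_mj`, the decremented `store`, and
#'   `dm_intake_by_source` (named kg DM for grass / residue /
#'   concentrate).
#' @export
energy_supply <- function(store, max_intake_dm, demand_mj) {
  stopifnot(max_intake_dm >= 0, demand_mj >= 0)
  remaining_mj <- demand_mj
  remaining_dm <- max_intake_dm
  drawn <- c(grass = 0, residue = 0, concentrate = 0)
  for (source in names(drawn)) {
    pool <- store[[paste0(source, "_dm")]]
    me <- store[[paste0("me_", source)]]
    take <- min(pool, remaining_dm, remaining_mj / me)
    drawn[[source]] <- take
    store[[paste0(source, "_dm")]] <- pool - take
    remaining_dm <- remaining_dm - take
    remaining_mj <- remaining_mj - take * me
    if (remaining_mj <= 0 || remaining_dm <= 0) break
  }
  supply_mj <- drawn[["grass"]] * store$me_grass +
    drawn[["residue"]] * store$me_residue +
    drawn[["concentrate"]] * store$me_concentrate
  list(supply_mj = supply_mj, store = store, dm_intake_by_source = drawn)
}

#' Feed-energy stress index
#'
#' Ratio of supply to demand capped at 1; 0 means high stress (no feed), 1
#' means no stress (demand fully met). Zero demand is unstressed by
#' definition.
#'
#' @param supply_mj,demand_mj Daily energy supply and demand (MJ, >= 0).
#' @return Stress index in `[0, 1]`.
#' @export
energy_stress <- function(supply_mj, demand_mj) {
  stopifnot(supply_mj >= 0, demand_mj >= 0)
  if (demand_mj == 0) 1 else min(1, supply_mj / demand_mj)
}

#' Buy concentrate feed within the cash limit
#'
#' Buys the dry matter needed to close an energy deficit, capped by
#' purchasing power; cash never goes negative.
#'
#' @param deficit_mj Unmet energy demand (MJ).
#' @param cash Available cash.
#' @param market A [market_params()].
#' @param me_concentrate ME content of the concentrate (MJ kg-1, > 0).
#' @return List with `dm_bought` (kg), `cost` and the updated `cash`.
#' @export
concentrate_purchase <- function(deficit_mj, cash, market, me_concentrate) {
  stopifnot(deficit_mj >= 0, cash >= 0)
  if (me_concentrate <= 0) stop("concentrate ME content must be > 0")
  dm_needed <- deficit_mj / me_concentrate
  affordable <- if (market$concentrate_price > 0)
    cash / market$concentrate_price else Inf
  dm_bought <- min(dm_needed, affordable)
  cost <- dm_bought * market$concentrate_price
  list(dm_bought = dm_bought, cost = cost, cash = cash - cost)
}

#' Sell-out decision under feed stress
#'
#' When stress has fallen below the sell threshold and an energy deficit
#' remains (purchasing power exhausted), animals are sold from the priority
#' classes, in order, in the fractional head-count whose removal closes the
#' remaining deficit (`sold = min(count, remaining_mj / per-head
#' demand)`); sold counts can be decimal fractions. Revenue (head times
#' mean weight times price) is credited to the herd's cash.
#'
#' @param herd A [herd_state()].
#' @param stress Current energy-stress index in `[0, 1]`.
#' @param unmet_demand_mj Energy deficit remaining after feeding and
#'   purchases (MJ).
#' @param market A [market_params()].
#' @param per_head_demand_mj Named per-class daily energy demand per head
#'   (MJ).
#' @return List with `sold` (named animals per class), `revenue`, and the
#'   updated `herd`.
#' @export
sell_out_decision <- function(herd, stress, unmet_demand_mj, market,
                              per_head_demand_mj) {
  stopifnot(stress >= 0, stress <= 1, unmet_demand_mj >= 0)
  sold <- stats::setNames(numeric(6), HERD_CLASSES)
  if (stress >= market$stress_sell_threshold || unmet_demand_mj == 0)
    return(list(sold = sold, revenue = 0, herd = herd))
  if (length(market$sell_priority) == 0)
    stop("sell priority list is empty while feed demand is unmet")
  remaining <- unmet_demand_mj
  revenue <- 0
  for (cls in market$sell_priority) {
    if (remaining <= 0) break
    per_head <- per_head_demand_mj[[cls]]
    if (per_head <= 0) next
    n_sell <- min(herd$count[[cls]], remaining / per_head)
    if (n_sell <= 0) next
    sold[[cls]] <- n_sell
    remaining <- remaining - n_sell * per_head
    revenue <- revenue + n_sell * herd$mean_weight[[cls]] * market$animal_price
    herd$count[[cls]] <- herd$count[[cls]] - n_sell
  }
  herd$cash <- herd$cash + revenue
  list(sold = sold, revenue = revenue, herd = herd)
}

#' Update the residue pool with new inputs and decay
#'
#' Standing hay (annual grass dieback) and harvest residues enter the
#' residue pool, which then loses a fixed relative fraction per day to
#' decomposition and trampling. Concentrates do not decay.
#'
#' @param store A [feed_store()].
#' @param standing_hay_in,residue_in Inputs (kg DM, >= 0).
#' @param decay_rate Daily relative loss in `[0, 1]`.
#' @return The updated `feed_store`.
#' @export
update_feed_store <- function(store, standing_hay_in = 0, residue_in = 0,
                              decay_rate = 0.001) {
  stopifnot(standing_hay_in >= 0, residue_in >= 0,
            decay_rate >= 0, decay_rate <= 1)
  store$residue_dm <- (store$residue_dm + standing_hay_in + residue_in) *
    (1 - decay_rate)
  store
}
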