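# Feed energy supply, stress index, concentrate purchase, sell-out
# management and the residue pool.

test_that("energy demand scales with metabolic weight and herd size", {
  herd <- single_class_herd(10, weight = 256)
  expect_equal(energy_demand(herd, 0.5), 10 * 0.5 * 64)   # 256^0.75 = 64
  expect_equal(energy_demand(make_herd(counts = rep(0, 6))), 0)
  expect_equal(energy_demand(single_class_herd(20, 256), 0.5),
               2 * energy_demand(single_class_herd(10, 256), 0.5))
})

test_that("feed is drawn in order under intake and demand caps", {
  # intake-capacity-limited draw
  store <- feed_store(residue_dm = 100, me_residue = 7)
  out <- energy_supply(store, max_intake_dm = 50, demand_mj = 1000)
  expect_equal(out$supply_mj, 350)
  expect_equal(out$store$residue_dm, 50)
  # demand-limited draw: exactly 10 kg of grass at 8 MJ covers 80 MJ
  store2 <- feed_store(grass_dm = 100, me_grass = 8)
  out2 <- energy_supply(store2, 50, 80)
  expect_equal(out2$dm_intake_by_source[["grass"]], 10)
  expect_equal(out2$supply_mj, 80)
  # order: grass before residue before concentrate
  store3 <- feed_store(grass_dm = 5, residue_dm = 5, concentrate_dm = 5,
                       me_grass = 8, me_residue = 7, me_concentrate = 12)
  out3 <- energy_supply(store3, 12, 1000)
  expect_equal(unname(out3$dm_intake_by_source), c(5, 5, 2))
  # empty store
  expect_equal(energy_supply(feed_store(), 50, 100)$supply_mj, 0)
})

test_that("pool decrements equal intakes and never go negative", {
  withr::with_seed(12, {
    for (i in 1:200) {
      store <- feed_store(grass_dm = runif(1, 0, 50),
                          residue_dm = runif(1, 0, 50),
                          concentrate_dm = runif(1, 0, 20))
      before <- c(store$grass_dm, store$residue_dm, store$concentrate_dm)
      out <- energy_supply(store, runif(1, 0, 60), runif(1, 0, 800))
      after <- c(out$store$grass_dm, out$store$residue_dm,
                 out$store$concentrate_dm)
      expect_equal(before - after, unname(out$dm_intake_by_source),
                   tolerance = 1e-12)
      expect_true(all(after >= 0))
    }
  })
})

test_that("the stress index has exact endpoints and is monotone", {
  expect_equal(energy_stress(0, 100), 0)
  expect_equal(energy_stress(120, 100), 1)
  expect_equal(energy_stress(100, 100), 1)
  expect_equal(energy_stress(50, 100), 0.5)
  expect_equal(energy_stress(0, 0), 1)     # no animals, no stress
  withr::with_seed(2, {
    demand <- runif(1, 50, 150)
    supplies <- sort(runif(50, 0, 2 * demand))
    stresses <- vapply(supplies, energy_stress, numeric(1),
                       demand_mj = demand)
    expect_true(all(diff(stresses) >= 0))          # non-decreasing in supply
    supply <- runif(1, 0, 100)
    demands <- sort(runif(50, 1, 200))
    s2 <- vapply(demands, function(d) energy_stress(supply, d), numeric(1))
    expect_true(all(diff(s2) <= 1e-12))            # non-increasing in demand
  })
})

test_that("concentrate purchases respect the cash limit", {
  market <- market_params(concentrate_price = 1)
  out <- concentrate_purchase(100, cash = 100, market, me_concentrate = 10)
  expect_equal(out$dm_bought, 10)
  expect_equal(out$cost, 10)
  expect_equal(out$cash, 90)
  out2 <- concentrate_purchase(100, cash = 4, market, 10)
  expect_equal(out2$dm_bought, 4)
  expect_equal(out2$cash, 0)
  expect_equal(concentrate_purchase(0, 100, market, 10)$dm_bought, 0)
  expect_error(concentrate_purchase(10, 100, market, 0), "ME")
})

test_that("sell-out closes the deficit with decimal head counts", {
  market <- market_params(animal_price = 10, stress_sell_threshold = 0.6,
                          sell_priority = c("AdultsMale"))
  herd <- single_class_herd(10, weight = 300)
  per_head <- stats::setNames(rep(30, 6), HERD_CLASSES)
  out <- sell_out_decision(herd, stress = 0.3, unmet_demand_mj = 60,
                           market, per_head)
  expect_equal(out$sold[["AdultsMale"]], 2.0)
  out2 <- sell_out_decision(herd, 0.3, 45, market, per_head)
  expect_equal(out2$sold[["AdultsMale"]], 1.5)       # decimal fraction
  expect_equal(out2$herd$count[["AdultsMale"]], 8.5)
  expect_equal(out2$revenue, 1.5 * 300 * 10)
  expect_equal(out2$herd$cash, herd$cash + out2$revenue)
  # no sale above the stress threshold or with no deficit
  expect_equal(sum(sell_out_decision(herd, 1, 60, market, per_head)$sold), 0)
  expect_equal(sum(sell_out_decision(herd, 0.3, 0, market, per_head)$sold), 0)
  # sales cannot exceed the class and spill to the next priority class
  market2 <- market_params(animal_price = 10,
                           sell_priority = c("AdultsMale", "SubAdultsMale"))
  herd2 <- make_herd(counts = c(0, 4, 1, 0, 0, 0))
  out3 <- sell_out_decision(herd2, 0.2, 90, market2, per_head)
  expect_equal(out3$sold[["AdultsMale"]], 1)
  expect_equal(out3$sold[["SubAdultsMale"]], 2)
  empty <- market_params(sell_priority = character(0))
  expect_error(sell_out_decision(herd, 0.2, 60, empty, per_head), "priority")
})

test_that("the residue pool gains inputs and decays relatively", {
  store <- feed_store(residue_dm = 1000)
  expect_equal(update_feed_store(store, 0, 0, 0.001)$residue_dm, 999)
  expect_equal(update_feed_store(store, 0, 0, 0)$residue_dm, 1000)
  # a harvest event credits exactly its feedable residue
  h <- harvest(local({
    s <- crop_state(); s$stage <- "mature"
    s$biomass <- c(leaf = 100, stem = 100, root = 50, storage = 100)
    s
  }), crop_params("millet"))
  grown <- update_feed_store(store, 0, h$residue_feed, 0)
  expect_equal(grown$residue_dm, 1000 + h$residue_feed)
})

test_that("closing the feed gap by selling raises next-day stress", {
  coeff <- 0.5
  herd <- single_class_herd(20, weight = 256)   # demand 20*32 = 640 MJ
  supply <- 320                                  # half met, stress 0.5
  demand <- energy_demand(herd, coeff)
  stress <- energy_stress(supply, demand)
  market <- market_params(animal_price = 1, stress_sell_threshold = 0.6,
                          sell_priority = "AdultsMale")
  per_head <- stats::setNames(rep(coeff * 256^0.75, 6), HERD_CLASSES)
  out <- sell_out_decision(herd, stress, demand - supply, market, per_head)
  new_demand <- energy_demand(out$herd, coeff)
  expect_gte(energy_stress(supply, new_demand), stress)
})
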