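# Six-class demographic projection: rates, conservation, stationary
# structure, weights and the production functions.

test_that("the gamma promotion rate is survival over duration", {
  expect_equal(class_transition_rate(1, 1), 1)
  expect_equal(class_transition_rate(365, 1), 1 / 365)
  expect_equal(class_transition_rate(730, 0.9), 0.9 / 730)
  expect_error(class_transition_rate(0, 1))
  expect_error(class_transition_rate(365, 0))
})

test_that("births split by the sex ratio at the daily parturition rate", {
  herd <- make_herd(counts = c(0, 0, 0, 0, 0, 50))
  dp <- null_demography(parturition_annual = 0.73, prolification = 1,
                        sex_ratio_male = 0.5)
  out <- step_demography(herd, dp, energy_stress = 1)
  expect_equal(out$flows$births[out$flows$class == "JuvenilesMale"], 0.05)
  expect_equal(out$flows$births[out$flows$class == "JuvenilesFemale"], 0.05)
  expect_equal(out$herd$count[["JuvenilesMale"]], 0.05)
})

test_that("all-zero rates leave the herd untouched", {
  herd <- make_herd()
  out <- step_demography(herd, null_demography(), 1)
  expect_equal(out$herd$count, herd$count, tolerance = 1e-9)
  expect_true(all(abs(out$flows[, -1]) < 1e-9))
})

test_that("constant mortality follows the geometric-decay closed form", {
  zero6 <- stats::setNames(rep(0, 6), HERD_CLASSES)
  m <- zero6; m[["AdultsMale"]] <- 0.365
  dp <- null_demography(base_mortality_annual = m)
  herd <- single_class_herd(100)
  out1 <- step_demography(herd, dp, 1)
  expect_equal(out1$herd$count[["AdultsMale"]], 99.9, tolerance = 1e-9)
  for (t in 2:365) out1 <- step_demography(out1$herd, dp, 1)
  expect_equal(out1$herd$count[["AdultsMale"]], 100 * (1 - 0.001)^365,
               tolerance = 1e-9)
})

test_that("per-class bookkeeping closes over random-rate simulations", {
  withr::with_seed(31, {
    worst <- 0
    for (rep in 1:20) {
      per6 <- function(hi) stats::setNames(runif(6, 0, hi), HERD_CLASSES)
      dp <- demography_params(
        parturition_annual = runif(1, 0, 1.2),
        prolification = runif(1, 0.8, 1.5),
        sex_ratio_male = runif(1, 0.3, 0.7),
        base_mortality_annual = per6(0.3),
        starvation_mortality_max_annual = per6(0.5),
        offtake_annual = per6(0.3),
        intake_annual = per6(2))
      herd <- make_herd(counts = runif(6, 0, 30))
      for (day in 1:200) {
        stress <- runif(1)
        before <- herd$count
        out <- step_demography(herd, dp, stress)
        herd <- out$herd
        f <- out$flows
        delta <- f$births + f$promotions_in + f$intake -
          f$deaths - f$promotions_out - f$offtake
        worst <- max(worst, max(abs(herd$count[f$class] - (before[f$class] + delta))))
        if (any(herd$count < 0)) fail("negative count")
      }
    }
    expect_lt(worst, 1e-9)
  })
})

test_that("removals exceeding a class empty it exactly to zero", {
  zero6 <- stats::setNames(rep(0, 6), HERD_CLASSES)
  off <- zero6; off[["AdultsMale"]] <- 365 * 2   # 200 % per day
  dp <- null_demography(offtake_annual = off)
  herd <- single_class_herd(5)
  out <- step_demography(herd, dp, 1)
  expect_equal(out$herd$count[["AdultsMale"]], 0)
  expect_equal(out$flows$offtake[out$flows$class == "AdultsMale"], 5)
})

test_that("class proportions converge to the dominant eigenvector", {
  # stress = 1 and constant rates make the update linear; the oracle is the
  # brute-force 6x6 daily projection matrix taken to a high power
  dp <- demography_params()
  A <- matrix(0, 6, 6, dimnames = list(HERD_CLASSES, HERD_CLASSES))
  for (j in seq_along(HERD_CLASSES)) {
    unit <- stats::setNames(rep(0, 6), HERD_CLASSES)
    unit[[HERD_CLASSES[j]]] <- 1
    h <- herd_state(count = unit,
                    mean_weight = stats::setNames(rep(100, 6), HERD_CLASSES))
    A[, j] <- step_demography(h, dp, 1)$herd$count
  }
  # power the matrix until the direction stabilizes
  v <- rep(1, 6)
  M <- A
  for (i in 1:60) M <- M %*% M / max(M)   # repeated squaring, renormalized
  v <- M %*% rep(1, 6)
  v <- as.numeric(v / sum(v))
  # simulate the same herd forward
  herd <- make_herd()
  for (t in 1:20000) herd <- step_demography(herd, dp, 1)$herd
  prop <- herd$count / sum(herd$count)
  expect_lt(max(abs(prop - v)), 1e-6)
})

test_that("live weights blend gain and loss linearly in stress", {
  per6 <- function(x) stats::setNames(rep(x, 6), HERD_CLASSES)
  dp <- demography_params(weight_gain_max = per6(0.2),
                          weight_loss_max = per6(0.4))
  herd <- make_herd()
  up <- update_live_weights(herd, dp, 1)
  expect_equal(up$mean_weight, herd$mean_weight + 0.2)
  down <- update_live_weights(herd, dp, 0)
  expect_equal(down$mean_weight, herd$mean_weight - 0.4)
  half <- update_live_weights(herd, dp, 0.5)
  expect_equal(half$mean_weight, herd$mean_weight - 0.1)
  # floor at the minimum viable weight
  light <- make_herd(weights = rep(10.1, 6))
  floored <- update_live_weights(light, dp, 0)
  expect_equal(unname(floored$mean_weight), rep(10, 6))
})

test_that("total live weight is the count-weighted sum of class weights", {
  herd <- make_herd()
  expect_equal(total_live_weight(herd), sum(herd$count * herd$mean_weight))
  out <- step_demography(herd, demography_params(), 0.7)
  expect_equal(total_live_weight(out$herd),
               sum(out$herd$count * out$herd$mean_weight))
})

test_that("production functions are simple products", {
  expect_equal(meat_production(0, 0.5), 0)
  expect_equal(meat_production(2000, 0.5), 1000)
  expect_equal(meat_production(1.5 * 300, 0.5), 225)  # decimal head sale
  expect_error(meat_production(100, 1.2))

  herd <- make_herd(counts = c(0, 0, 0, 0, 0, 10))
  dp <- demography_params(lactating_fraction = 0.5, milk_yield_potential = 2)
  expect_equal(milk_production(herd, dp, 1), 10)
  expect_equal(milk_production(herd, dp, 0), 0)
  empty <- make_herd(counts = rep(0, 6))
  expect_equal(milk_production(empty, dp, 1), 0)

  expect_equal(methane_emission(0, 0.021), 0)
  expect_equal(methane_emission(10, 0.021), 0.21)
  expect_equal(methane_emission(20, 0.021), 2 * methane_emission(10, 0.021))

  expect_equal(manure_nitrogen(0, 0.8), 0)
  expect_equal(manure_nitrogen(0.1, 0.8), 0.08)
  expect_error(manure_nitrogen(0.1, 1.5))
})
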