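test_that("fluid distribution follows the body-water rules", {
  d <- distribute_fluid("dextrose5", 1000)
  expect_equal(d[["intracellular"]], 2000 / 3, tolerance = 1e-9)
  expect_equal(d[["plasma"]] + d[["interstitial"]], 1000 / 3,
               tolerance = 1e-9)

  expect_true(all(distribute_fluid("balanced_crystalloid", 0) == 0))
  expect_equal(distribute_fluid("balanced_crystalloid", 500)[["intracellular"]],
               0)
  wb <- distribute_fluid("whole_blood", 100, hematocrit = 0.4)
  expect_equal(wb[["plasma"]], 60)
  expect_equal(wb[["intracellular"]], 40)
  expect_error(distribute_fluid("dextrose5", -1), class = "hemobia_bad_volume")
})

test_that("compartment simulation conserves water to 1e-9 ml per step", {
  for (g in groups_all) {
    sim <- simulate_compartments(subject_params(), standard_protocol(g))
    tbw <- sim$plasma + sim$interstitial + sim$intracellular
    balance <- diff(tbw) - (diff(sim$infused_water) - diff(sim$bled_water))
    expect_lt(max(abs(balance)), 1e-9)
  }
})

test_that("with all exchange rates zero, hemorrhage removes exactly 1 L of blood", {
  p <- subject_params(refill_rate = 0, equil_rate = 0,
                      glucose_osmotic_shift = 0, albumin_leak_rate = 0,
                      icw_pull_coefficient = 0, icw_osmotic_per_g = 0)
  sim <- simulate_compartments(p, standard_protocol("crystalloid"))
  b <- attr(sim, "baseline")
  # before any infusion has begun, the only change is the withdrawal
  expect_equal(sim$circulating_blood[sim$t == 60], b$blood - 1000,
               tolerance = 1e-9)
})

test_that("crystalloid-only kinetics leave intracellular water constant after hemorrhage", {
  p <- subject_params()
  sim <- simulate_compartments(p, standard_protocol("crystalloid"))
  b <- attr(sim, "baseline")
  icw_post <- sim$intracellular[sim$t >= 60]
  expect_lt(max(icw_post) - min(icw_post), 1e-9)
  expect_equal(icw_post[1], b$icw - 1000 * p$hematocrit, tolerance = 1e-9)
})

test_that("fast glucose metabolism routes two thirds of the dextrose water into cells", {
  p <- subject_params(glucose_half_life = 1, glucose_osmotic_shift = 0)
  sim <- simulate_compartments(p, standard_protocol("crystalloid_dextrose"))
  b <- attr(sim, "baseline")
  g_end <- sim$glucose_pool[sim$t == 180]
  # analytic limit: metabolized water x 2/3 into ICW, minus red-cell loss
  expected <- (2 / 3) * (1000 - g_end) - 1000 * p$hematocrit
  expect_equal(sim$intracellular[sim$t == 180] - b$icw, expected,
               tolerance = 1e-6)
  expect_lt(g_end, 15)  # pool nearly exhausted at this half-life
})

test_that("simulation rejects bad time steps and impossible states", {
  p <- subject_params()
  proto <- standard_protocol("crystalloid")
  expect_error(simulate_compartments(p, proto, dt = -1),
               class = "hemobia_bad_dt")
  expect_error(simulate_compartments(p, proto, dt = 0.7),
               class = "hemobia_bad_dt")
  # draining far more than the plasma holds must be caught, not silently run
  p$hemo_baseline$MAP0 <- 55
  p_bad <- subject_params(blood_volume_per_kg = 20)
  expect_error(simulate_compartments(p_bad, proto),
               class = "hemobia_negative_volume")
})

test_that("Cole impedance has the correct limits and monotonicity", {
  p <- subject_params()
  sim <- simulate_compartments(p, standard_protocol("crystalloid"))
  state <- sim[1, ]
  sw <- segment_water(state, p, "torso")
  r0 <- p$cole$k_e / (sw$ecw / 1000)

  expect_equal(cole_impedance(state, p, "torso", 1e-9), r0,
               tolerance = 1e-6)
  # doubling extracellular water halves the low-frequency magnitude
  state2 <- state
  state2$plasma <- 2 * state$plasma
  state2$interstitial <- 2 * state$interstitial
  expect_equal(cole_impedance(state2, p, "torso", 1e-9), r0 / 2,
               tolerance = 1e-6)
  # strictly decreasing across a dense frequency sweep
  freqs <- exp(seq(log(1), log(1000), length.out = 200))
  z <- cole_impedance(state, p, "torso", freqs)
  expect_true(all(diff(z) < 0))
  expect_gt(cole_impedance(state, p, "torso", 5) /
              cole_impedance(state, p, "torso", 1000), 1)
  bad <- state
  bad$intracellular <- 0
  expect_error(cole_impedance(bad, p, "torso", 5),
               class = "hemobia_bad_volume")
})

test_that("hemodynamics anchor at baseline and respond monotonically to volume", {
  p <- subject_params()
  b <- baseline_state_for_test(p)
  at_phi <- function(phi) {
    hemodynamics_from_volume(list(t = 0, circulating_blood = phi * b$blood),
                             p)
  }
  h1 <- at_phi(1)
  expect_equal(h1$PR, p$hemo_baseline$PR0)
  expect_equal(h1$MAP, p$hemo_baseline$MAP0)
  expect_equal(h1$SV, p$hemo_baseline$SV0)
  expect_equal(h1$SVV, p$hemo_baseline$SVV0)

  h_low <- at_phi(0.85)
  expect_lt(h_low$MAP, h1$MAP)
  expect_lt(h_low$SV, h1$SV)
  expect_gt(h_low$PR, h1$PR)
  expect_gt(h_low$SVV, h1$SVV)

  h_shock <- at_phi(0.5)
  expect_true(is.na(h_shock$MAP) && is.na(h_shock$SV) && is.na(h_shock$SVV))
  expect_false(is.na(h_shock$PR))
})

test_that("dataset generation is deterministic and has the full design shape", {
  a <- generate_dataset(2, "crystalloid", noise_cv = 0.005, seed = 7)
  b <- generate_dataset(2, "crystalloid", noise_cv = 0.005, seed = 7)
  expect_identical(a$impedance, b$impedance)
  expect_identical(a$vitals, b$vitals)
  expect_identical(a$truth, b$truth)

  d5 <- generate_dataset(5, "crystalloid", noise_cv = 0.005, seed = 1)
  expect_equal(nrow(d5$impedance), 5 * 61 * 5 * 6)
  expect_error(generate_dataset(0, "crystalloid"),
               class = "hemobia_bad_params")
})

test_that("noise-free impedance rows equal the Cole map of the true states", {
  ds <- generate_dataset(1, "crystalloid", noise_cv = 0, seed = 3)
  p <- subject_params(weight = ds$subjects$weight[1])
  row <- ds$impedance[ds$impedance$segment == "torso" &
                        ds$impedance$frequency_khz == 5 &
                        ds$impedance$t_min == 60, ]
  tr <- ds$truth[ds$truth$t_min == 60, ]
  z <- cole_impedance(list(plasma = tr$plasma,
                           interstitial = tr$interstitial,
                           intracellular = tr$intracellular),
                      p, "torso", 5)
  expect_equal(row$z_ohm, z, tolerance = 1e-9)
})
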