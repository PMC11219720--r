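test_that("standard protocol encodes the per-group fluid compositions", {
  p1 <- standard_protocol("crystalloid")
  expect_equal(unname(cumulative_infused(p1, 180)), 2000)
  expect_named(cumulative_infused(p1, 180), "balanced_crystalloid")

  p2 <- standard_protocol("crystalloid_dextrose")
  tot2 <- cumulative_infused(p2, 180)
  expect_equal(tot2[["balanced_crystalloid"]], 1000)
  expect_equal(tot2[["dextrose5"]], 1000)

  p3 <- standard_protocol("crystalloid_albumin")
  tot3 <- cumulative_infused(p3, 180)
  expect_equal(tot3[["balanced_crystalloid"]], 1600)
  expect_equal(tot3[["albumin20"]], 400)

  expect_error(standard_protocol("saline"), class = "hemobia_unknown_group")
})

test_that("measurement schedule counts timepoints including the baseline", {
  p <- standard_protocol("crystalloid")
  sched <- measurement_schedule(p)
  expect_length(sched, 61)
  expect_equal(sched[1], 0)
  expect_equal(sched[61], 180)

  expect_equal(measurement_schedule(standard_protocol("crystalloid",
                                                      bia_interval = 180)),
               c(0, 180))
  for (iv in c(1, 2, 5, 6, 9, 12, 20, 45, 90)) {
    expect_length(measurement_schedule(
      standard_protocol("crystalloid", bia_interval = iv)), 180 / iv + 1)
  }
  expect_error(standard_protocol("crystalloid", bia_interval = 7),
               class = "hemobia_bad_interval")
})

test_that("cumulative bled volume is the right-continuous event sum", {
  p <- standard_protocol("crystalloid")
  expect_equal(cumulative_bled_volume(p, 0), 0)
  expect_equal(cumulative_bled_volume(p, 13), 200)  # events at 6 and 12 fired
  expect_equal(cumulative_bled_volume(p, 6), 100)   # right-continuous
  expect_equal(cumulative_bled_volume(p, 60), 1000)
  expect_equal(cumulative_bled_volume(p, 180), 1000)
  grid <- cumulative_bled_volume(p, seq(0, 180, 0.5))
  expect_true(all(diff(grid) >= 0))
  expect_error(cumulative_bled_volume(p, -1), class = "hemobia_time_range")
  expect_error(cumulative_bled_volume(p, 200), class = "hemobia_time_range")
})

test_that("cumulative infusion is zero through hemorrhage, linear within phases", {
  p <- standard_protocol("crystalloid")
  expect_true(all(cumulative_infused(p, 60) == 0))
  expect_true(all(cumulative_infused(p, 30) == 0))
  expect_equal(cumulative_infused(p, 90)[["balanced_crystalloid"]], 500)
  # albumin is a rapid piggyback over the first minutes of each phase
  p3 <- standard_protocol("crystalloid_albumin")
  expect_equal(cumulative_infused(p3, 65)[["albumin20"]], 100)
  expect_equal(cumulative_infused(p3, 70)[["albumin20"]], 200)
  expect_equal(cumulative_infused(p3, 119)[["albumin20"]], 200)
  expect_error(cumulative_infused(p, c(10, 20)), class = "hemobia_time_range")
})

test_that("protocols survive JSON and YAML round trips", {
  p <- standard_protocol("crystalloid_albumin", bia_interval = 6)
  for (ext in c("json", "yaml")) {
    path <- file.path(tempdir(), paste0("proto.", ext))
    write_protocol(p, path)
    q <- read_protocol(path)
    expect_equal(q$group, p$group)
    expect_equal(q$bleed_events, p$bleed_events)
    expect_equal(q$bia_interval, p$bia_interval)
    expect_equal(q$albumin_bolus_min, p$albumin_bolus_min)
    expect_equal(cumulative_infused(q, 180), cumulative_infused(p, 180))
    unlink(path)
  }
})

test_that("phase labels use half-open intervals", {
  expect_equal(phase_of(c(0, 59.9, 60, 119, 120, 180)),
               c("hemorrhage", "hemorrhage", "resus1", "resus1",
                 "resus2", "resus2"))
})
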