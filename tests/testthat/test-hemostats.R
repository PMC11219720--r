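make_vitals <- function(fun_map, subjects = paste0("s", 1:5)) {
  times <- 0:180
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    v <- fun_map(i, times)
    data.frame(subject_id = subjects[i], t_min = times,
               pr = v$pr, map = v$map, sv = v$sv, svv = v$svv)
  }))
}

test_that("endpoint extraction picks the five named minutes", {
  vit <- make_vitals(function(i, t) {
    list(pr = 90 + i + 0 * t, map = 50 + i - t / 20, sv = 70 + i - t / 10,
         svv = 12 + 0 * t)
  })
  proto <- standard_protocol("crystalloid")
  ep <- extract_endpoints(vit, proto, recovery_minute = 135)
  expect_setequal(unique(ep$timepoint),
                  c("start", "end_hemorrhage", "start_resus2",
                    "recovery_1M", "end_infusion"))
  m135 <- ep[ep$variable == "MAP" & ep$timepoint == "recovery_1M" &
               ep$subject_id == "s2", ]
  expect_equal(m135$t_min, 135)
  expect_equal(m135$value, 52 - 135 / 20)

  # equidistant readings resolve to the earlier one
  ep2 <- extract_endpoints(vit, proto, recovery_minute = 134.5)
  expect_equal(unique(ep2$t_min[ep2$timepoint == "recovery_1M"]), 134)

  # absent recovery leaves the other four endpoints in place
  ep3 <- extract_endpoints(vit, proto, recovery_minute = NA)
  expect_false("recovery_1M" %in% ep3$timepoint)
  expect_equal(length(unique(ep3$timepoint)), 4)
})

test_that("missing MAP propagates into the endpoints", {
  vit <- make_vitals(function(i, t) {
    map <- 50 + i - t / 20
    map[t == 60] <- NA
    list(pr = 90 + 0 * t, map = map, sv = map * 1.2, svv = 12 + 0 * t)
  })
  ep <- extract_endpoints(vit, standard_protocol("crystalloid"), NA)
  expect_true(all(is.na(ep$value[ep$variable == "MAP" &
                                   ep$timepoint == "end_hemorrhage"])))
})

test_that("Jarque-Bera matches the moment formula and is affine invariant", {
  v <- c(1, 2, 3, 4, 5)
  jb <- jarque_bera(v)
  # symmetric sample: S = 0, K = 1.7 -> JB = 5/6 * (1.3^2 / 4)
  expect_equal(jb$statistic, 5 / 6 * (1.69 / 4), tolerance = 1e-12)
  expect_equal(jb$p_value, pchisq(jb$statistic, 2, lower.tail = FALSE))

  set.seed(31)
  for (i in 1:100) {
    x <- rnorm(sample(4:30, 1))
    expect_equal(jarque_bera(x)$statistic, oracle_jb(x), tolerance = 1e-9)
    expect_equal(jarque_bera(2.5 * x - 3)$statistic,
                 jarque_bera(x)$statistic, tolerance = 1e-9)
  }
  expect_error(jarque_bera(1:3), class = "hemobia_bad_series")
  expect_error(jarque_bera(rep(2, 6)), class = "hemobia_zero_variance")
})

test_that("the pooled t-test matches the hand formula", {
  same <- ttest_two(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  tt <- ttest_two(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(tt$p_value, 0.021312, tolerance = 1e-4)
  flip <- ttest_two(c(4, 5, 6), c(1, 2, 3))
  expect_equal(flip$statistic, -tt$statistic)
  expect_equal(flip$p_value, tt$p_value)

  set.seed(41)
  for (i in 1:100) {
    a <- rnorm(sample(2:12, 1)); b <- rnorm(sample(2:12, 1), 0.5)
    got <- ttest_two(a, b)
    want <- oracle_pooled_t(a, b)
    expect_lt(abs(got$statistic - want$t), 1e-9)
    expect_lt(abs(got$p_value - want$p), 1e-9)
  }
  expect_error(ttest_two(1, c(2, 3)), class = "hemobia_bad_series")
})

test_that("percent change uses the decrease-positive convention", {
  expect_equal(round(percent_change(49.9, 39.4), 1), 21.0)
  expect_equal(round(percent_change(88, 42.7), 1), 51.5)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), class = "hemobia_bad_series")
})

test_that("the stroke-volume responsiveness rule uses the 10 percent boundary", {
  r <- delta_sv_responsiveness(100, 109.1)
  expect_equal(r$delta_pct, 9.1, tolerance = 1e-9)
  expect_false(r$responsive)
  expect_true(delta_sv_responsiveness(100, 115)$responsive)
  expect_true(delta_sv_responsiveness(100, 110)$responsive)  # boundary
  expect_error(delta_sv_responsiveness(0, 10), class = "hemobia_bad_series")
})

test_that("endpoint comparisons flag restoration correctly", {
  # subjects constant over time (but varying across subjects): all p = 1
  vit <- make_vitals(function(i, t) {
    base <- c(49, 50, 51, 49, 50)[i]
    list(pr = 90 + i + 0 * t, map = base + 0 * t, sv = base * 1.4 + 0 * t,
         svv = 12 + i / 10 + 0 * t)
  })
  ep <- extract_endpoints(vit, standard_protocol("crystalloid"), 135)
  rep1 <- endpoint_comparison_report(ep)
  expect_true(all(rep1$comparisons$p == 1))
  expect_true(all(rep1$restored))

  # a clear start-to-end drop is significant and not "restored"
  starts <- c(49, 50, 51, 49, 50)
  ends <- c(39, 40, 39, 40, 39)
  vit2 <- make_vitals(function(i, t) {
    map <- approx(c(0, 180), c(starts[i], ends[i]), xout = t)$y
    list(pr = 90 + 0 * t, map = map, sv = map * 1.4, svv = 12 + i / 10 + 0 * t)
  })
  ep2 <- extract_endpoints(vit2, standard_protocol("crystalloid"), 135)
  rep2 <- endpoint_comparison_report(ep2)
  row <- rep2$comparisons[rep2$comparisons$variable == "MAP" &
                            rep2$comparisons$pair == "start-end_infusion", ]
  expect_lt(row$p, 0.05)
  expect_false(rep2$restored[["MAP"]])
  expect_equal(row$percent_change,
               percent_change(mean(starts), mean(ends)), tolerance = 1e-9)

  # invariant to the order of subjects in the table
  perm <- ep2[sample(nrow(ep2)), ]
  class(perm) <- class(ep2)
  attr(perm, "timepoint_minutes") <- attr(ep2, "timepoint_minutes")
  rep3 <- endpoint_comparison_report(perm)
  expect_equal(rep3$comparisons, rep2$comparisons)
})
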