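test_that("turc_aet matches hand-evaluated values and zero-rain case", {
  # hand evaluation: L = 300 + 25t + 0.05 t^3; AET = P / sqrt(0.9 + P^2/L^2)
  expect_equal(turc_aet(20.1, 8.0), 8.432535, tolerance = 1e-6)
  expect_equal(turc_aet(15.0, 100.0), 104.5962, tolerance = 1e-6)
  expect_identical(turc_aet(c(-5, 0, 12, 30), rep(0, 4)), rep(0, 4))
})

test_that("turc_aet input contracts: negative P, vanishing heat term", {
  expect_error(turc_aet(10, -1), class = "tb_domain_error")
  # L = 300 + 25t + 0.05t^3 goes negative for strongly negative t
  expect_error(turc_aet(-15, 5), class = "tb_domain_error")
  expect_silent(turc_aet(0, 5))  # L = 300 at freezing, still valid
})

test_that("turc_aet properties: upper bound and monotonicity in P", {
  for (t in c(0, 5, 15, 25)) {
    P <- seq(0, 300, by = 7.5)
    a <- turc_aet(t, P)
    expect_true(all(a <= P / sqrt(0.9) + 1e-12))
    expect_true(all(diff(a) > 0 | P[-1] == 0))
  }
  expect_true(all(turc_aet(12, c(5, 50), cap = TRUE) <= c(5, 50)))
})

test_that("window_aggregate on constant and sawtooth series", {
  met <- make_meteo(temp = 10, precip = 1)
  w <- window_aggregate(met, as.Date("2004-03-01"))
  expect_equal(w$avt_m, 10)
  expect_equal(w$ap_m, 30)
  expect_equal(w$aet_m, turc_aet(10, 30))

  # sawtooth mean is phase-invariant
  met2 <- make_meteo(temp = 1, precip = 0)
  met2$temp_mean <- rep_len(c(0, 20), nrow(met2))
  for (d in as.Date(c("2004-05-01", "2004-05-02"))) {
    expect_equal(window_aggregate(met2, d)$avt_m, 10)
  }
})

test_that("window is half-open: the sampling day itself is excluded", {
  met <- make_meteo(temp = 10, precip = 0)
  met$temp_mean[met$date == as.Date("2004-02-15")] <- 100
  # window [Jan 16, Feb 14] before Feb 15 must not see the spike
  expect_equal(window_aggregate(met, as.Date("2004-02-15"))$avt_m, 10)
  expect_gt(window_aggregate(met, as.Date("2004-02-16"))$avt_m, 10)
})

test_that("missing days give an error listing the dates, not a value", {
  met <- make_meteo()
  met <- met[met$date != as.Date("2004-03-10"), ]
  err <- expect_error(window_aggregate(met, as.Date("2004-04-01")),
                      class = "tb_missing_data_error")
  expect_match(conditionMessage(err), "2004-03-10")
  # 29 of 30 days present is not enough
  expect_error(window_aggregate(met, as.Date("2004-03-25")),
               class = "tb_missing_data_error")
})

test_that("window_aggregate is translation-invariant", {
  withr::with_seed(7, {
    met <- make_meteo()
    met$temp_mean <- rnorm(nrow(met), 12, 4)
    met$precip <- rexp(nrow(met))
  })
  shift <- 370L
  met2 <- met
  met2$date <- met2$date + shift
  d <- as.Date("2004-06-15")
  w1 <- window_aggregate(met, d)
  w2 <- window_aggregate(met2, d + shift)
  expect_equal(w1$avt_m, w2$avt_m)
  expect_equal(w1$ap_m, w2$ap_m)
})

test_that("lag_census retrieves published counts and honours boundaries", {
  cen <- survey_census()
  # deer count two years before 2004 is the 2002 count, 363
  expect_equal(lag_census(cen, 2004, lag = 2), 363)
  expect_equal(lag_census(cen, 2004, lag = 0), 286)
  expect_equal(lag_census(cen, 2010, lag = 1, column = "boar_count"), 16)
  short <- cen[cen$year >= 2003, ]
  expect_error(lag_census(short, 2004, lag = 2), class = "tb_lookup_error")
  expect_error(lag_census(cen, 2004, lag = 3), class = "tb_config_error")
})

test_that("build_design: empty input keeps full schema; rows never reorder", {
  cfg <- sim_config(seed = 21)
  env <- simulate_environment(cfg)
  hosts <- simulate_cohort(cfg, env)
  d <- build_design(hosts, env$meteo, env$census)
  expect_identical(d$host_id, hosts$host_id)
  expect_equal(nrow(d), nrow(hosts))
  grouping <- attr(d, "grouping")
  expect_true(all(grouping %in% c("Ind", "Pop", "Env")))

  d0 <- build_design(hosts[0, ], env$meteo, env$census)
  expect_equal(nrow(d0), 0)
  expect_identical(names(d0), names(d))
})

test_that("build_design composes window_aggregate and census lags per host", {
  cfg <- sim_config(seed = 22)
  env <- simulate_environment(cfg)
  hosts <- simulate_cohort(cfg, env)[1:5, ]
  d <- build_design(hosts, env$meteo, env$census)
  for (i in 1:5) {
    w <- window_aggregate(env$meteo, hosts$sampling_date[i])
    expect_equal(d$avt_m[i], w$avt_m)
    expect_equal(d$ap_m[i], w$ap_m)
    expect_equal(d$aet_m[i], w$aet_m)
    expect_equal(d$deer_c_lag2[i],
                 env$census$deer_count[match(hosts$year[i] - 2,
                                             env$census$year)])
  }
  expect_equal(d$sex_female, as.numeric(hosts$sex == "female"))
  # a predictor missing from the grouping is a configuration error
  expect_error(
    build_design(hosts, env$meteo, env$census,
                 grouping = c(total_length = "Ind")),
    class = "tb_config_error"
  )
})
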