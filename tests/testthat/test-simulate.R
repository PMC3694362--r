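test_that("config validation names the offending field", {
  expect_error(sim_config(dispersion_k = 0), class = "tb_config_error")
  expect_error(sim_config(dispersion_k = -1), class = "tb_config_error")
  expect_error(sim_config(census_noise = -0.1), class = "tb_config_error")
  expect_error(sim_config(collected_p = 1.5), class = "tb_config_error")
  bad_beta <- c(intercept = 0)
  err <- expect_error(sim_config(beta_male = bad_beta),
                      class = "tb_config_error")
  expect_match(conditionMessage(err), "beta_male")
  # default generating processes differ by sex
  cfg <- sim_config()
  expect_false(identical(cfg$beta_male, cfg$beta_female))
})

test_that("degenerate meteorology config gives constant temperature", {
  cfg <- sim_config(meteo = list(temp_mean = 12, temp_amplitude = 0,
                                 temp_peak_doy = 207, temp_noise_sd = 0,
                                 rain_prob_mean = 0, rain_prob_amplitude = 0,
                                 rain_shape = 1, rain_scale = 1))
  env <- simulate_environment(cfg)
  expect_true(all(env$meteo$temp_mean == 12))
  expect_true(all(env$meteo$precip == 0))
})

test_that("environment and cohort are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 61)
  e1 <- simulate_environment(cfg)
  e2 <- simulate_environment(cfg)
  expect_identical(e1, e2)
  h1 <- simulate_cohort(cfg, e1)
  h2 <- simulate_cohort(cfg, e2)
  expect_identical(h1, h2)
  # a different seed changes the draw
  expect_false(identical(h1, simulate_cohort(cfg, e1, seed = 9999)))
})

test_that("environment coverage: daily meteorology and lagged censuses", {
  cfg <- sim_config(seed = 62)
  env <- simulate_environment(cfg)
  expect_true(all(diff(as.integer(env$meteo$date)) == 1))
  expect_lte(min(env$meteo$date), as.Date("2003-12-02"))
  expect_gte(max(env$meteo$date), as.Date("2010-12-31"))
  expect_equal(env$census$year, 2002:2010)
  expect_true(all(env$census$deer_count >= 0))
  expect_true(all(env$meteo$precip >= 0))
})

test_that("annual precipitation stays in the Mediterranean 300-700 mm band", {
  # 100 simulated years; the study area's stated range, with stochastic slack
  cfg <- sim_config(n_years = 100, start_year = 2000, seed = 63,
                    n_per_year_by_sex = cbind(male = rep(1L, 100),
                                              female = rep(1L, 100)))
  env <- simulate_environment(cfg)
  yr <- format(env$meteo$date, "%Y")
  annual <- tapply(env$meteo$precip, yr, sum)
  annual <- annual[names(annual) %in% as.character(2000:2099)]
  expect_length(annual, 100)
  expect_gte(mean(annual), 300 * 0.9)
  expect_lte(mean(annual), 700 * 1.1)
  expect_gte(mean(annual >= 250 & annual <= 780), 0.9)
})

test_that("host records satisfy their invariants", {
  cfg <- sim_config(seed = 64)
  env <- simulate_environment(cfg)
  h <- simulate_cohort(cfg, env)
  expect_equal(nrow(h), 306)
  expect_equal(sum(h$sex == "male"), 182)
  expect_equal(sum(h$sex == "female"), 124)
  expect_true(all(h$tick_count >= 0))
  expect_true(all(h$tick_count == round(h$tick_count)))
  expect_true(all(h$ticks_collected <= h$tick_count))
  expect_true(all(h$age_class %in% 1:5))
  expect_true(all(h$total_length > 0))
  expect_true(all(h$thoracic_perimeter > 0))
  expect_true(all(h$hind_foot > 0))
  expect_true(all(h$kidney_fat_index > 0))
  mo <- as.integer(format(h$sampling_date, "%m"))
  season_expected <- c("winter", "winter", "spring", "spring", "spring",
                       "summer", "summer", "summer", "autumn", "autumn",
                       "autumn", "winter")[mo]
  expect_identical(h$season, season_expected)
  # ground truth retained
  expect_equal(h$mu_true, exp(h$eta_true), tolerance = 1e-12)
})

test_that("collection protocol: complete below threshold, thinned above", {
  cfg <- sim_config(seed = 65)
  env <- simulate_environment(cfg)
  h <- simulate_cohort(scale_cohort_size(cfg, 3000, 300, n_years = 7), env)
  low <- h$tick_count <= 30
  expect_true(all(h$ticks_collected[low] == h$tick_count[low]))
  high <- h$tick_count > 30
  expect_true(all(h$ticks_collected[high] >= 30))
  expect_true(all(h$ticks_collected[high] <= h$tick_count[high]))
})

test_that("NB count draws match the variance identity and Poisson limit", {
  flat <- function(k, n, mu) {
    b <- c(intercept = log(mu), total_length = 0, age_class = 0, kfi = 0,
           avt_m = 0, ap_m = 0, aet_m = 0, year = 0, deer_census = 0,
           deer_census_lag2 = 0, boar_census_lag2 = 0)
    cfg <- sim_config(seed = 66, dispersion_k = k, beta_male = b,
                      beta_female = b)
    cfg <- scale_cohort_size(cfg, n / 2, n / 2, n_years = 7)
    env <- simulate_environment(cfg)
    simulate_cohort(cfg, env)$tick_count
  }
  # fixed mu = 5, k = 0.5: variance = mu + mu^2/k = 55
  y <- flat(0.5, 50000, 5)
  expect_lt(abs(mean(y) / 5 - 1), 0.05)
  expect_lt(abs(var(y) / 55 - 1), 0.05)
  # k -> infinity: Poisson limit, variance ~ mean
  y2 <- flat(1e6, 50000, 5)
  expect_lt(abs(var(y2) / mean(y2) - 1), 0.05)
})

test_that("burdens are aggregated: variance exceeds mean for k <= 1", {
  cfg <- scale_cohort_size(sim_config(seed = 67), 5000, 5000, n_years = 14)
  env <- simulate_environment(cfg)
  h <- simulate_cohort(cfg, env)
  for (sx in c("male", "female")) {
    y <- h$tick_count[h$sex == sx]
    expect_gte(var(y), 1.5 * mean(y))
  }
})

test_that("default cohort reproduces the field study's mean burdens", {
  cfg <- scale_cohort_size(sim_config(seed = 68), 5000, 5000)
  env <- simulate_environment(cfg)
  h <- simulate_cohort(cfg, env)
  m <- mean(h$tick_count[h$sex == "male"])
  f <- mean(h$tick_count[h$sex == "female"])
  expect_lt(abs(m / 20.4 - 1), 0.2)
  expect_lt(abs(f / 2.4 - 1), 0.2)
})

test_that("correctly specified fits recover the generating coefficients", {
  # nonzero-coefficient recovery averaged over replicates, plus pooled
  # empirical coverage of 95% Wald intervals
  preds <- c("total_length", "age_class", "kfi", "avt_m", "ap_m",
             "deer_c", "deer_c_lag2", "boar_c_lag2")
  truth_map <- c(total_length = "total_length", age_class = "age_class",
                 kfi = "kfi", avt_m = "avt_m", ap_m = "ap_m",
                 deer_c = "deer_census", deer_c_lag2 = "deer_census_lag2",
                 boar_c_lag2 = "boar_census_lag2")
  cfg0 <- sim_config()
  est_m <- est_f <- NULL
  cover <- c()
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    cfg <- scale_cohort_size(sim_config(seed = 7000 + i), 5000, 5000)
    env <- simulate_environment(cfg)
    d <- build_design(simulate_cohort(cfg, env), env$meteo, env$census)
    for (sx in c("male", "female")) {
      ds <- dplyr::filter(d, sex == sx)
      f <- fit_nb(ds, preds)
      truth <- cfg[[paste0("beta_", sx)]][truth_map]
      est <- f$coefficients[preds]
      se <- f$se[-1]
      cover <- c(cover, abs(est - truth) <= 1.96 * se)
      if (sx == "male") est_m <- rbind(est_m, est) else
        est_f <- rbind(est_f, est)
    }
  }
  for (sx in c("male", "female")) {
    truth <- cfg0[[paste0("beta_", sx)]][truth_map]
    est <- colMeans(if (sx == "male") est_m else est_f)
    nz <- which(truth != 0)
    expect_lt(max(abs(est[nz] / truth[nz] - 1)), 0.10)
  }
  cov_rate <- mean(cover)
  expect_gte(cov_rate, 0.90)
  expect_lte(cov_rate, 0.98)
})
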