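test_that("intercept-only fit returns the sample mean exactly", {
  d <- tibble::tibble(tick_count = c(3L, 3L, 3L, 3L, 3L, 3L))
  f <- fit_nb(d)
  expect_equal(unname(f$fitted), rep(3, 6), tolerance = 1e-9)
  expect_equal(f$explained_deviance, 0)

  d2 <- tibble::tibble(tick_count = c(0L, 2L, 5L, 9L, 1L, 4L, 3L))
  f2 <- fit_nb(d2)
  expect_equal(unname(f2$coefficients[["(Intercept)"]]), log(mean(d2$tick_count)),
               tolerance = 1e-7)
})

test_that("parameter recovery against the generating NB regression", {
  d <- make_nb_data(10000, beta0 = 1.0, beta1 = 0.5, theta = 1.0, seed = 11)
  f <- fit_nb(d, "x")
  expect_lt(abs(f$coefficients[["(Intercept)"]] - 1.0), 0.05)
  expect_lt(abs(f$coefficients[["x"]] - 0.5), 0.05)
  expect_lt(abs(f$theta - 1.0), 0.1)
  expect_true(f$converged)
})

test_that("log-likelihood agrees with direct pmf evaluation and generic ML", {
  d <- make_nb_data(800, beta0 = 0.5, beta1 = -0.4, theta = 0.7, seed = 12)
  f <- fit_nb(d, "x")
  mu <- f$fitted
  expect_equal(f$loglik, sum(nb_logpmf_direct(d$tick_count, mu, f$theta)),
               tolerance = 1e-8)

  # independent oracle: generic numerical optimisation of the same likelihood
  nll <- function(par) {
    m <- exp(par[1] + par[2] * d$x)
    -sum(nb_logpmf_direct(d$tick_count, m, exp(par[3])))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS")
  expect_equal(unname(f$coefficients), opt$par[1:2], tolerance = 1e-3)
  expect_equal(log(f$theta), opt$par[3], tolerance = 1e-2)
  expect_lte(-opt$value, f$loglik + 1e-6)
})

test_that("fit matches the reference ecology implementation", {
  d <- make_nb_data(2000, beta0 = 1.2, beta1 = 0.3, theta = 0.6, seed = 13)
  f <- fit_nb(d, "x")
  m <- MASS::glm.nb(tick_count ~ x, data = d)
  expect_equal(unname(f$coefficients), unname(coef(m)), tolerance = 1e-5)
  expect_equal(f$theta, m$theta, tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
})

test_that("Poisson-limit data reproduce a Poisson GLM fit", {
  withr::with_seed(14, {
    x <- rnorm(5000)
    d <- tibble::tibble(x = x, tick_count = rpois(5000, exp(1 + 0.4 * x)))
  })
  f <- fit_nb(d, "x")
  g <- glm(tick_count ~ x, data = d, family = poisson())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-3)
})

test_that("deviance bookkeeping: nesting, explained fraction, AIC", {
  d <- make_nb_data(1500, beta0 = 1, beta1 = 0.5, theta = 1, seed = 15)
  f0 <- fit_nb(d)
  f1 <- fit_nb(d, "x")
  expect_gte(f0$null_deviance + 1e-6, f0$deviance)
  expect_gte(f1$null_deviance + 1e-6, f1$deviance)
  expect_gte(f1$explained_deviance, -1e-6)
  expect_lte(f1$explained_deviance, 1)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * 3)  # 2 betas + theta
  # adding a predictor never increases residual deviance at fixed theta
  f1_fix <- fit_nb(d, "x", theta = f0$theta)
  f0_fix <- fit_nb(d, character(), theta = f0$theta)
  expect_lte(f1_fix$deviance, f0_fix$deviance + 1e-6)
})

test_that("input contracts: bad responses, rank deficiency, degenerate fits", {
  d <- make_nb_data(100, 1, 0.5, 1, seed = 16)
  bad <- d; bad$tick_count[1] <- -1L
  expect_error(fit_nb(bad, "x"), class = "tb_validation_error")
  bad2 <- d; bad2$tick_count <- bad2$tick_count + 0.5
  expect_error(fit_nb(bad2, "x"), class = "tb_validation_error")

  d$x2 <- d$x * 2
  err <- expect_error(fit_nb(d, c("x", "x2")), class = "tb_singular_error")
  expect_match(conditionMessage(err), "x2")

  zeros <- tibble::tibble(tick_count = rep(0L, 50))
  fz <- fit_nb(zeros)
  expect_identical(fz$status, "degenerate_all_zero")
  expect_equal(unname(fz$fitted), rep(0, 50))
})

test_that("predict_burden: consistency, log-link identity, schema check", {
  d <- make_nb_data(500, 0.8, 0.5, 1, seed = 17)
  f <- fit_nb(d, "x")
  expect_equal(predict_burden(f, d), unname(f$fitted), tolerance = 1e-9)
  expect_true(all(predict_burden(f, d) > 0))
  b <- f$coefficients[["x"]]
  d2 <- d; d2$x <- d2$x + 1
  expect_equal(predict_burden(f, d2), predict_burden(f, d) * exp(b),
               tolerance = 1e-9)
  d0 <- d; d0$x <- 0
  expect_equal(unique(round(predict_burden(f, d0), 9)),
               round(exp(f$coefficients[["(Intercept)"]]), 9))
  expect_error(predict_burden(f, d["tick_count"]), class = "tb_schema_error")
})

test_that("tidy and glance expose the broom-style summaries", {
  d <- make_nb_data(400, 1, 0.5, 1, seed = 18)
  f <- fit_nb(d, "x")
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$statistic, td$estimate / td$std.error)
  gl <- glance(f)
  expect_equal(gl$AIC, f$aic)
  expect_equal(gl$nobs, 400)
})

test_that("overdispersion statistic: Poisson null, NB closed form, constant", {
  withr::with_seed(19, {
    x <- rnorm(10000)
    dpois <- tibble::tibble(x = x, tick_count = rpois(10000, exp(1 + 0.3 * x)))
  })
  expect_lt(abs(overdispersion_check(dpois, "x") - 1), 0.1)

  # NB with constant mu = 5, theta = 0.5: Pearson dispersion ~ 1 + mu/theta
  withr::with_seed(20, {
    dnb <- tibble::tibble(tick_count = rnbinom(10000, size = 0.5, mu = 5))
  })
  expect_lt(abs(overdispersion_check(dnb) / 11 - 1), 0.2)

  dconst <- tibble::tibble(tick_count = rep(4L, 30))
  expect_equal(overdispersion_check(dconst), 0)
})

test_that("VIF: orthogonal, correlated pair closed form, exact collinearity", {
  n <- 400
  withr::with_seed(21, {
    x1 <- rnorm(n)
    x2 <- rnorm(n)
  })
  # exactly orthogonalise and standardise
  x2o <- residuals(lm(x2 ~ x1))
  d <- tibble::tibble(a = x1, b = x2o)
  v <- vif(d, c("a", "b"))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-12)

  # construct an exact sample correlation r = 0.6 -> VIF = 1/(1-0.36)
  z <- x2o / sd(x2o) * sd(x1)
  r <- 0.6
  b2 <- r * x1 + sqrt(1 - r^2) * z
  d2 <- tibble::tibble(a = x1, b = b2)
  r_emp <- cor(d2$a, d2$b)
  v2 <- vif(d2, c("a", "b"))
  expect_equal(v2$vif, rep(1 / (1 - r_emp^2), 2), tolerance = 1e-9)
  expect_equal(v2$vif[1], 1.5625, tolerance = 1e-6)

  d3 <- tibble::tibble(a = x1, b = b2, c = x1 + b2)
  expect_warning(v3 <- vif(d3, c("a", "b", "c")), "collinearity")
  expect_true(all(is.infinite(v3$vif)))
  d4 <- tibble::tibble(a = x1, b = rep(2, n))
  expect_error(vif(d4, c("a", "b")), class = "tb_validation_error")
})
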