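#' Fit a negative binomial GLM with log link
#'
#' Maximum-likelihood fit of a negative binomial (NB2) regression for
#' overdispersed counts: \eqn{y_i \sim NB(\mu_i, \theta)} with
#' \eqn{\log \mu_i = x_i^\top \beta} and variance
#' \eqn{\mu + \mu^2/\theta}. The size parameter \eqn{\theta} measures
#' aggregation: smaller \eqn{\theta} means more aggregated counts. (Note the
#' parameterisation: some software uses \eqn{\alpha = 1/\theta}.)
#'
#' The likelihood is maximised jointly over \eqn{(\beta, \theta)} by
#' alternating iteratively reweighted least squares updates of \eqn{\beta} at
#' fixed \eqn{\theta} with univariate ML updates of \eqn{\theta} at fixed
#' \eqn{\beta} (safeguarded Newton with a golden-section fallback), until the
#' log-likelihood changes by less than `1e-8` or 100 outer iterations are
#' reached. Non-convergence is reported loudly in the `status` field and via
#' a warning, never silently.
#'
#' Deviance is \eqn{2\sum_i [y_i \log(y_i/\hat\mu_i) -
#' (y_i+\theta)\log((y_i+\theta)/(\hat\mu_i+\theta))]} (with
#' \eqn{y\log(y/\mu) \equiv 0} at \eqn{y = 0}); the null deviance uses the
#' intercept-only mean at the *same* \eqn{\theta} so that explained-deviance
#' fractions are comparable. AIC is \eqn{-2\ell + 2(|\beta|+1)}, counting
#' \eqn{\theta} as one estimated parameter (no `+1` when `theta` is supplied
#' fixed).
#'
#' @param data Data frame containing the response and predictor columns.
#' @param predictors Character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @param response Response column name, default `"tick_count"`. Must hold
#'   non-negative integers.
#' @param theta Optional fixed NB size parameter; if `NULL` (default)
#'   \eqn{\theta} is estimated by ML.
#' @param max_iter Maximum outer iterations, default 100.
#' @param tol Log-likelihood convergence tolerance, default `1e-8`.
#' @return An object of class `nb_fit`: a list with `coefficients`, `se`,
#'   `theta`, `loglik`, `deviance`, `null_deviance`, `explained_deviance`,
#'   `aic`, `fitted`, `n`, `status`, `converged`, and bookkeeping fields.
#' @seealso [predict_burden()], [stepwise_nb()], [tidy.nb_fit()],
#'   [glance.nb_fit()]
#' @export
fit_nb <- function(data, predictors = character(), response = "tick_count",
                   theta = NULL, max_iter = 100, tol = 1e-8) {
  data <- as_tibble(data)
  if (!response %in% names(data)) {
    stop_tb(sprintf("Response column '%s' not found.", response),
            "tb_schema_error")
  }
  miss <- setdiff(predictors, names(data))
  if (length(miss)) {
    stop_tb(paste0("Predictor column(s) not found: ",
                   paste(miss, collapse = ", ")), "tb_schema_error")
  }
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop_tb("Response must consist of non-negative integers.",
            "tb_validation_error")
  }
  y <- as.numeric(round(y))
  n <- length(y)
  if (length(predictors) == 0) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    xm <- as.matrix(data[predictors])
    if (!is.numeric(xm)) {
      stop_tb("All predictors must be numeric columns.", "tb_validation_error")
    }
    X <- cbind("(Intercept)" = 1, xm)
  }
  p <- ncol(X)
  if (n <= p + 2) {
    stop_tb("Too few observations for the number of predictors.",
            "tb_validation_error")
  }
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop_tb(paste0("Design is rank deficient; collinear column(s): ",
                   paste(bad, collapse = ", ")), "tb_singular_error")
  }

  if (all(y == 0)) {
    cf <- c(-Inf, rep(0, p - 1))
    names(cf) <- colnames(X)
    fit <- structure(list(
      coefficients = cf, se = rep(NA_real_, p), theta = NA_real_,
      theta_fixed = !is.null(theta), loglik = 0, deviance = 0,
      null_deviance = 0, explained_deviance = 0, aic = 0, fitted = rep(0, n),
      n = n, df_residual = n - p, predictors = predictors,
      response = response, converged = FALSE, status = "degenerate_all_zero",
      iterations = 0L, vcov = NULL, y = y
    ), class = "nb_fit")
    return(fit)
  }

  theta_fixed <- !is.null(theta)

  # initialise beta from a Poisson fit (same link)
  pois <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  beta <- coef(pois)
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- exp(eta)

  if (theta_fixed) {
    th <- theta
    if (!is.finite(th) || th <= 0) {
      stop_tb("`theta` must be a positive number.", "tb_config_error")
    }
  } else {
    # method-of-moments start, clipped
    th <- sum(mu^2) / max(sum((y - mu)^2 - mu), sum(mu^2) / 1e4)
    th <- min(max(th, 1e-3), 1e6)
  }

  ll <- nb_loglik(y, mu, th)
  status <- "converged"
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # IRLS update of beta at fixed theta
    for (k in 1:25) {
      w <- mu * th / (mu + th)
      z <- eta + (y - mu) / mu
      wls <- stats::lm.wfit(X, z, w)
      beta_new <- coef(wls)
      if (anyNA(beta_new)) {
        status <- "diverged"
        break
      }
      eta_new <- pmin(pmax(drop(X %*% beta_new), -30), 30)
      mu_new <- exp(eta_new)
      if (max(abs(beta_new - beta)) < 1e-10) {
        beta <- beta_new; eta <- eta_new; mu <- mu_new
        break
      }
      beta <- beta_new; eta <- eta_new; mu <- mu_new
    }
    if (status == "diverged") break
    if (!theta_fixed) th <- nb_theta_ml(y, mu, th)
    ll_new <- nb_loglik(y, mu, th)
    if (!is.finite(ll_new)) {
      status <- "diverged"
      break
    }
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged && status == "converged") status <- "non_converged"
  if (status != "converged") {
    warn(sprintf("fit_nb did not converge (status: %s) after %d iterations.",
                 status, it))
  }

  w <- mu * th / (mu + th)
  xw <- X * sqrt(w)
  R <- qr.R(qr(xw))
  vcov <- tryCatch(chol2inv(R), error = function(e) matrix(NA_real_, p, p))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))

  dev <- nb_deviance(y, mu, th)
  null_dev <- nb_deviance(y, rep(mean(y), n), th)
  expl <- if (null_dev > 1e-12) 1 - dev / null_dev else 0
  k_par <- p + if (theta_fixed) 0 else 1
  aic <- -2 * ll + 2 * k_par

  structure(list(
    coefficients = setNames(beta, colnames(X)), se = se, theta = th,
    theta_fixed = theta_fixed, loglik = ll, deviance = dev,
    null_deviance = null_dev, explained_deviance = expl, aic = aic,
    fitted = mu, n = n, df_residual = n - p, predictors = predictors,
    response = response, converged = converged, status = status,
    iterations = it, vcov = vcov, y = y
  ), class = "nb_fit")
}

# NB log-likelihood (size theta, mean mu)
nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# NB deviance with 0*log(0) = 0
nb_deviance <- function(y, mu, theta) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + theta) * log((y + theta) / (mu + theta))
  2 * sum(t1 - t2)
}

# univariate ML update of theta given mu: safeguarded Newton on theta with
# golden-section fallback on log(theta)
nb_theta_ml <- function(y, mu, theta0) {
  n <- length(y)
  score <- function(th) {
    sum(digamma(y + th)) - n * digamma(th) + n * (log(th) + 1) -
      sum(log(mu + th) + (y + th) / (mu + th))
  }
  dscore <- function(th) {
    sum(trigamma(y + th)) - n * trigamma(th) + n / th -
      sum(2 / (mu + th) - (y + th) / (mu + th)^2)
  }
  th <- theta0
  ok <- FALSE
  for (i in 1:30) {
    s <- score(th)
    d <- dscore(th)
    if (!is.finite(s) || !is.finite(d) || d >= 0) break
    step <- s / d
    th_new <- th - step
    if (!is.finite(th_new) || th_new <= 0) th_new <- th / 2
    if (abs(th_new - th) < 1e-10 * (th + 1e-10)) {
      th <- th_new
      ok <- TRUE
      break
    }
    th <- min(th_new, 1e7)
  }
  if (!ok || !is.finite(score(th))) {
    opt <- optimize(function(lt) nb_loglik(y, mu, exp(lt)),
                    interval = c(log(1e-4), log(1e7)),
                    maximum = TRUE, tol = 1e-10)
    th <- exp(opt$maximum)
  }
  min(max(th, 1e-4), 1e7)
}

#' Predict expected burdens from a fitted NB model
#'
#' Returns \eqn{\exp(x^\top \hat\beta)} per row of `newdata`; strictly
#' positive expected counts on the response scale.
#'
#' @param fit An [fit_nb()] object.
#' @param newdata Data frame containing all predictor columns of the fit.
#' @return Numeric vector of expected counts.
#' @export
predict_burden <- function(fit, newdata) {
  stopifnot(inherits(fit, "nb_fit"))
  newdata <- as_tibble(newdata)
  miss <- setdiff(fit$predictors, names(newdata))
  if (length(miss)) {
    stop_tb(paste0("`newdata` lacks predictor column(s): ",
                   paste(miss, collapse = ", ")), "tb_schema_error")
  }
  X <- cbind(1, as.matrix(newdata[fit$predictors]))
  exp(drop(X %*% fit$coefficients))
}

#' @export
predict.nb_fit <- function(object, newdata, ...) predict_burden(object, newdata)

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative binomial GLM (log link)\n")
  cat(sprintf("  n = %d, theta = %s%s, AIC = %.2f\n", x$n,
              format(signif(x$theta, 4)),
              if (x$theta_fixed) " (fixed)" else "", x$aic))
  cat(sprintf("  deviance %.3f on null %.3f (explained %.1f%%), status: %s\n",
              x$deviance, x$null_deviance, 100 * x$explained_deviance,
              x$status))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy coefficient table for an NB fit
#'
#' @param x An [fit_nb()] object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (Wald z) and `p.value`.
#' @export
tidy.nb_fit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' One-row model summary for an NB fit
#'
#' @param x An [fit_nb()] object.
#' @param ... Unused.
#' @return A one-row tibble with `theta`, `logLik`, `AIC`, `deviance`,
#'   `null.deviance`, `explained.deviance`, `nobs`, `df.residual`, `status`.
#' @export
glance.nb_fit <- function(x, ...) {
  tibble(
    theta = x$theta, logLik = x$loglik, AIC = x$aic, deviance = x$deviance,
    null.deviance = x$null_deviance, explained.deviance = x$explained_deviance,
    nobs = x$n, df.residual = x$df_residual, status = x$status
  )
}
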