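#' Poisson overdispersion check
#'
#' Fits the corresponding Poisson GLM (log link) and returns the Pearson
#' dispersion statistic \eqn{\chi^2 / (n - p)}. Values much larger than 1
#' indicate overdispersion and motivate the negative binomial family: under
#' an NB truth with mean \eqn{\mu} and size \eqn{\theta} the statistic
#' approaches \eqn{1 + \mu/\theta}.
#'
#' @inheritParams fit_nb
#' @return A single number, the Pearson chi-square divided by residual df.
#' @export
overdispersion_check <- function(data, predictors = character(),
                                 response = "tick_count") {
  data <- as_tibble(data)
  y <- data[[response]]
  if (is.null(y)) {
    stop_tb(sprintf("Response column '%s' not found.", response),
            "tb_schema_error")
  }
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop_tb("Response must consist of non-negative integers.",
            "tb_validation_error")
  }
  n <- length(y)
  if (length(predictors) == 0) {
    X <- matrix(1, n, 1)
  } else {
    X <- cbind(1, as.matrix(data[predictors]))
  }
  if (all(y == y[1]) && abs(y[1] - mean(y)) < 1e-12) {
    # constant response equal to its fitted mean: zero Pearson statistic
    return(0)
  }
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  mu <- fit$fitted.values
  sum((y - mu)^2 / mu) / (n - ncol(X))
}

#' Variance inflation factors
#'
#' VIF of predictor \eqn{j} is \eqn{1/(1 - R^2_j)} where \eqn{R^2_j} comes
#' from an ordinary least-squares regression (with intercept) of predictor
#' \eqn{j} on all the others — the inverse of the coefficient of
#' non-determination. Computed on the numeric design columns as entered in
#' the model (ordinal age class and numeric year included as-is).
#'
#' @param data Data frame with the predictor columns.
#' @param predictors Character vector of at least two predictor names.
#' @return A tibble with columns `predictor` and `vif`. Perfect collinearity
#'   is reported as `Inf` with a warning.
#' @export
vif <- function(data, predictors) {
  data <- as_tibble(data)
  if (length(predictors) < 2) {
    stop_tb("VIF needs at least two predictors.", "tb_config_error")
  }
  miss <- setdiff(predictors, names(data))
  if (length(miss)) {
    stop_tb(paste0("Predictor column(s) not found: ",
                   paste(miss, collapse = ", ")), "tb_schema_error")
  }
  xm <- as.matrix(data[predictors])
  consts <- predictors[apply(xm, 2, function(v) var(v) < 1e-14)]
  if (length(consts)) {
    stop_tb(paste0("Constant predictor(s): ", paste(consts, collapse = ", ")),
            "tb_validation_error")
  }
  out <- purrr::map_dbl(seq_along(predictors), function(j) {
    yj <- xm[, j]
    Xo <- cbind(1, xm[, -j, drop = FALSE])
    f <- stats::lm.fit(Xo, yj)
    rss <- sum(f$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  if (any(is.infinite(out))) {
    warn(paste0("Perfect collinearity (infinite VIF) for: ",
                paste(predictors[is.infinite(out)], collapse = ", ")))
  }
  tibble(predictor = predictors, vif = out)
}
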