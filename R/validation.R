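#' Stratified train/validation split
#'
#' Random, disjoint and exhaustive split of a data set into training and
#' validation subsets, stratified so that every stratum (by default host sex)
#' is represented in both subsets in approximately its overall proportion.
#'
#' @param data Data frame to split.
#' @param train_fraction Fraction assigned to training, default 0.70.
#' @param seed Integer seed; the split is reproducible under it.
#' @param stratum Stratification column name, default `"sex"`; `NULL` for an
#'   unstratified split.
#' @return A list with tibbles `train` and `validate`.
#' @export
split_train_validate <- function(data, train_fraction = 0.70, seed,
                                 stratum = "sex") {
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < 10) stop_tb("Need at least 10 records to split.",
                      "tb_validation_error")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_tb("`train_fraction` must be in (0, 1).", "tb_config_error")
  }
  strata <- if (is.null(stratum)) rep("all", n) else as.character(data[[stratum]])
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(n), strata), function(ii) {
      k <- round(length(ii) * train_fraction)
      if (k < 1 || k >= length(ii)) {
        stop_tb(sprintf(
          "A stratum with %d record(s) cannot appear in both subsets.",
          length(ii)), "tb_validation_error")
      }
      sample(ii, k)
    }), use.names = FALSE)
  })
  list(train = data[sort(idx_train), , drop = FALSE],
       validate = data[sort(setdiff(seq_len(n), idx_train)), , drop = FALSE])
}

#' Calibration table of binned observed vs predicted burdens
#'
#' Sorts records by predicted burden (ties keep their input order), cuts them
#' into `n_bins` contiguous equal-count bins (sizes differ by at most one;
#' earlier bins take the extra records), and reports per-bin means. Two
#' global metrics operationalise the precision/accuracy distinction:
#' *precision* is the Spearman rank correlation of bin mean observed burden
#' with bin order (does observed burden increase with predicted?), and
#' *accuracy* is the calibration ratio mean observed / mean predicted,
#' overall and per bin (is the magnitude right?). An OLS slope and intercept
#' of bin mean observed on bin mean predicted are also returned.
#'
#' With `auto_bins = TRUE`, when `n / n_bins < 10` the number of bins is
#' halved (to a minimum of 5) and a message is emitted, following the
#' practice of using fewer intervals for small validation sets.
#'
#' @param observed Non-negative observed counts.
#' @param predicted Positive predicted burdens, same length.
#' @param n_bins Number of equal-count bins, default 10.
#' @param auto_bins Halve the bin count for small samples? Default `FALSE`
#'   (the requested bin count is used as-is).
#' @return A `tb_calibration` object: tibble with columns `bin`, `n`,
#'   `mean_predicted`, `mean_observed`, `ratio`; metrics in the `metrics`
#'   attribute (see [glance.tb_calibration()]).
#' @export
bin_calibration <- function(observed, predicted, n_bins = 10,
                            auto_bins = FALSE) {
  if (length(observed) != length(predicted)) {
    stop_tb("`observed` and `predicted` must have equal length.",
            "tb_validation_error")
  }
  n <- length(observed)
  if (n < 5) stop_tb("Need at least 5 records to bin.", "tb_validation_error")
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop_tb("Observed and predicted values must be finite.",
            "tb_validation_error")
  }
  b <- n_bins
  if (auto_bins) {
    while (n / b < 10 && b > 5) {
      b <- max(5L, ceiling(b / 2))
      inform(sprintf("Small validation set (n = %d): using %d bins.", n, b))
    }
  }
  b <- min(b, n)

  degenerate <- var(predicted) < 1e-14
  if (degenerate) {
    warn("Constant predictions: single degenerate calibration bin.")
    b <- 1L
  }

  ord <- order(predicted)  # stable for ties: radix keeps input order
  sizes <- rep(floor(n / b), b)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin_id <- rep(seq_len(b), times = sizes)

  tab <- tibble(bin = bin_id,
                observed = observed[ord],
                predicted = predicted[ord]) %>%
    group_by(.data$bin) %>%
    summarise(n = dplyr::n(),
              mean_predicted = mean(.data$predicted),
              mean_observed = mean(.data$observed),
              .groups = "drop") %>%
    mutate(ratio = .data$mean_observed / .data$mean_predicted)

  overall_ratio <- mean(observed) / mean(predicted)
  prec <- if (b > 2) {
    suppressWarnings(cor(tab$mean_observed, seq_len(b), method = "spearman"))
  } else {
    NA_real_
  }
  ols <- if (b > 1 && var(tab$mean_predicted) > 1e-14) {
    cf <- coef(lm(tab$mean_observed ~ tab$mean_predicted))
    c(intercept = unname(cf[1]), slope = unname(cf[2]))
  } else {
    c(intercept = NA_real_, slope = NA_real_)
  }
  structure(tab,
            metrics = list(
              n = n, n_bins = b,
              rank_correlation = prec,
              calibration_ratio = overall_ratio,
              ols_intercept = ols[["intercept"]],
              ols_slope = ols[["slope"]],
              degenerate = degenerate
            ),
            class = c("tb_calibration", class(tab)))
}

#' Apply a fitted model to another data set and score calibration
#'
#' Predicts expected burdens on `newdata` with [predict_burden()] (the source
#' model's coefficients are used unchanged — no recalibration) and returns
#' the binned calibration table of observed against predicted burdens. This
#' is the cross-population (e.g. cross-sex) validation step: a model fitted
#' on one group is judged on how precisely (rank order) and accurately
#' (magnitude) it predicts burdens in the other.
#'
#' @param fit An [fit_nb()] object.
#' @param newdata Validation data containing the fit's predictors and the
#'   response column.
#' @param n_bins Number of calibration bins, default 10.
#' @param auto_bins Halve the bin count for small validation sets? Default
#'   `TRUE` here (a 10-bin request on a set of a few dozen records drops to
#'   5 intervals).
#' @return A `tb_calibration` object (see [bin_calibration()]).
#' @export
cross_apply <- function(fit, newdata, n_bins = 10, auto_bins = TRUE) {
  newdata <- as_tibble(newdata)
  if (!fit$response %in% names(newdata)) {
    stop_tb(sprintf("Response column '%s' not found in `newdata`.",
                    fit$response), "tb_schema_error")
  }
  pred <- predict_burden(fit, newdata)
  bin_calibration(newdata[[fit$response]], pred, n_bins = n_bins,
                  auto_bins = auto_bins)
}

#' @export
print.tb_calibration <- function(x, ...) {
  m <- attr(x, "metrics")
  cat(sprintf(
    "Calibration table: %d records in %d bins\n  rank correlation %.3f, calibration ratio %.3f, OLS slope %.3f\n",
    m$n, m$n_bins, m$rank_correlation, m$calibration_ratio, m$ols_slope))
  NextMethod()
  invisible(x)
}

#' One-row metric summary of a calibration table
#'
#' @param x A `tb_calibration` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n.bins`, `rank.correlation`,
#'   `calibration.ratio`, `ols.slope`, `ols.intercept`, `degenerate`.
#' @export
glance.tb_calibration <- function(x, ...) {
  m <- attr(x, "metrics")
  tibble(n = m$n, n.bins = m$n_bins, rank.correlation = m$rank_correlation,
         calibration.ratio = m$calibration_ratio, ols.slope = m$ols_slope,
         ols.intercept = m$ols_intercept, degenerate = m$degenerate)
}

#' Calibration plot of bin means with the 1:1 line
#'
#' @param object A `tb_calibration` object.
#' @param ... Unused.
#' @return A ggplot object: mean observed vs mean predicted burden per bin,
#'   with the identity line.
#' @export
autoplot.tb_calibration <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_predicted,
                                   y = .data$mean_observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Mean predicted burden (bin)",
                  y = "Mean observed burden (bin)",
                  title = "Calibration of binned predictions") +
    ggplot2::theme_minimal()
}
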