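#' Turc actual evapotranspiration
#'
#' Computes actual evapotranspiration (AET, mm) from accumulated precipitation
#' and mean temperature with the Turc formula
#' \deqn{AET = P / \sqrt{0.9 + P^2/L^2}, \qquad L = 300 + 25t + 0.05t^3,}
#' where `P` is accumulated precipitation (mm) over the period and `t` the mean
#' temperature (deg C). AET is used as an index of the hydric stress
#' experienced by off-host (questing) ticks.
#'
#' By default the raw Turc value is returned, which can slightly exceed `P`
#' (as \eqn{P^2/L^2 \to 0}, \eqn{AET \to P/\sqrt{0.9} \approx 1.054 P}).
#' `cap = TRUE` clamps the result at `P`, the classical water-balance
#' convention \eqn{AET \le P}.
#'
#' @param t Mean temperature in deg C (vectorised).
#' @param P Accumulated precipitation in mm, `>= 0` (vectorised).
#' @param cap If `TRUE`, cap AET at `P`. Default `FALSE`.
#' @return Numeric vector of AET in mm.
#' @examples
#' turc_aet(20.1, 8.0)   # ~ 8.43
#' turc_aet(15.0, 100.0) # ~ 104.6
#' @export
turc_aet <- function(t, P, cap = FALSE) {
  if (any(!is.finite(t)) || any(!is.finite(P))) {
    stop_tb("`t` and `P` must be finite.", "tb_domain_error")
  }
  if (any(P < 0)) {
    stop_tb("`P` must be non-negative.", "tb_domain_error")
  }
  L <- 300 + 25 * t + 0.05 * t^3
  if (any(L <= 0)) {
    bad <- t[L <= 0]
    stop_tb(
      sprintf(
        "Turc heat term L = 300 + 25t + 0.05t^3 is non-positive at t = %s.",
        paste(signif(bad, 4), collapse = ", ")
      ),
      "tb_domain_error"
    )
  }
  aet <- P / sqrt(0.9 + P^2 / L^2)
  if (cap) aet <- pmin(aet, P)
  aet
}

#' Aggregate daily meteorology over a pre-sampling window
#'
#' Summarises a daily meteorology series over the `window_days` days strictly
#' before each sampling date (half-open window: the sampling day itself is
#' excluded). Returns, per sampling date, the average of daily mean
#' temperatures (`avt_m`, deg C), accumulated precipitation (`ap_m`, mm) and
#' the Turc actual evapotranspiration of the window (`aet_m`, mm; see
#' [turc_aet()]), together with the intermediate Turc heat term `L`.
#'
#' Missing days inside a window are an error (no silent imputation).
#'
#' @param meteo Data frame with columns `date` (Date), `temp_mean` (deg C) and
#'   `precip` (mm, `>= 0`).
#' @param sampling_date Date vector (one window per element).
#' @param window_days Window length in days, default 30.
#' @param cap_aet Passed to [turc_aet()] as `cap`.
#' @return A tibble with one row per sampling date and columns
#'   `sampling_date`, `avt_m`, `ap_m`, `aet_m`, `turc_l`.
#' @export
window_aggregate <- function(meteo, sampling_date, window_days = 30,
                             cap_aet = FALSE) {
  meteo <- as_tibble(meteo)
  need <- c("date", "temp_mean", "precip")
  miss <- setdiff(need, names(meteo))
  if (length(miss)) {
    stop_tb(paste0("`meteo` lacks column(s): ", paste(miss, collapse = ", ")),
            "tb_schema_error")
  }
  sampling_date <- as.Date(sampling_date)
  dates <- as.Date(meteo$date)

  contiguous <- length(dates) > 1 &&
    all(diff(as.integer(dates)) == 1) &&
    !anyNA(meteo$temp_mean) && !anyNA(meteo$precip)

  if (contiguous) {
    # cumulative-sum fast path over the daily grid
    start <- match(sampling_date - window_days, dates)
    end <- start + window_days - 1
    bad <- is.na(start) | end > length(dates)
    if (any(bad)) {
      report_missing_window(dates, sampling_date[bad][1], window_days)
    }
    cs_t <- c(0, cumsum(meteo$temp_mean))
    cs_p <- c(0, cumsum(meteo$precip))
    avt <- (cs_t[end + 1] - cs_t[start]) / window_days
    ap <- cs_p[end + 1] - cs_p[start]
  } else {
    res <- purrr::map(sampling_date, function(d) {
      want <- seq(d - window_days, d - 1, by = "day")
      idx <- match(want, dates)
      if (anyNA(idx) || anyNA(meteo$temp_mean[idx]) ||
          anyNA(meteo$precip[idx])) {
        report_missing_window(dates[!is.na(meteo$temp_mean) &
                                      !is.na(meteo$precip)], d, window_days)
      }
      c(mean(meteo$temp_mean[idx]), sum(meteo$precip[idx]))
    })
    avt <- purrr::map_dbl(res, 1)
    ap <- purrr::map_dbl(res, 2)
  }

  tibble(
    sampling_date = sampling_date,
    avt_m = avt,
    ap_m = ap,
    aet_m = turc_aet(avt, ap, cap = cap_aet),
    turc_l = 300 + 25 * avt + 0.05 * avt^3
  )
}

report_missing_window <- function(have_dates, d, window_days) {
  want <- seq(d - window_days, d - 1, by = "day")
  gone <- want[!want %in% have_dates]
  stop_tb(
    sprintf(
      "Meteorology series is missing %d day(s) in the %d-day window before %s: %s",
      length(gone), window_days, format(d),
      paste(format(gone), collapse = ", ")),
    "tb_missing_data_error"
  )
}

#' Look up a (possibly lagged) annual census count
#'
#' @param census Data frame with a `year` column and count columns
#'   (e.g. `deer_count`, `boar_count`).
#' @param year Census year(s) of interest (the host's sampling year).
#' @param lag Lag in years: 0 (same year), 1 or 2.
#' @param column Name of the count column, default `"deer_count"`.
#' @return Numeric vector of counts for `year - lag`.
#' @export
lag_census <- function(census, year, lag = 0, column = "deer_count") {
  census <- as_tibble(census)
  if (!all(c("year", column) %in% names(census))) {
    stop_tb(sprintf("`census` needs columns 'year' and '%s'.", column),
            "tb_schema_error")
  }
  if (!all(lag %in% 0:2)) {
    stop_tb("`lag` must be 0, 1 or 2.", "tb_config_error")
  }
  target <- year - lag
  idx <- match(target, census$year)
  if (anyNA(idx)) {
    stop_tb(
      sprintf("Census year(s) absent from series: %s",
              paste(sort(unique(target[is.na(idx)])), collapse = ", ")),
      "tb_lookup_error"
    )
  }
  census[[column]][idx]
}

#' Default predictor-to-factor grouping
#'
#' Maps each model predictor to one of the three factor groups used in
#' deviance partitioning: host-individual (`Ind`), host-population (`Pop`)
#' and environment (`Env`).
#'
#' @return Named character vector: names are predictor columns of
#'   [build_design()], values are `"Ind"`, `"Pop"` or `"Env"`.
#' @export
default_grouping <- function() {
  c(
    total_length = "Ind", age_class = "Ind", kfi = "Ind", sex_female = "Ind",
    deer_c = "Pop", deer_c_lag1 = "Pop", deer_c_lag2 = "Pop",
    boar_c = "Pop", boar_c_lag1 = "Pop", boar_c_lag2 = "Pop",
    avt_m = "Env", ap_m = "Env", aet_m = "Env", year = "Env"
  )
}

#' Assemble the model design table
#'
#' Joins host records with their 30-day pre-sampling meteorological window and
#' the (lagged) annual censuses, producing one row per host with the response
#' `tick_count` and all candidate predictors, in the input row order. Each
#' predictor's factor group is attached as the `"grouping"` attribute.
#'
#' Predictors: `total_length`, `age_class` (ordinal 1-5 entered as numeric),
#' `kfi`, `sex_female` (indicator; male is the reference level), `year`
#' (numeric), `avt_m`, `ap_m`, `aet_m`, `deer_c` (+ lags 1, 2), `boar_c`
#' (+ lags 1, 2).
#'
#' @param hosts Host record table (see [simulate_cohort()] for the schema).
#' @param meteo Daily meteorology table (`date`, `temp_mean`, `precip`).
#' @param census Annual census table (`year`, `deer_count`, `boar_count`).
#' @param grouping Named character vector mapping predictors to factor groups;
#'   default [default_grouping()]. Every predictor column must appear.
#' @param window_days Meteorological window length, default 30.
#' @param cap_aet Cap AET at accumulated precipitation? Default `FALSE`.
#' @return A tibble (class `tb_design`) with bookkeeping columns `host_id`,
#'   `sampling_date`, `sex`, `season`, the response `tick_count`, and the
#'   predictor columns above; attribute `grouping` carries the factor map.
#' @export
build_design <- function(hosts, meteo, census, grouping = default_grouping(),
                         window_days = 30, cap_aet = FALSE) {
  hosts <- as_tibble(hosts)
  need <- c("host_id", "sampling_date", "year", "sex", "age_class",
            "total_length", "kidney_fat_index", "tick_count")
  miss <- setdiff(need, names(hosts))
  if (length(miss)) {
    stop_tb(paste0("`hosts` lacks column(s): ", paste(miss, collapse = ", ")),
            "tb_schema_error")
  }
  predictors <- c("total_length", "age_class", "kfi", "sex_female", "year",
                  "avt_m", "ap_m", "aet_m",
                  "deer_c", "deer_c_lag1", "deer_c_lag2",
                  "boar_c", "boar_c_lag1", "boar_c_lag2")
  ungrouped <- setdiff(predictors, names(grouping))
  if (length(ungrouped)) {
    stop_tb(paste0("Predictor(s) missing from `grouping`: ",
                   paste(ungrouped, collapse = ", ")),
            "tb_config_error")
  }

  if (nrow(hosts) == 0) {
    empty <- tibble(
      host_id = character(), sampling_date = as.Date(character()),
      sex = character(), season = character(), tick_count = integer()
    )
    for (p in predictors) empty[[p]] <- numeric()
    return(structure(empty, grouping = grouping[predictors],
                     class = c("tb_design", class(empty))))
  }

  win <- window_aggregate(meteo, hosts$sampling_date,
                          window_days = window_days, cap_aet = cap_aet)

  season <- if ("season" %in% names(hosts)) hosts$season else
    season_of(hosts$sampling_date)

  out <- tibble(
    host_id = as.character(hosts$host_id),
    sampling_date = as.Date(hosts$sampling_date),
    sex = hosts$sex,
    season = season,
    tick_count = hosts$tick_count,
    total_length = hosts$total_length,
    age_class = as.numeric(hosts$age_class),
    kfi = hosts$kidney_fat_index,
    sex_female = as.numeric(hosts$sex == "female"),
    year = as.numeric(hosts$year),
    avt_m = win$avt_m,
    ap_m = win$ap_m,
    aet_m = win$aet_m,
    deer_c = lag_census(census, hosts$year, 0, "deer_count"),
    deer_c_lag1 = lag_census(census, hosts$year, 1, "deer_count"),
    deer_c_lag2 = lag_census(census, hosts$year, 2, "deer_count"),
    boar_c = lag_census(census, hosts$year, 0, "boar_count"),
    boar_c_lag1 = lag_census(census, hosts$year, 1, "boar_count"),
    boar_c_lag2 = lag_census(census, hosts$year, 2, "boar_count")
  )
  structure(out, grouping = grouping[predictors],
            class = c("tb_design", class(out)))
}

# meteorological quarters: Dec-Feb winter, Mar-May spring, Jun-Aug summer,
# Sep-Nov autumn
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}
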