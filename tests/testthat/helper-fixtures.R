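# constant daily meteorology covering a window of dates
make_meteo <- function(from = "2004-01-01", to = "2004-12-31",
                       temp = 10, precip = 1) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  tibble::tibble(date = dates,
                 temp_mean = rep_len(temp, length(dates)),
                 precip = rep_len(precip, length(dates)))
}

# simulate a plain NB regression data set with one covariate
make_nb_data <- function(n, beta0, beta1, theta, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    mu <- exp(beta0 + beta1 * x)
    tibble::tibble(x = x,
                   tick_count = stats::rnbinom(n, size = theta, mu = mu))
  })
}

# independent brute-force oracle: solve the 7x7 linear system expressing each
# fitted model's explained deviance as the sum of the components it contains
solve_partition_oracle <- function(d) {
  # component order: I, P, E, IP, IE, PE, IPE
  contains <- rbind(
    ind     = c(1, 0, 0, 1, 1, 0, 1),
    pop     = c(0, 1, 0, 1, 0, 1, 1),
    env     = c(0, 0, 1, 0, 1, 1, 1),
    ind_pop = c(1, 1, 0, 1, 1, 1, 1),
    ind_env = c(1, 0, 1, 1, 1, 1, 1),
    pop_env = c(0, 1, 1, 1, 1, 1, 1),
    full    = c(1, 1, 1, 1, 1, 1, 1)
  )
  stats::setNames(solve(contains, d), c("I", "P", "E", "IP", "IE", "PE", "IPE"))
}

# direct NB log-pmf evaluation from lgamma (independent of dnbinom)
nb_logpmf_direct <- function(y, mu, theta) {
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu))
}
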