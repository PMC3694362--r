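#' Deviance-partition components from seven explained-deviance fractions
#'
#' Splits the explained deviance of a full three-group model into pure and
#' shared components by inclusion-exclusion over the seven fitted models:
#' the three single-group models, the three pairwise models and the full
#' model. With `d_full = D(Ind+Pop+Env)` the subtraction rules are
#' \itemize{
#'   \item pure: `I = d_full - D(Pop+Env)`, `P = d_full - D(Ind+Env)`,
#'     `E = d_full - D(Ind+Pop)`;
#'   \item pairwise shared: `IP = d_full - D(Env) - I - P`,
#'     `IE = d_full - D(Pop) - I - E`, `PE = d_full - D(Ind) - P - E`;
#'   \item triple shared: `IPE = d_full - I - P - E - IP - IE - PE`.
#' }
#' The seven components sum to `d_full` by construction, and equal the unique
#' solution of the linear system that writes each fitted model's explained
#' deviance as the sum of the components it contains. Shared components may
#' legitimately be negative (suppression); they are reported as-is, never
#' clamped.
#'
#' @param d_ind,d_pop,d_env Explained-deviance fractions of the single-group
#'   models.
#' @param d_ind_pop,d_ind_env,d_pop_env Fractions of the pairwise models.
#' @param d_full Fraction of the full model.
#' @return A `tb_partition` object: tibble with one row per component
#'   (`I`, `P`, `E`, `IP`, `IE`, `PE`, `IPE`), columns `component`, `raw` and
#'   `standardized` (percent of `d_full`; `NA` with a warning when
#'   `d_full = 0`). The seven input deviances are kept in the `deviances`
#'   attribute.
#' @examples
#' partition_components(0.30, 0.20, 0.25, 0.40, 0.45, 0.35, 0.50)
#' @export
partition_components <- function(d_ind, d_pop, d_env, d_ind_pop, d_ind_env,
                                 d_pop_env, d_full) {
  vals <- c(d_ind, d_pop, d_env, d_ind_pop, d_ind_env, d_pop_env, d_full)
  if (length(vals) != 7 || any(!is.finite(vals))) {
    stop_tb("All seven explained-deviance values must be supplied and finite.",
            "tb_validation_error")
  }
  I <- d_full - d_pop_env
  P <- d_full - d_ind_env
  E <- d_full - d_ind_pop
  IP <- d_full - d_env - I - P
  IE <- d_full - d_pop - I - E
  PE <- d_full - d_ind - P - E
  IPE <- d_full - I - P - E - IP - IE - PE
  raw <- c(I = I, P = P, E = E, IP = IP, IE = IE, PE = PE, IPE = IPE)
  if (abs(d_full) < 1e-15) {
    warn("Full-model explained deviance is zero; standardized components are NA.")
    std <- rep(NA_real_, 7)
  } else {
    std <- 100 * raw / d_full
  }
  out <- tibble(component = names(raw), raw = unname(raw),
                standardized = unname(std))
  structure(out,
            deviances = c(ind = d_ind, pop = d_pop, env = d_env,
                          ind_pop = d_ind_pop, ind_env = d_ind_env,
                          pop_env = d_pop_env, full = d_full),
            class = c("tb_partition", class(out)))
}

#' Partition a model's explained deviance across factor groups
#'
#' Fits the seven models implied by the three factor groups (Ind, Pop, Env)
#' restricted to the supplied final predictor set, computes each model's
#' explained-deviance fraction \eqn{1 - D_{res}/D_{null}}, and decomposes the
#' full model's fraction into pure and shared components with
#' [partition_components()].
#'
#' By default \eqn{\theta} is fixed at the full model's estimate for every
#' partial model, so deviance fractions are measured at a common dispersion
#' and are directly comparable; `refit_theta = TRUE` re-estimates
#' \eqn{\theta} per partial model instead.
#'
#' A factor group with no predictors in `predictors` yields structurally zero
#' components for its intersections (with a warning); at least two groups
#' must be represented.
#'
#' @inheritParams fit_nb
#' @param predictors Character vector: the final model's predictors.
#' @param grouping Named character vector mapping predictors to
#'   `"Ind"`/`"Pop"`/`"Env"`; defaults to the `grouping` attribute of `data`
#'   (as set by [build_design()]) or [default_grouping()].
#' @param refit_theta Re-estimate theta per partial model? Default `FALSE`.
#' @return A `tb_partition` object (see [partition_components()]); the
#'   `fits_explained` attribute carries the seven explained-deviance
#'   fractions and `theta` the dispersion used.
#' @export
partition_deviance <- function(data, predictors, grouping = NULL,
                               response = "tick_count", refit_theta = FALSE) {
  data <- as_tibble(data)
  if (is.null(grouping)) grouping <- attr(data, "grouping")
  if (is.null(grouping)) grouping <- default_grouping()
  miss <- setdiff(predictors, names(grouping))
  if (length(miss)) {
    stop_tb(paste0("Predictor(s) missing from `grouping`: ",
                   paste(miss, collapse = ", ")), "tb_config_error")
  }
  groups <- list(
    Ind = predictors[grouping[predictors] == "Ind"],
    Pop = predictors[grouping[predictors] == "Pop"],
    Env = predictors[grouping[predictors] == "Env"]
  )
  present <- names(groups)[lengths(groups) > 0]
  if (length(present) < 2) {
    stop_tb("Partitioning needs predictors from at least two factor groups.",
            "tb_validation_error")
  }
  if (length(present) < 3) {
    warn(paste0("Factor group(s) with no predictors in the final model: ",
                paste(setdiff(names(groups), present), collapse = ", "),
                "; their components are structurally zero."))
  }

  full <- fit_nb(data, predictors, response = response)
  theta_use <- if (refit_theta) NULL else full$theta

  expl <- function(terms, label) {
    if (length(terms) == 0) return(0)
    ft <- tryCatch(
      suppressWarnings(
        fit_nb(data, terms, response = response, theta = theta_use)
      ),
      error = function(e) {
        stop_tb(sprintf("Partial model '%s' failed to fit: %s", label,
                        conditionMessage(e)), "tb_partition_error")
      }
    )
    ft$explained_deviance
  }

  d <- c(
    ind = expl(groups$Ind, "Ind"),
    pop = expl(groups$Pop, "Pop"),
    env = expl(groups$Env, "Env"),
    ind_pop = expl(c(groups$Ind, groups$Pop), "Ind+Pop"),
    ind_env = expl(c(groups$Ind, groups$Env), "Ind+Env"),
    pop_env = expl(c(groups$Pop, groups$Env), "Pop+Env"),
    full = full$explained_deviance
  )
  # empty pairwise groups collapse to the non-empty member
  if (length(groups$Ind) == 0) {
    d[["ind_pop"]] <- d[["pop"]]; d[["ind_env"]] <- d[["env"]]
  }
  if (length(groups$Pop) == 0) {
    d[["ind_pop"]] <- d[["ind"]]; d[["pop_env"]] <- d[["env"]]
  }
  if (length(groups$Env) == 0) {
    d[["ind_env"]] <- d[["ind"]]; d[["pop_env"]] <- d[["pop"]]
  }

  out <- partition_components(d[["ind"]], d[["pop"]], d[["env"]],
                              d[["ind_pop"]], d[["ind_env"]], d[["pop_env"]],
                              d[["full"]])
  attr(out, "fits_explained") <- d
  attr(out, "theta") <- full$theta
  attr(out, "groups") <- groups
  out
}

#' @export
print.tb_partition <- function(x, ...) {
  cat("Deviance partition (pure and shared components)\n")
  d <- attr(x, "deviances")
  cat(sprintf("  full-model explained deviance: %.4f\n", d[["full"]]))
  NextMethod()
  invisible(x)
}

#' @export
tidy.tb_partition <- function(x, ...) as_tibble(x)

#' Bar chart of deviance-partition components
#'
#' @param object A `tb_partition` object.
#' @param ... Unused.
#' @return A ggplot object: standardized component shares (% of the full
#'   model's explained deviance).
#' @export
autoplot.tb_partition <- function(object, ...) {
  df <- as_tibble(object)
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$standardized)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Share of explained deviance (%)",
                  title = "Pure and shared deviance components") +
    ggplot2::theme_minimal()
}
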