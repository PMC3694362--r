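#' Default candidate predictors for burden models
#'
#' @param include_sex Include the female indicator (for models pooling both
#'   sexes)? Default `FALSE`.
#' @return Character vector of predictor columns of [build_design()].
#' @export
default_candidates <- function(include_sex = FALSE) {
  out <- c("total_length", "age_class", "kfi", "year", "avt_m", "ap_m",
           "aet_m", "deer_c", "deer_c_lag1", "deer_c_lag2", "boar_c",
           "boar_c_lag1", "boar_c_lag2")
  if (include_sex) c(out, "sex_female") else out
}

stage_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
}

#' Run the full tick-burden analysis pipeline
#'
#' Orchestrates, deterministically under `seed`: cohort simulation (or
#' loading of supplied tables), covariate construction, three stepwise-
#' selected NB models (males, females, combined with a sex factor), VIF
#' diagnostics, deviance partitioning of each final model, cross-sex and
#' split-sample calibration validation, descriptive tables, and a run
#' manifest. All artifacts are written to `out_dir` as RFC-4180 CSV and JSON.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer run seed; all stage streams derive from it.
#' @param sim A [sim_config()] for simulate mode, or `NULL` when supplying
#'   `hosts`/`meteo`/`census`.
#' @param hosts,meteo,census Data frames (or CSV paths) used when
#'   `sim = NULL`.
#' @param candidates Candidate predictors for the per-sex models; the
#'   combined model adds `sex_female`.
#' @param grouping Factor grouping for partitioning, default
#'   [default_grouping()].
#' @param stepwise Use stepwise AIC selection (`TRUE`, default) or fit the
#'   full candidate set directly. Note the default candidate set contains
#'   all census lags plus year, which are jointly collinear over a short
#'   study (one value per year); `stepwise = FALSE` therefore needs a
#'   reduced, full-rank candidate set.
#' @param n_bins Calibration bins, default 10.
#' @param train_fraction Training fraction of the combined-model split,
#'   default 0.70.
#' @return Invisibly, a list with the three fits, partitions, calibration
#'   tables, descriptive tables and the manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                         hosts = NULL, meteo = NULL, census = NULL,
                         candidates = default_candidates(),
                         grouping = default_grouping(), stepwise = TRUE,
                         n_bins = 10, train_fraction = 0.70) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_tb(sprintf("Pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), "tb_pipeline_error")
    })
  }

  # -- data ------------------------------------------------------------
  if (!is.null(sim)) {
    env <- stage("simulate", simulate_environment(sim, seed = stage_seed(seed, 1)))
    hosts <- stage("simulate",
                   simulate_cohort(sim, env, seed = stage_seed(seed, 2)))
    meteo <- env$meteo
    census <- env$census
    readr::write_csv(hosts, file.path(out_dir, "hosts.csv"))
    readr::write_csv(meteo, file.path(out_dir, "meteo_daily.csv"))
    readr::write_csv(census, file.path(out_dir, "census.csv"))
    jsonlite::write_json(
      list(beta_male = as.list(sim$beta_male),
           beta_female = as.list(sim$beta_female),
           dispersion_k = sim$dispersion_k, seed = seed),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    read_maybe <- function(x) if (is.character(x))
      readr::read_csv(x, show_col_types = FALSE) else as_tibble(x)
    hosts <- read_maybe(hosts); meteo <- read_maybe(meteo)
    census <- read_maybe(census)
  }

  design <- stage("covariates",
                  build_design(hosts, meteo, census, grouping = grouping))
  readr::write_csv(as_tibble(design), file.path(out_dir, "design.csv"))
  jsonlite::write_json(as.list(attr(design, "grouping")),
                       file.path(out_dir, "grouping.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  datasets <- list(
    males = filter(design, .data$sex == "male"),
    females = filter(design, .data$sex == "female"),
    combined = design
  )
  cand <- list(
    males = candidates,
    females = candidates,
    combined = unique(c(candidates, "sex_female"))
  )

  # -- fits ------------------------------------------------------------
  fits <- purrr::imap(datasets, function(d, nm) {
    stage(paste0("fit_", nm), {
      if (stepwise) stepwise_nb(d, cand[[nm]]) else fit_nb(d, cand[[nm]])
    })
  })
  vifs <- purrr::imap(fits, function(f, nm) {
    if (length(f$predictors) >= 2) {
      stage(paste0("vif_", nm), vif(datasets[[nm]], f$predictors))
    } else {
      tibble(predictor = f$predictors, vif = NA_real_)
    }
  })
  for (nm in names(fits)) {
    write_fit_artifacts(fits[[nm]], vifs[[nm]], out_dir, nm)
  }

  # -- partitions -------------------------------------------------------
  partitions <- purrr::imap(fits, function(f, nm) {
    stage(paste0("partition_", nm), {
      grp <- grouping
      suppressWarnings(
        partition_deviance(datasets[[nm]], f$predictors, grouping = grp)
      )
    })
  })
  for (nm in names(partitions)) {
    write_partition_artifacts(partitions[[nm]], out_dir, nm)
  }

  # -- cross-validation -------------------------------------------------
  calib <- list()
  calib$male_model_on_females <- stage("crossval",
    cross_apply(fits$males, datasets$females, n_bins = n_bins))
  calib$female_model_on_males <- stage("crossval",
    cross_apply(fits$females, datasets$males, n_bins = n_bins))
  split <- stage("crossval",
    split_train_validate(design, train_fraction = train_fraction,
                         seed = stage_seed(seed, 3)))
  comb_train <- stage("crossval", {
    if (stepwise) stepwise_nb(split$train, cand$combined)
    else fit_nb(split$train, cand$combined)
  })
  calib$combined_holdout <- stage("crossval",
    cross_apply(comb_train, split$validate, n_bins = n_bins))
  for (nm in names(calib)) {
    readr::write_csv(as_tibble(calib[[nm]]),
                     file.path(out_dir, paste0("calibration_", nm, ".csv")))
    jsonlite::write_json(attr(calib[[nm]], "metrics"),
                         file.path(out_dir, paste0("metrics_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # -- descriptives -----------------------------------------------------
  summaries <- stage("descriptives", list(
    by_sex_age = summarize_burdens(hosts, by = c("sex", "age_class")),
    by_year_season = summarize_burdens(hosts, by = c("year", "season"))
  ))
  readr::write_csv(summaries$by_sex_age,
                   file.path(out_dir, "summaries_by_sex_age.csv"))
  readr::write_csv(summaries$by_year_season,
                   file.path(out_dir, "summaries_by_year_season.csv"))
  prev <- stage("descriptives",
                prevalence_ci(sum(hosts$tick_count > 0), nrow(hosts)))
  jsonlite::write_json(as.list(prev), file.path(out_dir, "prevalence.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- manifest ---------------------------------------------------------
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(list(sim = unclass(sim), candidates = candidates,
                                   grouping = grouping, stepwise = stepwise,
                                   n_bins = n_bins,
                                   train_fraction = train_fraction)),
    package_version = as.character(utils::packageVersion("tickburden")),
    n_hosts = nrow(hosts),
    fits = names(fits), partitions = names(partitions),
    calibrations = names(calib)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(fits = fits, vifs = vifs, partitions = partitions,
                 calibrations = calib, summaries = summaries,
                 prevalence = prev, manifest = manifest, design = design))
}

signif_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
    p < 0.1 ~ "#", TRUE ~ "ns"
  )
}

write_fit_artifacts <- function(fit, vif_tab, out_dir, name) {
  td <- tidy(fit)
  jsonlite::write_json(
    list(coefficients = as.list(setNames(td$estimate, td$term)),
         se = as.list(setNames(td$std.error, td$term)),
         z = as.list(setNames(td$statistic, td$term)),
         p = as.list(setNames(td$p.value, td$term)),
         theta = fit$theta, aic = fit$aic, loglik = fit$loglik,
         deviance = fit$deviance, null_deviance = fit$null_deviance,
         explained_deviance = fit$explained_deviance, n = fit$n,
         status = fit$status),
    file.path(out_dir, paste0("fit_", name, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # plain-text coefficient table: coefficient/test-value and stars
  lines <- c(
    sprintf("NB model (%s): explained deviance %.2f%%, theta %.3f, AIC %.1f",
            name, 100 * fit$explained_deviance, fit$theta, fit$aic),
    "predictor\tcoefficient/test-value\tsignificance",
    sprintf("%s\t%.4f/%.2f\t%s", td$term, td$estimate, td$statistic,
            signif_stars(td$p.value))
  )
  writeLines(lines, file.path(out_dir, paste0("fit_", name, ".txt")))
  readr::write_csv(vif_tab, file.path(out_dir, paste0("vif_", name, ".csv")))
}

write_partition_artifacts <- function(part, out_dir, name) {
  d <- attr(part, "fits_explained")
  tab <- as_tibble(part)
  jsonlite::write_json(
    list(model_explained_deviance = as.list(d),
         components_raw = as.list(setNames(tab$raw, tab$component)),
         components_standardized = as.list(setNames(tab$standardized,
                                                    tab$component))),
    file.path(out_dir, paste0("partition_", name, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  g <- function(comp) tab$standardized[tab$component == comp]
  lines <- c(
    sprintf("Deviance partition (%s), %% of full-model explained deviance:",
            name),
    sprintf("  pure Ind %6.1f   pure Pop %6.1f   pure Env %6.1f",
            g("I"), g("P"), g("E")),
    sprintf("  Ind&Pop  %6.1f   Ind&Env  %6.1f   Pop&Env  %6.1f",
            g("IP"), g("IE"), g("PE")),
    sprintf("  Ind&Pop&Env %6.1f", g("IPE")),
    sprintf("  full-model explained deviance: %.4f", d[["full"]])
  )
  writeLines(lines, file.path(out_dir, paste0("partition_", name, ".txt")))
}
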