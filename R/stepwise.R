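#' Forward-backward stepwise AIC selection for NB models
#'
#' Starting from the intercept-only model, repeatedly evaluates every
#' single-predictor addition and deletion, applies the move with the lowest
#' AIC provided it is strictly lower than the current AIC, and stops when no
#' move improves. Ties are broken by fewer model terms, then lexicographically
#' by predictor name. \eqn{\theta} is re-estimated for every candidate model,
#' and AIC counts it as a parameter, so model sizes are compared consistently.
#'
#' Candidate fits that fail (e.g. numerically singular subsets) are skipped
#' and recorded in the trace rather than aborting the search.
#'
#' @inheritParams fit_nb
#' @param candidates Character vector of candidate predictor columns.
#' @return The selected [fit_nb()] object, with a `trace` element: a tibble
#'   of the moves evaluated and applied (`step`, `move`, `term`, `aic`,
#'   `applied`, `note`).
#' @export
stepwise_nb <- function(data, candidates, response = "tick_count") {
  data <- as_tibble(data)
  current <- fit_nb(data, character(), response = response)
  if (current$status == "degenerate_all_zero") {
    stop_tb("Null model is degenerate (all-zero response).",
            "tb_validation_error")
  }
  selected <- character()
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    adds <- setdiff(candidates, selected)
    drops <- selected
    moves <- tibble(
      move = c(rep("add", length(adds)), rep("drop", length(drops))),
      term = c(adds, drops)
    )
    if (nrow(moves) == 0) break
    evals <- purrr::pmap(moves, function(move, term) {
      terms_new <- if (move == "add") c(selected, term)
        else setdiff(selected, term)
      ft <- tryCatch(
        suppressWarnings(fit_nb(data, terms_new, response = response)),
        error = function(e) NULL
      )
      if (is.null(ft) || !ft$converged) {
        list(aic = NA_real_, nterms = length(terms_new), fit = NULL,
             note = if (is.null(ft)) "fit_failed" else ft$status)
      } else {
        list(aic = ft$aic, nterms = length(terms_new), fit = ft, note = "")
      }
    })
    moves$aic <- purrr::map_dbl(evals, "aic")
    moves$nterms <- purrr::map_int(evals, ~ as.integer(.x$nterms))
    moves$note <- purrr::map_chr(evals, "note")
    moves$step <- step
    ok <- which(!is.na(moves$aic))
    if (length(ok) == 0) break
    ord <- ok[order(moves$aic[ok], moves$nterms[ok], moves$term[ok])]
    best <- ord[1]
    moves$applied <- FALSE
    if (moves$aic[best] < current$aic - 1e-8) {
      moves$applied[best] <- TRUE
      current <- evals[[best]]$fit
      selected <- if (moves$move[best] == "add") {
        c(selected, moves$term[best])
      } else {
        setdiff(selected, moves$term[best])
      }
      trace[[step]] <- moves
    } else {
      trace[[step]] <- moves
      break
    }
  }
  empty_trace <- tibble(step = integer(), move = character(),
                        term = character(), aic = numeric(),
                        nterms = integer(), applied = logical(),
                        note = character())
  current$trace <- dplyr::bind_rows(empty_trace, dplyr::bind_rows(trace)) %>%
    select(all_of(names(empty_trace)))
  current
}
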