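#' Screen growth on sole carbon or nitrogen sources
#'
#' For each substrate: start from the base medium, close the default source
#' of the substrate's role (e.g. glucose when testing alternative carbon
#' sources; when testing nitrogen sources the carbon source stays open),
#' open the substrate's uptake, run FBA and call growth if the optimum
#' exceeds `threshold`. A substrate whose exchange reaction is absent from
#' the model is reported as no-growth with the note
#' `"no transporter/exchange"` — the in-silico signature of a missing
#' assimilation route.
#'
#' @param model a `gem`.
#' @param medium_base a `medium` defining the non-varied components.
#' @param substrates tibble with columns `exchange`, `role` (`"carbon"` or
#'   `"nitrogen"`), optionally `observed` (`"growth"`, `"no-growth"`,
#'   `"unknown"`).
#' @param default_sources named character vector role -> exchange id of the
#'   default source to close when varying that role.
#' @param uptake_bound uptake allowance for the tested substrate
#'   (mmol/gDW/h).
#' @param threshold growth-call threshold (1/h).
#' @return A tibble of class `phenotype_screen` with columns `substrate`,
#'   `role`, `predicted_growth`, `call`, `observed`, `agreement`, `note`.
#' @export
sole_source_screen <- function(model, medium_base, substrates,
                               default_sources = character(),
                               uptake_bound = 10, threshold = 1e-4) {
  substrates <- tibble::as_tibble(substrates)
  if (!"observed" %in% names(substrates)) substrates$observed <- "unknown"
  rows <- purrr::map(seq_len(nrow(substrates)), function(i) {
    ex <- substrates$exchange[i]; role <- substrates$role[i]
    m <- apply_medium(model, medium_base)
    default_ex <- default_sources[role]
    if (!is.na(default_ex) && default_ex %in% m$reactions$id && default_ex != ex)
      m <- set_bounds(m, default_ex, lower = 0)
    if (!ex %in% m$reactions$id) {
      pred <- 0; note <- "no transporter/exchange"
    } else {
      m <- set_bounds(m, ex, lower = -uptake_bound)
      sol <- solve_fba(m)
      pred <- if (sol$status == "optimal") sol$objective else 0
      note <- if (sol$status == "optimal") NA_character_ else sol$status
    }
    call <- if (pred > threshold) "growth" else "no-growth"
    obs <- substrates$observed[i]
    tibble::tibble(substrate = ex, role = role, predicted_growth = pred,
                   call = call, observed = obs,
                   agreement = if (obs %in% c("growth", "no-growth")) call == obs else NA,
                   note = note)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phenotype_screen", class(out))
  out
}

#' Predict the growth rate at a measured uptake rate
#'
#' Fixes the substrate exchange to exactly the measured uptake
#' (lower = upper = -uptake) and maximises growth. An infeasible model (e.g.
#' maintenance unsatisfiable at that uptake) yields 0 with a warning.
#'
#' @param model a `gem`.
#' @param exchange substrate exchange reaction id.
#' @param uptake measured uptake rate, positive (mmol/gDW/h).
#' @param objective objective reaction id.
#' @return Predicted growth rate (1/h).
#' @export
predict_growth_at_uptake <- function(model, exchange, uptake,
                                     objective = model$objective) {
  stopifnot(uptake >= 0)
  model <- set_bounds(model, exchange, lower = -uptake, upper = -uptake)
  sol <- solve_fba(model, objective)
  if (sol$status != "optimal") {
    warning("growth LP ", sol$status, " at uptake ", uptake, " for ", exchange)
    return(0)
  }
  sol$objective
}

#' Predicted vs observed growth rates over a substrate panel
#'
#' @param model a `gem`.
#' @param panel tibble with columns `substrate` (exchange id), `uptake`
#'   (mmol/gDW/h) and `observed_mu` (1/h).
#' @return A tibble of class `rate_prediction` with columns `substrate`,
#'   `uptake_rate`, `predicted_mu`, `observed_mu`.
#' @export
rate_predictions <- function(model, panel) {
  panel <- tibble::as_tibble(panel)
  pred <- vapply(seq_len(nrow(panel)), function(i)
    predict_growth_at_uptake(model, panel$substrate[i], panel$uptake[i]),
    numeric(1))
  out <- tibble::tibble(substrate = panel$substrate,
                        uptake_rate = panel$uptake,
                        predicted_mu = pred,
                        observed_mu = panel$observed_mu)
  class(out) <- c("rate_prediction", class(out))
  out
}

#' Correlation between observed and predicted growth rates
#'
#' Pearson correlation over the (observed, predicted) pairs, its square, and
#' per-point residuals (predicted - observed). With fewer than 3 points or
#' zero variance in either vector the correlation is undefined and reported
#' as `NA`.
#'
#' @param preds a `rate_prediction` tibble (columns `observed_mu`,
#'   `predicted_mu`; other columns are carried into the residual table).
#' @return A list of class `correlation_report` with `pearson_r`,
#'   `r_squared`, `n`, and `residuals` (tibble).
#' @export
correlation_report <- function(preds) {
  obs <- preds$observed_mu; pred <- preds$predicted_mu
  n <- length(obs)
  r <- if (n < 3 || stats::sd(obs) == 0 || stats::sd(pred) == 0) NA_real_
       else stats::cor(obs, pred)
  res <- tibble::as_tibble(preds)
  res$residual <- pred - obs
  structure(list(pearson_r = r,
                 r_squared = if (is.na(r)) NA_real_ else r^2,
                 n = n, residuals = res),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> n = %d, r = %s, r^2 = %s\n", x$n,
              format(x$pearson_r, digits = 4), format(x$r_squared, digits = 4)))
  invisible(x)
}
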