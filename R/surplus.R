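#' Surplus production capacity of a biomass component at fixed growth
#'
#' Measures how much of a biomass precursor the cell could still synthesise
#' beyond the demand of growing at a fixed fraction of its optimum: solve
#' for the maximal growth rate, fix the biomass reaction's lower AND upper
#' bound to `fraction * mu_max` (fixing both matters — a lower bound alone
#' would let precursor secretion trade against extra growth), add a demand
#' reaction for the component, and maximise that demand.
#'
#' In a model where an auxotrophy for the measured component has been
#' rescued by medium uptake (see [rescue_auxotrophies()]), the rescue influx
#' of that component is subtracted from the demand in the objective, so the
#' reported value is the net de-novo synthesis capacity: a condition that
#' can only obtain the compound from the medium has surplus 0 (negative net
#' values are clamped to 0).
#'
#' @param model a `gem` (or `condition_model`).
#' @param component metabolite id.
#' @param fraction fraction of the growth optimum to fix, in \[0, 1\];
#'   0 disables growth and returns plain producibility.
#' @param objective biomass reaction id.
#' @return Maximal surplus production flux (mmol/gDW/h).
#' @export
surplus_capacity <- function(model, component, fraction = 0.9,
                             objective = NULL) {
  if (inherits(model, "condition_model")) model <- model$model
  stopifnot(fraction >= 0, fraction <= 1)
  objective <- objective %||% model$objective
  sol <- solve_fba(model, objective)
  if (sol$status != "optimal" || sol$objective <= 1e-9)
    stop("no growth, surplus undefined (status ", sol$status,
         ", mu_max ", format(sol$objective), ")")
  mu_fix <- fraction * sol$objective
  model <- set_bounds(model, objective, lower = mu_fix, upper = mu_fix)
  dm <- add_demand(model, component)
  model <- dm$model
  rxn <- model$reactions
  cvec <- as.numeric(rxn$id == dm$reaction)
  rescue_tr <- paste0("T_rescue_", component)
  if (rescue_tr %in% rxn$id) cvec[rxn$id == rescue_tr] <- -1
  out <- lp_solve(cvec, stoich_matrix(model), rep(0, nrow(model$metabolites)),
                  rxn$lower_bound, rxn$upper_bound, maximize = TRUE)
  if (out$status != "optimal")
    stop("surplus LP not optimal for ", component, ": ", out$status)
  max(out$objective, 0)
}

#' Surplus capacities across conditions, absolute and relative
#'
#' Applies [surplus_capacity()] to every (condition, component) pair and
#' normalises per component: 100% is the largest capacity over the
#' conditions; if all conditions have (numerically) zero capacity the
#' relative value is 0 for all. Per-cell failures (e.g. a condition that
#' cannot grow) are recorded as `NA` with the reason in `note`.
#'
#' @param models list of `condition_model`s (or `gem`s); names or condition
#'   labels identify the rows.
#' @param components metabolite ids.
#' @param fraction growth fraction to fix (default 0.9).
#' @return A tibble of class `surplus_table` with columns `condition`,
#'   `metabolite`, `absolute`, `relative`, `note`, and the fraction as
#'   attribute `growth_fraction`.
#' @export
surplus_table <- function(models, components, fraction = 0.9) {
  labels <- names(models) %||% rep(NA_character_, length(models))
  rows <- purrr::map2(models, seq_along(models), function(cm, i) {
    label <- if (inherits(cm, "condition_model") && !is.na(cm$condition))
      cm$condition else if (!is.na(labels[i]) && nzchar(labels[i])) labels[i]
      else paste0("model", i)
    purrr::map(components, function(met) {
      val <- tryCatch(surplus_capacity(cm, met, fraction),
                      error = function(e) conditionMessage(e))
      if (is.character(val))
        tibble::tibble(condition = label, metabolite = met,
                       absolute = NA_real_, note = val)
      else
        tibble::tibble(condition = label, metabolite = met,
                       absolute = val, note = NA_character_)
    }) |> dplyr::bind_rows()
  })
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::mutate(
    dplyr::group_by(tab, .data$metabolite),
    relative = {
      mx <- max(abs(.data$absolute), na.rm = TRUE)
      if (!is.finite(mx) || mx <= 1e-9) ifelse(is.na(.data$absolute), NA_real_, 0)
      else 100 * .data$absolute / mx
    }) |> dplyr::ungroup()
  tab <- tab[c("condition", "metabolite", "absolute", "relative", "note")]
  class(tab) <- c("surplus_table", class(tab))
  attr(tab, "growth_fraction") <- fraction
  tab
}
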