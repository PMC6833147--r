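#' Flux balance analysis
#'
#' Solves the FBA linear program \eqn{\max v_{obj}} subject to steady-state
#' mass balance \eqn{S v = 0} and the flux bounds, using the package's
#' bounded-variable simplex. The returned solution carries the duals: shadow
#' prices per metabolite (marginal objective value of relaxing a mass-balance
#' row) and reduced costs per reaction, with the convention that a reaction's
#' reduced cost is \eqn{\partial(\mathrm{objective})/\partial(\mathrm{bound})}
#' at its binding bound (0 for interior fluxes). A growth limited by the
#' availability of some substrate therefore shows up as the largest-magnitude
#' reduced cost on that substrate's uptake exchange.
#'
#' Infeasibility and unboundedness are reported in `status`, never as errors.
#'
#' @param model a `gem`.
#' @param objective reaction id to optimise; defaults to the model objective.
#' @param direction `"max"` (default) or `"min"`.
#' @return A `flux_solution`: list with `status`, `objective`, `fluxes`,
#'   `reduced_costs` (named per reaction), `shadow_prices` (named per
#'   metabolite), `objective_reaction`, `direction`.
#' @examples
#' solve_fba(toy_model("TOY1"))
#' @export
solve_fba <- function(model, objective = model$objective, direction = c("max", "min")) {
  direction <- match.arg(direction)
  rxn <- model$reactions
  if (is.na(objective) || !objective %in% rxn$id)
    stop("objective reaction not in model: ", objective)
  S <- stoich_matrix(model)
  cvec <- as.numeric(rxn$id == objective)
  sol <- lp_solve(cvec, S, rep(0, nrow(S)), rxn$lower_bound, rxn$upper_bound,
                  maximize = direction == "max")
  structure(list(
    status = sol$status,
    objective = if (sol$status == "optimal") sol$objective else NA_real_,
    fluxes = stats::setNames(sol$x, rxn$id),
    reduced_costs = stats::setNames(sol$reduced_costs, rxn$id),
    shadow_prices = stats::setNames(sol$duals, rownames(S)),
    objective_reaction = objective,
    direction = direction), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s %s of %s", x$status, x$direction, x$objective_reaction))
  if (x$status == "optimal") cat(sprintf(": %.6g", x$objective))
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimises and maximises its flux subject to
#' the model constraints plus \eqn{v_{obj} \ge f \cdot \mu_{max}}, where
#' \eqn{f} is `growth_fraction` and \eqn{\mu_{max}} the FBA optimum. At
#' `growth_fraction = 0` the objective constraint is void and the ranges
#' describe the whole flux cone.
#'
#' @param model a `gem`.
#' @param reactions reaction ids (default: all).
#' @param growth_fraction fraction of the optimum to enforce, in \[0, 1\].
#' @param objective objective reaction id.
#' @return Tibble with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, reactions = model$reactions$id,
                             growth_fraction = 0, objective = model$objective) {
  stopifnot(growth_fraction >= 0, growth_fraction <= 1)
  base <- solve_fba(model, objective)
  if (base$status != "optimal")
    stop("FVA requires an optimal base solution; status was ", base$status)
  idx <- match(objective, model$reactions$id)
  floor_mu <- growth_fraction * base$objective
  model$reactions$lower_bound[idx] <- max(model$reactions$lower_bound[idx], floor_mu)
  rxn <- model$reactions
  S <- stoich_matrix(model)
  b0 <- rep(0, nrow(S))
  res <- purrr::map(reactions, function(r) {
    cvec <- as.numeric(rxn$id == r)
    lo <- lp_solve(cvec, S, b0, rxn$lower_bound, rxn$upper_bound, maximize = FALSE)
    hi <- lp_solve(cvec, S, b0, rxn$lower_bound, rxn$upper_bound, maximize = TRUE)
    tibble::tibble(reaction = r,
                   min = if (lo$status == "optimal") lo$objective else
                         if (lo$status == "unbounded") -Inf else NA_real_,
                   max = if (hi$status == "optimal") hi$objective else
                         if (hi$status == "unbounded") Inf else NA_real_)
  })
  dplyr::bind_rows(res)
}

#' Reactions forced to zero flux at a growth fraction
#'
#' A reaction is zero-flux when its FVA minimum and maximum are both zero
#' (within `tol`) at the given growth fraction, i.e. the whole feasible space
#' pins it to zero — a stricter and degeneracy-proof alternative to "zero in
#' one particular FBA solution".
#'
#' @param model a `gem`.
#' @param growth_fraction fraction of the optimum to enforce.
#' @param objective objective reaction id.
#' @param tol flux-zero tolerance (mmol/gDW/h).
#' @return Character vector of reaction ids.
#' @export
zero_flux_reactions <- function(model, growth_fraction = 0,
                                objective = model$objective, tol = 1e-6) {
  fva <- flux_variability(model, growth_fraction = growth_fraction,
                          objective = objective)
  sort(fva$reaction[!is.na(fva$min) & !is.na(fva$max) &
                    abs(fva$min) <= tol & abs(fva$max) <= tol])
}

#' Add a demand (sink) reaction for a metabolite
#'
#' Adds an irreversible reaction `met ->` with bounds \[0, 1000\] and id
#' `DM_<met>`, used to measure a metabolite's maximal production. Adding a
#' demand that already exists returns the existing id without duplicating.
#'
#' @param model a `gem`.
#' @param metabolite metabolite id.
#' @return List with `model` (new model) and `reaction` (demand reaction id).
#' @export
add_demand <- function(model, metabolite) {
  if (!metabolite %in% model$metabolites$id)
    stop("unknown metabolite: ", metabolite)
  dm_id <- paste0("DM_", metabolite)
  if (dm_id %in% model$reactions$id)
    return(list(model = model, reaction = dm_id))
  model <- add_reaction(model, dm_id,
                        stats::setNames(-1, metabolite),
                        lower = 0, upper = 1000,
                        name = paste("demand for", metabolite))
  list(model = model, reaction = dm_id)
}

#' Maximal production flux of a metabolite
#'
#' Maximises the flux of a demand reaction for the metabolite. A value above
#' `tol` means the metabolite is producible from the current medium.
#'
#' @param model a `gem`.
#' @param metabolite metabolite id.
#' @return Maximal production flux (mmol/gDW/h); `NA_real_` when the model
#'   itself is infeasible.
#' @export
producibility <- function(model, metabolite) {
  dm <- add_demand(model, metabolite)
  sol <- solve_fba(dm$model, objective = dm$reaction)
  if (sol$status == "unbounded") return(Inf)
  if (sol$status != "optimal") return(NA_real_)
  sol$objective
}

#' Compare a reduced cost against an empirical finite-difference slope
#'
#' Identifies the bound at which the exchange flux is binding at the optimum,
#' perturbs that bound by `delta`, re-solves, and reports both the solver's
#' reduced cost and the empirical slope
#' \eqn{(\mathrm{obj}(b+\delta) - \mathrm{obj}(b)) / \delta}. For small
#' `delta` within the same optimal basis the two agree; a large `delta` that
#' changes the basis makes the slope an average over bases and the two can
#' legitimately differ.
#'
#' @param model a `gem`.
#' @param objective objective reaction id.
#' @param exchange exchange (or any) reaction id whose bound to perturb.
#' @param delta bound perturbation (mmol/gDW/h).
#' @return Tibble with `reaction`, `bound` (`"lower"`/`"upper"`/`"interior"`),
#'   `reduced_cost`, `slope`.
#' @export
finite_difference_check <- function(model, objective = model$objective,
                                    exchange, delta = -1) {
  base <- solve_fba(model, objective)
  if (base$status != "optimal") stop("base solution not optimal: ", base$status)
  idx <- match(exchange, model$reactions$id)
  if (is.na(idx)) stop("unknown reaction: ", exchange)
  v <- base$fluxes[[exchange]]
  lb <- model$reactions$lower_bound[idx]; ub <- model$reactions$upper_bound[idx]
  tol <- 1e-7
  bound <- if (abs(v - lb) < tol) "lower" else if (abs(v - ub) < tol) "upper" else "interior"
  if (bound == "interior") {
    return(tibble::tibble(reaction = exchange, bound = bound,
                          reduced_cost = base$reduced_costs[[exchange]],
                          slope = 0))
  }
  if (bound == "lower") {
    model$reactions$lower_bound[idx] <- lb + delta
  } else {
    model$reactions$upper_bound[idx] <- ub + delta
  }
  pert <- solve_fba(model, objective)
  slope <- if (pert$status == "optimal") (pert$objective - base$objective) / delta else NA_real_
  tibble::tibble(reaction = exchange, bound = bound,
                 reduced_cost = base$reduced_costs[[exchange]],
                 slope = slope)
}
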