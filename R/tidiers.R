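#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flux solution into a per-reaction tibble
#'
#' @param x a `flux_solution`.
#' @param ... unused.
#' @return Tibble with `reaction`, `flux`, `reduced_cost`.
#' @export
tidy.flux_solution <- function(x, ...) {
  tibble::tibble(reaction = names(x$fluxes),
                 flux = unname(x$fluxes),
                 reduced_cost = unname(x$reduced_costs))
}

#' One-row summary of a flux solution
#'
#' @param x a `flux_solution`.
#' @param ... unused.
#' @return Tibble with `status`, `objective_reaction`, `direction`,
#'   `objective`.
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_reaction = x$objective_reaction,
                 direction = x$direction, objective = x$objective)
}

#' Tidy a condition model into its per-reaction deactivation status
#'
#' @param x a `condition_model`.
#' @param ... unused.
#' @return Tibble with `reaction`, `deactivated`.
#' @export
tidy.condition_model <- function(x, ...) {
  tibble::tibble(reaction = x$model$reactions$id,
                 deactivated = x$model$reactions$id %in% x$deactivated_reactions)
}

#' One-row summary of a condition model
#'
#' @param x a `condition_model`.
#' @param ... unused.
#' @return Tibble with `condition`, `n_inactive_genes`,
#'   `n_deactivated_reactions`, `n_rescued`.
#' @export
glance.condition_model <- function(x, ...) {
  tibble::tibble(condition = x$condition,
                 n_inactive_genes = length(x$inactive_genes),
                 n_deactivated_reactions = length(x$deactivated_reactions),
                 n_rescued = length(x$rescued_metabolites))
}

#' One-row summary of a correlation report
#'
#' @param x a `correlation_report`.
#' @param ... unused.
#' @return Tibble with `n`, `pearson_r`, `r_squared`.
#' @export
glance.correlation_report <- function(x, ...) {
  tibble::tibble(n = x$n, pearson_r = x$pearson_r, r_squared = x$r_squared)
}
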