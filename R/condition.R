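#' Derive a condition-specific model from inactive genes
#'
#' Deactivates (bounds to \[0, 0\]) every reaction whose GPR evaluates to
#' `FALSE` given the inactive gene set, leaving all other constraints
#' intact. Reactions without a GPR are never deactivated. Gene ids not in
#' the model are ignored.
#'
#' @param model a `gem`.
#' @param inactive character vector of inactive gene ids.
#' @param condition optional condition label.
#' @return A `condition_model`: list with `model` (the constrained `gem`),
#'   `base_model_id`, `condition`, `inactive_genes`,
#'   `deactivated_reactions`, `rescued_metabolites`.
#' @export
derive_condition_model <- function(model, inactive, condition = NA_character_) {
  inactive <- intersect(inactive, model$genes)
  rxn <- model$reactions
  dead <- character()
  for (i in seq_len(nrow(rxn))) {
    if (is.na(rxn$gpr[i])) next
    if (!evaluate_gpr(parse_gpr(rxn$gpr[i]), inactive)) dead <- c(dead, rxn$id[i])
  }
  if (length(dead)) model <- set_bounds(model, dead, lower = 0, upper = 0)
  structure(list(model = model,
                 base_model_id = model$id,
                 condition = condition,
                 inactive_genes = sort(inactive),
                 deactivated_reactions = sort(dead),
                 rescued_metabolites = character()),
            class = "condition_model")
}

#' @export
print.condition_model <- function(x, ...) {
  cat(sprintf("<condition_model> %s (base %s): %d inactive gene(s), %d deactivated reaction(s), %d rescue(s)\n",
              x$condition, x$base_model_id, length(x$inactive_genes),
              length(x$deactivated_reactions), length(x$rescued_metabolites)))
  invisible(x)
}

#' Detect auxotrophies among biomass components
#'
#' A component is auxotrophic in a condition model when its maximal
#' production flux in the given medium is at most `tol` (or the model is
#' infeasible): the condition's gene inactivations have severed every
#' biosynthetic route.
#'
#' @param cm a `condition_model` (or plain `gem`).
#' @param components metabolite ids to test.
#' @param medium optional `medium` applied first.
#' @param tol producibility tolerance (mmol/gDW/h).
#' @return Sorted character vector of non-producible component ids.
#' @export
detect_auxotrophies <- function(cm, components, medium = NULL, tol = 1e-6) {
  model <- if (inherits(cm, "condition_model")) cm$model else cm
  if (!is.null(medium)) model <- apply_medium(model, medium)
  flag <- vapply(components, function(met) {
    p <- producibility(model, met)
    is.na(p) || p <= tol
  }, logical(1))
  sort(components[flag])
}

#' Rescue auxotrophies by allowing uptake from the medium
#'
#' For each auxotrophic metabolite, ensures (adding only what is missing) an
#' extracellular counterpart, an exchange reaction with uptake open, and a
#' spontaneous (GPR-free, so never expression-deactivated) transport reaction
#' into the metabolite's own compartment — modelling the assumption that the
#' compound is available in the rich medium. Rescuing an empty set is the
#' identity and the operation is idempotent.
#'
#' @param cm a `condition_model`.
#' @param aux metabolite ids to rescue.
#' @param uptake_bound maximal uptake rate for the rescued compounds.
#' @return The updated `condition_model` with `rescued_metabolites` extended.
#' @export
rescue_auxotrophies <- function(cm, aux, uptake_bound = 1000) {
  stopifnot(inherits(cm, "condition_model"))
  model <- cm$model
  roles <- compartment_roles(model)
  e_id <- roles[["extracellular"]] %||% stop("no extracellular compartment identified")
  for (met in aux) {
    if (!met %in% model$metabolites$id) stop("unknown metabolite: ", met)
    ext <- paste0(met, "_rescue_", e_id)
    ex_id <- paste0("EX_rescue_", met)
    tr_id <- paste0("T_rescue_", met)
    model <- add_metabolite(model, ext, e_id)
    if (!ex_id %in% model$reactions$id)
      model <- add_reaction(model, ex_id, stats::setNames(-1, ext),
                            lower = -uptake_bound, upper = 1000,
                            name = paste("rescue exchange for", met),
                            is_exchange = TRUE)
    if (!tr_id %in% model$reactions$id)
      model <- add_reaction(model, tr_id, stats::setNames(c(-1, 1), c(ext, met)),
                            lower = 0, upper = 1000,
                            name = paste("rescue transport for", met))
  }
  cm$model <- model
  cm$rescued_metabolites <- sort(union(cm$rescued_metabolites, aux))
  cm
}

#' Summary report over condition-specific models
#'
#' One row per condition: numbers of inactive genes, deactivated reactions
#' and zero-flux reactions (FVA at `growth_fraction`), the rescued
#' auxotrophies, the growth optimum, and the growth-limiting exchange — the
#' uptake exchange with the largest-magnitude reduced cost at the optimum.
#'
#' @param models list of `condition_model`s sharing a base model.
#' @param growth_fraction fraction for the zero-flux classification.
#' @return A tibble.
#' @export
condition_report <- function(models, growth_fraction = 0.9) {
  if (!length(models)) {
    return(tibble::tibble(condition = character(), n_inactive_genes = integer(),
                          n_deactivated_reactions = integer(),
                          n_zero_flux = integer(), auxotrophies = character(),
                          mu_max = numeric(), limiting_exchange = character(),
                          limiting_reduced_cost = numeric()))
  }
  base_ids <- unique(vapply(models, function(m) m$base_model_id, character(1)))
  if (length(base_ids) > 1) stop("condition models do not share a base model")
  rows <- purrr::map(models, function(cm) {
    sol <- solve_fba(cm$model)
    zf <- if (sol$status == "optimal" && sol$objective > 1e-9)
      length(zero_flux_reactions(cm$model, growth_fraction)) else NA_integer_
    lim_id <- NA_character_; lim_rc <- NA_real_
    if (sol$status == "optimal") {
      ex <- exchange_reactions(cm$model)
      rc <- sol$reduced_costs[ex]
      if (length(rc) && any(abs(rc) > 1e-9)) {
        lim_id <- ex[which.max(abs(rc))]
        lim_rc <- unname(rc[which.max(abs(rc))])
      }
    }
    tibble::tibble(condition = cm$condition,
                   n_inactive_genes = length(cm$inactive_genes),
                   n_deactivated_reactions = length(cm$deactivated_reactions),
                   n_zero_flux = zf,
                   auxotrophies = paste(cm$rescued_metabolites, collapse = ";"),
                   mu_max = sol$objective,
                   limiting_exchange = lim_id,
                   limiting_reduced_cost = lim_rc)
  })
  dplyr::bind_rows(rows)
}
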