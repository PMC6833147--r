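#' Construct a genome-scale metabolic model (GEM)
#'
#' The in-memory representation used throughout the package: a list of
#' tibbles describing compartments, metabolites, reactions and stoichiometry,
#' plus the gene list, the objective reaction and the maintenance parameters
#' (growth-associated maintenance GAM in mmol ATP/gDW, non-growth-associated
#' maintenance NGAM in mmol ATP/gDW/h, and the P/O ratio). Flux bounds are in
#' mmol/gDW/h; for exchange reactions negative flux is uptake and positive
#' flux secretion.
#'
#' @param id model identifier.
#' @param compartments tibble/data frame with columns `id`, `name`.
#' @param metabolites tibble with columns `id`, `name`, `compartment`,
#'   `formula` (Hill-notation string, `NA`/`""` = unknown), `charge`
#'   (integer, `NA` = unknown). Missing optional columns are filled.
#' @param reactions tibble with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr` (rule string, `NA` = no gene association),
#'   `subsystem`, `is_exchange`.
#' @param stoichiometry long tibble with columns `reaction`, `metabolite`,
#'   `coefficient` (negative = consumed).
#' @param genes character vector of gene ids.
#' @param objective id of the objective (typically biomass) reaction, or `NA`.
#' @param maintenance list with elements `gam`, `ngam`, `po_ratio` (numeric,
#'   `NA` = unset).
#' @param validate run [validate_gem()] (default `TRUE`).
#' @return An object of class `gem`.
#' @export
gem <- function(id, compartments, metabolites, reactions, stoichiometry,
                genes = character(), objective = NA_character_,
                maintenance = list(gam = NA_real_, ngam = NA_real_, po_ratio = NA_real_),
                validate = TRUE) {
  compartments <- tibble::as_tibble(compartments)
  metabolites <- fill_cols(tibble::as_tibble(metabolites),
                           name = NA_character_, formula = NA_character_,
                           charge = NA_integer_)
  reactions <- fill_cols(tibble::as_tibble(reactions),
                         name = NA_character_, gpr = NA_character_,
                         subsystem = NA_character_, is_exchange = FALSE)
  stoichiometry <- tibble::as_tibble(stoichiometry)
  # canonical forms so structurally equal models compare equal:
  # GPR strings rendered canonically, genes sorted, stoichiometry ordered
  reactions$gpr <- vapply(reactions$gpr,
                          function(g) render_gpr(parse_gpr(g)),
                          character(1), USE.NAMES = FALSE)
  genes <- sort(unique(as.character(genes)))
  stoichiometry <- stoichiometry[order(match(stoichiometry$reaction, reactions$id),
                                       stoichiometry$metabolite), ]
  m <- structure(
    list(id = id,
         compartments = compartments[c("id", "name")],
         metabolites = metabolites[c("id", "name", "compartment", "formula", "charge")],
         reactions = reactions[c("id", "name", "lower_bound", "upper_bound",
                                 "gpr", "subsystem", "is_exchange")],
         stoichiometry = stoichiometry[c("reaction", "metabolite", "coefficient")],
         genes = as.character(genes),
         objective = objective,
         maintenance = maintenance),
    class = "gem")
  if (validate) validate_gem(m)
  m
}

fill_cols <- function(df, ...) {
  defaults <- list(...)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  df
}

#' Validate a GEM's structural invariants
#'
#' Checks id uniqueness, referential integrity (compartments, metabolites,
#' GPR genes, objective), bound ordering, non-empty stoichiometries and the
#' single-metabolite rule for reactions flagged as exchanges. Stops with an
#' informative error on the first violation.
#'
#' @param model a `gem`.
#' @return The model, invisibly.
#' @export
validate_gem <- function(model) {
  stopifnot(inherits(model, "gem"))
  met <- model$metabolites; rxn <- model$reactions; st <- model$stoichiometry
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids: ",
                                  paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids: ",
                                  paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  bad <- setdiff(met$compartment, model$compartments$id)
  if (length(bad)) stop("metabolite compartment(s) not in compartment list: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(st$metabolite, met$id)
  if (length(bad)) stop("stoichiometry references unknown metabolite(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(st$reaction, rxn$id)
  if (length(bad)) stop("stoichiometry references unknown reaction(s): ",
                        paste(bad, collapse = ", "))
  bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
  if (length(bad)) stop("lower bound exceeds upper bound for reaction(s): ",
                        paste(bad, collapse = ", "))
  empty <- setdiff(rxn$id, st$reaction)
  if (length(empty)) stop("reaction(s) with empty stoichiometry: ",
                          paste(empty, collapse = ", "))
  n_met <- table(st$reaction)
  exch <- rxn$id[rxn$is_exchange]
  multi <- exch[n_met[exch] != 1]
  if (length(multi)) stop("exchange reaction(s) touching more than one metabolite: ",
                          paste(multi, collapse = ", "))
  for (i in seq_len(nrow(rxn))) {
    g <- parse_gpr(rxn$gpr[i])
    missing_g <- setdiff(gpr_genes(g), model$genes)
    if (length(missing_g)) stop("GPR of reaction ", rxn$id[i],
                                " references gene(s) not in gene list: ",
                                paste(missing_g, collapse = ", "))
  }
  if (!is.na(model$objective) && !model$objective %in% rxn$id)
    stop("objective reaction not in model: ", model$objective)
  invisible(model)
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem> %s: %d reactions (%d exchange), %d metabolites, %d genes, %d compartments\n",
              x$id, nrow(x$reactions), sum(x$reactions$is_exchange),
              nrow(x$metabolites), length(x$genes), nrow(x$compartments)))
  if (!is.na(x$objective)) cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#'
#' @param model a `gem`.
#' @return Numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  st <- model$stoichiometry
  S[cbind(match(st$metabolite, rownames(S)), match(st$reaction, colnames(S)))] <-
    S[cbind(match(st$metabolite, rownames(S)), match(st$reaction, colnames(S)))] + st$coefficient
  S
}

#' Ids of the exchange reactions of a model
#' @param model a `gem`.
#' @return Character vector.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[model$reactions$is_exchange]
}

#' Summary statistics of a model
#'
#' Entity counts in the shape used to characterise a reconstruction: genes,
#' reactions (total and exchange), metabolites, and per-compartment
#' breakdowns. A reaction is counted in every compartment where it has at
#' least one participant, so a transport reaction contributes to several
#' compartments and the per-compartment reaction counts can sum to more than
#' the total.
#'
#' @param model a `gem`.
#' @return A list with `genes`, `reactions`, `exchange_reactions`,
#'   `metabolites` (scalars) and tibbles `reactions_by_compartment`,
#'   `metabolites_by_compartment`.
#' @export
model_statistics <- function(model) {
  st <- model$stoichiometry
  met_comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  rxn_comp <- unique(tibble::tibble(reaction = st$reaction,
                                    compartment = unname(met_comp[st$metabolite])))
  comp_ids <- model$compartments$id
  rbc <- tibble::tibble(
    compartment = comp_ids,
    n_reactions = vapply(comp_ids, function(cc) sum(rxn_comp$compartment == cc), integer(1)))
  mbc <- tibble::tibble(
    compartment = comp_ids,
    n_metabolites = vapply(comp_ids, function(cc) sum(model$metabolites$compartment == cc), integer(1)))
  list(genes = length(model$genes),
       reactions = nrow(model$reactions),
       exchange_reactions = sum(model$reactions$is_exchange),
       metabolites = nrow(model$metabolites),
       reactions_by_compartment = rbc,
       metabolites_by_compartment = mbc)
}

#' Parse a Hill-notation chemical formula
#'
#' @param formula string like `"C6H12O6"`; `NA`/`""` means unknown.
#' @return Named integer vector element -> count, or `NULL` if unknown.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula))
    stop("cannot parse chemical formula: ", formula)
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(ct, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Check elemental and charge balance of a reaction
#'
#' Sums element counts and charges weighted by stoichiometric coefficients.
#' Exchange reactions are exempt (they move mass across the system boundary
#' by construction); any participant with an unknown formula makes the
#' verdict `"unknown"`.
#'
#' @param model a `gem`.
#' @param rxn_id reaction id.
#' @return A list with `verdict` (`"balanced"`, `"unbalanced"`, `"unknown"`
#'   or `"exchange"`), `element_balance` (named numeric net counts) and
#'   `charge_balance` (numeric or `NA`).
#' @export
check_mass_charge_balance <- function(model, rxn_id) {
  rxn <- model$reactions[model$reactions$id == rxn_id, ]
  if (!nrow(rxn)) stop("unknown reaction id: ", rxn_id)
  if (rxn$is_exchange)
    return(list(verdict = "exchange", element_balance = stats::setNames(numeric(), character()),
                charge_balance = NA_real_))
  st <- model$stoichiometry[model$stoichiometry$reaction == rxn_id, ]
  met <- model$metabolites[match(st$metabolite, model$metabolites$id), ]
  net <- list()
  unknown <- FALSE
  for (i in seq_len(nrow(st))) {
    f <- parse_formula(met$formula[i])
    if (is.null(f)) { unknown <- TRUE; next }
    for (el in names(f)) net[[el]] <- (net[[el]] %||% 0) + st$coefficient[i] * f[[el]]
  }
  charge <- if (any(is.na(met$charge))) NA_real_ else sum(st$coefficient * met$charge)
  net <- unlist(net) %||% stats::setNames(numeric(), character())
  verdict <- if (unknown) "unknown"
             else if (all(abs(net) < 1e-9) && !is.na(charge) && abs(charge) < 1e-9) "balanced"
             else "unbalanced"
  list(verdict = verdict, element_balance = net, charge_balance = charge)
}

#' Guess compartment roles from ids and names
#'
#' Maps the model's compartment ids to the roles used by downstream analyses
#' (`extracellular`, `cytosol`, `mitochondria`, `er`, ...) by matching common
#' id schemes (`e`, `c`, `m`, ...) and names. Override by passing an explicit
#' named vector role -> compartment id to the consumers.
#'
#' @param model a `gem`.
#' @return Named character vector, names are roles, values compartment ids.
#' @export
compartment_roles <- function(model) {
  comp <- model$compartments
  nm <- tolower(paste(comp$id, comp$name))
  pick <- function(patterns, ids) {
    for (p in patterns) {
      hit <- which(grepl(p, nm))
      if (length(hit)) return(comp$id[hit[1]])
    }
    NA_character_
  }
  roles <- c(extracellular = pick(c("^e\\b", "extracell", "external", "boundary")),
             cytosol = pick(c("^c\\b", "cytosol", "cytoplasm")),
             mitochondria = pick(c("^m\\b", "mitochond")),
             er = pick(c("^r\\b", "endoplasmic", "\\ber\\b")))
  roles[!is.na(roles)]
}

#' Cytosolic metabolites connected to the extracellular space
#'
#' A cytosolic metabolite is counted as transportable when it participates in
#' at least one reaction that also involves an extracellular metabolite
#' (cross-compartment participation; `method = "cross_compartment"`). The
#' alternative counting rule (`method = "exchange"`) counts a cytosolic
#' metabolite when an extracellular metabolite of the same base id (id minus
#' compartment suffix) has an exchange reaction.
#'
#' @param model a `gem`.
#' @param roles named character vector mapping roles to compartment ids;
#'   defaults to [compartment_roles()]. Must contain `extracellular` and
#'   `cytosol`.
#' @param method counting rule, see above.
#' @return Character vector of cytosolic metabolite ids.
#' @export
transportable_cytosolic_metabolites <- function(model, roles = compartment_roles(model),
                                                method = c("cross_compartment", "exchange")) {
  method <- match.arg(method)
  if (!all(c("extracellular", "cytosol") %in% names(roles)))
    stop("compartment role mapping must provide 'extracellular' and 'cytosol'")
  e_id <- roles[["extracellular"]]; c_id <- roles[["cytosol"]]
  met_comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  cyt <- model$metabolites$id[model$metabolites$compartment == c_id]
  if (method == "cross_compartment") {
    st <- model$stoichiometry
    st$compartment <- unname(met_comp[st$metabolite])
    has_e <- unique(st$reaction[st$compartment == e_id])
    sort(unique(st$metabolite[st$reaction %in% has_e & st$metabolite %in% cyt]))
  } else {
    ex_mets <- model$stoichiometry$metabolite[
      model$stoichiometry$reaction %in% exchange_reactions(model)]
    strip <- function(ids, comp) sub(paste0("[_\\[]", comp, "\\]?$"), "", ids)
    base_ex <- strip(ex_mets[met_comp[ex_mets] == e_id], e_id)
    sort(cyt[strip(cyt, c_id) %in% base_ex])
  }
}

#' Modify reaction bounds
#'
#' @param model a `gem`.
#' @param reaction reaction id(s).
#' @param lower,upper new bounds (recycled); `NULL` leaves a side unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NULL, upper = NULL) {
  idx <- match(reaction, model$reactions$id)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(reaction[is.na(idx)], collapse = ", "))
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- upper
  bad <- model$reactions$lower_bound[idx] > model$reactions$upper_bound[idx]
  if (any(bad)) stop("lower bound exceeds upper bound for reaction(s): ",
                     paste(reaction[bad], collapse = ", "))
  model
}

#' Add a reaction to a model
#'
#' @param model a `gem`.
#' @param id,name reaction id and name.
#' @param stoichiometry named numeric vector metabolite id -> coefficient.
#' @param lower,upper flux bounds.
#' @param gpr GPR string or `NA`.
#' @param subsystem subsystem label.
#' @param is_exchange exchange flag.
#' @return The modified model.
#' @export
add_reaction <- function(model, id, stoichiometry, lower = 0, upper = 1000,
                         name = id, gpr = NA_character_,
                         subsystem = NA_character_, is_exchange = FALSE) {
  if (id %in% model$reactions$id) stop("reaction already in model: ", id)
  missing_m <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(missing_m)) stop("unknown metabolite(s): ", paste(missing_m, collapse = ", "))
  model$reactions <- dplyr::bind_rows(model$reactions, tibble::tibble(
    id = id, name = name, lower_bound = lower, upper_bound = upper,
    gpr = gpr, subsystem = subsystem, is_exchange = is_exchange))
  model$stoichiometry <- dplyr::bind_rows(model$stoichiometry, tibble::tibble(
    reaction = id, metabolite = names(stoichiometry),
    coefficient = unname(stoichiometry)))
  model
}

#' Remove reactions from a model
#' @param model a `gem`.
#' @param ids reaction ids to drop (unknown ids are ignored).
#' @return The modified model.
#' @export
remove_reactions <- function(model, ids) {
  model$reactions <- model$reactions[!model$reactions$id %in% ids, ]
  model$stoichiometry <- model$stoichiometry[!model$stoichiometry$reaction %in% ids, ]
  if (!is.na(model$objective) && model$objective %in% ids) model$objective <- NA_character_
  model
}

#' Add a metabolite to a model (no-op if present)
#' @param model a `gem`.
#' @param id metabolite id.
#' @param compartment compartment id.
#' @param name,formula,charge optional annotation.
#' @return The modified model.
#' @export
add_metabolite <- function(model, id, compartment, name = id,
                           formula = NA_character_, charge = NA_integer_) {
  if (id %in% model$metabolites$id) return(model)
  if (!compartment %in% model$compartments$id)
    stop("unknown compartment: ", compartment)
  model$metabolites <- dplyr::bind_rows(model$metabolites, tibble::tibble(
    id = id, name = name, compartment = compartment,
    formula = formula, charge = charge))
  model
}
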