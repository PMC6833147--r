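#' Construct a universal reaction pool for gap filling
#'
#' A pool of candidate reactions (typically harvested from template models
#' or reference databases) from which a minimal subset is chosen to restore
#' producibility of a target metabolite. Pool reactions need no GPRs; each
#' carries a provenance tag so a curator can review what source proposed it.
#'
#' @param reactions tibble with the same columns as a `gem` reaction table.
#' @param stoichiometry long tibble `reaction`, `metabolite`, `coefficient`.
#' @param metabolites tibble of metabolites that appear in the pool but not
#'   necessarily in a target model (may be `NULL`).
#' @param provenance named character vector reaction id -> source tag.
#' @return An object of class `universal_pool`.
#' @export
universal_pool <- function(reactions, stoichiometry, metabolites = NULL,
                           provenance = character()) {
  reactions <- fill_cols(tibble::as_tibble(reactions),
                         name = NA_character_, gpr = NA_character_,
                         subsystem = NA_character_, is_exchange = FALSE)
  structure(list(reactions = reactions,
                 stoichiometry = tibble::as_tibble(stoichiometry),
                 metabolites = if (is.null(metabolites)) NULL else tibble::as_tibble(metabolites),
                 provenance = provenance),
            class = "universal_pool")
}

#' @export
print.universal_pool <- function(x, ...) {
  cat(sprintf("<universal_pool> %d candidate reaction(s)\n", nrow(x$reactions)))
  invisible(x)
}

# Merge a subset of pool reactions (by id) into a model.
augment_with_pool <- function(model, pool, ids) {
  if (!length(ids)) return(model)
  pm <- pool$metabolites
  if (!is.null(pm)) {
    for (i in seq_len(nrow(pm))) {
      if (!pm$compartment[i] %in% model$compartments$id)
        model$compartments <- dplyr::bind_rows(
          model$compartments, tibble::tibble(id = pm$compartment[i],
                                             name = pm$compartment[i]))
      model <- add_metabolite(model, pm$id[i], pm$compartment[i],
                              name = pm$name[i] %||% pm$id[i])
    }
  }
  for (id in ids) {
    r <- pool$reactions[pool$reactions$id == id, ]
    st <- pool$stoichiometry[pool$stoichiometry$reaction == id, ]
    model <- add_reaction(model, id,
                          stats::setNames(st$coefficient, st$metabolite),
                          lower = r$lower_bound, upper = r$upper_bound,
                          name = r$name, is_exchange = r$is_exchange)
  }
  model
}

# Build the gap-filling LP relaxation:
# variables [v_model, v_pool, v_demand, y_pool, slacks]; rows: mass balance
# over the union metabolite set, plus big-M linking rows per pool reaction.
gapfill_lp <- function(model, pool, target, medium = NULL, epsilon = 0.01) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  clash <- intersect(pool$reactions$id, model$reactions$id)
  if (length(clash)) stop("pool reaction id(s) clash with model: ",
                          paste(clash, collapse = ", "))
  full <- augment_with_pool(model, pool, pool$reactions$id)
  dm <- add_demand(full, target)
  full <- dm$model
  rxn <- full$reactions
  S <- stoich_matrix(full)
  m <- nrow(S); n <- nrow(rxn)
  pool_ids <- sort(pool$reactions$id)
  p <- length(pool_ids)
  pidx <- match(pool_ids, rxn$id)
  didx <- match(dm$reaction, rxn$id)
  bigM <- 1000
  # columns: n fluxes, p binaries, 2p slacks
  A <- matrix(0, m + 2 * p, n + 3 * p)
  A[seq_len(m), seq_len(n)] <- S
  for (j in seq_len(p)) {
    # v_j - M y_j + s1_j = 0  => v_j <= M y_j
    A[m + j, pidx[j]] <- 1; A[m + j, n + j] <- -bigM; A[m + j, n + p + j] <- 1
    # -v_j - M y_j + s2_j = 0 => v_j >= -M y_j
    A[m + p + j, pidx[j]] <- -1; A[m + p + j, n + j] <- -bigM; A[m + p + j, n + 2 * p + j] <- 1
  }
  lb <- c(rxn$lower_bound, rep(0, p), rep(0, 2 * p))
  ub <- c(rxn$upper_bound, rep(1, p), rep(Inf, 2 * p))
  lb[didx] <- epsilon   # force producibility
  cvec <- c(rep(0, n + 3 * p))
  cvec[n + seq_len(p)] <- 1
  list(c = cvec, A = A, b = rep(0, m + 2 * p), lb = lb, ub = ub,
       y_idx = n + seq_len(p), pool_ids = pool_ids)
}

# Branch-and-bound minimisation of the number of active pool reactions.
# forced_in / forced_out fix binaries; returns list(size, members) or NULL
# when infeasible. cap prunes branches that cannot beat it.
milp_min_additions <- function(lp, forced_in = character(), forced_out = character(),
                               cap = Inf) {
  yi <- lp$y_idx
  lb0 <- lp$lb; ub0 <- lp$ub
  lb0[yi[match(forced_in, lp$pool_ids)]] <- 1
  ub0[yi[match(forced_out, lp$pool_ids)]] <- 0
  best <- NULL
  best_size <- cap
  rec <- function(lb, ub) {
    sol <- lp_solve(lp$c, lp$A, lp$b, lb, ub, maximize = FALSE)
    if (sol$status != "optimal") return()
    if (sol$objective >= best_size - 1e-6) return()
    y <- sol$x[yi]
    frac <- which(y > 1e-6 & y < 1 - 1e-6)
    if (!length(frac)) {
      members <- sort(lp$pool_ids[y > 0.5])
      # round: the true size is the integral count
      if (length(members) < best_size) {
        best_size <<- length(members)
        best <<- members
      }
      return()
    }
    j <- frac[which.max(pmin(y[frac], 1 - y[frac]))]
    ub1 <- ub; ub1[yi[j]] <- 0
    rec(lb, ub1)                      # exclude first: favours small sets
    lb1 <- lb; lb1[yi[j]] <- 1
    rec(lb1, ub)
  }
  rec(lb0, ub0)
  if (is.null(best)) NULL else list(size = best_size, members = best)
}

# Metabolites upstream of the target with no producing reaction anywhere in
# model+pool — the usual reason a gap is unfillable.
dead_end_upstream <- function(model, pool, target) {
  full <- augment_with_pool(model, pool, pool$reactions$id)
  st <- full$stoichiometry
  rxn <- full$reactions
  rev_ids <- rxn$id[rxn$lower_bound < 0]
  producers <- function(met) {
    fwd <- st$reaction[st$metabolite == met & st$coefficient > 0]
    bwd <- st$reaction[st$metabolite == met & st$coefficient < 0 & st$reaction %in% rev_ids]
    union(fwd, bwd)
  }
  seen <- character(); queue <- target; dead <- character()
  while (length(queue)) {
    met <- queue[1]; queue <- queue[-1]
    if (met %in% seen) next
    seen <- c(seen, met)
    prods <- producers(met)
    if (!length(prods)) { dead <- c(dead, met); next }
    subs <- unique(st$metabolite[st$reaction %in% prods & st$coefficient < 0])
    queue <- c(queue, setdiff(subs, seen))
  }
  sort(dead)
}

#' Minimal-addition gap filling for one target metabolite
#'
#' Finds the smallest set of pool reactions whose addition makes the target
#' metabolite producible (maximal demand flux >= `epsilon`) in the given
#' medium, by a branch-and-bound MILP with one binary indicator per pool
#' reaction. Among equal-cardinality optima the lexicographically smallest
#' id set is returned, so results are deterministic. The returned set is
#' verified minimal: removing any single member breaks producibility.
#'
#' @param model a `gem`.
#' @param pool a [universal_pool()].
#' @param target metabolite id to make producible.
#' @param medium optional `medium` applied before testing.
#' @param epsilon minimal production flux counting as producible
#'   (mmol/gDW/h).
#' @return Sorted character vector of pool reaction ids (empty when the
#'   target is already producible), with provenance tags as the
#'   `"provenance"` attribute.
#' @export
fill_gaps <- function(model, pool, target, medium = NULL, epsilon = 0.01) {
  mtest <- if (is.null(medium)) model else apply_medium(model, medium)
  if (!target %in% mtest$metabolites$id) {
    if (is.null(pool$metabolites) || !target %in% pool$metabolites$id)
      stop("target metabolite unknown to model and pool: ", target)
  } else {
    p0 <- producibility(mtest, target)
    if (!is.na(p0) && p0 > 1e-6) return(structure(character(), provenance = character()))
  }
  lp <- gapfill_lp(model, pool, target, medium, epsilon)
  opt <- milp_min_additions(lp)
  if (is.null(opt)) {
    dead <- dead_end_upstream(mtest, pool, target)
    stop(sprintf(paste0("unfillable: no subset of the pool makes %s producible; ",
                        "dead-end metabolite(s) upstream: %s"),
                 target, paste(dead, collapse = ", ")), call. = FALSE)
  }
  k <- opt$size
  # lexicographic refinement: prefer inclusion of the smallest ids
  chosen <- character(); excluded <- character()
  for (id in lp$pool_ids) {
    if (length(chosen) == k) { excluded <- c(excluded, id); next }
    trial <- milp_min_additions(lp, forced_in = c(chosen, id),
                                forced_out = excluded, cap = k + 1e-6 + 1)
    if (!is.null(trial) && trial$size <= k) chosen <- c(chosen, id)
    else excluded <- c(excluded, id)
  }
  result <- sort(chosen)
  # post-hoc minimality assertion
  aug <- augment_with_pool(mtest, pool, result)
  stopifnot(producibility(aug, target) > 1e-6)
  for (drop1 in result) {
    sub <- augment_with_pool(mtest, pool, setdiff(result, drop1))
    p <- producibility(sub, target)
    if (!is.na(p) && p > 1e-6)
      stop("internal error: gap-fill set not minimal (", drop1, " removable)")
  }
  structure(result,
            provenance = stats::setNames(
              unname(pool$provenance[result]), result))
}

#' Gap fill each biomass component in sequence
#'
#' Runs [fill_gaps()] for every component in the given order, adding each
#' component's reactions to the working model before the next component is
#' processed (so a reaction needed by several components is added, and
#' attributed, once). The union of additions is order-invariant; the
#' per-component attribution may depend on the order.
#'
#' @param model a `gem`.
#' @param pool a [universal_pool()].
#' @param components character vector of metabolite ids, in processing order.
#' @param medium optional `medium`.
#' @param epsilon producibility threshold.
#' @return List with `additions` (tibble `component`, `reaction`,
#'   `provenance`; zero rows for components needing nothing) and `model`
#'   (the augmented model).
#' @export
fill_gaps_per_component <- function(model, pool, components, medium = NULL,
                                    epsilon = 0.01) {
  work <- model
  remaining <- pool
  out <- list()
  for (comp in components) {
    added <- tryCatch(
      fill_gaps(work, remaining, comp, medium, epsilon),
      error = function(e) stop("component ", comp, ": ", conditionMessage(e),
                               call. = FALSE))
    if (length(added)) {
      work <- augment_with_pool(work, remaining, added)
      prov <- attr(added, "provenance")
      out[[comp]] <- tibble::tibble(component = comp, reaction = as.character(added),
                                    provenance = unname(prov[added]))
      remaining$reactions <- remaining$reactions[!remaining$reactions$id %in% added, ]
      remaining$stoichiometry <-
        remaining$stoichiometry[!remaining$stoichiometry$reaction %in% added, ]
    } else {
      out[[comp]] <- tibble::tibble(component = character(), reaction = character(),
                                    provenance = character())
    }
  }
  additions <- dplyr::bind_rows(out)
  list(additions = additions, model = work)
}
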