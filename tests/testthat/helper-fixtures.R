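# Shared helpers: planted-truth fixture, FBA-as-LP serialisation, and the
# scipy/HiGHS oracle bridge (python is part of the runtime environment).

`%||%` <- function(a, b) if (is.null(a)) b else a

planted_spec <- function() {
  toy_spec(
    planted_inactive = list(
      cool = character(),
      static = "gRIB3",
      hot = c("gRIB4", "gFMN1", "gP1")),
    planted_auxotrophies = list(
      static = "FAD_c",
      hot = c("FAD_c", "P1_c")))
}

# The FBA LP of a model, in the matrix form lp_solve() and the oracle take.
model_lp <- function(model, objective = model$objective, maximize = TRUE) {
  rxn <- model$reactions
  list(c = as.numeric(rxn$id == objective),
       A = stoich_matrix(model),
       b = rep(0, nrow(model$metabolites)),
       lb = rxn$lower_bound, ub = rxn$upper_bound,
       maximize = maximize)
}

# Solve a batch of LPs with scipy.optimize.linprog (HiGHS) in one python
# process; problems is a list of model_lp() results.
oracle_solve <- function(problems) {
  script <- system.file("python", "lp_oracle.py", package = "gemkit")
  stopifnot(nzchar(script))
  inf_clamp <- function(x) pmax(pmin(x, 1e30), -1e30)
  payload <- lapply(problems, function(p) {
    A <- as.matrix(p$A)
    list(c = as.numeric(p$c), A = as.numeric(t(A)),
         m = nrow(A), n = ncol(A), b = as.numeric(p$b),
         lb = inf_clamp(p$lb), ub = inf_clamp(p$ub),
         maximize = isTRUE(p$maximize))
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = TRUE)
  status <- system2("python", c(script, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) stop("LP oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

# Exhaustive-enumeration oracle for gap filling: smallest subset of pool
# reactions restoring producibility; ties broken by lexicographically
# smallest sorted id vector.
enumerate_gapfill <- function(model, pool, target, medium = NULL, epsilon = 0.01) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  ids <- sort(pool$reactions$id)
  best <- NULL
  for (size in 0:length(ids)) {
    combos <- if (size == 0) list(character()) else
      utils::combn(ids, size, simplify = FALSE)
    feas <- Filter(function(s) {
      aug <- gemkit:::augment_with_pool(model, pool, s)
      if (!target %in% aug$metabolites$id) return(FALSE)
      p <- producibility(aug, target)
      !is.na(p) && p >= epsilon - 1e-9
    }, combos)
    if (length(feas)) {
      keys <- vapply(feas, function(s) paste(sort(s), collapse = "\r"), character(1))
      best <- feas[[order(keys)[1]]]
      break
    }
  }
  best
}

expect_flux_solution_consistent <- function(model, sol, tol_sv = 1e-6, tol_bound = 1e-9) {
  if (sol$status != "optimal") return(invisible(sol))
  S <- stoich_matrix(model)
  v <- sol$fluxes[colnames(S)]
  expect_lt(max(abs(S %*% v)), tol_sv)
  rxn <- model$reactions
  expect_true(all(v >= rxn$lower_bound - tol_bound))
  expect_true(all(v <= rxn$upper_bound + tol_bound))
  invisible(sol)
}
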