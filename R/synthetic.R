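#' Specification for a synthetic toy model
#'
#' Describes the world a generated toy GEM should realise: number of
#' compartments (2 = extracellular + cytosol, 3 adds mitochondria), number
#' of precursor pathway modules feeding biomass, and per-condition planted
#' truths — genes switched off and the biomass components that must thereby
#' become non-producible (auxotrophies). Consistency of the planted sets is
#' verified at generation time by GPR evaluation and producibility.
#'
#' @param n_compartments 2 or 3.
#' @param n_pathway_modules number of precursor modules (>= 3).
#' @param planted_inactive named list condition -> character vector of genes.
#' @param planted_auxotrophies named list condition -> character vector of
#'   metabolite ids expected to become non-producible.
#' @param seed integer seed (the skeleton is deterministic; the seed is kept
#'   for provenance and downstream draws).
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_compartments = 2, n_pathway_modules = 5,
                     planted_inactive = list(), planted_auxotrophies = list(),
                     seed = 1L) {
  stopifnot(n_compartments %in% c(2, 3), n_pathway_modules >= 3)
  extra <- setdiff(names(planted_auxotrophies), names(planted_inactive))
  if (length(extra)) stop("planted auxotrophies for condition(s) with no planted inactive genes: ",
                          paste(extra, collapse = ", "))
  structure(list(n_compartments = n_compartments,
                 n_pathway_modules = n_pathway_modules,
                 planted_inactive = planted_inactive,
                 planted_auxotrophies = planted_auxotrophies,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

#' Generate a toy genome-scale model from a specification
#'
#' Deterministic for a given spec. The skeleton is: one carbon substrate
#' `A_e` with exchange `EX_A` (uptake bound -10), a GPR-carrying transporter,
#' `n_pathway_modules` linear precursor pathways `A_c -> Pi_c` each under its
#' own gene, and a riboflavin-like cofactor branch mirroring the topology of
#' a GTP + pentose-phosphate convergence: two linear branches
#' (`A_c -> G_c -> X_c` and `A_c -> Y0_c -> Y_c`, the two final steps sharing
#' one gene), a converging step to a lumazine-like intermediate, a linear
#' tail to the riboflavin-like metabolite `RIBO_c` and onward kinase steps to
#' `FMN_c` and `FAD_c`. Biomass consumes every precursor (1/k each), 0.01
#' `FAD_c`, and with three compartments also 0.05 of a mitochondrially made
#' component. Growth is strictly positive in the default open medium.
#'
#' @param spec a [toy_spec()].
#' @return A validated `gem`.
#' @export
make_toy_model <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  k <- spec$n_pathway_modules
  with_m <- spec$n_compartments >= 3

  comps <- tibble::tibble(id = c("e", "c"), name = c("extracellular", "cytosol"))
  if (with_m) comps <- dplyr::bind_rows(comps, tibble::tibble(id = "m", name = "mitochondria"))

  mets <- tibble::tibble(
    id = c("A_e", "A_c", paste0("P", seq_len(k), "_c"),
           "G_c", "X_c", "Y0_c", "Y_c", "L_c", "RIBO_c", "FMN_c", "FAD_c"),
    compartment = c("e", rep("c", 1 + k), rep("c", 8)))
  mets$name <- mets$id
  mets$formula <- NA_character_
  mets$charge <- NA_integer_
  mets$formula[mets$id %in% c("A_e", "A_c")] <- "CH2O"
  mets$charge[mets$id %in% c("A_e", "A_c")] <- 0L
  if (with_m) mets <- dplyr::bind_rows(
    mets, tibble::tibble(id = c("A_m", "Q_m", "Q_c"), name = c("A_m", "Q_m", "Q_c"),
                         compartment = c("m", "m", "c"),
                         formula = NA_character_, charge = NA_integer_))

  rxn <- list(); st <- list()
  put <- function(id, stoich, lb, ub, gpr = NA_character_, exch = FALSE) {
    rxn[[length(rxn) + 1L]] <<- tibble::tibble(
      id = id, name = id, lower_bound = lb, upper_bound = ub,
      gpr = gpr, subsystem = NA_character_, is_exchange = exch)
    st[[length(st) + 1L]] <<- tibble::tibble(
      reaction = id, metabolite = names(stoich), coefficient = unname(stoich))
  }

  put("EX_A", c(A_e = -1), -10, 1000, exch = TRUE)
  put("T_A", c(A_e = -1, A_c = 1), 0, 1000, gpr = "gT")
  for (i in seq_len(k))
    put(paste0("R", i), stats::setNames(c(-1, 1), c("A_c", paste0("P", i, "_c"))),
        0, 1000, gpr = paste0("gP", i))
  # riboflavin-like branch
  put("B1A", c(A_c = -1, G_c = 1), 0, 1000, gpr = "gGTP")
  put("B1B", c(G_c = -1, X_c = 1), 0, 1000, gpr = "gRIB3")
  put("B2A", c(A_c = -1, Y0_c = 1), 0, 1000, gpr = "gRU5P")
  put("B2B", c(Y0_c = -1, Y_c = 1), 0, 1000, gpr = "gRIB3")
  put("CONV", c(X_c = -1, Y_c = -1, L_c = 1), 0, 1000, gpr = "gRIB4")
  put("TAIL", c(L_c = -1, RIBO_c = 1), 0, 1000, gpr = "gRIB5")
  put("K1", c(RIBO_c = -1, FMN_c = 1), 0, 1000, gpr = "gFMN1")
  put("K2", c(FMN_c = -1, FAD_c = 1), 0, 1000, gpr = "gFAD1")
  if (with_m) {
    put("T_AM", c(A_c = -1, A_m = 1), 0, 1000, gpr = "gM")
    put("RM", c(A_m = -1, Q_m = 1), 0, 1000, gpr = "gQ")
    put("T_Q", c(Q_m = -1, Q_c = 1), 0, 1000)
  }
  bio <- stats::setNames(rep(-1 / k, k), paste0("P", seq_len(k), "_c"))
  bio <- c(bio, FAD_c = -0.02, if (with_m) c(Q_c = -0.05))
  put("BIOMASS", bio, 0, 1000)

  genes <- sort(unique(unlist(lapply(rxn, function(r) gpr_genes(parse_gpr(r$gpr))))))
  model <- gem(id = sprintf("toy_c%d_k%d", spec$n_compartments, k),
               compartments = comps, metabolites = mets,
               reactions = dplyr::bind_rows(rxn),
               stoichiometry = dplyr::bind_rows(st),
               genes = genes, objective = "BIOMASS",
               maintenance = list(gam = 0, ngam = 0, po_ratio = NA_real_))

  # verify planted truths are consistent with the network
  for (cond in names(spec$planted_inactive)) {
    inact <- spec$planted_inactive[[cond]]
    bad <- setdiff(inact, model$genes)
    if (length(bad)) stop("planted inactive gene(s) not in generated model: ",
                          paste(bad, collapse = ", "))
    aux <- spec$planted_auxotrophies[[cond]] %||% character()
    if (length(aux)) {
      cm <- derive_condition_model(model, inact, condition = cond)
      for (met0 in aux) {
        p <- producibility(cm$model, met0)
        if (is.na(p) || p > 1e-6)
          stop(sprintf("inconsistent spec: %s still producible (%.3g) in condition %s",
                       met0, p, cond))
      }
    }
  }
  model
}

#' Named catalogue of frozen toy fixtures
#'
#' * `TOY1` — minimal 4-reaction, 3-metabolite, 3-gene chain
#'   (`EX_A -> T_A -> R1 -> GROWTH`), growth optimum 10 at uptake 10.
#' * `TOY-BIO` — precursor network with a 5-component biomass (optimum 10);
#'   with `biomass = FALSE` the biomass reaction is left out so
#'   [assemble_biomass()] can be exercised on it.
#' * `RIBO` — `TOY-BIO` plus the riboflavin-like cofactor branch
#'   (see [make_toy_model()]).
#' * `GAP1` / `GAP2` — gap-filling fixtures; the model is returned together
#'   with its universal pool and target, as a list.
#'
#' @param name fixture name.
#' @param biomass for `TOY-BIO`: include the biomass reaction?
#' @return A `gem`, or for the GAP fixtures a list
#'   `(model, pool, target, medium)`.
#' @export
toy_model <- function(name = c("TOY1", "TOY-BIO", "RIBO", "GAP1", "GAP2"),
                      biomass = TRUE) {
  name <- match.arg(name)
  if (name == "TOY1") return(toy1_model())
  if (name == "RIBO") return(make_toy_model(toy_spec()))
  if (name == "TOY-BIO") return(toy_bio_model(biomass))
  if (name == "GAP1") return(gap1_fixture())
  gap2_fixture()
}

toy1_model <- function() {
  comps <- tibble::tibble(id = c("e", "c"), name = c("extracellular", "cytosol"))
  mets <- tibble::tibble(id = c("A_e", "A_c", "B_c"), name = c("A_e", "A_c", "B_c"),
                         compartment = c("e", "c", "c"),
                         formula = "CH2O", charge = 0L)
  rxns <- tibble::tibble(
    id = c("EX_A", "T_A", "R1", "GROWTH"),
    name = c("EX_A", "T_A", "R1", "GROWTH"),
    lower_bound = c(-10, 0, 0, 0), upper_bound = rep(1000, 4),
    gpr = c(NA, "g1", "g2 and g3", NA),
    subsystem = NA_character_,
    is_exchange = c(TRUE, FALSE, FALSE, FALSE))
  st <- tibble::tibble(
    reaction = c("EX_A", "T_A", "T_A", "R1", "R1", "GROWTH"),
    metabolite = c("A_e", "A_e", "A_c", "A_c", "B_c", "B_c"),
    coefficient = c(-1, -1, 1, -1, 1, -1))
  gem("TOY1", comps, mets, rxns, st, genes = c("g1", "g2", "g3"),
      objective = "GROWTH", maintenance = list(gam = 0, ngam = 0, po_ratio = NA_real_))
}

toy_bio_model <- function(biomass = TRUE) {
  k <- 5L
  comps <- tibble::tibble(id = c("e", "c"), name = c("extracellular", "cytosol"))
  mets <- tibble::tibble(id = c("A_e", "A_c", paste0("P", 1:k, "_c")),
                         compartment = c("e", rep("c", 1 + k)))
  mets$name <- mets$id; mets$formula <- NA_character_; mets$charge <- NA_integer_
  rxns <- list(); st <- list()
  put <- function(id, stoich, lb, ub, gpr = NA_character_, exch = FALSE) {
    rxns[[length(rxns) + 1L]] <<- tibble::tibble(
      id = id, name = id, lower_bound = lb, upper_bound = ub, gpr = gpr,
      subsystem = NA_character_, is_exchange = exch)
    st[[length(st) + 1L]] <<- tibble::tibble(
      reaction = id, metabolite = names(stoich), coefficient = unname(stoich))
  }
  put("EX_A", c(A_e = -1), -10, 1000, exch = TRUE)
  put("T_A", c(A_e = -1, A_c = 1), 0, 1000, gpr = "gT")
  for (i in 1:k)
    put(paste0("R", i), stats::setNames(c(-1, 1), c("A_c", paste0("P", i, "_c"))),
        0, 1000, gpr = paste0("gP", i))
  if (biomass)
    put("BIOMASS", stats::setNames(rep(-1 / k, k), paste0("P", 1:k, "_c")), 0, 1000)
  genes <- c("gT", paste0("gP", 1:k))
  gem("TOY-BIO", comps, mets, dplyr::bind_rows(rxns), dplyr::bind_rows(st),
      genes = genes, objective = if (biomass) "BIOMASS" else NA_character_,
      maintenance = list(gam = 0, ngam = 0, po_ratio = NA_real_))
}

gap_base_model <- function(extra_step = FALSE) {
  comps <- tibble::tibble(id = c("e", "c"), name = c("extracellular", "cytosol"))
  ids <- c("S_e", "S_c", "M_c", "T_c", "D2_c", if (extra_step) "M2_c")
  mets <- tibble::tibble(id = ids, name = ids, compartment = c("e", rep("c", length(ids) - 1)),
                         formula = NA_character_, charge = NA_integer_)
  rxns <- tibble::tibble(
    id = c("EX_S", "T_S", "RA"),
    name = c("EX_S", "T_S", "RA"),
    lower_bound = c(-10, 0, 0), upper_bound = rep(1000, 3),
    gpr = NA_character_, subsystem = NA_character_,
    is_exchange = c(TRUE, FALSE, FALSE))
  st <- tibble::tibble(
    reaction = c("EX_S", "T_S", "T_S", "RA", "RA"),
    metabolite = c("S_e", "S_e", "S_c", "S_c", "M_c"),
    coefficient = c(-1, -1, 1, -1, 1))
  gem("GAP-base", comps, mets, rxns, st, objective = NA_character_)
}

gap1_fixture <- function() {
  model <- gap_base_model()
  pool <- universal_pool(
    reactions = tibble::tibble(
      id = c("R_fix", "R_decoy1", "R_decoy2"),
      name = c("R_fix", "R_decoy1", "R_decoy2"),
      lower_bound = 0, upper_bound = 1000,
      gpr = NA_character_, subsystem = NA_character_, is_exchange = FALSE),
    stoichiometry = tibble::tibble(
      reaction = c("R_fix", "R_fix", "R_decoy1", "R_decoy1", "R_decoy2", "R_decoy2"),
      metabolite = c("M_c", "T_c", "M_c", "D1_c", "D2_c", "T_c"),
      coefficient = c(-1, 1, -1, 1, -1, 1)),
    metabolites = tibble::tibble(
      id = "D1_c", name = "D1_c", compartment = "c",
      formula = NA_character_, charge = NA_integer_),
    provenance = c(R_fix = "template-model", R_decoy1 = "reference-db",
                   R_decoy2 = "reference-db"))
  list(model = model, pool = pool, target = "T_c",
       medium = medium("gap-medium", list(EX_S = c(-10, 1000))))
}

gap2_fixture <- function() {
  model <- gap_base_model(extra_step = TRUE)
  # target T_c needs M_c -> M2_c (P1) then M2_c -> T_c (P2)
  model <- remove_reactions(model, character())
  pool <- universal_pool(
    reactions = tibble::tibble(
      id = c("P1", "P2", "P3", "P4", "P5"),
      name = c("P1", "P2", "P3", "P4", "P5"),
      lower_bound = 0, upper_bound = 1000,
      gpr = NA_character_, subsystem = NA_character_, is_exchange = FALSE),
    stoichiometry = tibble::tibble(
      reaction = c("P1", "P1", "P2", "P2", "P3", "P3", "P4", "P4", "P5", "P5"),
      metabolite = c("M_c", "M2_c", "M2_c", "T_c", "M_c", "D1_c",
                     "D2_c", "T_c", "D1_c", "D2_c"),
      coefficient = c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1)),
    metabolites = tibble::tibble(
      id = "D1_c", name = "D1_c", compartment = "c",
      formula = NA_character_, charge = NA_integer_),
    provenance = c(P1 = "template-model", P2 = "template-model",
                   P3 = "reference-db", P4 = "reference-db", P5 = "reference-db"))
  list(model = model, pool = pool, target = "T_c",
       medium = medium("gap-medium", list(EX_S = c(-10, 1000))))
}

#' Generate a random toy model
#'
#' A random but always-growing network for property tests: a guaranteed
#' linear backbone `S_e -> S_c = M1 -> M2 -> ... -> Mk` with a sink objective
#' on `Mk`, decorated with random cross-connections (some reversible, some
#' with stoichiometric coefficient 2) and a random uptake bound. All bounds
#' finite, so the FBA is always optimal with a strictly positive objective.
#'
#' @param seed integer seed.
#' @param n_internal number of internal metabolites (default random 3-8).
#' @return A validated `gem`.
#' @export
random_toy_model <- function(seed, n_internal = NULL) {
  set.seed(seed)
  k <- n_internal %||% sample(3:8, 1)
  comps <- tibble::tibble(id = c("e", "c"), name = c("extracellular", "cytosol"))
  ids <- c("S_e", paste0("M", seq_len(k), "_c"))
  mets <- tibble::tibble(id = ids, name = ids,
                         compartment = c("e", rep("c", k)),
                         formula = NA_character_, charge = NA_integer_)
  uptake <- sample(1:20, 1)
  rxns <- list(); st <- list()
  put <- function(id, stoich, lb, ub, exch = FALSE) {
    rxns[[length(rxns) + 1L]] <<- tibble::tibble(
      id = id, name = id, lower_bound = lb, upper_bound = ub,
      gpr = NA_character_, subsystem = NA_character_, is_exchange = exch)
    st[[length(st) + 1L]] <<- tibble::tibble(
      reaction = id, metabolite = names(stoich), coefficient = unname(stoich))
  }
  put("EX_S", c(S_e = -1), -uptake, 1000, exch = TRUE)
  put("T_S", c(S_e = -1, M1_c = 1), 0, 1000)
  for (i in seq_len(k - 1)) {
    rev_i <- stats::runif(1) < 0.3
    put(paste0("C", i),
        stats::setNames(c(-1, 1), paste0("M", c(i, i + 1), "_c")),
        if (rev_i) -1000 else 0, 1000)
  }
  n_extra <- sample(0:4, 1)
  for (j in seq_len(n_extra)) {
    pair <- sample(k, 2)
    coef <- sample(1:2, 1)
    put(paste0("X", j),
        stats::setNames(c(-coef, 1), paste0("M", pair, "_c")),
        if (stats::runif(1) < 0.3) -1000 else 0, 1000)
  }
  put("SINK", stats::setNames(-1, paste0("M", k, "_c")), 0, 1000)
  gem(sprintf("random_%d", seed), comps, mets,
      dplyr::bind_rows(rxns), dplyr::bind_rows(st),
      objective = "SINK",
      maintenance = list(gam = 0, ngam = 0, po_ratio = NA_real_))
}

#' Generate a replicate expression matrix with planted inactive genes
#'
#' Emulates the structure of a per-condition, per-replicate expression table
#' used for binary (zero vs non-zero) integration: planted genes get exactly
#' zero in all replicates of their condition; every other model gene gets a
#' strictly positive log-normal draw (meanlog 2, sdlog 1 — only zero versus
#' non-zero matters downstream); and in each condition one non-planted gene
#' gets a zero in exactly one replicate, so the all-replicates-zero rule is
#' exercised against near-misses.
#'
#' @param model a `gem` whose genes to cover.
#' @param planted_inactive named list condition -> genes set to zero.
#' @param n_replicates replicates per condition (default 3).
#' @param seed integer seed.
#' @return An `expression_set`.
#' @export
make_expression <- function(model, planted_inactive, n_replicates = 3, seed = 1L) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  genes <- model$genes
  for (cond in names(planted_inactive)) {
    bad <- setdiff(planted_inactive[[cond]], genes)
    if (length(bad)) stop("planted gene(s) not in model: ", paste(bad, collapse = ", "))
  }
  set.seed(seed)
  rows <- list()
  for (cond in names(planted_inactive)) {
    planted <- planted_inactive[[cond]]
    vals <- matrix(stats::rlnorm(length(genes) * n_replicates, meanlog = 2, sdlog = 1),
                   nrow = length(genes))
    vals[genes %in% planted, ] <- 0
    near_miss <- setdiff(genes, planted)
    if (length(near_miss) && n_replicates >= 1)
      vals[match(near_miss[1], genes), 1] <- 0
    rows[[cond]] <- tibble::tibble(
      gene = rep(genes, times = n_replicates),
      condition = cond,
      replicate = rep(seq_len(n_replicates), each = length(genes)),
      value = as.vector(vals))
  }
  expression_set(dplyr::bind_rows(rows))
}

#' Generate a noisy substrate-uptake vs growth-rate table
#'
#' For each substrate exchange and uptake rate, the true growth rate is the
#' FBA prediction at that fixed uptake; the observed rate adds Gaussian noise
#' truncated at zero, emulating experimental growth-rate measurements.
#'
#' @param model a `gem`.
#' @param substrates tibble with columns `exchange`, `uptake`.
#' @param noise_sd standard deviation of the additive noise (1/h).
#' @param seed integer seed.
#' @return Tibble with `substrate`, `uptake`, `true_mu`, `observed_mu`.
#' @export
make_growth_table <- function(model, substrates, noise_sd = 0.02, seed = 1L) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  true_mu <- vapply(seq_len(nrow(substrates)), function(i) {
    predict_growth_at_uptake(model, substrates$exchange[i], substrates$uptake[i])
  }, numeric(1))
  observed <- pmax(0, true_mu + stats::rnorm(length(true_mu), sd = noise_sd))
  tibble::tibble(substrate = substrates$exchange, uptake = substrates$uptake,
                 true_mu = true_mu, observed_mu = observed)
}
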