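# Biomass construction: monomer fractions, scaling, partitioning, assembly

test_that("monomer fractions follow the weighted-count formula", {
  expect_equal(monomer_fractions_from_sequences(list(list("AAAA", 1)), "protein")[["Ala"]], 1)
  f <- monomer_fractions_from_sequences(list(list("AT", 1), list("GC", 1)), "dna")
  expect_equal(sort(unname(f[c("dA", "dT", "dG", "dC")])), rep(0.25, 4))
  # weighted: 2x AAT + 1x G -> dA 4/7, dT 2/7, dG 1/7
  f2 <- monomer_fractions_from_sequences(list(list("AAT", 2), list("G", 1)), "dna")
  expect_equal(unname(f2[c("dA", "dT", "dG", "dC")]), c(4, 2, 1, 0) / 7)
  expect_equal(sum(f2), 1)
  expect_error(monomer_fractions_from_sequences(list(list("AXT", 1)), "dna"),
               "position 2")
  expect_error(monomer_fractions_from_sequences(list(list("AT", 0)), "dna"),
               "zero")
})

test_that("monomer fractions are invariant under duplication with halved weights", {
  seqs <- list(list("ACGT", 2), list("AAT", 3))
  dup <- list(list("ACGT", 1), list("ACGT", 1), list("AAT", 1.5), list("AAT", 1.5))
  expect_equal(monomer_fractions_from_sequences(dup, "dna"),
               monomer_fractions_from_sequences(seqs, "dna"))
})

test_that("scaling to biomass reproduces the hand-derived coefficients", {
  # single monomer, mass 0.1 g/mmol, full mass in one class -> 10 mmol/gDW
  comp <- biomass_composition(
    macro_fractions = c(protein = 1),
    monomer_fractions = list(protein = c(Ala = 1)),
    monomer_masses = c(Ala = 0.1))
  co <- scale_to_biomass(comp)
  expect_equal(co$coefficient, 10)
  expect_equal(biomass_mass(co, comp$monomer_masses), 1, tolerance = 1e-12)

  # two monomers 0.5/0.5 with masses 0.1/0.3 -> 2.5 each (mass check 1 g)
  comp2 <- biomass_composition(
    macro_fractions = c(protein = 1),
    monomer_fractions = list(protein = c(a = 0.5, b = 0.5)),
    monomer_masses = c(a = 0.1, b = 0.3))
  co2 <- scale_to_biomass(comp2)
  expect_equal(co2$coefficient, c(2.5, 2.5))

  # zero-mass class contributes no rows
  comp3 <- biomass_composition(
    macro_fractions = c(protein = 1, dna = 0),
    monomer_fractions = list(protein = c(a = 1), dna = c(dA = 1)),
    monomer_masses = c(a = 0.1, dA = 0.3))
  expect_false("dna" %in% scale_to_biomass(comp3)$class)
})

test_that("mass closure holds for random compositions", {
  set.seed(5)
  for (i in 1:50) {
    n_cls <- sample(2:5, 1)
    fr <- stats::runif(n_cls); fr <- fr / sum(fr)
    classes <- paste0("cls", seq_len(n_cls))
    monof <- list(); masses <- numeric()
    for (k in seq_len(n_cls)) {
      n_m <- sample(1:6, 1)
      f <- stats::runif(n_m); f <- f / sum(f)
      ids <- paste0("m", k, "_", seq_len(n_m))
      monof[[classes[k]]] <- stats::setNames(f, ids)
      masses[ids] <- stats::runif(n_m, 0.05, 0.5)
    }
    comp <- biomass_composition(stats::setNames(fr, classes), monof, masses)
    co <- scale_to_biomass(comp)
    expect_equal(biomass_mass(co, masses), 1, tolerance = 1e-6)
  }
})

test_that("composition invariants are enforced", {
  expect_error(biomass_composition(c(protein = 0.8),
                                   list(protein = c(a = 1)), c(a = 0.1)),
               "sum to 0.8")
  expect_error(biomass_composition(c(protein = 1),
                                   list(protein = c(a = 0.7, b = 0.2)),
                                   c(a = 0.1, b = 0.1)),
               "monomer fractions")
  expect_error(biomass_composition(c(protein = 1), list(protein = c(a = 1)),
                                   c(a = -1)),
               "positive")
})

test_that("carbohydrate partitioning respects the trehalose:amylose molar ratio", {
  masses <- c(trehalose = 0.2, amylose = 0.2)
  # remainder zero
  p0 <- partition_carbohydrates(0.3, c(glucan = 0.2, mannan = 0.08, chitin = 0.02),
                                1, masses)
  expect_equal(unname(p0[c("trehalose", "amylose")]), c(0, 0))
  # ratio 1 with equal masses splits the remainder evenly
  p1 <- partition_carbohydrates(0.4, c(glucan = 0.2, mannan = 0.08, chitin = 0.02),
                                1, masses)
  expect_equal(unname(p1[c("trehalose", "amylose")]), c(0.05, 0.05))
  expect_equal(sum(p1), 0.4)
  # general ratio: molar ratio of the result matches the input
  masses2 <- c(trehalose = 0.342, amylose = 0.162)
  p2 <- partition_carbohydrates(0.35, c(glucan = 0.2, mannan = 0.05, chitin = 0.01),
                                2.5, masses2)
  expect_equal((p2[["trehalose"]] / 0.342) / (p2[["amylose"]] / 0.162), 2.5)
  expect_error(partition_carbohydrates(0.4, c(glucan = 0.4, mannan = 0.08,
                                              chitin = 0.02), 1, masses),
               "exceeds")
})

test_that("assembled biomass supports growth on the precursor fixture", {
  m <- toy_model("TOY-BIO", biomass = FALSE)
  comp <- read_biomass_composition(
    system.file("extdata", "biomass_composition_synthetic.yaml", package = "gemkit"))
  co <- scale_to_biomass(comp)
  m2 <- assemble_biomass(m, co)
  expect_equal(m2$objective, "BIOMASS")
  sol <- solve_fba(m2)
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
  # re-assembly is idempotent
  m3 <- assemble_biomass(m2, co)
  expect_equal(m3, m2)
  # GAM = 0: no ATP term anywhere in the biomass reaction
  bio <- m2$stoichiometry[m2$stoichiometry$reaction == "BIOMASS", ]
  expect_true(all(grepl("^biomass_", bio$metabolite)))
  expect_error(
    assemble_biomass(m, tibble::tibble(class = "protein", monomer = "nope",
                                       coefficient = 1)),
    "nope")
})

test_that("raising GAM never raises the growth optimum", {
  base <- toy_model("TOY-BIO", biomass = FALSE)
  # give the toy world an ATP cycle: A_c -> atp (capped by carbon), hydrolysis
  base <- add_metabolite(base, "atp_c", "c")
  base <- add_metabolite(base, "adp_c", "c")
  base <- add_metabolite(base, "pi_c", "c")
  base <- add_metabolite(base, "h_c", "c")
  base <- add_metabolite(base, "h2o_c", "c")
  base <- add_reaction(base, "H2O_in", c(h2o_c = 1), lower = 0, upper = 1000)
  base <- add_reaction(base, "ATP_syn", c(A_c = -1, adp_c = -1, pi_c = -1,
                                          atp_c = 1, h2o_c = 1),
                       lower = 0, upper = 1000)
  base <- add_reaction(base, "ADP_seed", c(adp_c = 1, pi_c = 1), lower = 0, upper = 1000)
  base <- add_reaction(base, "H_out", c(h_c = -1), lower = 0, upper = 1000)
  comp <- read_biomass_composition(
    system.file("extdata", "biomass_composition_synthetic.yaml", package = "gemkit"))
  co <- scale_to_biomass(comp)
  atp_ids <- c(atp = "atp_c", h2o = "h2o_c", adp = "adp_c", pi = "pi_c", h = "h_c")
  mus <- vapply(c(0, 5, 20, 60), function(gam) {
    m <- assemble_biomass(base, co, gam = gam, atp = atp_ids)
    solve_fba(m)$objective
  }, numeric(1))
  expect_true(all(diff(mus) <= 1e-9))
  expect_lt(mus[4], mus[1])  # a large GAM must actually cost growth
})

test_that("NGAM is a fixed ATP drain that reduces growth", {
  base <- toy_model("TOY-BIO", biomass = FALSE)
  for (id in c("atp_c", "adp_c", "pi_c", "h_c", "h2o_c"))
    base <- add_metabolite(base, id, "c")
  base <- add_reaction(base, "H2O_in", c(h2o_c = 1), lower = 0, upper = 1000)
  base <- add_reaction(base, "ATP_syn", c(A_c = -1, adp_c = -1, pi_c = -1,
                                          atp_c = 1, h2o_c = 1),
                       lower = 0, upper = 1000)
  base <- add_reaction(base, "ADP_seed", c(adp_c = 1, pi_c = 1), lower = 0, upper = 1000)
  base <- add_reaction(base, "H_out", c(h_c = -1), lower = 0, upper = 1000)
  comp <- read_biomass_composition(
    system.file("extdata", "biomass_composition_synthetic.yaml", package = "gemkit"))
  m <- assemble_biomass(base, scale_to_biomass(comp))
  atp_ids <- c(atp = "atp_c", h2o = "h2o_c", adp = "adp_c", pi = "pi_c", h = "h_c")
  mu0 <- solve_fba(m)$objective
  m2 <- set_ngam(m, 2, atp = atp_ids)
  mu2 <- solve_fba(m2)$objective
  expect_lt(mu2, mu0)
  expect_equal(m2$maintenance$ngam, 2)
})
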