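# Synthetic-data generators: determinism, planted consistency, noise model

test_that("toy model generation is deterministic down to the SBML bytes", {
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(make_toy_model(toy_spec(seed = 7)), f1)
  write_sbml(make_toy_model(toy_spec(seed = 7)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the toy skeleton grows and its optimum matches the stoichiometry", {
  m2 <- make_toy_model(toy_spec(n_compartments = 2, n_pathway_modules = 5))
  # biomass drains 1 A through precursors + 0.02 FAD costing 2 A each
  expect_equal(solve_fba(m2)$objective, 10 / 1.04, tolerance = 1e-9)
  m3 <- make_toy_model(toy_spec(n_compartments = 3))
  expect_equal(solve_fba(m3)$objective, 10 / 1.09, tolerance = 1e-9)
  expect_true("m" %in% m3$compartments$id)
  k7 <- make_toy_model(toy_spec(n_pathway_modules = 7))
  expect_equal(sum(grepl("^R[0-9]+$", k7$reactions$id)), 7)
})

test_that("an inconsistent planted spec is rejected", {
  # gP1 inactive does not break FAD_c -> spec inconsistency must be caught
  spec <- toy_spec(planted_inactive = list(hot = "gP1"),
                   planted_auxotrophies = list(hot = "FAD_c"))
  expect_error(make_toy_model(spec), "still producible")
  expect_error(toy_spec(planted_auxotrophies = list(hot = "FAD_c")),
               "no planted inactive genes")
  expect_error(make_toy_model(toy_spec(planted_inactive = list(x = "nope"))),
               "not in generated model")
})

test_that("planted breaks make their targets non-producible in the condition model", {
  spec <- planted_spec()
  mod <- make_toy_model(spec)
  cm <- derive_condition_model(mod, spec$planted_inactive$static)
  expect_lte(producibility(cm$model, "FAD_c"), 1e-9)
  expect_gt(producibility(mod, "FAD_c"), 0)
})

test_that("generated expression has planted zeros, a near-miss, and seed stability", {
  mod <- make_toy_model(toy_spec())
  planted <- list(c1 = c("gP1", "gRIB3"), c2 = character())
  ex <- make_expression(mod, planted, n_replicates = 3, seed = 21)
  expect_s3_class(ex, "expression_set")
  expect_equal(nrow(ex), 2 * 3 * length(mod$genes))
  # planted genes: all replicates zero
  sub <- ex[ex$condition == "c1" & ex$gene %in% planted$c1, ]
  expect_true(all(sub$value == 0))
  # exactly one near-miss gene with a single zero replicate
  zero_by_gene <- with(ex[ex$condition == "c1" & !ex$gene %in% planted$c1, ],
                       tapply(value == 0, gene, sum))
  expect_equal(sum(zero_by_gene == 1), 1)
  expect_true(all(zero_by_gene %in% c(0, 1)))
  # the near-miss is not called inactive
  expect_identical(call_inactive_genes(ex, "c1"), sort(planted$c1))
  # determinism and single-replicate degeneration
  expect_identical(make_expression(mod, planted, seed = 21), ex)
  ex1 <- make_expression(mod, planted, n_replicates = 1, seed = 3)
  expect_equal(length(unique(ex1$replicate)), 1)
  expect_error(make_expression(mod, planted, n_replicates = 0), "n_replicates")
  expect_error(make_expression(mod, list(c1 = "ghost")), "not in model")
})

test_that("noise-free growth tables give a perfect correlation", {
  t1 <- toy_model("TOY1")
  subs <- tibble::tibble(exchange = "EX_A", uptake = c(2, 4, 6, 8, 10))
  gt <- make_growth_table(t1, subs, noise_sd = 0, seed = 1)
  expect_equal(gt$observed_mu, gt$true_mu)
  cr <- correlation_report(tibble::tibble(observed_mu = gt$observed_mu,
                                          predicted_mu = gt$true_mu))
  expect_equal(cr$r_squared, 1)
  expect_identical(make_growth_table(t1, subs, noise_sd = 0.1, seed = 5),
                   make_growth_table(t1, subs, noise_sd = 0.1, seed = 5))
})

test_that("correlation degrades with the noise level in expectation", {
  t1 <- toy_model("TOY1")
  subs <- tibble::tibble(exchange = "EX_A", uptake = c(1, 3, 5, 7, 9))
  mean_r2 <- function(noise_sd) {
    r2 <- vapply(1:50, function(seed) {
      gt <- make_growth_table(t1, subs, noise_sd = noise_sd, seed = seed)
      correlation_report(tibble::tibble(observed_mu = gt$observed_mu,
                                        predicted_mu = gt$true_mu))$r_squared
    }, numeric(1))
    mean(r2)
  }
  r2s <- vapply(c(0, 1, 4), mean_r2, numeric(1))
  expect_true(all(diff(r2s) < 0))
  expect_equal(r2s[1], 1)
})

test_that("generated models pass the structural invariants and round-trip", {
  for (seed in c(1, 2, 3)) {
    m <- random_toy_model(seed)
    expect_no_error(validate_gem(m))
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, f)
    expect_equal(read_sbml(f), m)
  }
  m <- make_toy_model(toy_spec(n_compartments = 3))
  expect_no_error(validate_gem(m))
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  expect_equal(read_sbml(f), m)
})
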