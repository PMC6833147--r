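# Condition-specific model extraction, auxotrophy detection and rescue

test_that("inactive-gene calling requires all replicates present and zero", {
  ex <- expression_set(tibble::tibble(
    gene = c(rep("gz", 3), rep("gmix", 3), rep("gpos", 3), "gshort"),
    condition = "30D",
    replicate = c(1:3, 1:3, 1:3, 1),
    value = c(0, 0, 0, 0, 5, 0, 2, 1, 4, 0)))
  inact <- call_inactive_genes(ex, "30D")
  expect_equal(inact, "gz")               # all three replicates zero
  expect_false("gmix" %in% inact)         # one positive replicate
  expect_false("gshort" %in% inact)       # missing replicates = no evidence
  expect_error(call_inactive_genes(ex, "45D"), "unknown condition")
})

test_that("deactivation follows the GPR and closes growth when the pathway dies", {
  t1 <- toy_model("TOY1")
  cm <- derive_condition_model(t1, "g2", condition = "hot")
  expect_equal(cm$deactivated_reactions, "R1")  # R1 needs g2 and g3
  expect_equal(solve_fba(cm$model)$objective, 0, tolerance = 1e-9)
  rl <- cm$model$reactions
  expect_equal(rl$lower_bound[rl$id == "R1"], 0)
  expect_equal(rl$upper_bound[rl$id == "R1"], 0)
  # all other constraints untouched
  expect_equal(rl[rl$id != "R1", ], t1$reactions[t1$reactions$id != "R1", ])

  expect_equal(derive_condition_model(t1, character())$model, t1)
  expect_equal(derive_condition_model(t1, "not_a_gene")$model, t1)
  # isoenzyme: knocking one OR branch keeps the reaction
  m <- t1
  m$genes <- c(m$genes, "g4")
  m$reactions$gpr[m$reactions$id == "R1"] <- "(g2 and g3) or g4"
  expect_equal(derive_condition_model(m, "g2")$deactivated_reactions, character())
})

test_that("condition-model growth never exceeds the base optimum", {
  mod <- make_toy_model(toy_spec())
  mu0 <- solve_fba(mod)$objective
  set.seed(31)
  for (i in 1:15) {
    inact <- sample(mod$genes, sample(0:4, 1))
    cm <- derive_condition_model(mod, inact)
    sol <- solve_fba(cm$model)
    expect_lte(sol$objective, mu0 + 1e-9)
  }
})

test_that("deactivation is monotone in the inactive gene set", {
  mod <- make_toy_model(toy_spec())
  set.seed(13)
  for (i in 1:15) {
    a <- sample(mod$genes, sample(1:3, 1))
    b <- union(a, sample(mod$genes, sample(1:3, 1)))
    da <- derive_condition_model(mod, a)$deactivated_reactions
    db <- derive_condition_model(mod, b)$deactivated_reactions
    expect_true(all(da %in% db))
  }
})

test_that("planted auxotrophies are detected and rescued, restoring growth", {
  spec <- planted_spec()
  mod <- make_toy_model(spec)
  comps <- c(paste0("P", 1:5, "_c"), "FAD_c")
  for (cond in c("static", "hot")) {
    cm <- derive_condition_model(mod, spec$planted_inactive[[cond]], cond)
    expect_equal(solve_fba(cm$model)$objective, 0, tolerance = 1e-9)
    aux <- detect_auxotrophies(cm, comps)
    expect_equal(aux, sort(spec$planted_auxotrophies[[cond]]))
    cm2 <- rescue_auxotrophies(cm, aux)
    expect_gt(solve_fba(cm2$model)$objective, 0)
    expect_equal(cm2$rescued_metabolites, sort(aux))
    # idempotent; rescuing nothing is the identity
    expect_equal(rescue_auxotrophies(cm2, aux), cm2)
    expect_equal(rescue_auxotrophies(cm, character()), cm)
  }
  # the unstressed condition has no auxotrophy
  cm0 <- derive_condition_model(mod, character(), "cool")
  expect_equal(detect_auxotrophies(cm0, comps), character())
})

test_that("with every gene off, all gene-dependent components are flagged", {
  mod <- make_toy_model(toy_spec())
  cm <- derive_condition_model(mod, mod$genes)
  comps <- c(paste0("P", 1:5, "_c"), "FAD_c")
  expect_equal(detect_auxotrophies(cm, comps), sort(comps))
})

test_that("planted inactive sets are recovered exactly from generated expression data", {
  mod <- make_toy_model(toy_spec())
  for (seed in 1:100) {
    set.seed(seed * 3 + 1)
    planted <- list(
      c1 = sample(mod$genes, sample(0:5, 1)),
      c2 = sample(mod$genes, sample(0:5, 1)))
    ex <- make_expression(mod, planted, n_replicates = 3, seed = seed)
    for (cond in names(planted)) {
      expect_identical(call_inactive_genes(ex, cond), sort(planted[[cond]]))
    }
    # "inactive in at least one condition" equals the union of the calls
    expect_identical(inactive_in_any_condition(ex),
                     sort(unique(unlist(planted))))
  }
})

test_that("a four-condition union includes conditions excluded from modelling", {
  mod <- make_toy_model(toy_spec())
  planted <- list(`30D` = "gP1", `30DS` = "gP2", `30X` = c("gP3", "gRIB4"),
                  `45D` = "gRIB3")
  ex <- make_expression(mod, planted, seed = 4)
  expect_identical(inactive_in_any_condition(ex),
                   sort(c("gP1", "gP2", "gP3", "gRIB3", "gRIB4")))
  # modelling can still use only three of them
  expect_identical(inactive_in_any_condition(ex, c("30D", "30DS", "45D")),
                   sort(c("gP1", "gP2", "gRIB3")))
})

test_that("condition report reproduces planted inactive-gene counts", {
  mod <- make_toy_model(toy_spec())
  planted <- list(a = c("gP1", "gP2", "gP3", "gGTP", "gRU5P"),
                  b = c("gRIB3", "gFMN1"), c = "gFAD1")
  ex <- make_expression(mod, planted, seed = 9)
  cms <- lapply(names(planted), function(cond) {
    cm <- derive_condition_model(mod, call_inactive_genes(ex, cond), cond)
    aux <- detect_auxotrophies(cm, c(paste0("P", 1:5, "_c"), "FAD_c"))
    if (length(aux)) cm <- rescue_auxotrophies(cm, aux) else cm
  })
  rep <- condition_report(cms, growth_fraction = 0.9)
  expect_equal(rep$n_inactive_genes, c(5, 2, 1))
  expect_equal(rep$condition, c("a", "b", "c"))
  expect_true(all(rep$mu_max > 0))
  expect_true(all(rep$n_zero_flux >= 0))
  # identical conditions give identical rows
  cm_dup <- derive_condition_model(mod, "gP1", "x")
  rep2 <- condition_report(list(cm_dup, cm_dup), growth_fraction = 0.9)
  expect_equal(rep2[1, -1], rep2[2, -1])
  # empty input gives an empty table
  expect_equal(nrow(condition_report(list())), 0)
})

test_that("the growth-limiting exchange is found by reduced cost", {
  t1 <- toy_model("TOY1")
  cm <- derive_condition_model(t1, character(), "base")
  rep <- condition_report(list(cm))
  expect_equal(rep$limiting_exchange, "EX_A")
  expect_equal(abs(rep$limiting_reduced_cost), 1, tolerance = 1e-9)
})
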