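# FBA engine: optima, duals, FVA, producibility, zero-flux classification

test_that("TOY1 FBA reproduces the hand-solved LP", {
  t1 <- toy_model("TOY1")
  sol <- solve_fba(t1)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[c("EX_A", "T_A", "R1", "GROWTH")]),
               c(-10, 10, 10, 10), tolerance = 1e-9)
  expect_flux_solution_consistent(t1, sol)
  # growth is limited by the uptake bound: reduced cost d(obj)/d(lb) = -1
  expect_equal(unname(sol$reduced_costs["EX_A"]), -1, tolerance = 1e-9)
  # interior reactions carry zero reduced cost
  expect_equal(unname(sol$reduced_costs["R1"]), 0, tolerance = 1e-9)
})

test_that("closed medium, unbounded and infeasible cases are reported in status", {
  t1 <- toy_model("TOY1")
  closed <- apply_medium(t1, medium("closed", list()))
  expect_equal(solve_fba(closed)$objective, 0, tolerance = 1e-9)

  unb <- t1
  unb$reactions$lower_bound[unb$reactions$id == "EX_A"] <- -Inf
  unb$reactions$upper_bound <- Inf
  expect_equal(solve_fba(unb)$status, "unbounded")

  inf <- set_bounds(apply_medium(t1, medium("closed", list())), "GROWTH", lower = 1)
  expect_equal(solve_fba(inf)$status, "infeasible")
})

test_that("strong duality holds at the optimum", {
  # c'x = y'b + sum over bound-binding nonbasic vars of d_j x_j; with b = 0
  # the objective must equal the reduced-cost/bound inner product.
  for (seed in c(3, 17, 42)) {
    m <- random_toy_model(seed)
    sol <- solve_fba(m)
    expect_equal(sol$status, "optimal")
    dual_obj <- sum(sol$reduced_costs * sol$fluxes[names(sol$reduced_costs)])
    expect_equal(sol$objective, dual_obj, tolerance = 1e-6)
  }
})

test_that("FVA pins the unique pathway at full growth and relaxing the fraction widens intervals", {
  t1 <- toy_model("TOY1")
  fva1 <- flux_variability(t1, growth_fraction = 1)
  expect_equal(fva1$min[fva1$reaction == "T_A"], 10, tolerance = 1e-7)
  expect_equal(fva1$max[fva1$reaction == "T_A"], 10, tolerance = 1e-7)

  fva0 <- flux_variability(t1, growth_fraction = 0)
  merged <- merge(fva0, fva1, by = "reaction", suffixes = c("_0", "_1"))
  expect_true(all(merged$min_0 <= merged$min_1 + 1e-7))
  expect_true(all(merged$max_0 >= merged$max_1 - 1e-7))

  # intermediate fraction keeps nesting (monotonicity in the fraction)
  fva5 <- flux_variability(t1, growth_fraction = 0.5)
  m2 <- merge(fva5, fva1, by = "reaction", suffixes = c("_5", "_1"))
  expect_true(all(m2$min_5 <= m2$min_1 + 1e-7))
  expect_true(all(m2$max_5 >= m2$max_1 - 1e-7))
})

test_that("an isolated reversible 2-cycle spans its bounds at fraction 0", {
  t1 <- toy_model("TOY1")
  m <- add_metabolite(t1, "C_c", "c")
  m <- add_metabolite(m, "D_c", "c")
  m <- add_reaction(m, "LOOP1", c(C_c = -1, D_c = 1), lower = -1000, upper = 1000)
  m <- add_reaction(m, "LOOP2", c(D_c = -1, C_c = 1), lower = -1000, upper = 1000)
  fva <- flux_variability(m, reactions = c("LOOP1", "LOOP2"), growth_fraction = 0)
  expect_equal(fva$min, c(-1000, -1000))
  expect_equal(fva$max, c(1000, 1000))
})

test_that("zero-flux classification finds disconnected and starved reactions", {
  t1 <- toy_model("TOY1")
  m <- add_metabolite(t1, "Z_c", "c")
  m <- add_metabolite(m, "Z2_c", "c")
  m <- add_reaction(m, "R_dead", c(Z_c = -1, Z2_c = 1), lower = 0, upper = 1000)
  for (f in c(0, 0.5, 1)) {
    expect_true("R_dead" %in% zero_flux_reactions(m, growth_fraction = f))
  }
  expect_equal(zero_flux_reactions(t1, growth_fraction = 0), character())
  # closed medium pins every mass-moving reaction to zero
  closed <- apply_medium(t1, medium("closed", list()))
  expect_equal(zero_flux_reactions(closed, growth_fraction = 0),
               sort(t1$reactions$id))
})

test_that("demand reactions are idempotent and drive producibility", {
  t1 <- toy_model("TOY1")
  d1 <- add_demand(t1, "B_c")
  d2 <- add_demand(d1$model, "B_c")
  expect_equal(d1$reaction, "DM_B_c")
  expect_equal(d2$reaction, "DM_B_c")
  expect_equal(nrow(d2$model$reactions), nrow(d1$model$reactions))
  expect_error(add_demand(t1, "XYZ"), "unknown metabolite")

  expect_equal(producibility(t1, "B_c"), 10, tolerance = 1e-9)
  expect_equal(producibility(remove_reactions(t1, "R1"), "B_c"), 0, tolerance = 1e-9)
  # extracellular A_e can only come from the exchange: capped by the uptake bound
  expect_equal(producibility(t1, "A_e"), 10, tolerance = 1e-9)
})

test_that("reduced costs match finite-difference slopes at binding bounds", {
  t1 <- toy_model("TOY1")
  fd <- finite_difference_check(t1, exchange = "EX_A", delta = -1)
  expect_equal(fd$bound, "lower")
  expect_equal(fd$reduced_cost, -1, tolerance = 1e-9)
  expect_equal(fd$slope, -1, tolerance = 1e-9)
  expect_equal(abs(fd$reduced_cost), abs(fd$slope), tolerance = 1e-9)

  # non-binding bound: reduced cost 0
  fd2 <- finite_difference_check(t1, exchange = "R1")
  expect_equal(fd2$bound, "interior")
  expect_equal(fd2$reduced_cost, 0, tolerance = 1e-9)

  # a perturbation large enough to cross a basis change makes the empirical
  # slope an average over bases: uptake bound relaxed past the downstream cap
  m <- set_bounds(t1, "R1", upper = 12)
  fd3 <- finite_difference_check(m, exchange = "EX_A", delta = -10)
  expect_equal(fd3$reduced_cost, -1, tolerance = 1e-9)
  expect_equal(fd3$slope, -0.2, tolerance = 1e-9)  # only 2 of 10 extra units usable
  expect_false(isTRUE(all.equal(fd3$reduced_cost, fd3$slope)))
})

test_that("every optimal solution satisfies mass balance and bounds", {
  for (seed in 1:12) {
    m <- random_toy_model(seed)
    sol <- solve_fba(m)
    expect_equal(sol$status, "optimal")
    expect_flux_solution_consistent(m, sol)
  }
})
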