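# Surplus production capacity at fixed fractional growth

test_that("TOY-BIO surplus matches the hand LP at the reference fractions", {
  tb <- toy_model("TOY-BIO")
  # at 90% of mu_max = 10, 10% of the 10 mmol/h carbon inflow is free
  expect_equal(surplus_capacity(tb, "P1_c", 0.9), 1, tolerance = 1e-7)
  # at the optimum every precursor is fully consumed
  expect_equal(surplus_capacity(tb, "P1_c", 1), 0, tolerance = 1e-7)
  # with growth off the surplus is the plain producibility
  expect_equal(surplus_capacity(tb, "P1_c", 0), producibility(tb, "P1_c"),
               tolerance = 1e-7)
  expect_error(
    surplus_capacity(apply_medium(tb, medium("closed", list())), "P1_c", 0.9),
    "no growth")
})

test_that("surplus is non-increasing in the growth fraction", {
  for (m in list(toy_model("TOY-BIO"), make_toy_model(toy_spec()))) {
    for (met in c("P1_c", "P3_c")) {
      vals <- vapply(c(0, 0.25, 0.5, 0.75, 0.9, 1),
                     function(f) surplus_capacity(m, met, f), numeric(1))
      expect_true(all(diff(vals) <= 1e-7))
    }
  }
})

test_that("a condition model never out-produces its base model", {
  mod <- make_toy_model(toy_spec())
  cm <- derive_condition_model(mod, "gGTP")
  cm <- rescue_auxotrophies(cm, detect_auxotrophies(cm, "FAD_c"))
  for (met in c("P1_c", "P4_c")) {
    expect_lte(surplus_capacity(cm, met, 0.9),
               surplus_capacity(mod, met, 0.9) + 1e-7)
  }
})

test_that("relative normalisation: max condition = 100%, all-zero stays 0, scale-invariant", {
  tb <- toy_model("TOY-BIO")
  half <- set_bounds(tb, "EX_A", lower = -5)   # half the carbon
  st <- surplus_table(list(full = tb, half = half), c("P1_c", "P2_c"), 0.9)
  expect_s3_class(st, "surplus_table")
  expect_true(all(st$relative >= 0 & st$relative <= 100))
  for (met in c("P1_c", "P2_c")) {
    sub <- st[st$metabolite == met, ]
    expect_equal(max(sub$relative), 100)
    expect_equal(sub$relative[sub$condition == "full"], 100)
    expect_equal(sub$relative[sub$condition == "half"], 50, tolerance = 1e-6)
    # relative = 100 * absolute / max(absolute): scale invariance by construction
    expect_equal(sub$relative, 100 * sub$absolute / max(sub$absolute))
  }
})

test_that("surplus handles per-cell failure and the all-zero component", {
  tb <- toy_model("TOY-BIO")
  dead <- apply_medium(tb, medium("closed", list()))
  st <- surplus_table(list(ok = tb, dead = dead), "P1_c", 0.9)
  expect_true(is.na(st$absolute[st$condition == "dead"]))
  expect_match(st$note[st$condition == "dead"], "no growth")
  expect_equal(st$relative[st$condition == "ok"], 100)

  # a metabolite no condition can produce: relative 0 everywhere
  noP1 <- remove_reactions(tb, "R1")
  noP1$reactions$upper_bound[noP1$reactions$id == "BIOMASS"] <- 1000
  # keep growth possible by relaxing biomass to the other precursors
  noP1$stoichiometry <- noP1$stoichiometry[
    !(noP1$stoichiometry$reaction == "BIOMASS" &
        noP1$stoichiometry$metabolite == "P1_c"), ]
  st2 <- surplus_table(list(a = noP1, b = noP1), "P1_c", 0.9)
  expect_equal(st2$relative, c(0, 0))
})

test_that("the planted broken pathway shows 0% relative surplus in its condition", {
  spec <- planted_spec()
  mod <- make_toy_model(spec)
  comps <- c(paste0("P", 1:5, "_c"), "FAD_c")
  cms <- lapply(c("cool", "static", "hot"), function(cond) {
    cm <- derive_condition_model(mod, spec$planted_inactive[[cond]], cond)
    aux <- detect_auxotrophies(cm, comps)
    if (length(aux)) cm <- rescue_auxotrophies(cm, aux)
    cm
  })
  st <- surplus_table(cms, comps, 0.9)
  broken_hot <- st[st$condition == "hot" & st$metabolite %in% c("P1_c", "FAD_c"), ]
  expect_equal(broken_hot$absolute, c(0, 0))
  expect_equal(broken_hot$relative, c(0, 0))
  broken_static <- st[st$condition == "static" & st$metabolite == "FAD_c", ]
  expect_equal(broken_static$relative, 0)
  # the intact condition holds the 100% reference for those components
  expect_equal(st$relative[st$condition == "cool" & st$metabolite == "P1_c"], 100)
  expect_equal(st$relative[st$condition == "cool" & st$metabolite == "FAD_c"], 100)
})

test_that("autoplot renders a radar chart without error", {
  tb <- toy_model("TOY-BIO")
  st <- surplus_table(list(full = tb), c("P1_c", "P2_c"), 0.9)
  p <- ggplot2::ggplot_build(autoplot(st))
  expect_true(length(p$data) > 0)
})
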