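test_that("ideal solubility matches its closed form and limits", {
  db <- test_db()
  na_melt <- db$melting[["NA"]]
  sa_melt <- db$melting[["SA"]]
  # exponent vanishes at the melting point
  expect_equal(ideal_solubility(na_melt, 401.15), 1)
  expect_equal(ideal_solubility(sa_melt, 461.15), 1)
  # frozen values from direct high-precision evaluation of the closed form
  expect_equal(ideal_solubility(na_melt, 298.15), 0.0348, tolerance = 2e-3)
  expect_equal(ideal_solubility(sa_melt, 298.15), 1.54e-3, tolerance = 2e-3)
  # solid does not exist above the melting point
  expect_error(ideal_solubility(na_melt, 410), class = "cocrysol_domain_error")
  # strictly increasing in temperature up to the melting point
  Ts <- seq(250, 401.15, length.out = 40)
  expect_true(all(diff(ideal_solubility(na_melt, Ts)) > 0))
})

test_that("saturation solver reduces to the ideal law when gamma is 1", {
  # solute dissolved in a "solvent" with identical parameters and kij = 0:
  # indistinguishability forces gamma = 1 and x = x_ideal
  db <- ideal_system_db()
  pt <- solve_solubility("api_x", c(solv_x = 1), 298.15, db)
  expect_equal(pt$gamma_solute, 1, tolerance = 1e-7)
  expect_equal(pt$x_solute, pt$x_ideal, tolerance = 1e-6)
})

test_that("converged points satisfy the equilibrium residual contract", {
  db <- test_db()
  for (cfg in list(list("NA", c(ethanol = 1)),
                   list("SA", c(ethanol = 0.5, water = 0.5)))) {
    pt <- solve_solubility(cfg[[1]], cfg[[2]], 298.15, db)
    expect_equal(pt$status, "converged")
    # re-evaluate gamma at the solution: ln(x gamma) must equal ln(x_ideal)
    comp <- cocrysol:::full_composition(db, cfg[[1]], pt$x_solute, cfg[[2]])
    g <- activity_coefficients(
      mixture_state(comp$component_ids, comp$mole_fractions, 298.15), db)
    resid <- log(pt$x_solute * g[[cfg[[1]]]]) - log(pt$x_ideal)
    expect_lt(abs(resid), 1e-7)
  }
})

test_that("solubility lines are endpoint-consistent and refinable", {
  db <- test_db()
  grid <- c(0, 0.5, 1)
  line <- solubility_line_vs_solvent_ratio("NA", c("ethanol", "water"),
                                           grid, 298.15, db)
  expect_equal(nrow(line), 3)
  expect_true(all(line$status == "converged"))
  pure_w <- solve_solubility("NA", c(water = 1), 298.15, db)$x_solute
  pure_e <- solve_solubility("NA", c(ethanol = 1), 298.15, db)$x_solute
  expect_equal(line$x_solute[line$w_first == 0], pure_w, tolerance = 1e-9)
  expect_equal(line$x_solute[line$w_first == 1], pure_e, tolerance = 1e-9)
  # grid refinement does not move shared nodes (grid independence)
  line2 <- solubility_line_vs_solvent_ratio("NA", c("ethanol", "water"),
                                            seq(0, 1, 0.25), 298.15, db)
  expect_equal(line2$x_solute[line2$w_first %in% grid], line$x_solute,
               tolerance = 1e-8)
})

test_that("cosolute-free record equals the single-solute solubility", {
  db <- test_db()
  base <- solve_solubility("SA", c(ethanol = 1), 298.15, db)
  line <- api_or_cf_line_with_cosolute("SA", "NA", c(0, 0.005),
                                       c(ethanol = 1), 298.15, db)
  expect_equal(line$x_solute[1], base$x_solute, tolerance = 1e-9)
  # with a real mixture, a small amount of the partner changes gamma
  expect_false(isTRUE(all.equal(line$x_solute[2], line$x_solute[1],
                                tolerance = 1e-4)))
  # with ideal gamma the cosolute has no effect at all
  dbi <- ideal_system_db()
  li <- api_or_cf_line_with_cosolute("api_x", "cf_x", c(0, 0.002, 0.004),
                                     c(solv_x = 1), 298.15, dbi)
  expect_lt(diff(range(li$x_solute)) / li$x_solute[1], 1e-5)
})
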