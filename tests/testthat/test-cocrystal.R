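test_that("solubility products follow their defining algebra", {
  expect_equal(ks_from_point(0.01, 0.004, 1, 1, 2, 1), 4e-7)
  expect_equal(ks_ideal_from_point(0.01, 0.004, 2, 1), 4e-7)
  # ratio of the two conventions is the gamma product
  g_api <- 1.7; g_cf <- 0.6
  full <- ks_from_point(0.01, 0.004, g_api, g_cf, 2, 1)
  idl <- ks_ideal_from_point(0.01, 0.004, 2, 1)
  expect_equal(full / idl, g_api^2 * g_cf)
})

test_that("Gibbs-Helmholtz scaling is exact at the reference and invertible", {
  db <- test_db()
  cc <- db$cocrystals[[1]]
  expect_equal(ks_at_temperature(cc, cc$t_ref), cc$ks_ref)
  # up-then-down extrapolation returns the reference to machine precision
  cc_hot <- cc
  cc_hot$ks_ref <- ks_at_temperature(cc, 340)
  cc_hot$t_ref <- 340
  expect_equal(ks_at_temperature(cc_hot, 298.15), cc$ks_ref,
               tolerance = 1e-14)
  # monotone increasing for a positive reference enthalpy
  Ts <- seq(280, 340, by = 5)
  expect_true(all(diff(ks_at_temperature(cc, Ts)) > 0))
})

test_that("ideal cocrystal line reduces to its closed form", {
  db <- ideal_system_db()
  cc <- ideal_cc(ks_ref = 4e-6)
  line <- cc_solubility_line(cc, c(solv_x = 1), 298.15, db,
                             ratio_grid = c(0.5, 1, 2, 5))
  # gamma = 1 throughout, so x_api^2 x_cf = Ks on every node
  expect_lt(max(abs(line$gamma_api - 1)), 1e-6)
  expect_lt(max(abs(line$x_api^2 * line$x_cf / 4e-6 - 1)), 1e-6)
  # r = 2 closed form: (2s)^2 s = Ks
  s <- line$x_cf[line$ratio == 2]
  expect_equal(s, (4e-6 / 4)^(1 / 3), tolerance = 1e-6)
})

test_that("cocrystal line points reproduce Ks independent of solvent", {
  db <- test_db()
  cc <- db$cocrystals[[1]]
  ks <- ks_at_temperature(cc, 298.15)
  for (sv in list(c(ethanol = 1), c(ethanol = 0.5, water = 0.5))) {
    line <- cc_solubility_line(cc, sv, 298.15, db,
                               ratio_grid = c(0.5, 2, 8))
    ks_back <- ks_from_point(line$x_api, line$x_cf, line$gamma_api,
                             line$gamma_cf, cc$nu_api, cc$nu_cf)
    expect_lt(max(abs(ks_back / ks - 1)), 1e-6)
  }
})

test_that("eutectic location matches the ideal-system closed form", {
  db <- ideal_system_db()
  cc <- ideal_cc(ks_ref = 1e-5)
  sv <- c(solv_x = 1)
  api_line <- api_or_cf_line_with_cosolute(
    "api_x", "cf_x", seq(0.001, 0.01, length.out = 8), sv, 298.15, db)
  cc_line <- cc_solubility_line(cc, sv, 298.15, db,
                                ratio_grid = exp(seq(log(0.5), log(50),
                                                     length.out = 12)))
  eu <- locate_eutectic(api_line, cc_line, db)
  expect_false(is.null(eu))
  expect_true(eu$converged)
  # ideal closed form: x_api = x_ideal(api), x_cf = Ks / x_api^2
  x_id <- ideal_solubility(db$melting$api_x, 298.15)
  expect_equal(eu$x_api, x_id, tolerance = 1e-5)
  expect_equal(eu$x_cf, 1e-5 / x_id^2, tolerance = 1e-4)
  # argument order does not matter
  eu2 <- locate_eutectic(cc_line, api_line, db)
  expect_equal(eu2$x_api, eu$x_api, tolerance = 1e-8)
  expect_equal(eu2$x_cf, eu$x_cf, tolerance = 1e-8)
})

test_that("phase diagram assembly is internally consistent", {
  db <- test_db()
  cc <- db$cocrystals[[1]]
  pd <- cached("pd_ew", build_phase_diagram(
    cc, c(ethanol = 0.5, water = 0.5), 298.15, db, n_cosolute = 6,
    ratio_grid = exp(seq(log(0.05), log(20), length.out = 13))))
  # branch endpoints reconcile with the single-solute solubilities
  expect_equal(pd$api_line$x_api[1], pd$sat_api$x_solute, tolerance = 1e-9)
  expect_equal(pd$cf_line$x_cf[1], pd$sat_cf$x_solute, tolerance = 1e-9)
  # each eutectic satisfies both parent equilibria
  for (eu in list(pd$eutectic_api_cc, pd$eutectic_cf_cc)) {
    expect_false(is.null(eu))
    expect_lt(max(abs(eu$residuals)), 1e-6)
  }
  # the cocrystal branch lies between the eutectics
  expect_true(all(pd$cc_line$x_api <= pd$eutectic_api_cc$x_api + 1e-12))
  expect_true(all(pd$cc_line$x_cf <= pd$eutectic_cf_cc$x_cf + 1e-12))
  # every point on the kept cocrystal branch still satisfies Ks
  ks_back <- ks_from_point(pd$cc_line$x_api, pd$cc_line$x_cf,
                           pd$cc_line$gamma_api, pd$cc_line$gamma_cf,
                           cc$nu_api, cc$nu_cf)
  expect_lt(max(abs(ks_back / pd$ks_used - 1)), 1e-6)
})
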