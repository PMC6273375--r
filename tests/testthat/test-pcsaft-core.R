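test_that("combining rules match their closed forms and are symmetric", {
  expect_equal(combine_sigma(3.1771, 3.3079), 3.2425)
  expect_equal(combine_sigma(2.9, 2.9), 2.9)
  expect_equal(combine_sigma(2.1, 3.4), combine_sigma(3.4, 2.1))
  expect_equal(combine_u(198.24, 353.94, 0), sqrt(198.24 * 353.94))
  expect_equal(combine_u(198.24, 353.94, 0), 264.9, tolerance = 1e-3)
  expect_equal(combine_u(198.24, 353.94, -0.0382),
               1.0382 * sqrt(198.24 * 353.94))
  expect_equal(combine_u(200, 300, 1), 0)
  expect_equal(combine_u(198.24, 353.94, 0.1), combine_u(353.94, 198.24, 0.1))
})

test_that("cross-association follows the Wolbach-Sandler rules", {
  db <- test_db()
  eth <- db$components$ethanol
  # self-combination returns the pure-component values exactly
  self <- combine_association(eth, eth)
  expect_equal(self$eps_AiBj, eth$assoc_energy)
  expect_equal(self$kappa_AiBj, eth$assoc_volume)
  # induced partner: energy is half the self-association energy
  acn <- db$components$acetonitrile
  cross <- combine_association(eth, acn)
  expect_equal(cross$eps_AiBj, 2653.4 / 2)
  s_fac <- (sqrt(3.1771 * 3.1898) / ((3.1771 + 3.1898) / 2))^3
  expect_equal(cross$kappa_AiBj, sqrt(0.03284 * 0.01) * s_fac)
  # equal diameters: volume rule reduces to the plain geometric mean
  na_ <- db$components[["NA"]]
  fake <- na_; fake$assoc_volume <- 0.05
  expect_equal(combine_association(na_, fake)$kappa_AiBj,
               sqrt(na_$assoc_volume * fake$assoc_volume))
  bare <- acn
  bare$n_donor_sites <- 0L; bare$n_acceptor_sites <- 0L
  expect_error(combine_association(bare, bare), "association sites")
})

test_that("residual Helmholtz contributions are additive and behave at limits", {
  db <- test_db()
  # pure induced associator alone: no partner, zero association term
  st <- mixture_state("ethyl_acetate", 1, 298.15)
  es <- residual_helmholtz(st, 0.38, db)
  hc <- es$helmholtz_contributions
  expect_equal(hc[["association"]], 0)
  expect_equal(hc[["residual"]],
               hc[["hard_chain"]] + hc[["dispersion"]] + hc[["association"]])
  # associating liquid: all contributions finite, bonding lowers energy
  st2 <- mixture_state("ethanol", 1, 298.15)
  es2 <- residual_helmholtz(st2, 0.45, db)
  hc2 <- es2$helmholtz_contributions
  expect_true(all(is.finite(hc2)))
  expect_lt(hc2[["association"]], 0)
  expect_equal(hc2[["residual"]], sum(hc2[1:3]))
  # ternary associating mixture: additivity to machine precision
  st3 <- mixture_state(c("NA", "ethanol", "water"), c(0.05, 0.45, 0.5),
                       310.15)
  hc3 <- residual_helmholtz(st3, 0.42, db)$helmholtz_contributions
  expect_equal(hc3[["residual"]], sum(hc3[1:3]), tolerance = 1e-14)
})

test_that("association fractions solve the Wertheim mass balance", {
  db <- test_db()
  # 1-donor/1-acceptor pure fluid: scalar quadratic closed form
  sys <- cocrysol:::pcsaft_system(db, "ethanol", 298.15)
  es <- solve_density(mixture_state("ethanol", 1, 298.15), db)
  eta <- es$packing_fraction
  rho <- cocrysol:::rho_from_eta(sys, 1, eta)
  ev <- cocrysol:::eos_eval(sys, 1, rho)
  om <- 1 - eta
  z2 <- pi / 6 * rho * sys$m * sys$d^2
  cpar <- sys$d / 2
  gii <- 1 / om + cpar * 3 * z2 / om^2 + cpar^2 * 2 * z2^2 / om^3
  Delta <- sys$assoc_pref[1, 1] * gii
  X_closed <- (-1 + sqrt(1 + 4 * rho * Delta)) / (2 * rho * Delta)
  expect_equal(ev$XD[1], X_closed, tolerance = 1e-10)
  # symmetric site inventory: donor and acceptor fractions coincide
  expect_equal(ev$XD, ev$XA, tolerance = 1e-12)
  # zero association strength: all sites unbonded (pure induced fluid)
  sys0 <- cocrysol:::pcsaft_system(db, "acetonitrile", 298.15)
  ev0 <- cocrysol:::eos_eval(sys0, 1, rho * 0.8)
  expect_equal(ev0$XD, 1)
  expect_equal(ev0$XA, 1)
  # unbonded fractions in (0, 1], non-increasing with density
  etas <- seq(0.05, 0.5, by = 0.05)
  xs <- vapply(etas, function(e) {
    cocrysol:::eos_eval(sys, 1, cocrysol:::rho_from_eta(sys, 1, e))$XD[1]
  }, 0)
  expect_true(all(xs > 0 & xs <= 1))
  expect_true(all(diff(xs) <= 0))
})

test_that("analytic derivatives agree with finite differences", {
  db <- test_db()
  sys <- cocrysol:::pcsaft_system(db, c("SA", "ethanol", "ethyl_acetate"),
                                  298.15)
  x <- c(0.04, 0.48, 0.48)
  rho <- cocrysol:::rho_from_eta(sys, x, 0.41)
  ev <- cocrysol:::eos_eval(sys, x, rho)
  h <- 1e-6
  fd_rho <- (cocrysol:::eos_eval(sys, x, rho * (1 + h))$a_res -
               cocrysol:::eos_eval(sys, x, rho * (1 - h))$a_res) /
    (2 * rho * h)
  expect_equal(ev$dadrho, fd_rho, tolerance = 1e-6)
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    fd <- (cocrysol:::eos_eval(sys, xp, rho)$a_res -
             cocrysol:::eos_eval(sys, xm, rho)$a_res) / (2 * h)
    expect_equal(ev$dadx[k], fd, tolerance = 1e-6)
  }
})

test_that("density solver honors its pressure and phase contracts", {
  db <- test_db()
  st <- mixture_state(c("ethanol", "water"), c(0.4, 0.6), 298.15)
  es <- solve_density(st, db, "liquid")
  expect_lt(abs(es$pressure - st$pressure) / st$pressure, 1e-9)
  # subcritical pure fluid: liquid root denser than vapor root
  stp <- mixture_state("ethanol", 1, 298.15)
  eliq <- solve_density(stp, db, "liquid")
  evap <- solve_density(stp, db, "vapor")
  expect_gt(eliq$packing_fraction, evap$packing_fraction)
  expect_lt(abs(evap$pressure - stp$pressure) / stp$pressure, 1e-9)
  # coarse realism bound for water with these parameters
  stw <- mixture_state("water", 1, 298.15)
  rho_mass <- solve_density(stw, db)$molar_density * 18.015 / 1000
  expect_lt(abs(rho_mass - 997) / 997, 0.15)
})

test_that("activity coefficients satisfy thermodynamic limits", {
  db <- test_db()
  # pure-component limit
  st <- mixture_state(c("ethanol", "water"), c(1 - 1e-9, 1e-9), 298.15)
  expect_equal(unname(activity_coefficients(st, db)[1]), 1,
               tolerance = 1e-6)
  # indistinguishability: one species formally split into two
  db2 <- clone_component(test_db(), "ethanol", "ethanol_b")
  for (split in c(0.2, 0.5, 0.8)) {
    st <- mixture_state(c("ethanol", "ethanol_b"), c(split, 1 - split),
                        298.15)
    g <- activity_coefficients(st, db2)
    expect_equal(unname(g), c(1, 1), tolerance = 1e-8)
  }
})

test_that("Gibbs-Duhem closure holds along a binary composition path", {
  db <- test_db()
  sys <- cocrysol:::pcsaft_system(db, c("ethanol", "water"), 298.15)
  h <- 1e-4
  for (x1 in c(0.2, 0.5, 0.8)) {
    gp <- log(cocrysol:::gamma_sys(sys, c(x1 + h, 1 - x1 - h)))
    gm <- log(cocrysol:::gamma_sys(sys, c(x1 - h, 1 - x1 + h)))
    dlng <- (gp - gm) / (2 * h)
    gd <- x1 * dlng[1] + (1 - x1) * dlng[2]
    expect_lt(abs(gd) / max(1, abs(dlng[1])), 1e-6)
  }
})
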