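test_that("packaged database reproduces the published parameter tables", {
  db <- test_db()
  na_ <- db$components[["NA"]]
  expect_equal(na_$segment_number, 4.6485)
  expect_equal(na_$segment_diameter, 2.1775)
  expect_equal(na_$dispersion_energy, 176.69)
  expect_equal(na_$assoc_energy, 2195.3)
  expect_equal(na_$assoc_volume, 0.02)
  expect_equal(na_$n_donor_sites, 2L)
  expect_equal(na_$n_acceptor_sites, 2L)
  sa_melt <- db$melting[["SA"]]
  expect_equal(sa_melt$melting_temperature, 461.15)
  expect_equal(sa_melt$fusion_enthalpy, 38.91)
  expect_equal(sa_melt$delta_cp, 69.79)
  expect_equal(db$R, 8.314)
  # induced associators carry the zero-energy / 0.01-volume convention
  for (id in c("acetonitrile", "ethyl_acetate")) {
    cp <- db$components[[id]]
    expect_true(cp$induced_association)
    expect_equal(cp$assoc_energy, 0)
    expect_equal(cp$assoc_volume, 0.01)
  }
  cc <- db$cocrystals[[1]]
  expect_equal(cc$ks_ref, 3.70e-7)
  expect_equal(cc$t_ref, 298.15)
  expect_equal(cc$dh_ref, 64.75)
  expect_equal(c(cc$nu_api, cc$nu_cf), c(2L, 1L))
})

test_that("validation rejects out-of-range and unresolvable parameters", {
  db <- test_db()
  bad <- db
  bad$components$ethanol$assoc_volume <- 1.5
  expect_error(validate_parameter_db(bad), class = "cocrysol_validation_error")
  expect_error(validate_parameter_db(bad), "assoc_volume")
  bad2 <- db
  bad2$melting$ghost <- structure(list(component_id = "ghost",
                                       melting_temperature = 400,
                                       fusion_enthalpy = 20, delta_cp = 0),
                                  class = "melting_properties")
  expect_error(validate_parameter_db(bad2),
               class = "cocrysol_resolution_error")
  bad3 <- db
  bad3$components$ethanol$induced_association <- TRUE
  expect_error(validate_parameter_db(bad3),
               class = "cocrysol_validation_error")
})

test_that("kij temperature rule is linear and defaults to zero", {
  db <- test_db()
  bi <- db_binary(db, "NA", "ethanol")
  expect_equal(kij_at_temperature(bi, 298.15), 8.39e-5 * 298.15 - 2.10e-2)
  expect_equal(kij_at_temperature(bi, 298.15), 4.015e-3, tolerance = 1e-4)
  # constant solvent/solvent rule warns outside its validity window
  bi2 <- db_binary(db, "ethanol", "ethyl_acetate")
  expect_warning(v <- kij_at_temperature(bi2, 298.15), "validity range")
  expect_equal(v, -0.018)
  # absent pair: default-zero rule, order-insensitive lookup
  expect_equal(kij_at_temperature(db_binary(db, "NA", "SA"), 310.15), 0)
  expect_identical(db_binary(db, "water", "NA")$k_slope,
                   db_binary(db, "NA", "water")$k_slope)
  # affine in T: midpoint value equals mean of endpoint values
  for (key in names(db$binaries)) {
    bi <- db$binaries[[key]]
    k1 <- bi$k_slope * 280 + bi$k_intercept
    k2 <- bi$k_slope * 400 + bi$k_intercept
    expect_equal(bi$k_slope * 340 + bi$k_intercept, (k1 + k2) / 2)
  }
})

test_that("segment diameter rules evaluate correctly", {
  db <- test_db()
  w <- db$components$water
  expected <- 2.7927 + 10.11 * exp(-0.01775 * 298.15) -
    1.417 * exp(-0.01146 * 298.15)
  expect_equal(sigma_at_temperature(w, 298.15), expected)
  expect_equal(sigma_at_temperature(w, 298.15), 2.797, tolerance = 1e-3)
  expect_equal(sigma_at_temperature(db$components$ethanol, 350), 3.1771)
  expect_equal(sigma_at_temperature(db$components[["NA"]], 310.15), 2.1775)
  # the two exponential corrections shrink with temperature at different
  # rates: the diameter contracts monotonically over the liquid range of
  # water (its derivative only changes sign near 382 K)
  grid <- seq(273, 373, by = 1)
  sig <- sigma_at_temperature(w, grid)
  expect_true(all(diff(sig) < 0))
  expect_true(all(sig > 2.78 & sig < 2.82))
})

test_that("serialize -> load round trip reproduces the database", {
  db <- test_db()
  path <- withr::local_tempfile(fileext = ".json")
  write_parameter_db(db, path)
  db2 <- load_parameter_db(path)
  for (id in names(db$components))
    expect_equal(unclass(db$components[[id]]),
                 unclass(db2$components[[id]]))
  for (id in names(db$melting))
    expect_equal(unclass(db$melting[[id]]), unclass(db2$melting[[id]]))
  expect_equal(names(db$binaries), names(db2$binaries))
  for (key in names(db$binaries))
    expect_equal(unclass(db$binaries[[key]]), unclass(db2$binaries[[key]]))
  expect_equal(unclass(db$cocrystals[[1]]), unclass(db2$cocrystals[[1]]))
  expect_equal(db$R, db2$R)
})
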