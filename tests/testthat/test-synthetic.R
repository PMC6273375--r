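test_that("zero-noise generation reproduces the model exactly", {
  db <- test_db()
  des <- synthetic_design("NA", "ethanol", 1, c(293.15, 298.15, 310.15),
                          noise_rel_sd = 0, seed = 5)
  ds <- generate_binary_solubility(des, db = db)
  x_model <- vapply(ds$T_K, function(T)
    solve_solubility("NA", c(ethanol = 1), T, db)$x_solute, 0)
  expect_equal(ard(x_model, ds$x_solute), 0)
  expect_true(all(ds$provenance == "synthetic"))
  expect_true(all(ds$seed == 5L))
})

test_that("the seed fixes the full output stream", {
  db <- test_db()
  des <- synthetic_design("NA", "ethanol", 1, c(298.15, 310.15),
                          noise_rel_sd = 0.05, n_replicates = 2, seed = 11)
  ds1 <- generate_binary_solubility(des, db = db)
  ds2 <- generate_binary_solubility(des, db = db)
  expect_identical(ds1, ds2)
  des3 <- des; des3$seed <- 12L
  ds3 <- generate_binary_solubility(des3, db = db)
  expect_false(isTRUE(all.equal(ds1$x_solute, ds3$x_solute)))
  # generation does not disturb the global random stream
  set.seed(99); before <- stats::rnorm(1)
  set.seed(99); invisible(generate_binary_solubility(des, db = db))
  expect_identical(stats::rnorm(1), before)
})

test_that("noise has the designed lognormal scale", {
  db <- test_db()
  des <- synthetic_design("NA", "ethanol", 1, 298.15,
                          noise_rel_sd = 0.03, n_replicates = 200,
                          seed = 123)
  ds <- generate_binary_solubility(des, db = db)
  x_model <- solve_solubility("NA", c(ethanol = 1), 298.15, db)$x_solute
  s <- stats::sd(log(ds$x_solute / x_model))
  expect_gt(s, 0.025)
  expect_lt(s, 0.035)
  expect_lt(abs(mean(log(ds$x_solute / x_model))), 3 * 0.03 / sqrt(200))
})

test_that("cocrystal datasets round-trip the solubility product", {
  db <- test_db()
  cc <- db$cocrystals[[1]]
  des <- synthetic_design("NA", "ethanol", 1, 298.15, noise_rel_sd = 0,
                          seed = 3)
  ds <- cached("cc_ds_clean", generate_cc_dataset(
    des, cc, db, solute_ratio_grid = c(0.5, 1, 2, 4)))
  expect_true(all(ds$solid_phase == "CC"))
  expect_true(all(ds$x_solute > 0 & ds$x_cosolute > 0))
  ks_true <- ks_at_temperature(cc, 298.15)
  ks_back <- vapply(seq_len(nrow(ds)), function(i)
    fit_ks(ds[i, ], cc, db), 0)
  expect_lt(max(abs(ks_back / ks_true - 1)), 1e-6)
  # noisy Ks recovery stays within first-order propagation bounds
  des_n <- synthetic_design("NA", "ethanol", 1, 298.15,
                            noise_rel_sd = 0.02, n_replicates = 3,
                            seed = 17)
  ds_n <- generate_cc_dataset(des_n, cc, db,
                              solute_ratio_grid = c(0.7, 2, 4))
  ks_n <- vapply(seq_len(nrow(ds_n)), function(i)
    fit_ks(ds_n[i, ], cc, db), 0)
  expect_lt(abs(stats::median(ks_n) / ks_true - 1), 0.05)
})

test_that("generate -> fit -> rebuild closes the loop within the noise bound", {
  db <- test_db()
  truth <- list(k_slope = 8.39e-5, k_intercept = -0.021)
  temps <- c(293.15, 298.15, 303.15, 310.15, 318.15)
  des <- synthetic_design("NA", "ethanol", 1, temps,
                          noise_rel_sd = 0.02, seed = 31)
  ds <- generate_binary_solubility(des, true_params = truth, db)
  fit <- fit_kij(ds, "NA", "ethanol", db)
  db_true <- set_binary(db, "NA", "ethanol", truth$k_slope,
                        truth$k_intercept)
  db_fit <- set_binary(db, "NA", "ethanol", fit$parameters[["k_slope"]],
                       fit$parameters[["k_intercept"]])
  x_truth <- vapply(temps, function(T)
    solve_solubility("NA", c(ethanol = 1), T, db_true)$x_solute, 0)
  x_refit <- vapply(temps, function(T)
    solve_solubility("NA", c(ethanol = 1), T, db_fit)$x_solute, 0)
  # rebuilt line deviates from the noise-free truth by less than the
  # measurement noise scale (2%), since fitting averages the errors
  expect_lt(ard(x_refit, x_truth), 2)
})
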