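# Estimation of binary interaction parameters and solubility products
# from saturation data, and the average-relative-deviation error metric.

#' Average relative deviation (percent)
#'
#' ARD = 100 / n * sum(|x_calc - x_exp| / x_exp), the standard accuracy
#' metric for correlated or predicted solubilities. Scale-aware:
#' multiplying both vectors by a positive constant leaves it unchanged.
#'
#' @param x_calc Calculated values.
#' @param x_exp Experimental (reference) values, all nonzero, same
#'   length as `x_calc`.
#' @return ARD in percent (>= 0).
#' @export
ard <- function(x_calc, x_exp) {
  if (length(x_calc) != length(x_exp))
    stop("x_calc and x_exp must have equal length")
  if (length(x_exp) < 1)
    stop("at least one data point is required")
  if (any(x_exp == 0))
    stop("experimental values must be nonzero")
  100 * mean(abs(x_calc - x_exp) / abs(x_exp))
}

# Model solubilities for a set of (T, pure-solvent) records of one
# solute/solvent pair; reuses one pcsaft system per temperature.
model_solubility_records <- function(records, solute_id, solvent_id, db) {
  vapply(seq_len(nrow(records)), function(i) {
    sc <- stats::setNames(1, solvent_id)
    pt <- solve_solubility(solute_id, sc, records$T_K[i], db)
    pt$x_solute
  }, 0)
}

#' Fit the binary interaction temperature rule to solubility data
#'
#' Estimates (k_slope, k_intercept) of kij(T) = k_slope T + k_intercept
#' for a solute/solvent pair by minimizing the sum of squared deviations
#' in ln x between modeled and measured saturation mole fractions (a
#' log-scale loss, since solubilities span orders of magnitude and
#' accuracy is reported as relative deviation). Datasets spanning a
#' single temperature fix the slope at zero and fit the intercept only.
#' The least squares are solved by Levenberg-Marquardt with multiple
#' starts on this smooth two-parameter problem; parameter standard
#' errors come from the finite-difference Jacobian at the optimum, and
#' the ARD is evaluated there.
#'
#' @param dataset A solubility dataset (see
#'   [read_solubility_dataset()]); only records of `solute_id` in pure
#'   `solvent_id` are used.
#' @param solute_id,solvent_id Component ids of the fitted pair.
#' @param db A `parameter_db`; its other parameters are held fixed.
#' @return A `fit_result` list: `parameters` (named: k_slope,
#'   k_intercept), `std_errors`, `objective` (sum of squared
#'   ln-residuals), `ard_percent`, `n_records`, `convergence`
#'   (0 = converged), `solute_id`, `solvent_id`.
#' @export
fit_kij <- function(dataset, solute_id, solvent_id, db) {
  rec <- dataset[dataset$solute == solute_id &
                   dataset$solvent_a == solvent_id &
                   (is.na(dataset$solvent_b) | dataset$w_a >= 1 - 1e-12) &
                   dataset$solid_phase == "solute", , drop = FALSE]
  if (nrow(rec) < 1)
    stop("no matching records for this solute/solvent pair")
  lnx_exp <- log(rec$x_solute)
  n_T <- length(unique(rec$T_K))
  # residuals in ln x; the slope is rescaled (1 unit ~ 1e-4 1/K) so both
  # parameters are O(0.1) for the least-squares machinery
  resid_fn <- function(par) {
    db2 <- set_binary(db, solute_id, solvent_id, par[1] * 1e-4, par[2])
    lnx <- tryCatch(
      log(model_solubility_records(rec, solute_id, solvent_id, db2)),
      error = function(e) NULL)
    if (is.null(lnx) || any(!is.finite(lnx)))
      return(rep(1e3, nrow(rec)))
    lnx - lnx_exp
  }
  if (n_T >= 2) {
    starts <- list(c(0, 0), c(1, -0.1), c(-1, 0.05))
    best <- NULL
    for (p0 in starts) {
      fit <- minpack.lm::nls.lm(p0, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(
                                  ftol = 1e-14, ptol = 1e-12, maxiter = 200))
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
      if (best$deviance < 1e-16) break   # later starts cannot improve
    }
    par <- c(best$par[1] * 1e-4, best$par[2])
    value <- best$deviance
    conv <- if (best$info %in% 1:4) 0L else as.integer(best$info)
    # standard errors from an explicit finite-difference Jacobian at the
    # optimum: cov = sigma^2 (J'J)^-1, sigma^2 = RSS / (n - p)
    se <- tryCatch({
      h <- 1e-4
      J <- vapply(1:2, function(k) {
        dp <- c(0, 0); dp[k] <- h
        (resid_fn(best$par + dp) - resid_fn(best$par - dp)) / (2 * h)
      }, numeric(nrow(rec)))
      dof <- max(nrow(rec) - 2, 1)
      v <- solve(crossprod(J)) * value / dof
      sqrt(pmax(diag(v), 0)) * c(1e-4, 1)
    }, error = function(e) c(NA_real_, NA_real_))
  } else {
    o1 <- stats::optimize(function(ki) sum(resid_fn(c(0, ki))^2),
                          c(-0.6, 0.6), tol = 1e-10)
    par <- c(0, o1$minimum); value <- o1$objective; conv <- 0L
    se <- c(NA_real_, NA_real_)
  }
  db_fit <- set_binary(db, solute_id, solvent_id, par[1], par[2])
  x_fit <- model_solubility_records(rec, solute_id, solvent_id, db_fit)
  structure(list(
    parameters = c(k_slope = unname(par[1]), k_intercept = unname(par[2])),
    std_errors = c(k_slope = unname(se[1]), k_intercept = unname(se[2])),
    objective = value,
    ard_percent = ard(x_fit, rec$x_solute),
    n_records = nrow(rec),
    convergence = conv,
    solute_id = solute_id, solvent_id = solvent_id
  ), class = "fit_result")
}

#' Solubility product from a single cocrystal saturation record
#'
#' Evaluates PC-SAFT activity coefficients of API and coformer at the
#' record's saturated liquid composition and applies
#' [ks_from_point()]. Because the solubility product is solvent- and
#' concentration-independent under the model, one record suffices; on
#' noise-free model-generated records the generating Ks is recovered
#' exactly.
#'
#' @param record A one-row cocrystal saturation record: list or data
#'   frame row with `x_solute` (API mole fraction), `x_cosolute`
#'   (coformer mole fraction), `T_K`, `solvent_a`, `w_a` and optionally
#'   `solvent_b`.
#' @param cc A `cocrystal_definition` giving the stoichiometry.
#' @param db A `parameter_db`.
#' @param ideal If `TRUE`, neglect the activity coefficients
#'   ([ks_ideal_from_point()]).
#' @return The dimensionless solubility product.
#' @export
fit_ks <- function(record, cc, db, ideal = FALSE) {
  record <- as.list(record)
  x_api <- record$x_solute; x_cf <- record$x_cosolute
  if (ideal)
    return(ks_ideal_from_point(x_api, x_cf, cc$nu_api, cc$nu_cf))
  w <- solvent_mass_fractions_of(record)
  comp <- full_composition(db, cc$api_id, x_api, w,
                           stats::setNames(x_cf, cc$cf_id))
  st <- mixture_state(comp$component_ids, comp$mole_fractions,
                      record$T_K)
  g <- activity_coefficients(st, db)
  ks_from_point(x_api, x_cf, g[[cc$api_id]], g[[cc$cf_id]],
                cc$nu_api, cc$nu_cf)
}

solvent_mass_fractions_of <- function(record) {
  if (is.null(record$solvent_b) || is.na(record$solvent_b) ||
      record$w_a >= 1 - 1e-12)
    stats::setNames(1, record$solvent_a)
  else
    stats::setNames(c(record$w_a, 1 - record$w_a),
                    c(record$solvent_a, record$solvent_b))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s/%s: k_slope = %.6g 1/K, k_intercept = %.6g\n",
              x$solute_id, x$solvent_id,
              x$parameters["k_slope"], x$parameters["k_intercept"]))
  cat(sprintf("  objective %.3e over %d records; ARD %.3f%%\n",
              x$objective, x$n_records, x$ard_percent))
  invisible(x)
}
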