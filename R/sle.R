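# Solid-liquid equilibrium: solubility of a pure crystalline solute in a
# solvent/anti-solvent (optionally cosolute-laden) liquid, from its
# melting properties and PC-SAFT activity coefficients.

#' Ideal solubility of a crystalline solute
#'
#' Mole-fraction solubility for an ideal liquid solution (activity
#' coefficient one), from the melting temperature, fusion enthalpy and
#' the solid/liquid heat-capacity difference at the melting point:
#' x = exp\[-dh/(RT) (1 - T/T0) - dcp/R (T0/T - 1 - ln(T0/T))\].
#' The value is clipped at 1. At T = T0 the exponent vanishes and x = 1.
#'
#' @param melting A `melting_properties` object (fusion enthalpy in
#'   kJ/mol, converted to J/mol internally; delta_cp in J/(mol K)).
#' @param temperature Temperature in K, 0 < T <= melting temperature.
#'   May be a vector.
#' @param R Ideal gas constant, J/(mol K).
#' @return Ideal mole-fraction solubility.
#' @export
ideal_solubility <- function(melting, temperature, R = 8.314) {
  stopifnot(all(temperature > 0))
  T0 <- melting$melting_temperature
  if (any(temperature > T0 + 1e-9))
    stop(errorCondition(
      sprintf("T = %g K exceeds the melting temperature %g K: the solid does not exist",
              max(temperature), T0),
      class = c("cocrysol_domain_error", "error", "condition")))
  dh <- melting$fusion_enthalpy * 1000     # kJ/mol -> J/mol (single site)
  dcp <- melting$delta_cp
  ex <- -dh / (R * temperature) * (1 - temperature / T0) -
    dcp / R * (T0 / temperature - 1 - log(T0 / temperature))
  pmin(exp(ex), 1)
}

# Solvent split: solute-free mass fractions -> mole fractions among the
# solvents only (conversion through molar masses).
solvent_mole_split <- function(db, solvent_mass_fractions) {
  ids <- names(solvent_mass_fractions)
  M <- vapply(ids, function(id) db$components[[id]]$molar_mass, 0)
  n <- solvent_mass_fractions / M
  n / sum(n)
}

# Assemble the full liquid composition: named solute mole fraction,
# fixed cosolute mole fractions, remainder split over the solvents in
# the given solute-free mass ratio.
full_composition <- function(db, solute_id, x_solute,
                             solvent_mass_fractions,
                             cosolute_amounts = NULL) {
  w <- solvent_mass_fractions / sum(solvent_mass_fractions)
  phi <- solvent_mole_split(db, w)
  x_cos <- if (is.null(cosolute_amounts)) numeric(0) else cosolute_amounts
  room <- 1 - x_solute - sum(x_cos)
  if (room <= 0)
    stop("solute and cosolute mole fractions leave no room for solvent")
  list(component_ids = c(solute_id, names(x_cos), names(phi)),
       mole_fractions = c(x_solute, unname(x_cos), unname(phi) * room))
}

# Core solver on a prebuilt pcsaft system; ids must be ordered
# c(solute, cosolutes, solvents).
solve_solubility_sys <- function(sys, db, solute_id,
                                 solvent_mass_fractions, x_ideal,
                                 cosolute_amounts = NULL,
                                 pressure = 101325, x_max = NULL) {
  w <- solvent_mass_fractions / sum(solvent_mass_fractions)
  phi <- solvent_mole_split(db, w)
  x_cos <- if (is.null(cosolute_amounts)) numeric(0) else cosolute_amounts
  if (is.null(x_max)) x_max <- 0.999 - sum(x_cos)
  comp_x <- function(x_s) c(x_s, unname(x_cos), unname(phi) * (1 - x_s - sum(x_cos)))
  gam <- function(x_s) gamma_sys(sys, comp_x(x_s), pressure)
  resid <- function(lnx) {
    x_s <- exp(lnx)
    lnx + log(gam(x_s)[[solute_id]]) - log(x_ideal)
  }
  lo <- log(x_ideal) - 1
  hi <- min(log(x_ideal) + 1, log(x_max))
  flo <- resid(lo); fhi <- resid(hi)
  it <- 0
  while (flo > 0 && it < 60) { lo <- lo - 1; flo <- resid(lo); it <- it + 1 }
  while (fhi < 0 && hi < log(x_max) - 1e-12 && it < 120) {
    hi <- min(hi + 1, log(x_max)); fhi <- resid(hi); it <- it + 1
  }
  if (fhi < 0)
    return(list(x_solute = NA_real_, gamma = NA_real_,
                status = "fully_miscible"))
  root <- stats::uniroot(resid, c(lo, hi), f.lower = flo, f.upper = fhi,
                         tol = 1e-10)
  x_s <- exp(root$root)
  g <- gam(x_s)
  list(x_solute = x_s, gamma = g[[solute_id]], gamma_all = g,
       status = "converged")
}

#' Solubility of a solid solute from solid-liquid equilibrium
#'
#' Solves the saturation condition x gamma(x) = x_ideal for the named
#' solute in a solvent/anti-solvent environment, with the activity
#' coefficient evaluated by PC-SAFT at the full liquid composition: the
#' solvents in the stated solute-free mass ratio, optional cosolutes
#' held at fixed mole fractions of the total liquid. Only the named
#' solute's solid is treated as the equilibrium phase.
#'
#' @param solute_id Component id of the crystallizing solute (must carry
#'   melting properties in `db`).
#' @param solvent_composition Named numeric vector of solute-free solvent
#'   mass fractions (normalized internally).
#' @param temperature Temperature in K.
#' @param db A `parameter_db`.
#' @param cosolute_amounts Optional named vector of cosolute mole
#'   fractions (of the total liquid).
#' @param pressure Pressure in Pa.
#' @return A `solubility_point` list: `solute_id`,
#'   `solvent_composition`, `temperature`, `x_solute`, `gamma_solute`,
#'   `cosolute_amounts`, `gamma_all`, `x_ideal` and `status`
#'   (`"converged"` or `"fully_miscible"`, the latter with `x_solute =
#'   NA` when the saturation condition has no root below full
#'   miscibility).
#' @export
solve_solubility <- function(solute_id, solvent_composition, temperature,
                             db, cosolute_amounts = NULL,
                             pressure = 101325) {
  mp <- db$melting[[solute_id]]
  if (is.null(mp))
    stop(errorCondition(
      sprintf("no melting properties for component '%s'", solute_id),
      class = c("cocrysol_resolution_error", "error", "condition")))
  x_ideal <- ideal_solubility(mp, temperature, db$R)
  w <- solvent_composition / sum(solvent_composition)
  ids <- c(solute_id, names(cosolute_amounts), names(w))
  sys <- pcsaft_system(db, ids, temperature)
  sol <- solve_solubility_sys(sys, db, solute_id, w, x_ideal,
                              cosolute_amounts, pressure)
  structure(list(solute_id = solute_id,
                 solvent_composition = w,
                 temperature = temperature,
                 x_solute = sol$x_solute,
                 gamma_solute = sol$gamma,
                 cosolute_amounts = cosolute_amounts,
                 gamma_all = sol$gamma_all,
                 x_ideal = x_ideal,
                 status = sol$status),
            class = "solubility_point")
}

#' Solubility across a solvent/anti-solvent composition line
#'
#' Computes saturation points of one solute over a grid of solute-free
#' mass ratios of a solvent pair at fixed temperature. Endpoints of a
#' \[0, 1\] grid equal the pure-solvent solubilities. Nodes where the
#' solver fails are returned with `NA` and flagged in the `status`
#' column rather than aborting the line.
#'
#' @param solute_id Solute component id.
#' @param solvent_pair Character vector of the two solvent ids; the grid
#'   refers to the mass fraction of the first.
#' @param ratio_grid Numeric vector of solute-free mass fractions of the
#'   first solvent, in \[0, 1\].
#' @param temperature Temperature in K.
#' @param db A `parameter_db`.
#' @return A data frame with columns `w_first`, `x_solute`,
#'   `gamma_solute`, `status`.
#' @export
solubility_line_vs_solvent_ratio <- function(solute_id, solvent_pair,
                                             ratio_grid, temperature, db) {
  stopifnot(length(solvent_pair) == 2,
            all(ratio_grid >= 0), all(ratio_grid <= 1))
  rows <- lapply(ratio_grid, function(w1) {
    sc <- stats::setNames(c(w1, 1 - w1), solvent_pair)
    sc <- sc[sc > 0]
    pt <- tryCatch(solve_solubility(solute_id, sc, temperature, db),
                   error = function(e) NULL)
    if (is.null(pt))
      data.frame(w_first = w1, x_solute = NA_real_,
                 gamma_solute = NA_real_, status = "failed")
    else
      data.frame(w_first = w1, x_solute = pt$x_solute,
                 gamma_solute = pt$gamma_solute, status = pt$status)
  })
  do.call(rbind, rows)
}

#' @export
print.solubility_point <- function(x, ...) {
  cat(sprintf("<solubility_point> %s in %s at %.2f K\n", x$solute_id,
              paste(sprintf("%s:%.3g", names(x$solvent_composition),
                            x$solvent_composition), collapse = ","),
              x$temperature))
  cat(sprintf("  x = %.6g  gamma = %.6g  (ideal %.6g)  [%s]\n",
              x$x_solute, x$gamma_solute, x$x_ideal, x$status))
  invisible(x)
}
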