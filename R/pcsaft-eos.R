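# PC-SAFT residual Helmholtz energy: hard-chain reference + dispersion +
# Wertheim association, with analytic density and composition derivatives
# feeding pressure, fugacity and activity coefficients.

.kB <- 1.380649e-23     # J/K
.N_Avogadro <- 6.02214076e23

# Universal model constants of the dispersion integrals I1/I2
# (power series in packing fraction; transcribed from the original
# perturbed-chain SAFT dispersion term). Columns: order-0, (m-1)/m,
# (m-1)(m-2)/m^2 coefficients.
.disp_a <- matrix(c(
   0.9105631445, -0.3084016918, -0.0906148351,
   0.6361281449,  0.1860531159,  0.4527842806,
   2.6861347891, -2.5030047259,  0.5962700728,
 -26.5473624910, 21.4197936290, -1.7241829131,
  97.7592087840, -65.2558853300, -4.1302112531,
-159.5915408700, 83.3186804810, 13.7766318700,
  91.2977740840, -33.7469229300, -8.6728470368
), ncol = 3, byrow = TRUE)

.disp_b <- matrix(c(
   0.7240946941, -0.5755498075,  0.0976883116,
   2.2382791861,  0.6995095521, -0.2557574982,
  -4.0025849485,  3.8925673390, -9.1558561530,
 -21.0035768150, -17.2154716480, 20.6420759740,
  26.8556413630, 192.6722644700, -38.8044300520,
 206.5513384100, -161.8264616500, 93.6267740770,
-355.6023561200, -165.2076934600, -29.6669055850
), ncol = 3, byrow = TRUE)

#' Construct a mixture state
#'
#' A `mixture_state` fixes temperature, pressure and the liquid
#' composition over named components. Mole fractions must be
#' non-negative and sum to one within 1e-12.
#'
#' @param component_ids Character vector of component ids.
#' @param mole_fractions Numeric vector, same length, summing to 1.
#' @param temperature Temperature in K.
#' @param pressure Pressure in Pa (default one atmosphere; liquid-phase
#'   activity coefficients are insensitive to it).
#' @return A `mixture_state` object.
#' @export
mixture_state <- function(component_ids, mole_fractions, temperature,
                          pressure = 101325) {
  stopifnot(length(component_ids) == length(mole_fractions),
            temperature > 0, pressure > 0)
  x <- as.numeric(mole_fractions)
  if (any(x < 0))
    stop("mole fractions must be non-negative")
  if (abs(sum(x) - 1) > 1e-12)
    stop("mole fractions must sum to 1 within 1e-12")
  structure(list(component_ids = as.character(component_ids),
                 mole_fractions = x,
                 temperature = temperature,
                 pressure = pressure),
            class = "mixture_state")
}

#' Berthelot-Lorentz combining rule for segment diameters
#'
#' Arithmetic mean of the two pure-component segment diameters.
#'
#' @param sigma_i,sigma_j Segment diameters in Angstrom (> 0).
#' @return Cross segment diameter in Angstrom.
#' @export
combine_sigma <- function(sigma_i, sigma_j) {
  stopifnot(all(sigma_i > 0), all(sigma_j > 0))
  (sigma_i + sigma_j) / 2
}

#' Berthelot-Lorentz combining rule for dispersion energies
#'
#' Geometric mean corrected by the binary interaction parameter:
#' u_ij = (1 - kij) sqrt(u_i u_j).
#'
#' @param u_i,u_j Pure-component dispersion energies in K (>= 0).
#' @param kij Dimensionless binary interaction parameter in (-1, 1\].
#' @return Cross dispersion energy in K.
#' @export
combine_u <- function(u_i, u_j, kij = 0) {
  stopifnot(all(u_i >= 0), all(u_j >= 0), all(kij > -1), all(kij <= 1))
  (1 - kij) * sqrt(u_i * u_j)
}

#' Wolbach-Sandler combining rules for cross-association
#'
#' Cross association energy is the arithmetic mean of the
#' self-association energies; the cross association volume is the
#' geometric mean scaled by the cube of the ratio of geometric to
#' arithmetic mean segment diameter.
#'
#' @param comp_i,comp_j `pure_component_params` objects, at least one of
#'   which carries association sites.
#' @param temperature Temperature in K, used only to evaluate
#'   temperature-dependent segment diameters.
#' @return A list with elements `eps_AiBj` (K) and `kappa_AiBj`
#'   (dimensionless).
#' @export
combine_association <- function(comp_i, comp_j, temperature = 298.15) {
  n_i <- comp_i$n_donor_sites + comp_i$n_acceptor_sites
  n_j <- comp_j$n_donor_sites + comp_j$n_acceptor_sites
  if (n_i + n_j == 0)
    stop("at least one component must carry association sites")
  s_i <- sigma_at_temperature(comp_i, temperature)
  s_j <- sigma_at_temperature(comp_j, temperature)
  list(
    eps_AiBj = (comp_i$assoc_energy + comp_j$assoc_energy) / 2,
    kappa_AiBj = sqrt(comp_i$assoc_volume * comp_j$assoc_volume) *
      (sqrt(s_i * s_j) / ((s_i + s_j) / 2))^3
  )
}

# Precompute every temperature-dependent quantity for a component set.
# Returned object is reused across compositions and densities; carries a
# small cache environment for association warm starts and pure-liquid
# reference fugacities.
pcsaft_system <- function(db, component_ids, temperature) {
  comps <- lapply(component_ids, function(id) {
    cp <- db$components[[id]]
    if (is.null(cp))
      stop(errorCondition(sprintf("unknown component '%s'", id),
                          class = c("cocrysol_resolution_error",
                                    "error", "condition")))
    cp
  })
  n <- length(comps)
  m <- vapply(comps, `[[`, 0, "segment_number")
  sigma <- vapply(comps, sigma_at_temperature, 0, temperature = temperature)
  u <- vapply(comps, `[[`, 0, "dispersion_energy")
  eps_self <- vapply(comps, `[[`, 0, "assoc_energy")
  kap_self <- vapply(comps, `[[`, 0, "assoc_volume")
  nd <- vapply(comps, function(cp) as.numeric(cp$n_donor_sites), 0)
  na_ <- vapply(comps, function(cp) as.numeric(cp$n_acceptor_sites), 0)
  d <- sigma * (1 - 0.12 * exp(-3 * u / temperature))

  kij <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      bi <- db_binary(db, component_ids[i], component_ids[j])
      kij[i, j] <- kij[j, i] <- bi$k_slope * temperature + bi$k_intercept
    }
  }
  s_ij <- outer(sigma, sigma, combine_sigma)
  u_ij <- (1 - kij) * sqrt(outer(u, u))
  eps_ab <- outer(eps_self, eps_self, `+`) / 2
  kap_ab <- sqrt(outer(kap_self, kap_self)) *
    (sqrt(outer(sigma, sigma)) / s_ij)^3
  has_sites <- (nd + na_) > 0
  # association-strength prefactor: Delta_ij = P_ij * g_ij(hs)
  P <- s_ij^3 * kap_ab * (exp(eps_ab / temperature) - 1) *
    outer(has_sites, has_sites)

  list(component_ids = component_ids, temperature = temperature,
       n = n, m = m, sigma = sigma, u = u, d = d,
       nd = nd, na = na_, has_sites = has_sites, any_sites = any(has_sites),
       kij = kij, s_ij = s_ij, u_ij = u_ij,
       eps_ab = eps_ab, kap_ab = kap_ab, assoc_pref = P,
       c_ij = outer(d, d) / outer(d, d, `+`),   # d_i d_j / (d_i + d_j)
       md3 = m * d^3,
       cache = new.env(parent = emptyenv()))
}

# Wertheim mass balance for per-site unbonded fractions. Donor sites bond
# only to acceptor sites and vice versa; all donor (acceptor) sites on a
# component are equivalent. Damped successive substitution (damping 0.5,
# tolerance 1e-12, max 500 iterations).
assoc_fractions <- function(sys, x, rho, Delta, X_init = NULL) {
  n <- sys$n
  if (!sys$any_sites || all(Delta == 0))
    return(list(XD = rep(1, n), XA = rep(1, n), iter = 0L))
  XD <- XA <- rep(0.5, n)
  if (!is.null(X_init)) { XD <- X_init$XD; XA <- X_init$XA }
  wA <- rho * x * sys$na   # weights of acceptor sites
  wD <- rho * x * sys$nd
  for (it in 1:500) {
    XD_new <- 1 / (1 + as.numeric(Delta %*% (wA * XA)))
    XA_new <- 1 / (1 + as.numeric(Delta %*% (wD * XD)))
    dmax <- max(abs(XD_new - XD), abs(XA_new - XA))
    XD <- 0.5 * XD + 0.5 * XD_new
    XA <- 0.5 * XA + 0.5 * XA_new
    if (dmax < 1e-12)
      return(list(XD = pmin(XD, 1), XA = pmin(XA, 1), iter = it))
  }
  stop(errorCondition(
    sprintf("association fixed point did not converge in 500 iterations (last max change %.3e)", dmax),
    class = c("cocrysol_numerical_error", "error", "condition")))
}

# Full residual Helmholtz evaluation at number density rho (A^-3) and
# composition x, with analytic derivatives wrt rho (at fixed x) and wrt
# each x_k (at fixed total number density, unconstrained composition).
eos_eval <- function(sys, x, rho, X_init = NULL) {
  n <- sys$n; m <- sys$m; d <- sys$d
  mbar <- sum(x * m)
  pref <- pi / 6 * rho
  # zeta_k and their composition derivatives zk[l, i] = d zeta_{l-1} / d x_i
  zk0 <- pref * m
  zk1 <- zk0 * d
  zk2 <- zk1 * d
  zk3 <- zk2 * d
  z0 <- sum(x * zk0); z1 <- sum(x * zk1)
  z2 <- sum(x * zk2); z3 <- sum(x * zk3)
  eta <- z3
  if (eta <= 0 || eta >= 0.7405)
    stop(errorCondition(sprintf("packing fraction %.4f outside (0, 0.7405)", eta),
                        class = c("cocrysol_numerical_error", "error", "condition")))
  om <- 1 - z3   # (1 - eta)

  ## --- hard-sphere term (per segment) and partials wrt zeta_0..3
  lnom <- log(om)
  a_hs <- (3 * z1 * z2 / om + z2^3 / (z3 * om^2) +
             (z2^3 / z3^2 - z0) * lnom) / z0
  dahs_dz0 <- -(a_hs + lnom) / z0
  dahs_dz1 <- 3 * z2 / (om * z0)
  dahs_dz2 <- (3 * z1 / om + 3 * z2^2 / (z3 * om^2) +
                 3 * z2^2 / z3^2 * lnom) / z0
  dahs_dz3 <- (3 * z1 * z2 / om^2 +
                 z2^3 * (-1 / (z3^2 * om^2) + 2 / (z3 * om^3)) -
                 2 * z2^3 / z3^3 * lnom -
                 (z2^3 / z3^2 - z0) / om) / z0

  ## --- radial distribution function at contact, g_ij^hs
  cij <- sys$c_ij
  g <- 1 / om + cij * 3 * z2 / om^2 + cij^2 * 2 * z2^2 / om^3
  dg_dz2 <- cij * 3 / om^2 + cij^2 * 4 * z2 / om^3
  dg_dz3 <- 1 / om^2 + cij * 6 * z2 / om^3 + cij^2 * 6 * z2^2 / om^4
  gii <- diag(g)
  dgii_dz2 <- diag(dg_dz2)
  dgii_dz3 <- diag(dg_dz3)

  ## --- hard chain
  a_hc <- mbar * a_hs - sum(x * (m - 1) * log(gii))
  # composition derivative (fixed rho)
  dahs_dx <- dahs_dz0 * zk0 + dahs_dz1 * zk1 + dahs_dz2 * zk2 + dahs_dz3 * zk3
  chain_corr <- x * (m - 1) / gii        # weights of the ln g_ii terms
  dahc_dx <- m * a_hs + mbar * dahs_dx - (m - 1) * log(gii) -
    vapply(1:n, function(k)
      sum(chain_corr * (dgii_dz2 * zk2[k] + dgii_dz3 * zk3[k])), 0)
  # density derivative (fixed x); all zeta ~ rho
  dahs_drho <- (dahs_dz0 * z0 + dahs_dz1 * z1 + dahs_dz2 * z2 +
                  dahs_dz3 * z3) / rho
  dahc_drho <- mbar * dahs_drho -
    sum(chain_corr * (dgii_dz2 * z2 + dgii_dz3 * z3)) / rho

  ## --- dispersion
  Tm1 <- 1 - 1 / mbar
  Tm2 <- 1 - 2 / mbar
  ai <- .disp_a[, 1] + Tm1 * .disp_a[, 2] + Tm1 * Tm2 * .disp_a[, 3]
  bi <- .disp_b[, 1] + Tm1 * .disp_b[, 2] + Tm1 * Tm2 * .disp_b[, 3]
  dai_dm <- .disp_a[, 2] / mbar^2 +
    .disp_a[, 3] * (Tm2 / mbar^2 + 2 * Tm1 / mbar^2)
  dbi_dm <- .disp_b[, 2] / mbar^2 +
    .disp_b[, 3] * (Tm2 / mbar^2 + 2 * Tm1 / mbar^2)
  pow <- eta^(0:6)
  I1 <- sum(ai * pow); I2 <- sum(bi * pow)
  dI1_deta <- sum(ai * (0:6) * c(0, pow[1:6]))
  dI2_deta <- sum(bi * (0:6) * c(0, pow[1:6]))
  dI1_dm <- sum(dai_dm * pow); dI2_dm <- sum(dbi_dm * pow)

  ue <- sys$u_ij / sys$temperature
  A1 <- outer(x * m, x * m) * ue * sys$s_ij^3      # for m2 eps sigma^3
  A2 <- A1 * ue
  m2es3 <- sum(A1); m2e2s3 <- sum(A2)
  # d(m2es3)/dx_k = 2 m_k sum_j x_j m_j (u_kj/T) s_kj^3
  dm2es3_dx <- 2 * m * as.numeric((ue * sys$s_ij^3) %*% (x * m))
  dm2e2s3_dx <- 2 * m * as.numeric((ue^2 * sys$s_ij^3) %*% (x * m))

  C1den <- 1 + mbar * (8 * eta - 2 * eta^2) / om^4 +
    (1 - mbar) * (20 * eta - 27 * eta^2 + 12 * eta^3 - 2 * eta^4) /
    (om * (2 - eta))^2
  C1 <- 1 / C1den
  C2 <- -C1^2 * (mbar * (-4 * eta^2 + 20 * eta + 8) / om^5 +
                   (1 - mbar) * (2 * eta^3 + 12 * eta^2 - 48 * eta + 40) /
                   (om * (2 - eta))^3)
  dC1_dm <- -C1^2 * ((8 * eta - 2 * eta^2) / om^4 -
                       (20 * eta - 27 * eta^2 + 12 * eta^3 - 2 * eta^4) /
                       (om * (2 - eta))^2)

  a_disp <- -2 * pi * rho * I1 * m2es3 - pi * rho * mbar * C1 * I2 * m2e2s3
  dI1_dx <- dI1_deta * zk3 + dI1_dm * m
  dI2_dx <- dI2_deta * zk3 + dI2_dm * m
  dC1_dx <- C2 * zk3 + dC1_dm * m
  dadisp_dx <- -2 * pi * rho * (dI1_dx * m2es3 + I1 * dm2es3_dx) -
    pi * rho * (m * C1 * I2 * m2e2s3 +
                  mbar * (dC1_dx * I2 + C1 * dI2_dx) * m2e2s3 +
                  mbar * C1 * I2 * dm2e2s3_dx)
  dadisp_drho <- a_disp / rho +
    (-2 * pi * rho * dI1_deta * m2es3 -
       pi * rho * mbar * (C2 * I2 + C1 * dI2_deta) * m2e2s3) * z3 / rho

  ## --- association
  if (sys$any_sites) {
    Delta <- sys$assoc_pref * g
    Xs <- assoc_fractions(sys, x, rho, Delta, X_init)
    XD <- Xs$XD; XA <- Xs$XA
    fX <- function(X) log(X) - X / 2 + 0.5
    site_term <- sys$nd * fX(XD) + sys$na * fX(XA)
    site_term[!sys$has_sites] <- 0
    a_assoc <- sum(x * site_term)
    # envelope (Michelsen Q-function) derivatives: X held fixed
    W <- outer(sys$nd * XD, sys$na * XA) + outer(sys$na * XA, sys$nd * XD)
    B <- Delta * W                           # bond density kernel
    gq <- function(X) log(X) - X + 1
    term1 <- sys$nd * gq(XD) + sys$na * gq(XA)
    term1[!sys$has_sites] <- 0
    xxW <- outer(x, x) * W
    dDelta_fac <- sys$assoc_pref             # dDelta = pref * dg
    daassoc_dx <- term1 - rho * as.numeric(B %*% x) -
      rho / 2 * vapply(1:n, function(k)
        sum(xxW * dDelta_fac * (dg_dz2 * zk2[k] + dg_dz3 * zk3[k])), 0)
    daassoc_drho <- -0.5 * sum(xxW * (Delta +
      dDelta_fac * (dg_dz2 * z2 + dg_dz3 * z3)))
  } else {
    XD <- XA <- rep(1, n)
    a_assoc <- 0
    daassoc_dx <- rep(0, n)
    daassoc_drho <- 0
  }

  a_res <- a_hc + a_disp + a_assoc
  dadrho <- dahc_drho + dadisp_drho + daassoc_drho
  dadx <- dahc_dx + dadisp_dx + daassoc_dx
  Z <- 1 + rho * dadrho
  p <- Z * rho * 1e30 * .kB * sys$temperature

  list(a_hc = a_hc, a_disp = a_disp, a_assoc = a_assoc, a_res = a_res,
       dadrho = dadrho, dadx = dadx, Z = Z, pressure = p,
       eta = eta, rho = rho, XD = XD, XA = XA, mbar = mbar)
}

# number density (A^-3) from packing fraction
rho_from_eta <- function(sys, x, eta) eta / (pi / 6 * sum(x * sys$md3))

#' Residual Helmholtz energy of a mixture state
#'
#' Evaluates the three PC-SAFT contributions (hard chain, dispersion,
#' association) at a prescribed packing fraction, solving the Wertheim
#' mass balance self-consistently for the association term. A mixture of
#' only non-associating (or induced-association-only) components has an
#' exactly zero association contribution.
#'
#' @param state A [mixture_state()].
#' @param packing_fraction Reduced density eta in (0, 0.7405).
#' @param db A `parameter_db`.
#' @return An `eos_state` list: `mixture`, `packing_fraction`,
#'   `molar_density` (mol/m^3), `association_fractions` (list `XD`, `XA`,
#'   per-component unbonded fractions of donor/acceptor sites),
#'   `helmholtz_contributions` (named: hard_chain, dispersion,
#'   association, residual; per mole of molecules, units of kT),
#'   `compressibility` and `pressure` (Pa).
#' @export
residual_helmholtz <- function(state, packing_fraction, db) {
  sys <- pcsaft_system(db, state$component_ids, state$temperature)
  x <- state$mole_fractions
  rho <- rho_from_eta(sys, x, packing_fraction)
  ev <- eos_eval(sys, x, rho)
  structure(list(
    mixture = state,
    packing_fraction = ev$eta,
    molar_density = rho * 1e30 / .N_Avogadro,
    association_fractions = list(XD = stats::setNames(ev$XD, sys$component_ids),
                                 XA = stats::setNames(ev$XA, sys$component_ids)),
    helmholtz_contributions = c(hard_chain = ev$a_hc,
                                dispersion = ev$a_disp,
                                association = ev$a_assoc,
                                residual = ev$a_res),
    compressibility = ev$Z,
    pressure = ev$pressure
  ), class = "eos_state")
}

#' Unbonded association-site fractions
#'
#' Solves the Wertheim mass-balance fixed point for the fractions of
#' donor and acceptor sites not engaged in a hydrogen bond. Donor sites
#' bond only to acceptor sites and vice versa.
#'
#' @inheritParams residual_helmholtz
#' @return A list with per-component vectors `XD` and `XA` in (0, 1\].
#' @export
solve_association_fractions <- function(state, packing_fraction, db) {
  residual_helmholtz(state, packing_fraction, db)$association_fractions
}

# Pressure-explicit density solve on packing fraction. Returns the eos
# evaluation at the root. phase_hint selects among multiple roots:
# "liquid" takes the largest mechanically stable root, "vapor" the
# smallest.
solve_density_sys <- function(sys, x, pressure, phase_hint = "liquid",
                              eta_init = NULL) {
  f <- function(eta) {
    ev <- eos_eval(sys, x, rho_from_eta(sys, x, eta),
                   X_init = sys$cache$X_last)
    sys$cache$X_last <- list(XD = ev$XD, XA = ev$XA)
    ev$pressure - pressure
  }
  newton_polish <- function(eta) {
    for (k in 1:60) {
      fe <- f(eta)
      if (abs(fe) <= 1e-10 * pressure) return(eta)
      h <- max(1e-9, eta * 1e-7)
      dfe <- (f(eta + h) - f(eta - h)) / (2 * h)
      step <- fe / dfe
      eta_new <- eta - step
      if (!is.finite(eta_new) || eta_new <= 1e-12 || eta_new >= 0.7404)
        return(NA_real_)
      if (abs(step) < 1e-15) return(eta_new)
      eta <- eta_new
    }
    NA_real_
  }
  if (!is.null(eta_init) && is.finite(eta_init) &&
      eta_init > 1e-10 && eta_init < 0.74) {
    eta <- newton_polish(eta_init)
    if (is.finite(eta) && abs(f(eta)) <= 1e-9 * pressure) {
      ev <- eos_eval(sys, x, rho_from_eta(sys, x, eta))
      return(ev)
    }
  }
  if (phase_hint == "liquid") {
    # liquid branch: Newton from a dense start almost always lands on the
    # largest stable root; accept it when mechanically stable and dense,
    # fall back to the exhaustive bracketing scan otherwise
    eta <- newton_polish(0.45)
    if (is.finite(eta) && eta > 0.15 && abs(f(eta)) <= 1e-9 * pressure) {
      h <- max(1e-9, eta * 1e-6)
      if ((f(eta + h) - f(eta - h)) / (2 * h) > 0) {
        ev <- eos_eval(sys, x, rho_from_eta(sys, x, eta))
        return(ev)
      }
    }
  }
  # bracketing scan over the full packing-fraction range
  grid <- c(1e-10, 1e-8, 1e-6, 1e-5, 1e-4, 1e-3,
            seq(0.005, 0.7400, length.out = 120))
  fv <- vapply(grid, function(e) tryCatch(f(e), error = function(err) NA_real_),
               0)
  ok <- is.finite(fv)
  roots <- c()
  idx <- which(ok)
  for (k in seq_len(length(idx) - 1)) {
    i1 <- idx[k]; i2 <- idx[k + 1]
    if (i2 == i1 + 1 && fv[i1] * fv[i2] <= 0) {
      r <- stats::uniroot(f, c(grid[i1], grid[i2]),
                          f.lower = fv[i1], f.upper = fv[i2],
                          tol = .Machine$double.eps)$root
      r <- newton_polish(r)
      if (is.finite(r)) roots <- c(roots, r)
    }
  }
  if (length(roots) == 0)
    stop(errorCondition(
      sprintf("no density root in (1e-10, 0.7405) at T = %g K, p = %g Pa",
              sys$temperature, pressure),
      class = c("cocrysol_numerical_error", "error", "condition")))
  # mechanical stability: dp/deta > 0
  stable <- vapply(roots, function(r) {
    h <- max(1e-9, r * 1e-6)
    (f(r + h) - f(r - h)) / (2 * h) > 0
  }, TRUE)
  cand <- if (any(stable)) roots[stable] else roots
  eta <- if (phase_hint == "liquid") max(cand) else min(cand)
  eos_eval(sys, x, rho_from_eta(sys, x, eta))
}

#' Solve the equation of state for density
#'
#' Finds the packing fraction at which the PC-SAFT pressure equals the
#' state's pressure (relative residual below 1e-9). When the equation of
#' state admits several roots the `phase_hint` selects the liquid-like
#' (largest packing fraction with positive compressibility slope) or
#' vapor-like (smallest) solution.
#'
#' @inheritParams residual_helmholtz
#' @param phase_hint `"liquid"` or `"vapor"`.
#' @return An `eos_state` (see [residual_helmholtz()]).
#' @export
solve_density <- function(state, db, phase_hint = c("liquid", "vapor")) {
  phase_hint <- match.arg(phase_hint)
  sys <- pcsaft_system(db, state$component_ids, state$temperature)
  ev <- solve_density_sys(sys, state$mole_fractions, state$pressure,
                          phase_hint)
  structure(list(
    mixture = state,
    packing_fraction = ev$eta,
    molar_density = ev$rho * 1e30 / .N_Avogadro,
    association_fractions = list(
      XD = stats::setNames(ev$XD, sys$component_ids),
      XA = stats::setNames(ev$XA, sys$component_ids)),
    helmholtz_contributions = c(hard_chain = ev$a_hc,
                                dispersion = ev$a_disp,
                                association = ev$a_assoc,
                                residual = ev$a_res),
    compressibility = ev$Z,
    pressure = ev$pressure
  ), class = "eos_state")
}

# ln(fugacity coefficient) vector from an eos_eval result
lnphi_from_eval <- function(ev, x) {
  ev$a_res + (ev$Z - 1) + ev$dadx - sum(x * ev$dadx) - log(ev$Z)
}

# Pure-liquid reference fugacities depend only on the pure-component
# parameters, T and p (never on kij), so they are cached package-wide;
# the key carries the full parameter signature to stay valid when a
# database is modified.
.pure_ref_cache <- new.env(parent = emptyenv())

# Internal gamma: symmetric-convention activity coefficients for the
# components of `sys` at composition x, pressure p.
gamma_sys <- function(sys, x, pressure = 101325) {
  ev <- solve_density_sys(sys, x, pressure, "liquid",
                          eta_init = sys$cache$eta_last)
  sys$cache$eta_last <- ev$eta
  lnphi_mix <- lnphi_from_eval(ev, x)
  lnphi_pure <- vapply(seq_len(sys$n), function(i) {
    key <- paste(sys$component_ids[i], sys$temperature, pressure,
                 sys$m[i], sys$sigma[i], sys$u[i], sys$eps_ab[i, i],
                 sys$kap_ab[i, i], sys$nd[i], sys$na[i], sep = "|")
    hit <- .pure_ref_cache[[key]]
    if (!is.null(hit)) return(hit)
    xi <- rep(0, sys$n); xi[i] <- 1
    evp <- solve_density_sys(sys, xi, pressure, "liquid")
    val <- lnphi_from_eval(evp, xi)[i]
    assign(key, val, envir = .pure_ref_cache)
    val
  }, 0)
  gamma <- exp(lnphi_mix - lnphi_pure)
  stats::setNames(gamma, sys$component_ids)
}

#' Activity coefficients from PC-SAFT
#'
#' Symmetric-convention activity coefficients gamma_i =
#' phi_i(T, p, x) / phi_i^pure-liquid(T, p), with fugacity coefficients
#' obtained from residual chemical potentials at the liquid density root.
#' Solid solutes below their melting point use the (subcooled) liquid
#' root of the equation of state as reference. gamma_i -> 1 as x_i -> 1.
#'
#' @param state A [mixture_state()].
#' @param db A `parameter_db`.
#' @return Named vector of activity coefficients, one per component.
#' @export
activity_coefficients <- function(state, db) {
  sys <- pcsaft_system(db, state$component_ids, state$temperature)
  gamma_sys(sys, state$mole_fractions, state$pressure)
}
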