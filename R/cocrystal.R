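# Cocrystal solubility-product machinery: Ks from a saturation point,
# its Gibbs-Helmholtz temperature scaling, cocrystal solubility lines,
# eutectic points and ternary phase-diagram assembly.

#' Solubility product from one saturation point
#'
#' Ks = (x_API gamma_API)^nu_API (x_CF gamma_CF)^nu_CF. Under the model
#' the value is independent of the solvent or solvent/anti-solvent
#' mixture and of concentration; it varies only with temperature, so a
#' single cocrystal saturation point fixes it.
#'
#' @param x_api,x_cf Saturation mole fractions of API and coformer.
#' @param gamma_api,gamma_cf Their activity coefficients.
#' @param nu_api,nu_cf Stoichiometric coefficients (positive integers).
#' @return The dimensionless solubility product.
#' @export
ks_from_point <- function(x_api, x_cf, gamma_api, gamma_cf,
                          nu_api, nu_cf) {
  stopifnot(all(c(x_api, x_cf, gamma_api, gamma_cf) > 0),
            nu_api >= 1, nu_cf >= 1)
  (x_api * gamma_api)^nu_api * (x_cf * gamma_cf)^nu_cf
}

#' Ideal solubility product (activity coefficients neglected)
#'
#' Ks_ideal = x_API^nu_API x_CF^nu_CF. Unlike the activity-based
#' solubility product this quantity is specific to one saturation point
#' and one solvent mixture; it equals [ks_from_point()] exactly when
#' both activity coefficients are one.
#'
#' @inheritParams ks_from_point
#' @return The dimensionless ideal solubility product.
#' @export
ks_ideal_from_point <- function(x_api, x_cf, nu_api, nu_cf) {
  stopifnot(all(c(x_api, x_cf) > 0), nu_api >= 1, nu_cf >= 1)
  x_api^nu_api * x_cf^nu_cf
}

#' Solubility product at another temperature
#'
#' Gibbs-Helmholtz scaling of the reference solubility product:
#' ln Ks(T) = ln Ks_ref + dh_ref/R (1/T_ref - 1/T), with the reference
#' enthalpy assumed constant over the temperature interval. The mapping
#' is exactly invertible and, for positive dh_ref, strictly increasing
#' in temperature.
#'
#' @param cc A `cocrystal_definition` (ks_ref, t_ref in K, dh_ref in
#'   kJ/mol).
#' @param temperature Target temperature in K (> 0). May be a vector.
#' @param R Ideal gas constant, J/(mol K).
#' @return The dimensionless solubility product at `temperature`.
#' @export
ks_at_temperature <- function(cc, temperature, R = 8.314) {
  stopifnot(all(temperature > 0))
  exp(log(cc$ks_ref) +
        cc$dh_ref * 1000 / R * (1 / cc$t_ref - 1 / temperature))
}

#' Cocrystal solubility line in a solvent mixture
#'
#' Traces the locus of liquid compositions in equilibrium with the
#' cocrystal solid at fixed temperature and solute-free solvent
#' composition. The line is parameterized by the solute mole ratio
#' r = x_API / x_CF on a logarithmic grid; for each r the common scale
#' s (x_CF = s, x_API = r s) solves
#' (r s gamma_API)^nu_API (s gamma_CF)^nu_CF = Ks
#' by bracketed one-dimensional root finding in ln s, with the activity
#' coefficients evaluated at the full liquid composition. Only
#' converged nodes are returned; failures are flagged in the
#' `failed_ratios` attribute.
#'
#' @param cc A `cocrystal_definition`.
#' @param solvent_composition Named solute-free solvent mass fractions.
#' @param temperature Temperature in K.
#' @param db A `parameter_db`.
#' @param ratio_grid Grid of API/CF mole ratios (default 41 log-spaced
#'   nodes over \[0.02, 50\]).
#' @param ks Solubility product to use; defaults to
#'   [ks_at_temperature()] evaluated from the definition's reference.
#' @param pressure Pressure in Pa.
#' @return A `cocrystal_line`: data frame with columns `x_api`, `x_cf`,
#'   `gamma_api`, `gamma_cf`, `ratio`; attributes `cc`, `ks_used`,
#'   `solvent_composition`, `temperature`, `line_type = "cc"`.
#' @export
cc_solubility_line <- function(cc, solvent_composition, temperature, db,
                               ratio_grid = exp(seq(log(0.02), log(50),
                                                    length.out = 41)),
                               ks = NULL, pressure = 101325) {
  if (is.null(ks)) ks <- ks_at_temperature(cc, temperature, db$R)
  w <- solvent_composition / sum(solvent_composition)
  ids <- c(cc$api_id, cc$cf_id, names(w))
  sys <- pcsaft_system(db, ids, temperature)
  phi <- solvent_mole_split(db, w)
  nu_t <- cc$nu_api + cc$nu_cf
  rows <- list(); failed <- c()
  for (r in ratio_grid) {
    comp_x <- function(s) c(r * s, s, unname(phi) * (1 - s - r * s))
    resid <- function(u) {
      s <- exp(u)
      g <- gamma_sys(sys, comp_x(s), pressure)
      cc$nu_api * log(r * s * g[[cc$api_id]]) +
        cc$nu_cf * log(s * g[[cc$cf_id]]) - log(ks)
    }
    u0 <- log((ks / r^cc$nu_api)^(1 / nu_t))
    s_cap <- 0.45 / (1 + r)              # leave room for solvent
    out <- tryCatch({
      lo <- u0 - 1; hi <- min(u0 + 1, log(s_cap))
      flo <- resid(lo); fhi <- resid(hi); it <- 0
      while (flo > 0 && it < 40) { lo <- lo - 1; flo <- resid(lo); it <- it + 1 }
      while (fhi < 0 && hi < log(s_cap) - 1e-12 && it < 80) {
        hi <- min(hi + 1, log(s_cap)); fhi <- resid(hi); it <- it + 1
      }
      if (flo * fhi > 0) stop("no bracket for cocrystal scale")
      root <- stats::uniroot(resid, c(lo, hi), f.lower = flo,
                             f.upper = fhi, tol = 1e-10)
      s <- exp(root$root)
      g <- gamma_sys(sys, comp_x(s), pressure)
      data.frame(x_api = r * s, x_cf = s,
                 gamma_api = g[[cc$api_id]], gamma_cf = g[[cc$cf_id]],
                 ratio = r)
    }, error = function(e) NULL)
    if (is.null(out)) failed <- c(failed, r) else rows[[length(rows) + 1]] <- out
  }
  if (length(rows) == 0)
    stop(errorCondition("cocrystal solubility line: no node converged",
                        class = c("cocrysol_numerical_error", "error",
                                  "condition")))
  line <- do.call(rbind, rows)
  structure(line, cc = cc, ks_used = ks, solvent_composition = w,
            temperature = temperature, line_type = "cc",
            failed_ratios = failed, class = c("cocrystal_line",
                                              "data.frame"))
}

#' Solute solubility line in the presence of the other cocrystal former
#'
#' Saturation of a single solute (API or coformer) at a grid of fixed
#' cosolute mole fractions, each point solved from the solid-liquid
#' equilibrium condition with PC-SAFT activity coefficients at the full
#' liquid composition. The first point of a grid starting at zero
#' cosolute equals the single-solute solubility.
#'
#' @param solute_id Component id of the crystallizing solute.
#' @param cosolute_id Component id of the dissolved cosolute.
#' @param cosolute_grid Mole fractions of the cosolute in the total
#'   liquid (each below the cosolute's own saturation).
#' @param solvent_composition Named solute-free solvent mass fractions.
#' @param temperature Temperature in K.
#' @param db A `parameter_db`.
#' @return A `solute_line`: data frame with columns `x_solute`,
#'   `x_cosolute`, `gamma_solute`, `gamma_cosolute`, `status`;
#'   attributes `solute_id`, `cosolute_id`, `x_ideal`,
#'   `solvent_composition`, `temperature`, `line_type = "solute"`.
#' @export
api_or_cf_line_with_cosolute <- function(solute_id, cosolute_id,
                                         cosolute_grid,
                                         solvent_composition,
                                         temperature, db) {
  w <- solvent_composition / sum(solvent_composition)
  rows <- lapply(cosolute_grid, function(xc) {
    cos <- if (xc > 0) stats::setNames(xc, cosolute_id) else NULL
    pt <- tryCatch(solve_solubility(solute_id, w, temperature, db,
                                    cosolute_amounts = cos),
                   error = function(e) NULL)
    if (is.null(pt) || is.na(pt$x_solute))
      data.frame(x_solute = NA_real_, x_cosolute = xc,
                 gamma_solute = NA_real_, gamma_cosolute = NA_real_,
                 status = if (is.null(pt)) "failed" else pt$status)
    else
      data.frame(x_solute = pt$x_solute, x_cosolute = xc,
                 gamma_solute = pt$gamma_solute,
                 gamma_cosolute = if (xc > 0)
                   pt$gamma_all[[cosolute_id]] else NA_real_,
                 status = pt$status)
  })
  line <- do.call(rbind, rows)
  mp <- db$melting[[solute_id]]
  structure(line, solute_id = solute_id, cosolute_id = cosolute_id,
            x_ideal = ideal_solubility(mp, temperature, db$R),
            solvent_composition = w, temperature = temperature,
            line_type = "solute",
            class = c("solute_line", "data.frame"))
}

# Canonical (x_api, x_cf) view of any line, given which id plays the API
# role. Solute lines are mapped through their solute/cosolute ids.
line_as_api_cf <- function(line, api_id, cf_id) {
  if (attr(line, "line_type") == "cc")
    return(data.frame(x_api = line$x_api, x_cf = line$x_cf,
                      gamma_api = line$gamma_api,
                      gamma_cf = line$gamma_cf))
  sid <- attr(line, "solute_id")
  if (sid == api_id)
    data.frame(x_api = line$x_solute, x_cf = line$x_cosolute,
               gamma_api = line$gamma_solute,
               gamma_cf = line$gamma_cosolute)
  else
    data.frame(x_api = line$x_cosolute, x_cf = line$x_solute,
               gamma_api = line$gamma_cosolute,
               gamma_cf = line$gamma_solute)
}

# Equilibrium residual of a line's defining condition at a liquid
# composition, using precomputed gammas when supplied.
line_residual <- function(line, x_api, x_cf, gamma_api, gamma_cf,
                          api_id, cf_id) {
  if (attr(line, "line_type") == "cc") {
    cc <- attr(line, "cc")
    cc$nu_api * log(x_api * gamma_api) + cc$nu_cf * log(x_cf * gamma_cf) -
      log(attr(line, "ks_used"))
  } else {
    xi <- attr(line, "x_ideal")
    if (attr(line, "solute_id") == api_id)
      log(x_api * gamma_api) - log(xi)
    else
      log(x_cf * gamma_cf) - log(xi)
  }
}

#' Locate the eutectic point of two solubility lines
#'
#' A eutectic is a liquid composition simultaneously saturated with
#' respect to both solids (visible as a kink where the lines meet). The
#' discrete crossing is detected by evaluating each line's equilibrium
#' residual along the other line's stored points; the seed is then
#' refined by a damped two-dimensional Newton iteration in
#' (ln x_API, ln x_CF) on the pair of equilibrium conditions, with
#' activity coefficients re-evaluated by PC-SAFT at every step. The
#' result is symmetric in the argument order.
#'
#' @param line_a,line_b Two lines (`cocrystal_line` or `solute_line`)
#'   computed at the same temperature and solvent composition.
#' @param db The `parameter_db` used to build the lines.
#' @return A `eutectic_point` list (`x_api`, `x_cf`, `gamma_api`,
#'   `gamma_cf`, `residuals`, `converged`), or `NULL` (with a message)
#'   when the lines do not cross in the sampled region - a legitimate
#'   outcome, not an error.
#' @export
locate_eutectic <- function(line_a, line_b, db) {
  cc <- attr(line_a, "cc") %||% attr(line_b, "cc")
  if (is.null(cc))
    stop("at least one line must be a cocrystal line (to fix the API/CF roles)")
  api_id <- cc$api_id; cf_id <- cc$cf_id
  temperature <- attr(line_a, "temperature")
  w <- attr(line_a, "solvent_composition")
  stopifnot(abs(temperature - attr(line_b, "temperature")) < 1e-9)

  # residual of b along a's points (free: uses a's stored gammas); a
  # zero mole fraction makes the cocrystal residual -Inf, which still
  # carries the sign information needed for bracketing
  pa <- line_as_api_cf(line_a, api_id, cf_id)
  pa <- pa[is.finite(pa$x_api) & is.finite(pa$x_cf) &
             pa$x_api >= 0 & pa$x_cf >= 0, ]
  rb <- vapply(seq_len(nrow(pa)), function(i) {
    if (attr(line_b, "line_type") == "cc" &&
        (pa$x_api[i] <= 0 || pa$x_cf[i] <= 0)) return(-Inf)
    line_residual(line_b, pa$x_api[i], pa$x_cf[i], pa$gamma_api[i],
                  pa$gamma_cf[i], api_id, cf_id)
  }, 0)
  sc <- which(diff(sign(rb)) != 0 & is.finite(diff(sign(rb))))
  if (length(sc) == 0) {
    message("lines do not cross in the sampled region; no eutectic")
    return(NULL)
  }
  i <- sc[1]
  tfrac <- if (!is.finite(rb[i])) 1
  else if (!is.finite(rb[i + 1])) 0
  else abs(rb[i]) / (abs(rb[i]) + abs(rb[i + 1]))
  # seed strictly inside the positive quadrant
  lo_pt <- pmax(c(pa$x_api[i], pa$x_cf[i]),
                0.05 * c(pa$x_api[i + 1], pa$x_cf[i + 1]))
  z <- (1 - tfrac) * log(lo_pt) +
    tfrac * log(c(pa$x_api[i + 1], pa$x_cf[i + 1]))

  ids <- c(api_id, cf_id, names(w))
  sys <- pcsaft_system(db, ids, temperature)
  phi <- solvent_mole_split(db, w)
  Fz <- function(z) {
    xa <- exp(z[1]); xc <- exp(z[2])
    g <- gamma_sys(sys, c(xa, xc, unname(phi) * (1 - xa - xc)))
    c(line_residual(line_a, xa, xc, g[[api_id]], g[[cf_id]], api_id, cf_id),
      line_residual(line_b, xa, xc, g[[api_id]], g[[cf_id]], api_id, cf_id))
  }
  fv <- Fz(z)
  for (it in 1:50) {
    if (max(abs(fv)) < 1e-9) break
    J <- matrix(0, 2, 2); h <- 1e-6
    for (k in 1:2) {
      zp <- z; zp[k] <- z[k] + h
      zm <- z; zm[k] <- z[k] - h
      J[, k] <- (Fz(zp) - Fz(zm)) / (2 * h)
    }
    step <- solve(J, fv)
    lam <- 1
    repeat {
      z_new <- z - lam * step
      f_new <- tryCatch(Fz(z_new), error = function(e) NULL)
      if (!is.null(f_new) && max(abs(f_new)) < max(abs(fv)) * 0.999) break
      lam <- lam / 2
      if (lam < 1e-4) { f_new <- fv; z_new <- z; break }
    }
    z <- z_new; fv <- f_new
    if (lam < 1e-4) break
  }
  xa <- exp(z[1]); xc <- exp(z[2])
  g <- gamma_sys(sys, c(xa, xc, unname(phi) * (1 - xa - xc)))
  structure(list(x_api = xa, x_cf = xc,
                 gamma_api = g[[api_id]], gamma_cf = g[[cf_id]],
                 residuals = fv, converged = max(abs(fv)) < 1e-6),
            class = "eutectic_point")
}

#' Assemble a ternary phase diagram
#'
#' Builds the three solubility lines of an API/CF/solvent(/anti-solvent)
#' system at fixed temperature - API solid with CF as cosolute, CF solid
#' with API as cosolute, and the cocrystal line - locates the two
#' eutectic points, and clips every line to its stable segment: the
#' cocrystal is stable between the eutectics, the single-component
#' solids outside. Stability follows the line-crossing (kink) logic:
#' a point of one line is kept where the liquid is undersaturated with
#' respect to the other solids.
#'
#' @param cc A `cocrystal_definition`.
#' @param solvent_composition Named solute-free solvent mass fractions.
#' @param temperature Temperature in K.
#' @param db A `parameter_db`.
#' @param n_cosolute Nodes on each single-solid line.
#' @param ratio_grid Mole-ratio grid for the cocrystal line (see
#'   [cc_solubility_line()]).
#' @param ks Optional solubility product override.
#' @return A `ternary_phase_diagram` list: `api_line`, `cf_line`,
#'   `cc_line` (clipped, in canonical `x_api`/`x_cf` columns with a
#'   `branch` label), `eutectic_api_cc`, `eutectic_cf_cc`, the unclipped
#'   lines (`*_full`), `solvent_composition`, `temperature`, `ks_used`.
#' @export
build_phase_diagram <- function(cc, solvent_composition, temperature, db,
                                n_cosolute = 10,
                                ratio_grid = exp(seq(log(0.05), log(20),
                                                     length.out = 25)),
                                ks = NULL) {
  w <- solvent_composition / sum(solvent_composition)
  sat_api <- solve_solubility(cc$api_id, w, temperature, db)
  sat_cf <- solve_solubility(cc$cf_id, w, temperature, db)
  # cosolute grids reach past the partner's binary saturation: the
  # eutectic liquid is typically enriched in the cosolute because its
  # activity coefficient drops as the other former dissolves
  api_line <- api_or_cf_line_with_cosolute(
    cc$api_id, cc$cf_id,
    seq(0, 2 * sat_cf$x_solute, length.out = n_cosolute),
    w, temperature, db)
  cf_line <- api_or_cf_line_with_cosolute(
    cc$cf_id, cc$api_id,
    seq(0, 2 * sat_api$x_solute, length.out = n_cosolute),
    w, temperature, db)
  cc_line <- cc_solubility_line(cc, w, temperature, db,
                                ratio_grid = ratio_grid, ks = ks)
  eu_api <- locate_eutectic(api_line, cc_line, db)
  eu_cf <- locate_eutectic(cf_line, cc_line, db)

  canon <- function(line) {
    out <- line_as_api_cf(line, cc$api_id, cc$cf_id)
    out[stats::complete.cases(out[, c("x_api", "x_cf")]), ]
  }
  capi <- canon(api_line); ccf <- canon(cf_line); cccl <- canon(cc_line)
  lk <- log(attr(cc_line, "ks_used"))
  res_cc <- function(p) {
    a <- ifelse(p$x_api > 0, cc$nu_api * log(p$x_api * p$gamma_api), -Inf)
    b <- ifelse(p$x_cf > 0, cc$nu_cf * log(p$x_cf * p$gamma_cf), -Inf)
    a + b - lk
  }
  # single-solid branches stable where undersaturated wrt the cocrystal
  if (!is.null(eu_api)) {
    keep <- res_cc(capi) < 0
    capi <- capi[keep, ]
    capi <- rbind(capi, data.frame(x_api = eu_api$x_api, x_cf = eu_api$x_cf,
                                   gamma_api = eu_api$gamma_api,
                                   gamma_cf = eu_api$gamma_cf))
  }
  if (!is.null(eu_cf)) {
    keep <- res_cc(ccf) < 0
    ccf <- ccf[keep, ]
    ccf <- rbind(ccf, data.frame(x_api = eu_cf$x_api, x_cf = eu_cf$x_cf,
                                 gamma_api = eu_cf$gamma_api,
                                 gamma_cf = eu_cf$gamma_cf))
  }
  # cocrystal branch stable between the eutectics (kept where the liquid
  # is undersaturated with respect to both single-component solids)
  res_api <- log(cccl$x_api * cccl$gamma_api) - log(attr(api_line, "x_ideal"))
  res_cf <- log(cccl$x_cf * cccl$gamma_cf) - log(attr(cf_line, "x_ideal"))
  keep <- res_api < 0 & res_cf < 0
  cccl <- cccl[keep, ]
  if (!is.null(eu_api))
    cccl <- rbind(data.frame(x_api = eu_api$x_api, x_cf = eu_api$x_cf,
                             gamma_api = eu_api$gamma_api,
                             gamma_cf = eu_api$gamma_cf), cccl)
  if (!is.null(eu_cf))
    cccl <- rbind(cccl, data.frame(x_api = eu_cf$x_api, x_cf = eu_cf$x_cf,
                                   gamma_api = eu_cf$gamma_api,
                                   gamma_cf = eu_cf$gamma_cf))
  lab <- function(df, b) { df$branch <- b; df }
  structure(list(
    api_line = lab(capi, cc$api_id),
    cf_line = lab(ccf, cc$cf_id),
    cc_line = lab(cccl, "CC"),
    eutectic_api_cc = eu_api, eutectic_cf_cc = eu_cf,
    api_line_full = api_line, cf_line_full = cf_line,
    cc_line_full = cc_line,
    sat_api = sat_api, sat_cf = sat_cf,
    solvent_composition = w, temperature = temperature,
    ks_used = attr(cc_line, "ks_used"), cc = cc
  ), class = "ternary_phase_diagram")
}

#' @export
print.ternary_phase_diagram <- function(x, ...) {
  cat(sprintf("<ternary_phase_diagram> %s/%s in %s at %.2f K\n",
              x$cc$api_id, x$cc$cf_id,
              paste(sprintf("%s:%.3g", names(x$solvent_composition),
                            x$solvent_composition), collapse = ","),
              x$temperature))
  cat(sprintf("  Ks = %.4g; branches: %d API, %d CC, %d CF points\n",
              x$ks_used, nrow(x$api_line), nrow(x$cc_line),
              nrow(x$cf_line)))
  for (nm in c("eutectic_api_cc", "eutectic_cf_cc"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %s: x_API = %.5g, x_CF = %.5g\n", nm,
                  x[[nm]]$x_api, x[[nm]]$x_cf))
  invisible(x)
}
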