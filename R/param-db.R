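#' Load a PC-SAFT parameter database
#'
#' Reads a structured JSON parameter file into a validated `parameter_db`
#' object holding pure-component PC-SAFT parameters, melting properties,
#' temperature-dependent binary interaction parameters and cocrystal
#' solubility-product definitions. The packaged default (`path =
#' "packaged"`) carries the nicotinamide (NA) / succinic acid (SA) 2:1
#' cocrystal system together with the solvents water, ethanol,
#' acetonitrile and ethyl acetate.
#'
#' Component ids are case-sensitive tokens (`NA`, `SA`, `water`,
#' `ethanol`, `acetonitrile`, `ethyl_acetate` in the packaged database).
#'
#' @param path Path to a JSON parameter document, or `"packaged"` for the
#'   database shipped with the package.
#' @return An object of class `parameter_db`: a list with elements
#'   `components`, `melting`, `binaries`, `cocrystals` (named lists) and
#'   `R`, the ideal gas constant in J/(mol K).
#' @export
#' @examples
#' db <- load_parameter_db()
#' db$components[["NA"]]$segment_number
load_parameter_db <- function(path = "packaged") {
  if (identical(path, "packaged")) {
    path <- system.file("extdata", "pcsaft_parameters.json",
                        package = "cocrysol", mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  db <- list(
    components = stats::setNames(
      lapply(raw$components, new_pure_params),
      vapply(raw$components, `[[`, "", "component_id")),
    melting = stats::setNames(
      lapply(raw$melting, new_melting_properties),
      vapply(raw$melting, `[[`, "", "component_id")),
    binaries = stats::setNames(
      lapply(raw$binaries, new_binary_interaction),
      vapply(raw$binaries, function(b) pair_key(b$pair[1], b$pair[2]), "")),
    cocrystals = stats::setNames(
      lapply(raw$cocrystals, new_cocrystal_definition),
      vapply(raw$cocrystals, `[[`, "", "cocrystal_id")),
    R = if (!is.null(raw$universal_gas_constant))
      raw$universal_gas_constant else 8.314
  )
  class(db) <- "parameter_db"
  validate_parameter_db(db)
  db
}

#' Serialize a parameter database to JSON
#'
#' Writes `db` in the same JSON layout accepted by [load_parameter_db()],
#' so that a serialize/load round trip reproduces the database
#' field-for-field.
#'
#' @param db A `parameter_db` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_db <- function(db, path) {
  doc <- list(
    components = lapply(unname(db$components), unclass),
    melting = lapply(unname(db$melting), unclass),
    binaries = lapply(unname(db$binaries), unclass),
    cocrystals = lapply(unname(db$cocrystals), unclass),
    universal_gas_constant = db$R
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

new_pure_params <- function(rec) {
  rec$molar_mass <- as.numeric(rec$molar_mass)
  rec$segment_number <- as.numeric(rec$segment_number)
  rec$dispersion_energy <- as.numeric(rec$dispersion_energy)
  rec$assoc_energy <- as.numeric(rec$assoc_energy)
  rec$assoc_volume <- as.numeric(rec$assoc_volume)
  rec$n_donor_sites <- as.integer(rec$n_donor_sites)
  rec$n_acceptor_sites <- as.integer(rec$n_acceptor_sites)
  rec$induced_association <- isTRUE(rec$induced_association)
  if (!is.null(rec$segment_diameter))
    rec$segment_diameter <- as.numeric(rec$segment_diameter)
  structure(rec, class = "pure_component_params")
}

new_melting_properties <- function(rec) {
  structure(list(
    component_id = rec$component_id,
    melting_temperature = as.numeric(rec$melting_temperature),
    fusion_enthalpy = as.numeric(rec$fusion_enthalpy),
    delta_cp = as.numeric(rec$delta_cp)
  ), class = "melting_properties")
}

new_binary_interaction <- function(rec) {
  structure(list(
    pair = as.character(rec$pair),
    k_slope = as.numeric(rec$k_slope),
    k_intercept = as.numeric(rec$k_intercept),
    valid_T_range = as.numeric(rec$valid_T_range),
    provenance = rec$provenance
  ), class = "binary_interaction")
}

new_cocrystal_definition <- function(rec) {
  structure(list(
    cocrystal_id = rec$cocrystal_id,
    api_id = rec$api_id,
    cf_id = rec$cf_id,
    nu_api = as.integer(rec$nu_api),
    nu_cf = as.integer(rec$nu_cf),
    ks_ref = as.numeric(rec$ks_ref),
    t_ref = as.numeric(rec$t_ref),
    dh_ref = as.numeric(rec$dh_ref)
  ), class = "cocrystal_definition")
}

#' Validate a parameter database
#'
#' Checks every structural invariant of the database: positivity of molar
#' masses and energies, segment numbers >= 1, association volumes in
#' \[0, 1\], the induced-association convention (zero self-association
#' energy, association volume 0.01), positive segment diameters over
#' 273-500 K, resolvable component references, distinct pair members,
#' kij(T) inside (-1, 1) over the stated validity range, and positive
#' melting/cocrystal parameters.
#'
#' @param db A `parameter_db` object.
#' @return `db`, invisibly. Throws a classed error
#'   (`cocrysol_validation_error` or `cocrysol_resolution_error`) naming
#'   the offending field otherwise.
#' @export
validate_parameter_db <- function(db) {
  fail <- function(msg, class = "cocrysol_validation_error") {
    stop(errorCondition(msg, class = c(class, "error", "condition")))
  }
  ids <- names(db$components)
  for (cp in db$components) {
    id <- cp$component_id
    if (!is.finite(cp$molar_mass) || cp$molar_mass <= 0)
      fail(sprintf("component %s: molar_mass must be > 0", id))
    if (cp$segment_number < 1)
      fail(sprintf("component %s: segment_number must be >= 1", id))
    if (cp$assoc_volume < 0 || cp$assoc_volume > 1)
      fail(sprintf("component %s: assoc_volume must lie in [0, 1]", id))
    if (cp$induced_association &&
        (cp$assoc_energy != 0 || cp$assoc_volume != 0.01))
      fail(sprintf(
        "component %s: induced association requires assoc_energy = 0 and assoc_volume = 0.01",
        id))
    if (cp$n_donor_sites + cp$n_acceptor_sites == 0 && cp$assoc_energy != 0)
      fail(sprintf("component %s: assoc_energy must be 0 without sites", id))
    sig <- vapply(seq(273, 500, by = 1), function(T)
      sigma_at_temperature(cp, T), 0)
    if (any(!is.finite(sig)) || any(sig <= 0))
      fail(sprintf("component %s: segment_diameter must be > 0 on [273, 500] K", id))
  }
  for (mp in db$melting) {
    if (!mp$component_id %in% ids)
      fail(sprintf("melting: unknown component %s", mp$component_id),
           "cocrysol_resolution_error")
    if (mp$melting_temperature <= 273)
      fail(sprintf("melting %s: melting_temperature must exceed 273 K",
                   mp$component_id))
    if (mp$fusion_enthalpy <= 0)
      fail(sprintf("melting %s: fusion_enthalpy must be > 0", mp$component_id))
    if (mp$delta_cp < 0)
      fail(sprintf("melting %s: delta_cp must be >= 0", mp$component_id))
  }
  for (bi in db$binaries) {
    if (!all(bi$pair %in% ids))
      fail(sprintf("binaries: unknown component in pair %s",
                   paste(bi$pair, collapse = "/")),
           "cocrysol_resolution_error")
    if (bi$pair[1] == bi$pair[2])
      fail(sprintf("binaries: pair members must be distinct (%s)", bi$pair[1]))
    kk <- bi$k_slope * bi$valid_T_range + bi$k_intercept
    if (any(abs(kk) >= 1))
      fail(sprintf("binaries %s: kij(T) must lie in (-1, 1) over valid_T_range",
                   paste(bi$pair, collapse = "/")))
  }
  for (cc in db$cocrystals) {
    if (!all(c(cc$api_id, cc$cf_id) %in% ids))
      fail(sprintf("cocrystal %s: unknown component reference", cc$cocrystal_id),
           "cocrysol_resolution_error")
    if (cc$nu_api < 1 || cc$nu_cf < 1)
      fail(sprintf("cocrystal %s: stoichiometric coefficients must be >= 1",
                   cc$cocrystal_id))
    if (cc$ks_ref <= 0 || cc$t_ref <= 0)
      fail(sprintf("cocrystal %s: ks_ref and t_ref must be > 0", cc$cocrystal_id))
  }
  invisible(db)
}

#' Temperature-dependent binary interaction parameter
#'
#' Evaluates the linear temperature rule kij(T) = k_slope * T +
#' k_intercept. A warning is emitted when `T` lies outside the validity
#' range of the experimental data the pair was parameterized on; the
#' extrapolated value is still returned (the solvent/solvent pairs are
#' routinely applied outside their fitting temperatures).
#'
#' @param pair A `binary_interaction` object.
#' @param temperature Temperature in K (> 0). May be a vector.
#' @return kij(T), dimensionless.
#' @export
kij_at_temperature <- function(pair, temperature) {
  stopifnot(all(temperature > 0))
  rng <- pair$valid_T_range
  if (length(rng) == 2 &&
      any(temperature < rng[1] - 1e-9 | temperature > rng[2] + 1e-9))
    warning(sprintf("kij(%s) evaluated outside its validity range [%g, %g] K",
                    paste(pair$pair, collapse = "/"), rng[1], rng[2]),
            call. = FALSE)
  pair$k_slope * temperature + pair$k_intercept
}

#' Look up the binary interaction rule for a component pair
#'
#' Pairs absent from the database follow the default-zero rule
#' (k_slope = k_intercept = 0); the order of the two ids is immaterial.
#'
#' @param db A `parameter_db`.
#' @param id_a,id_b Component ids.
#' @return A `binary_interaction` object.
#' @export
db_binary <- function(db, id_a, id_b) {
  bi <- db$binaries[[pair_key(id_a, id_b)]]
  if (is.null(bi))
    bi <- new_binary_interaction(list(
      pair = c(id_a, id_b), k_slope = 0, k_intercept = 0,
      valid_T_range = c(0, Inf), provenance = "default_zero"))
  bi
}

#' Replace a binary interaction rule
#'
#' Returns a copy of `db` with the kij temperature rule of the
#' (unordered) pair set to the given slope and intercept. Used by the
#' fitting routines and by synthetic-data generation with non-packaged
#' "true" parameters.
#'
#' @param db A `parameter_db`.
#' @param id_a,id_b Component ids.
#' @param k_slope Slope of kij(T) in 1/K.
#' @param k_intercept Dimensionless intercept.
#' @return The modified `parameter_db`.
#' @export
set_binary <- function(db, id_a, id_b, k_slope, k_intercept) {
  db$binaries[[pair_key(id_a, id_b)]] <- new_binary_interaction(list(
    pair = c(id_a, id_b), k_slope = k_slope, k_intercept = k_intercept,
    valid_T_range = c(0, Inf), provenance = "user"))
  db
}

#' Segment diameter at temperature
#'
#' Returns the (possibly temperature-dependent) PC-SAFT segment diameter
#' of a component in Angstrom. Water carries an exponential temperature
#' rule; all other packaged components have constant diameters.
#'
#' @param comp A `pure_component_params` object.
#' @param temperature Temperature in K (> 0). May be a vector.
#' @return Segment diameter(s) in Angstrom.
#' @export
sigma_at_temperature <- function(comp, temperature) {
  stopifnot(all(temperature > 0))
  if (is.null(comp$sigma_rule)) {
    rep_len(comp$segment_diameter, length(temperature))
  } else {
    rule <- comp$sigma_rule
    out <- rep_len(rule$base, length(temperature))
    amps <- as.numeric(rule$terms$amplitude %||%
                         vapply(rule$terms, `[[`, 0, "amplitude"))
    rates <- as.numeric(rule$terms$rate %||%
                          vapply(rule$terms, `[[`, 0, "rate"))
    for (k in seq_along(amps))
      out <- out + amps[k] * exp(rates[k] * temperature)
    out
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.parameter_db <- function(x, ...) {
  cat("<parameter_db>\n")
  cat("  components:", paste(names(x$components), collapse = ", "), "\n")
  cat("  melting data:", paste(names(x$melting), collapse = ", "), "\n")
  cat("  binary pairs:", length(x$binaries), "\n")
  cat("  cocrystals:", paste(names(x$cocrystals), collapse = ", "), "\n")
  invisible(x)
}
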