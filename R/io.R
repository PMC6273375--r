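# Delimited-text dataset readers/writers, solvent-spec parsing and the
# assembled reproduction report (correlation/prediction ARD tables and
# solubility products).

#' Parse a solvent specification string
#'
#' Turns `"name:frac,name:frac"` tokens into a named vector of
#' solute-free mass fractions, normalized to sum to one. A single
#' solvent maps to fraction 1.
#'
#' @param text Specification such as `"ethanol:0.5,water:0.5"`.
#' @param db Optional `parameter_db`; when given, component names are
#'   checked against it.
#' @return Named numeric vector of mass fractions summing to 1.
#' @export
parse_solvent_spec <- function(text, db = NULL) {
  toks <- strsplit(trimws(strsplit(text, ",", fixed = TRUE)[[1]]),
                   ":", fixed = TRUE)
  nm <- vapply(toks, `[[`, "", 1)
  fr <- vapply(toks, function(t)
    if (length(t) > 1) suppressWarnings(as.numeric(t[2])) else 1, 0)
  if (any(is.na(fr)) || any(fr <= 0))
    stop("solvent fractions must be positive numbers")
  if (!is.null(db) && !all(nm %in% names(db$components)))
    stop(errorCondition(
      sprintf("unknown component(s): %s",
              paste(setdiff(nm, names(db$components)), collapse = ", ")),
      class = c("cocrysol_resolution_error", "error", "condition")))
  stats::setNames(fr / sum(fr), nm)
}

#' Write a solubility dataset to CSV
#'
#' Comma-separated, UTF-8, mandatory header, `.` decimal, temperatures
#' in K. The written file is re-readable by
#' [read_solubility_dataset()] into an equal data frame.
#'
#' @param dataset A solubility dataset data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_solubility_dataset <- function(dataset, path) {
  # missing values are written as empty fields: the nicotinamide id "NA"
  # must survive the round trip as a character token
  utils::write.csv(dataset, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a solubility dataset from CSV
#'
#' @param path CSV path with the schema written by
#'   [write_solubility_dataset()] (columns `solute`, `cosolute`,
#'   `solvent_a`, `solvent_b`, `w_a`, `T_K`, `x_solute`, `x_cosolute`,
#'   `sd`, `solid_phase`, and optionally `provenance`, `seed`).
#' @return The dataset data frame.
#' @export
read_solubility_dataset <- function(path) {
  cls_map <- c(solute = "character", cosolute = "character",
               solvent_a = "character", solvent_b = "character",
               w_a = "numeric", T_K = "numeric", x_solute = "numeric",
               x_cosolute = "numeric", sd = "numeric",
               solid_phase = "character", provenance = "character",
               seed = "integer")
  hdr <- names(utils::read.csv(path, nrows = 1, fileEncoding = "UTF-8"))
  cls <- ifelse(hdr %in% names(cls_map), cls_map[hdr], NA)
  ds <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = cls, fileEncoding = "UTF-8")
  need <- c("solute", "solvent_a", "w_a", "T_K", "x_solute", "solid_phase")
  missing <- setdiff(need, names(ds))
  if (length(missing) > 0)
    stop(sprintf("dataset is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (any(!is.finite(ds$x_solute)) ||
      any(ds$x_solute <= 0 | ds$x_solute >= 1))
    stop("x_solute values must lie in (0, 1)")
  if (any(ds$T_K <= 0)) stop("temperatures must be positive")
  ds
}

# Predict the API mole fraction on the cocrystal line at a fixed
# experimental coformer mole fraction (the API-based deviation
# convention for cocrystal ARDs).
cc_predict_x_api <- function(cc, x_cf, solvent_mass_fractions,
                             temperature, db, ks = NULL) {
  if (is.null(ks)) ks <- ks_at_temperature(cc, temperature, db$R)
  w <- solvent_mass_fractions / sum(solvent_mass_fractions)
  ids <- c(cc$api_id, cc$cf_id, names(w))
  sys <- pcsaft_system(db, ids, temperature)
  phi <- solvent_mole_split(db, w)
  resid <- function(u) {
    xa <- exp(u)
    g <- gamma_sys(sys, c(xa, x_cf, unname(phi) * (1 - xa - x_cf)))
    cc$nu_api * log(xa * g[[cc$api_id]]) +
      cc$nu_cf * log(x_cf * g[[cc$cf_id]]) - log(ks)
  }
  u0 <- log(ks / x_cf^cc$nu_cf) / cc$nu_api
  lo <- u0 - 1; hi <- min(u0 + 1, log(0.6 - x_cf))
  flo <- resid(lo); fhi <- resid(hi); it <- 0
  while (flo > 0 && it < 40) { lo <- lo - 1; flo <- resid(lo); it <- it + 1 }
  while (fhi < 0 && hi < log(0.6 - x_cf) - 1e-12 && it < 80) {
    hi <- min(hi + 1, log(0.6 - x_cf)); fhi <- resid(hi); it <- it + 1
  }
  exp(stats::uniroot(resid, c(lo, hi), f.lower = flo, f.upper = fhi,
                     tol = 1e-10)$root)
}

#' Reproduction report: ARD tables and solubility products
#'
#' Given a saturation dataset (an experimental transcription or a
#' synthetic stand-in), recomputes every record with the packaged model
#' and assembles average relative deviations by system and temperature,
#' mirroring the layout of the published correlation/prediction tables,
#' plus the solubility product at the reference temperatures. The
#' cocrystal deviations follow the API-based convention: the API mole
#' fraction is predicted on the cocrystal line at each record's
#' experimental coformer mole fraction and compared with the record's
#' API mole fraction. Deterministic given its inputs.
#'
#' @param dataset A solubility dataset data frame mixing single-solute
#'   records (`solid_phase = "solute"`) and cocrystal records
#'   (`solid_phase = "CC"`).
#' @param db A `parameter_db`.
#' @param cc A `cocrystal_definition` (required when cocrystal records
#'   are present); defaults to the first packaged definition.
#' @param ks_temperatures Temperatures (K) at which the solubility
#'   product is reported.
#' @return A list of data frames: `ard_solute` (solute, solvent system,
#'   temperature pooling, ARD %), `ard_cc` (solvent system,
#'   temperature, ARD % of the API mole fraction), `ks` (temperature,
#'   solubility product).
#' @export
reproduce_tables <- function(dataset, db, cc = NULL,
                             ks_temperatures = c(298.15, 310.15)) {
  if (is.null(cc) && length(db$cocrystals) > 0) cc <- db$cocrystals[[1]]
  sol <- dataset[dataset$solid_phase == "solute", , drop = FALSE]
  ccr <- dataset[dataset$solid_phase == "CC", , drop = FALSE]

  ard_solute <- NULL
  if (nrow(sol) > 0) {
    system_lab <- ifelse(is.na(sol$solvent_b) | sol$w_a >= 1 - 1e-12,
                         sol$solvent_a,
                         paste0(sol$solvent_a, "/", sol$solvent_b))
    pooled_T <- ifelse(is.na(sol$solvent_b) | sol$w_a >= 1 - 1e-12,
                       "all", format(sol$T_K))
    key <- paste(sol$solute, system_lab, pooled_T, sep = "#")
    x_calc <- vapply(seq_len(nrow(sol)), function(i) {
      w <- solvent_mass_fractions_of(as.list(sol[i, ]))
      pt <- tryCatch(solve_solubility(sol$solute[i], w, sol$T_K[i], db),
                     error = function(e) NULL)
      if (is.null(pt)) NA_real_ else pt$x_solute
    }, 0)
    grp <- split(seq_len(nrow(sol)), key)
    ard_solute <- do.call(rbind, lapply(names(grp), function(k) {
      idx <- grp[[k]]
      ok <- idx[is.finite(x_calc[idx])]
      parts <- strsplit(k, "#", fixed = TRUE)[[1]]
      data.frame(solute = parts[1], solvent_system = parts[2],
                 temperature = parts[3],
                 n = length(ok),
                 ard_percent = if (length(ok) > 0)
                   ard(x_calc[ok], sol$x_solute[ok]) else NA_real_)
    }))
    ard_solute <- ard_solute[order(ard_solute$solute,
                                   ard_solute$solvent_system), ]
  }

  ard_cc <- NULL
  if (nrow(ccr) > 0 && !is.null(cc)) {
    system_lab <- ifelse(is.na(ccr$solvent_b) | ccr$w_a >= 1 - 1e-12,
                         ccr$solvent_a,
                         sprintf("%s/%s %.2f/%.2f", ccr$solvent_a,
                                 ccr$solvent_b, ccr$w_a, 1 - ccr$w_a))
    key <- paste(system_lab, format(ccr$T_K), sep = "#")
    x_pred <- vapply(seq_len(nrow(ccr)), function(i) {
      w <- solvent_mass_fractions_of(as.list(ccr[i, ]))
      tryCatch(cc_predict_x_api(cc, ccr$x_cosolute[i], w, ccr$T_K[i], db),
               error = function(e) NA_real_)
    }, 0)
    grp <- split(seq_len(nrow(ccr)), key)
    ard_cc <- do.call(rbind, lapply(names(grp), function(k) {
      idx <- grp[[k]]
      ok <- idx[is.finite(x_pred[idx])]
      parts <- strsplit(k, "#", fixed = TRUE)[[1]]
      data.frame(solvent_system = parts[1],
                 temperature = as.numeric(parts[2]),
                 n = length(ok),
                 ard_percent = if (length(ok) > 0)
                   ard(x_pred[ok], ccr$x_solute[ok]) else NA_real_)
    }))
    ard_cc <- ard_cc[order(ard_cc$solvent_system, ard_cc$temperature), ]
  }

  ks_tab <- NULL
  if (!is.null(cc))
    ks_tab <- data.frame(temperature = ks_temperatures,
                         ks = ks_at_temperature(cc, ks_temperatures, db$R))

  list(ard_solute = ard_solute, ard_cc = ard_cc, ks = ks_tab)
}
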