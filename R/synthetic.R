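# Synthetic saturation datasets: model-generated solubilities with
# multiplicative lognormal measurement noise over stated temperature and
# solvent-composition designs, emulating equilibrated saturation
# experiments so fitting, error metrics and phase-diagram stages are
# testable without external data.

# evaluate code under a fixed seed without disturbing the global stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Define a synthetic measurement design
#'
#' Fixes the experimental design a synthetic dataset emulates: solute,
#' solvent pair (or single solvent), solute-free mass-ratio grid,
#' temperature grid, relative noise level and replicate count. The
#' noise model is multiplicative lognormal, x_obs = x_model exp(eps),
#' eps ~ Normal(0, noise_rel_sd^2), mimicking the relative scatter of
#' replicated gravimetric/photometric saturation measurements; the
#' default 0.02 corresponds to ~2% triplicate precision. The seed fixes
#' the full output stream.
#'
#' @param solute_id Solute component id (the API for cocrystal designs).
#' @param solvent_pair One or two solvent ids.
#' @param mass_ratio_grid Solute-free mass fractions of the first
#'   solvent (use `1` for a single solvent).
#' @param temperature_grid Temperatures in K.
#' @param noise_rel_sd Relative standard deviation of the lognormal
#'   noise (>= 0).
#' @param n_replicates Independent replicates per grid cell.
#' @param seed Integer seed fixing all draws.
#' @return A `synthetic_design` object.
#' @export
synthetic_design <- function(solute_id, solvent_pair, mass_ratio_grid = 1,
                             temperature_grid = 298.15,
                             noise_rel_sd = 0.02, n_replicates = 1,
                             seed = 1) {
  stopifnot(noise_rel_sd >= 0, length(mass_ratio_grid) >= 1,
            length(temperature_grid) >= 1, n_replicates >= 1,
            length(solvent_pair) %in% 1:2)
  structure(list(solute_id = solute_id, solvent_pair = solvent_pair,
                 mass_ratio_grid = mass_ratio_grid,
                 temperature_grid = temperature_grid,
                 noise_rel_sd = noise_rel_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

empty_dataset <- function() {
  data.frame(solute = character(), cosolute = character(),
             solvent_a = character(), solvent_b = character(),
             w_a = numeric(), T_K = numeric(), x_solute = numeric(),
             x_cosolute = numeric(), sd = numeric(),
             solid_phase = character(), provenance = character(),
             seed = integer())
}

#' Generate a synthetic single-solute saturation dataset
#'
#' Computes model solubilities on the design's temperature x
#' solvent-ratio grid (optionally under "true" kij parameters differing
#' from the packaged ones) and perturbs each record with independent
#' multiplicative lognormal noise. With `noise_rel_sd = 0` the dataset
#' reproduces the model exactly. Records are generated in row-major
#' stream order: temperature (outer), mass ratio, replicate (inner),
#' one normal draw per record. Grid nodes where the solubility solver
#' fails are skipped with a message.
#'
#' @param design A [synthetic_design()].
#' @param true_params Optional list with `k_slope` and `k_intercept`
#'   overriding the solute / first-solvent interaction parameter used
#'   for generation.
#' @param db A `parameter_db`.
#' @return A solubility dataset data frame (columns `solute`,
#'   `cosolute`, `solvent_a`, `solvent_b`, `w_a`, `T_K`, `x_solute`,
#'   `x_cosolute`, `sd`, `solid_phase`, `provenance`, `seed`).
#' @export
generate_binary_solubility <- function(design, true_params = NULL, db) {
  if (!is.null(true_params))
    db <- set_binary(db, design$solute_id, design$solvent_pair[1],
                     true_params$k_slope, true_params$k_intercept)
  sp <- design$solvent_pair
  rows <- list()
  with_seed(design$seed, {
    for (T_K in design$temperature_grid) {
      for (w1 in design$mass_ratio_grid) {
        sc <- if (length(sp) == 2)
          stats::setNames(c(w1, 1 - w1), sp) else stats::setNames(1, sp)
        sc <- sc[sc > 0]
        pt <- tryCatch(solve_solubility(design$solute_id, sc, T_K, db),
                       error = function(e) NULL)
        if (is.null(pt) || is.na(pt$x_solute)) {
          message(sprintf("skipping node T = %g K, w = %g: no solution",
                          T_K, w1))
          next
        }
        for (rep_i in seq_len(design$n_replicates)) {
          eps <- stats::rnorm(1, 0, design$noise_rel_sd)
          rows[[length(rows) + 1]] <- data.frame(
            solute = design$solute_id, cosolute = NA_character_,
            solvent_a = sp[1],
            solvent_b = if (length(sp) == 2) sp[2] else NA_character_,
            w_a = w1, T_K = T_K,
            x_solute = pt$x_solute * exp(eps),
            x_cosolute = NA_real_, sd = design$noise_rel_sd,
            solid_phase = "solute", provenance = "synthetic",
            seed = design$seed)
        }
      }
    }
  })
  if (length(rows) == 0) return(empty_dataset())
  do.call(rbind, rows)
}

#' Generate a synthetic cocrystal saturation dataset
#'
#' Samples points along model cocrystal solubility lines for every cell
#' of the design's temperature x solvent-ratio grid and perturbs the
#' API and coformer mole fractions with independent multiplicative
#' lognormal noise (API draw first, then coformer, per record). Records
#' carry both mole fractions and the branch label `"CC"`; on zero-noise
#' records [fit_ks()] returns the generating solubility product
#' exactly.
#'
#' @param design A [synthetic_design()]; its `solute_id` must equal the
#'   cocrystal's API id.
#' @param cc A `cocrystal_definition`.
#' @param db A `parameter_db`.
#' @param solute_ratio_grid API/CF mole ratios sampled on each line.
#' @param ks Optional solubility product override for generation.
#' @return A solubility dataset data frame (schema as
#'   [generate_binary_solubility()], with `x_cosolute` filled and
#'   `solid_phase = "CC"`).
#' @export
generate_cc_dataset <- function(design, cc, db,
                                solute_ratio_grid = 10^seq(-0.6, 0.6,
                                                           length.out = 7),
                                ks = NULL) {
  sp <- design$solvent_pair
  rows <- list()
  with_seed(design$seed, {
    for (T_K in design$temperature_grid) {
      for (w1 in design$mass_ratio_grid) {
        sc <- if (length(sp) == 2)
          stats::setNames(c(w1, 1 - w1), sp) else stats::setNames(1, sp)
        sc <- sc[sc > 0]
        line <- tryCatch(
          cc_solubility_line(cc, sc, T_K, db,
                             ratio_grid = solute_ratio_grid, ks = ks),
          error = function(e) NULL)
        if (is.null(line)) {
          message(sprintf("skipping cell T = %g K, w = %g: no line", T_K, w1))
          next
        }
        for (i in seq_len(nrow(line))) {
          for (rep_i in seq_len(design$n_replicates)) {
            eps_api <- stats::rnorm(1, 0, design$noise_rel_sd)
            eps_cf <- stats::rnorm(1, 0, design$noise_rel_sd)
            rows[[length(rows) + 1]] <- data.frame(
              solute = cc$api_id, cosolute = cc$cf_id,
              solvent_a = sp[1],
              solvent_b = if (length(sp) == 2) sp[2] else NA_character_,
              w_a = w1, T_K = T_K,
              x_solute = line$x_api[i] * exp(eps_api),
              x_cosolute = line$x_cf[i] * exp(eps_cf),
              sd = design$noise_rel_sd,
              solid_phase = "CC", provenance = "synthetic",
              seed = design$seed)
          }
        }
      }
    }
  })
  if (length(rows) == 0) return(empty_dataset())
  do.call(rbind, rows)
}
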