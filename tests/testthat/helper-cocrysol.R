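# Shared fixtures: the packaged parameter database, synthetic "ideal"
# systems built from clones of one component (so all activity
# coefficients are exactly 1), and a memo cache so expensive fits are
# computed once per test run.

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  hit <- .test_cache[[name]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  assign(name, val, envir = .test_cache)
  val
}

test_db <- function() cached("db", load_parameter_db())

# clone a component's PC-SAFT parameters under a new id
clone_component <- function(db, from, to) {
  cp <- db$components[[from]]
  cp$component_id <- to
  db$components[[to]] <- cp
  db
}

# a degenerate system in which API, coformer and solvent all share one
# parameter set: every gamma is exactly 1, so closed forms apply
ideal_system_db <- function() {
  cached("ideal_db", {
    db <- test_db()
    db <- clone_component(db, "NA", "api_x")
    db <- clone_component(db, "NA", "cf_x")
    db <- clone_component(db, "NA", "solv_x")
    db$melting$api_x <- structure(list(component_id = "api_x",
                                       melting_temperature = 401.15,
                                       fusion_enthalpy = 28.0,
                                       delta_cp = 78.12),
                                  class = "melting_properties")
    db$melting$cf_x <- structure(list(component_id = "cf_x",
                                      melting_temperature = 461.15,
                                      fusion_enthalpy = 38.91,
                                      delta_cp = 69.79),
                                 class = "melting_properties")
    db
  })
}

ideal_cc <- function(ks_ref = 4e-6) {
  structure(list(cocrystal_id = "ideal_2to1", api_id = "api_x",
                 cf_id = "cf_x", nu_api = 2L, nu_cf = 1L,
                 ks_ref = ks_ref, t_ref = 298.15, dh_ref = 64.75),
            class = "cocrystal_definition")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
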