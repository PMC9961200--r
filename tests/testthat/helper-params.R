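# Shared fixture builders. Everything is generated in code; no data files.

pyramid_params <- function(seed = 1L, ...) {
  defaults <- list(
    membrane_slope = 3, penetration_probability = 1,
    insertion_force_mean = 2, insertion_force_sd = 0.3,
    second_drop_probability = 0, noise_sd = 0,
    trigger_force = 12, approach_speed = 1, spring_constant = 0.02,
    tip_kind = "pyramid", tip_radius = 0.01, seed = seed
  )
  do.call(curve_gen_params, utils::modifyList(defaults, list(...)))
}

sphere_params <- function(E = 1000, seed = 1L, noise_sd = 0, ...) {
  defaults <- list(
    cell_modulus = E, tip_kind = "sphere", tip_radius = 2.25,
    spring_constant = 0.05, trigger_force = 2,
    penetration_probability = 0, insertion_force_mean = 1,
    substrate_onset_depth = 3, noise_sd = noise_sd, seed = seed
  )
  do.call(curve_gen_params, utils::modifyList(defaults, list(...)))
}

# Reduced FE model for unit tests (acceptance uses the default mesh). The
# domain must stay large relative to the deflection basin: with the clamped
# edge closer than ~800 nm the unprestressed basin is boundary-truncated and
# the prestress contrasts are contaminated by edge effects.
small_network <- function(...) {
  build_network(half_width = 800, filament_spacing = 100, ...)
}

reference_prestress <- function(model) {
  apply_prestress(model, membrane = 100, filament = 5e4, bundle = 5e4)
}

# Cache for expensive shared fixtures within one test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Generate + analyse one published condition (n curves, exact counts).
analyzed_condition <- function(label, seed = 101L, n = 60) {
  cached(paste0("cond_", label, "_", seed, "_", n), {
    params <- strain_conditions(seed = seed)[[label]]
    curves <- generate_condition_set(params, n, exact_count = TRUE)
    analyses <- lapply(curves, analyze_curve)
    list(params = params, curves = curves, analyses = analyses,
         events = lapply(analyses, `[[`, "events"))
  })
}
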