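# shared fixture builders (all fixtures are generated in code)

default_geom <- function() bend_geometry(L = 0.1, a = 0.025)

# perfectly linear trace F = slope * x
linear_trace <- function(slope, n = 20, xmax = 0.005, geometry = default_geom(),
                         id = "lin") {
  x <- seq(0, xmax, length.out = n)
  bending_trace(x, slope * x, geometry, sample_id = id)
}

# compact cohort for structural tests
small_cfg <- function(seed = 1L, ...) {
  synthetic_config(
    seed = seed,
    n_species = c(most_preferred = 2L, less_preferred = 2L, never_used = 2L),
    plants_per_species = 2L, ...)
}

# generator configuration consistent with the fitted model: no species-level
# variance component (the analysis model has only a plant random intercept)
# and a single material, so the plant effect is Gaussian rather than a
# material-mixture. This is the world in which the inference machinery's
# calibration is a well-posed question.
calib_cfg <- function(seed, n_species_side = 5L, plants_per_species = 3L,
                      effect = 0) {
  synthetic_config(
    seed = seed,
    n_species = c(most_preferred = n_species_side,
                  less_preferred = 0L, never_used = n_species_side),
    plants_per_species = plants_per_species,
    material_mix = c(twig = 1, vine = 0, bark = 0, grass = 0),
    species_sd = 0, plant_sd = 0.4, residual_sd = 0.3,
    effect_logE = c(most_preferred = 0, less_preferred = 0, never_used = effect))
}

# cohort -> traces -> mechanics -> analysis table for one scheme
pipeline_table <- function(cohort, scheme_name, response = "log_EI") {
  traces <- simulate_cohort_traces(cohort)
  derived <- derive_mechanics(traces, cohort$meta)
  qc <- qc_filter(derived)
  meta <- cohort$meta[cohort$meta$sample_id %in% qc$retained$sample_id, ]
  analysis_table(qc$retained, meta, assign_scheme(meta, scheme_name))
}
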