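#' Configuration for the synthetic bending-study generator
#'
#' Describes a complete simulated field study: a species -> plant -> sample
#' hierarchy (three samples cut per plant, mirroring standard field
#' practice), log-normal material stiffness with species-, plant- and
#' sample-level variance components, tool-like cross-section dimensions,
#' and the four-point bending rig that turns each sample's true EI into a
#' force--displacement trace.
#'
#' Default stiffness means put woody tissues (twig, vine, grass) in the
#' 1--35 GPa envelope typical of lignified plant parts and bark well below
#' them; with the default SDs essentially all draws land in the observed
#' 0.1--35 GPa range. Material proportions follow the mix seen in real
#' probe-tool assemblages (twig-dominated, bark common, vine and grass
#' rare). Bark strips are rectangular in section; other materials circular.
#' The rig geometry defaults (L = 0.1 m, a = 0.025 m) are an arbitrary but
#' plausible portable-rig scale.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param n_species Named integer vector: species per preference category.
#' @param plants_per_species Plants sampled per species.
#' @param samples_per_plant Samples cut per plant (default 3).
#' @param material_mix Named proportions over twig/vine/bark/grass
#'   (material is drawn once per plant).
#' @param logE_means Named numeric: mean log elastic modulus (log Pa) per
#'   material.
#' @param species_sd,plant_sd,residual_sd Log-scale SDs of the species,
#'   plant and within-plant components of log E.
#' @param effect_logE Named numeric: additive log-stiffness offset per
#'   preference category (shifts log E, hence log EI, leaving geometry
#'   untouched).
#' @param p_plant_used Probability a tool-source plant carries removal
#'   scars.
#' @param geometry A [bend_geometry()].
#' @param radius_range Radius range (m) for circular sections.
#' @param width_range,depth_range Width/depth ranges (m) for bark strips.
#' @param n_points Points per simulated trace.
#' @param max_displacement Trace displacement extent (m).
#' @param noise_sd Absolute Gaussian force noise SD (N).
#' @param noise_frac Force noise SD as a fraction of each trace's peak
#'   force (used when > 0; overrides `noise_sd`).
#' @param toe_fraction Fraction of the displacement range occupied by a
#'   quadratic toe region (0 = none).
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_species = c(most_preferred = 3L, less_preferred = 10L, never_used = 13L),
    plants_per_species = 7L,
    samples_per_plant = 3L,
    material_mix = c(twig = 0.65, vine = 0.06, bark = 0.26, grass = 0.03),
    logE_means = c(twig = log(8e9), vine = log(4e9),
                   bark = log(0.6e9), grass = log(10e9)),
    species_sd = 0.5, plant_sd = 0.4, residual_sd = 0.3,
    effect_logE = c(most_preferred = 0, less_preferred = 0, never_used = 0),
    p_plant_used = 0.22,
    geometry = bend_geometry(L = 0.1, a = 0.025),
    radius_range = c(0.5e-3, 4e-3),
    width_range = c(2e-3, 8e-3), depth_range = c(0.5e-3, 3e-3),
    n_points = 100L, max_displacement = 5e-3,
    noise_sd = 0, noise_frac = 0, toe_fraction = 0) {
  stopifnot(all(names(n_species) %in% .preference_levels),
            plants_per_species >= 1L, samples_per_plant >= 1L,
            species_sd >= 0, plant_sd >= 0, residual_sd >= 0,
            noise_sd >= 0, noise_frac >= 0,
            toe_fraction >= 0, toe_fraction < 1,
            n_points >= 2L, max_displacement > 0,
            all(radius_range > 0), all(width_range > 0), all(depth_range > 0))
  if (any(material_mix < 0) || abs(sum(material_mix) - 1) > 1e-8)
    stop("material_mix must be non-negative proportions summing to 1")
  if (!setequal(names(material_mix), .material_levels) ||
      !setequal(names(logE_means), .material_levels))
    stop("material_mix and logE_means must cover exactly: ",
         paste(.material_levels, collapse = ", "))
  if (sum(n_species) < 1L || any(n_species < 0))
    stop("need at least one species")
  structure(as.list(environment()), class = "synthetic_config")
}

# deterministic per-sample sub-seed below 2^31
.sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629) + 1L
}

#' Generate a synthetic study cohort with ground truth
#'
#' Draws the full hierarchy: species within preference categories, plants
#' within species, samples within plants. Each sample's true elastic
#' modulus is log-normal,
#' `log E = material mean + preference offset + species + plant + residual`,
#' its cross-section is drawn per material (bark rectangular, others
#' circular), and `EI = E * I`. The true initial slope follows from the
#' four-point bending relation, `slope = 48 EI / (a (3 L^2 - 4 a^2))`.
#' Deterministic under a fixed seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `"synthetic_cohort"` with `meta` (canonical SI
#'   metadata, see [read_metadata()]) and `truth` (`data.frame`:
#'   `sample_id`, `E_true_Pa`, `I_true_m4`, `EI_true_Nm2`,
#'   `slope_true_N_per_m`), plus the `cfg`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  cats <- names(cfg$n_species)[cfg$n_species > 0]
  meta_rows <- list()
  truth_rows <- list()
  sp_idx <- 0L
  plant_idx <- 0L
  samp_idx <- 0L
  for (cat in cats) {
    for (s in seq_len(cfg$n_species[[cat]])) {
      sp_idx <- sp_idx + 1L
      species_id <- sprintf("SP%03d", sp_idx)
      sp_eff <- stats::rnorm(1, 0, cfg$species_sd)
      is_source <- cat != "never_used"
      for (pl in seq_len(cfg$plants_per_species)) {
        plant_idx <- plant_idx + 1L
        plant_id <- sprintf("PL%04d", plant_idx)
        pl_eff <- stats::rnorm(1, 0, cfg$plant_sd)
        material <- sample(.material_levels, 1L, prob = cfg$material_mix[.material_levels])
        used <- is_source && stats::runif(1) < cfg$p_plant_used
        mound <- sprintf("GTM%03d", (plant_idx - 1L) %% 9L + 1L)
        for (sm in seq_len(cfg$samples_per_plant)) {
          samp_idx <- samp_idx + 1L
          sample_id <- sprintf("S%05d", samp_idx)
          logE <- cfg$logE_means[[material]] + cfg$effect_logE[[cat]] +
            sp_eff + pl_eff + stats::rnorm(1, 0, cfg$residual_sd)
          E <- exp(logE)
          if (material == "bark") {
            W <- stats::runif(1, cfg$width_range[1], cfg$width_range[2])
            D <- stats::runif(1, cfg$depth_range[1], cfg$depth_range[2])
            I <- second_moment_rectangular(W, D)
            shape <- "rectangular"; R <- NA_real_
          } else {
            R <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
            I <- second_moment_circular(R)
            shape <- "circular"; W <- NA_real_; D <- NA_real_
          }
          EI <- E * I
          slope <- 48 * EI / (cfg$geometry$a *
                                (3 * cfg$geometry$L^2 - 4 * cfg$geometry$a^2))
          meta_rows[[samp_idx]] <- data.frame(
            sample_id = sample_id, plant_id = plant_id, species = species_id,
            mound_id = mound, plant_part = if (material == "bark") "stem" else "branch",
            material_type = material, shape = shape,
            radius_m = R, width_m = W, depth_m = D,
            length_m = stats::runif(1, 0.15, 0.45),
            tool_source_species = is_source, preference = cat,
            plant_used = used, stringsAsFactors = FALSE)
          truth_rows[[samp_idx]] <- data.frame(
            sample_id = sample_id, E_true_Pa = E, I_true_m4 = I,
            EI_true_Nm2 = EI, slope_true_N_per_m = slope,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(meta = do.call(rbind, meta_rows),
                 truth = do.call(rbind, truth_rows),
                 cfg = cfg),
            class = "synthetic_cohort")
}

#' Simulate one force--displacement trace from ground truth
#'
#' Builds the trace a testing machine would record for a sample of known
#' true slope: a uniform displacement grid, an optional quadratic toe
#' region over the leading `toe_fraction` of the range (continuous in value
#' and slope at the junction), the linear elastic response beyond it, and
#' optional additive Gaussian force noise. Seeded per sample via a
#' deterministic substream of the master seed, so cohort generation is
#' reproducible regardless of trace generation order.
#'
#' @param truth_row One row of a cohort's `truth` table (or any list with
#'   `sample_id` and `slope_true_N_per_m`).
#' @param cfg The [synthetic_config()] used for the cohort.
#' @param index Integer used to derive the per-sample random substream;
#'   defaults to a hash of the sample_id digits.
#' @return A [bending_trace()].
#' @export
simulate_trace <- function(truth_row, cfg, index = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  s <- truth_row$slope_true_N_per_m
  if (!is.finite(s) || s <= 0) stop("non-positive slope")
  if (is.null(index))
    index <- as.integer(sum(utf8ToInt(as.character(truth_row$sample_id))))
  x <- seq(0, cfg$max_displacement, length.out = cfg$n_points)
  x_toe <- cfg$toe_fraction * cfg$max_displacement
  f <- if (x_toe > 0) {
    ifelse(x <= x_toe, s * x^2 / (2 * x_toe),
           s * x_toe / 2 + s * (x - x_toe))
  } else s * x
  sd_noise <- if (cfg$noise_frac > 0) cfg$noise_frac * max(f) else cfg$noise_sd
  if (sd_noise > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(.sub_seed(cfg$seed, index))
    f <- f + stats::rnorm(length(f), 0, sd_noise)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  bending_trace(x, f, cfg$geometry, sample_id = as.character(truth_row$sample_id))
}

#' Simulate all traces of a cohort
#'
#' @param cohort A `"synthetic_cohort"`.
#' @return Named list of [bending_trace()] objects, one per metadata row.
#' @export
simulate_cohort_traces <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- lapply(seq_len(nrow(cohort$truth)), function(i)
    simulate_trace(cohort$truth[i, ], cohort$cfg, index = i))
  names(tr) <- cohort$truth$sample_id
  tr
}

#' Write a synthetic cohort in the ingest module's on-disk layout
#'
#' Writes `metadata.tsv` (SI canonical form), one `traces/<sample_id>.csv`
#' per sample, and `truth.tsv`, closing the loop with [read_metadata()] and
#' [read_trace()].
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  write_metadata(cohort$meta, file.path(dir, "metadata.tsv"))
  tr <- simulate_cohort_traces(cohort)
  for (id in names(tr)) write_trace(tr[[id]], file.path(dir, "traces", paste0(id, ".csv")))
  truth <- cohort$truth
  for (col in setdiff(names(truth), "sample_id"))
    truth[[col]] <- sprintf("%.17g", truth[[col]])
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
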