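test_that("initial slope is exact on linear traces and rejects degenerate ones", {
  tr <- linear_trace(50, n = 20)
  est <- extract_initial_slope(tr)
  expect_equal(est$slope, 50, tolerance = 1e-12)
  expect_equal(est$fit_r2, 1)
  expect_gte(est$n_points, 5L)

  zero <- bending_trace(seq(0, 0.005, length.out = 10), rep(0, 10), default_geom())
  expect_error(extract_initial_slope(zero), "degenerate")
  neg <- bending_trace(seq(0, 0.005, length.out = 10),
                       seq(1, 0.1, length.out = 10), default_geom())
  expect_error(extract_initial_slope(neg), "negative")
})

test_that("toe region is excluded from the slope window", {
  cfg <- synthetic_config(seed = 5, toe_fraction = 0.2)
  truth <- list(sample_id = "toe1", slope_true_N_per_m = 120)
  tr <- simulate_trace(truth, cfg)
  est <- extract_initial_slope(tr)
  expect_equal(est$slope, 120, tolerance = 0.005)  # <= 0.5% on noiseless toe
  # windows start after the quadratic region
  expect_gt(tr$displacement[est$window_start_idx], 0)
})

test_that("four-point bending formula matches direct arithmetic and its limits", {
  expect_equal(flexural_rigidity(100, 0.1, 0.025),
               100 * 0.025 * (3 * 0.1^2 - 4 * 0.025^2) / 48)
  expect_equal(flexural_rigidity(100, 0.1, 0.025), 1.432291666667e-3,
               tolerance = 1e-10)
  expect_identical(flexural_rigidity(0, 0.1, 0.025), 0)
  # central loading limit a = L/2
  expect_equal(flexural_rigidity(77, 0.1, 0.05), 77 * 0.1^3 / 48)
  # strictly increasing in slope
  s <- seq(1, 100, length.out = 25)
  expect_true(all(diff(flexural_rigidity(s, 0.1, 0.025)) > 0))
  expect_error(flexural_rigidity(10, 0.1, 0.051), "geometry")
  expect_error(flexural_rigidity(-1, 0.1, 0.025), "non-negative")
})

test_that("second moments of area follow the closed forms and scalings", {
  expect_equal(second_moment_circular(1), pi / 4)
  expect_equal(second_moment_circular(0.0015), 3.976078e-12, tolerance = 1e-6)
  expect_equal(second_moment_circular(2), 16 * second_moment_circular(1))
  expect_equal(second_moment_rectangular(1, 1), 1 / 12)
  expect_equal(second_moment_rectangular(0.004, 0.002), 2.666667e-12,
               tolerance = 1e-6)
  # orientation sensitivity
  expect_equal(second_moment_rectangular(1, 2), 8 / 12)
  expect_equal(second_moment_rectangular(2, 1), 2 / 12)
  expect_error(second_moment_circular(0), "non-positive")
  expect_error(second_moment_rectangular(1, -1), "non-positive")
  sec <- cross_section("circular", radius = 0.0015)
  expect_equal(second_moment(sec), second_moment_circular(0.0015))
})

test_that("elastic modulus is the exact EI / I quotient", {
  I <- second_moment_circular(0.0015)
  expect_equal(elastic_modulus(0.019880, I), 5.0e9, tolerance = 1e-3)
  expect_identical(elastic_modulus(0, I), 0)
  # identity on random pairs
  set.seed(11)
  EI <- runif(50, 1e-5, 0.05); Iv <- runif(50, 1e-13, 1e-10)
  expect_equal(elastic_modulus(EI, Iv) * Iv, EI, tolerance = 1e-12)
  expect_error(elastic_modulus(1, 0), "second moment")
})

test_that("QC threshold is strict: exactly 35 GPa is retained, above is dropped", {
  d <- data.frame(sample_id = c("a", "b", "c"),
                  E_Pa = c(36e9, 0.105e9, 35e9))
  qc <- qc_filter(d)
  expect_setequal(qc$retained$sample_id, c("b", "c"))
  expect_equal(qc$dropped$sample_id, "a")
  expect_equal(nrow(qc$retained) + nrow(qc$dropped), nrow(d))
  expect_length(intersect(qc$retained$sample_id, qc$dropped$sample_id), 0L)
  expect_error(qc_filter(data.frame(sample_id = "x", E_Pa = NA_real_)), "E_Pa")
})

test_that("noiseless end-to-end mechanics recovers ground truth to 1e-9", {
  cohort <- generate_cohort(small_cfg(2L))
  traces <- simulate_cohort_traces(cohort)
  d <- derive_mechanics(traces, cohort$meta)
  expect_equal(d$EI_Nm2, cohort$truth$EI_true_Nm2, tolerance = 1e-9)
  expect_equal(d$E_Pa, cohort$truth$E_true_Pa, tolerance = 1e-9)
})

test_that("dimensional homogeneity: k-rescaled geometry scales EI by k^2", {
  k <- 3.7
  tr <- linear_trace(80, n = 30)
  trk <- bending_trace(tr$displacement * k, tr$force,
                       bend_geometry(tr$span_L * k, tr$offset_a * k))
  s <- extract_initial_slope(tr)$slope
  sk <- extract_initial_slope(trk)$slope
  EI <- flexural_rigidity(s, tr$span_L, tr$offset_a)
  EIk <- flexural_rigidity(sk, trk$span_L, trk$offset_a)
  expect_equal(EIk, EI * k^2, tolerance = 1e-9)
  # E is unchanged when I carries the same k^2 geometric rescaling
  I0 <- second_moment_circular(0.002)
  expect_equal(elastic_modulus(EIk, I0 * k^2), elastic_modulus(EI, I0),
               tolerance = 1e-9)
})

test_that("derived E matches generator truth on 100+ randomized noiseless beams", {
  cfg <- synthetic_config(seed = 9,
                          n_species = c(most_preferred = 4L, less_preferred = 5L,
                                        never_used = 4L),
                          plants_per_species = 3L)
  cohort <- generate_cohort(cfg)
  expect_gte(nrow(cohort$meta), 100L)
  d <- derive_mechanics(simulate_cohort_traces(cohort), cohort$meta)
  rel <- abs(d$E_Pa - cohort$truth$E_true_Pa) / cohort$truth$E_true_Pa
  expect_lt(max(rel), 0.001)
})
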