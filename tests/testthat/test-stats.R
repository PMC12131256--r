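# Fixed-seed cohort shared across the model tests. Reference values for the
# ANOVA, EMM and contrast checks were computed once on this exact cohort with
# an independent implementation of Satterthwaite mixed-model inference
# (lmerTest 3.x + emmeans 1.x) and frozen here; the package's own machinery
# must reproduce them.
stats_fixture <- local({
  cfg <- synthetic_config(
    seed = 42,
    n_species = c(most_preferred = 3L, less_preferred = 6L, never_used = 6L),
    plants_per_species = 4L,
    effect_logE = c(most_preferred = 0, less_preferred = 0.12, never_used = 0.7))
  cohort <- generate_cohort(cfg)
  derived <- derive_mechanics(simulate_cohort_traces(cohort), cohort$meta)
  qc <- qc_filter(derived)
  meta <- cohort$meta[cohort$meta$sample_id %in% qc$retained$sample_id, ]
  list(derived = qc$retained, meta = meta)
})

test_that("log-EI model reproduces independently computed ANOVA and contrasts", {
  fx <- stats_fixture
  tab <- analysis_table(fx$derived, fx$meta, assign_scheme(fx$meta, "preference"))
  fit <- fit_group_model(tab, "log_EI")
  av <- anova_type2(fit)

  expect_equal(av$term, c("group", "log_I"))
  expect_equal(av$F[av$term == "group"], 5.17136689563, tolerance = 1e-6)
  expect_equal(av$df1[av$term == "group"], 2)
  expect_equal(av$df2[av$term == "group"], 55.5786, tolerance = 1e-3)
  expect_equal(av$p[av$term == "group"], 8.71569e-3, tolerance = 1e-4)
  expect_equal(av$F[av$term == "log_I"], 7106.25210, tolerance = 1e-6)
  expect_equal(av$df2[av$term == "log_I"], 113.0870, tolerance = 1e-3)

  em <- emm_means(fit)
  expect_equal(em$emm, c(-3.889794, -4.231611, -3.058264), tolerance = 1e-6)
  expect_equal(em$SE, c(0.3662745, 0.2590028, 0.2650367), tolerance = 1e-5)

  ct <- emm_contrasts(fit)
  expect_equal(ct$contrast,
               c("most_preferred - less_preferred", "most_preferred - never_used",
                 "less_preferred - never_used"))
  expect_equal(ct$estimate, c(0.341817389, -0.831529634, -1.173347023),
               tolerance = 1e-7)
  expect_equal(ct$SE, c(0.448608796, 0.452102130, 0.370584551), tolerance = 1e-6)
  expect_equal(ct$t, c(0.7619498, -1.8392517, -3.1662060), tolerance = 1e-5)
  expect_equal(ct$df, c(55.46363, 55.58589, 55.66182), tolerance = 1e-3)
  expect_equal(ct$p_adj, c(0.72770764, 0.16637141, 0.00696769), tolerance = 1e-5)
  expect_true(all(ct$p_adj >= ct$p - 1e-12))
})

test_that("log-E model (no geometry covariate) matches the independent reference", {
  fx <- stats_fixture
  tab <- analysis_table(fx$derived, fx$meta, assign_scheme(fx$meta, "material_type"))
  fit <- fit_group_model(tab, "log_E")
  expect_null(fit$data$log_I)
  av <- anova_type2(fit)
  expect_equal(nrow(av), 1L)
  expect_equal(av$F, 65.4349998895, tolerance = 1e-6)
  expect_equal(av$df1, 2)  # only 3 material levels drawn in this cohort
  expect_equal(av$df2, 33.0000, tolerance = 1e-3)
  ct <- emm_contrasts(fit)
  expect_equal(ct$estimate, c(1.026885008, 2.438985622, 1.412100614),
               tolerance = 1e-7)
  expect_equal(ct$t, c(3.6112346, 11.4246690, 4.6035291), tolerance = 1e-5)
  expect_equal(ct$p_adj[c(1, 3)], c(0.00279917, 0.00017078), tolerance = 1e-4)
})

test_that("F and t statistics are invariant to unit rescaling and relabelling", {
  fx <- stats_fixture
  tab <- analysis_table(fx$derived, fx$meta, assign_scheme(fx$meta, "preference"))
  fit <- fit_group_model(tab, "log_EI")
  av <- anova_type2(fit); ct <- emm_contrasts(fit)

  # unit change: EI in mN m^2 instead of N m^2
  tab2 <- tab; tab2$EI_Nm2 <- tab2$EI_Nm2 * 1e3
  fit2 <- fit_group_model(tab2, "log_EI")
  av2 <- anova_type2(fit2); ct2 <- emm_contrasts(fit2)
  expect_equal(av2$F, av$F, tolerance = 1e-8)
  expect_equal(ct2$t, ct$t, tolerance = 1e-8)
  # adjusted p inherits finite-difference df noise; slacker bound
  expect_equal(ct2$p_adj, ct$p_adj, tolerance = 1e-5)
  # only the intercept absorbs the scale shift
  expect_equal(unname(fit2$sw$beta[1] - fit$sw$beta[1]), log(1e3), tolerance = 1e-6)

  # label permutation: reversing level order must not change any statistic
  tab3 <- tab; tab3$group <- factor(tab3$group, levels = rev(levels(tab$group)))
  fit3 <- fit_group_model(tab3, "log_EI")
  expect_equal(anova_type2(fit3)$F, av$F, tolerance = 1e-8)
  expect_equal(sort(abs(emm_contrasts(fit3)$t)), sort(abs(ct$t)), tolerance = 1e-8)
  expect_equal(sort(emm_contrasts(fit3)$p_adj), sort(ct$p_adj), tolerance = 1e-5)
  # antisymmetry under pair reversal: reversed levels give less - most,
  # the negation of the original most - less contrast
  expect_equal(emm_contrasts(fit3)$estimate[3], -ct$estimate[1], tolerance = 1e-8)
})

test_that("two-level schemes: single contrast, Tukey p equals unadjusted p", {
  fx <- stats_fixture
  tab <- analysis_table(fx$derived, fx$meta, assign_scheme(fx$meta, "tool_source"))
  fit <- fit_group_model(tab, "log_E")
  ct <- emm_contrasts(fit)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$p_adj, ct$p, tolerance = 1e-6)
  # t^2 equals the one-term F for a 2-level factor
  av <- anova_type2(fit)
  expect_equal(ct$t^2, av$F, tolerance = 1e-8)
})

test_that("model guards: single level, non-positive responses, singular fits", {
  fx <- stats_fixture
  tab <- analysis_table(fx$derived, fx$meta, assign_scheme(fx$meta, "preference"))
  one <- tab[tab$group == "never_used", ]
  expect_error(fit_group_model(one, "log_EI"), "single level")
  bad <- tab; bad$EI_Nm2[1] <- -1
  expect_error(fit_group_model(bad, "log_EI"), "log-transformed")

  # plants carry no variance of their own: singular fit, residual-df fallback
  set.seed(8)
  n <- 40
  sing <- data.frame(sample_id = paste0("s", 1:n),
                     plant_id = paste0("p", rep(1:(n / 2), each = 2)),
                     group = factor(rep(c("a", "b"), each = n / 2)),
                     EI_Nm2 = exp(rnorm(n, -4, 0.3)),
                     E_Pa = exp(rnorm(n, 22, 0.3)), I_m4 = exp(rnorm(n, -26, 0.5)))
  fit <- suppressWarnings(fit_group_model(sing, "log_E"))
  expect_true(fit$singular)
  av <- anova_type2(fit)
  expect_equal(av$df2, n - 2)  # residual fallback
  expect_true(is.finite(av$p))
})

test_that("percent rigidity differences back-transform correctly on both bases", {
  # identical groups -> 0 %
  same <- data.frame(group = rep(c("a", "b"), each = 5), value = rep(1:5, 2))
  expect_equal(percent_rigidity_difference(same, "a", "b"), 0)
  # median ratio 0.49 -> -51 %; ratio 2.75 -> +175 %
  raw <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                    value = c(1, 2, 3, 0.49, 0.98, 1.47, 2.75, 5.5, 8.25))
  expect_equal(percent_rigidity_difference(raw, "a", "b"), -51)
  expect_equal(percent_rigidity_difference(raw, "a", "c"), 175)
  expect_error(percent_rigidity_difference(raw, "a", "zz"), "missing level")

  # EMM basis: an exact ln(2.75) offset between noise-free groups -> +175 %
  plants <- paste0("p", rep(1:8, each = 3))
  grp <- rep(c("lo", "hi"), each = 12)
  EI <- ifelse(grp == "hi", 2.75, 1) * 1e-3
  noise_free <- data.frame(sample_id = seq_along(EI), plant_id = plants,
                           group = factor(grp, levels = c("lo", "hi")),
                           EI_Nm2 = EI, E_Pa = EI / 1e-12, I_m4 = 1e-12)
  fit <- suppressWarnings(fit_group_model(noise_free, "log_E"))
  expect_equal(percent_rigidity_difference(fit, "lo", "hi", basis = "emm"), 175,
               tolerance = 1e-6)
  expect_equal(percent_rigidity_difference(fit, "hi", "lo", basis = "emm"),
               (1 / 2.75 - 1) * 100, tolerance = 1e-6)
})
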