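sim_obs <- function(cfg) {
  ann <- generate_follicle_dataset(cfg)
  score_study(ann, outcomes = "total_primordial", level = "section")
}

test_that("log transform recomputes log10(X+1) elementwise and is idempotent", {
  obs <- data.frame(raw_per_mm2 = c(0, 9, 0.5, 26))
  t1 <- log_transform_outcomes(obs)
  expect_equal(t1$log_value, log10(c(1, 10, 1.5, 27)))
  expect_identical(log_transform_outcomes(t1), t1)
  expect_error(log_transform_outcomes(data.frame(raw_per_mm2 = -1)), ">= 0")
  expect_error(log_transform_outcomes(data.frame(x = 1)), "raw_per_mm2")
})

test_that("a single-cell design recovers the sample mean as intercept", {
  cfg <- study_gen_config(arms = "S1P", conditions = "F",
                          punches_per_condition = 12,
                          density_sections_per_punch = 4,
                          proliferation_sections_per_punch = 0,
                          baseline_log_density = 1.3,
                          arm_condition_effects = matrix(0, 1, 1),
                          fragment_sd = 0, residual_sd = 0.1, seed = 20)
  obs <- sim_obs(cfg)
  fit <- fit_mixed_model(obs, model_spec())
  expect_equal(nrow(fit$fixed_effects), 1L)
  expect_equal(fit$fixed_effects$estimate, mean(obs$log_value),
               tolerance = 1e-8)
  expect_equal(nrow(fit$contrasts), 0L)
})

test_that("with zero fragment variance the fixed effects match the OLS oracle", {
  cfg <- study_gen_config(arms = c("S1P", "CT_NaOH"), conditions = c("F", "D2"),
                          punches_per_condition = 10,
                          density_sections_per_punch = 6,
                          proliferation_sections_per_punch = 0,
                          baseline_log_density = 1.2,
                          arm_condition_effects = matrix(c(0, -0.2, -0.5, -0.7),
                                                         2, 2),
                          fragment_sd = 0, residual_sd = 0.1, seed = 21)
  obs <- sim_obs(cfg)
  fit <- fit_mixed_model(obs, model_spec())
  ols <- lm(log_value ~ 0 + interaction(arm, condition, sep = "|"), data = obs)
  expect_equal(sort(unname(fit$fixed_effects$estimate)),
               sort(unname(coef(ols))), tolerance = 1e-6)
})

test_that("variance components are recovered on a known simulation", {
  cfg <- study_gen_config(arms = "S1P", conditions = c("F", "D2"),
                          punches_per_condition = 150,
                          density_sections_per_punch = 8,
                          proliferation_sections_per_punch = 0,
                          baseline_log_density = 1.3,
                          arm_condition_effects = matrix(c(0, -0.4), 1, 2),
                          fragment_sd = 0.2, residual_sd = 0.1, seed = 22)
  fit <- fit_mixed_model(sim_obs(cfg), model_spec())
  expect_equal(unname(fit$variance_components["fragment"]), 0.04,
               tolerance = 0.25)
  expect_equal(unname(fit$variance_components["residual"]), 0.01,
               tolerance = 0.15)
  expect_true(all(fit$variance_components >= 0))
})

test_that("significance flags follow alpha exactly and re-flag without refitting", {
  cfg <- study_gen_config(punches_per_condition = 3,
                          density_sections_per_punch = 4, seed = 23)
  fit <- fit_mixed_model(sim_obs(cfg), model_spec(alpha = 0.01))
  expect_equal(fit$contrasts$significant, fit$contrasts$p_value < 0.01)
  loose <- update_alpha(fit, 0.2)
  expect_equal(loose$contrasts$significant, fit$contrasts$p_value < 0.2)
  expect_equal(loose$contrasts$p_value, fit$contrasts$p_value)
  none <- update_alpha(fit, 0)
  expect_false(any(none$contrasts$significant))
})

test_that("contrast families cover within-arm steps and drug-vs-vehicle pairs", {
  cfg <- study_gen_config(punches_per_condition = 2,
                          density_sections_per_punch = 3, seed = 24)
  fit <- fit_mixed_model(sim_obs(cfg), model_spec())
  # 4 arms x 3 successive condition pairs + 2 drug-vehicle pairs x 4 conditions
  expect_equal(nrow(fit$contrasts), 4 * 3 + 2 * 4)
  expect_true(any(grepl("^S1P: F vs F-T$", fit$contrasts$pair)))
  expect_true(any(grepl("^ZVAD vs CT_DMSO @ D6$", fit$contrasts$pair)))
  # single-arm studies report within-arm condition contrasts only
  cfg1 <- study_gen_config(arms = "S1P", punches_per_condition = 2,
                           density_sections_per_punch = 3, seed = 25)
  fit1 <- fit_mixed_model(sim_obs(cfg1), model_spec())
  expect_equal(fit1$contrasts$pair,
               c("S1P: F vs F-T", "S1P: F-T vs D2", "S1P: D2 vs D6"))
})

test_that("normal-approximation p-values are available and close at large n", {
  cfg <- study_gen_config(arms = c("S1P", "CT_NaOH"), conditions = c("F", "D2"),
                          punches_per_condition = 40,
                          density_sections_per_punch = 6,
                          proliferation_sections_per_punch = 0,
                          baseline_log_density = 1.2,
                          arm_condition_effects = matrix(c(0, -0.1, -0.4, -0.5),
                                                         2, 2),
                          fragment_sd = 0.15, residual_sd = 0.1, seed = 26)
  obs <- sim_obs(cfg)
  f_sat <- fit_mixed_model(obs, model_spec(df_method = "satterthwaite"))
  f_nrm <- fit_mixed_model(obs, model_spec(df_method = "normal"))
  expect_equal(f_sat$contrasts$estimate, f_nrm$contrasts$estimate)
  expect_equal(f_sat$contrasts$p_value, f_nrm$contrasts$p_value,
               tolerance = 0.02)
})

test_that("type-I check is deterministic under a seed and zero at alpha ~ 0", {
  null_cfg <- study_gen_config(arms = c("S1P", "CT_NaOH"),
                               punches_per_condition = 3,
                               density_sections_per_punch = 3,
                               proliferation_sections_per_punch = 0,
                               baseline_log_density = 1.2,
                               arm_condition_effects = matrix(0, 2, 4),
                               seed = 1)
  a <- type1_error_check(model_spec(), null_cfg, n_reps = 5, seed = 30)
  b <- type1_error_check(model_spec(), null_cfg, n_reps = 5, seed = 30)
  expect_identical(a, b)
  tiny <- type1_error_check(model_spec(alpha = 1e-12), null_cfg,
                            n_reps = 5, seed = 30)
  expect_equal(tiny$per_contrast_rate, 0)
  expect_error(type1_error_check(model_spec(), null_cfg, n_reps = 0), "n_reps")
  skew <- study_gen_config(arms = c("S1P", "CT_NaOH"),
                           arm_condition_effects = matrix(1:8, 2, 4))
  expect_error(type1_error_check(model_spec(), skew, n_reps = 2),
               "effects equal")
})
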