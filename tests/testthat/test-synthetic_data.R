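test_that("environmental generator is deterministic, satisfies the density identity and hits r = -1 noiselessly", {
  cfg <- env_gen_config(n_objects = 50, seed = 77)
  t1 <- gen_env_objects(cfg)
  t2 <- gen_env_objects(cfg)
  expect_identical(t1$volume_cm3, t2$volume_cm3)
  expect_identical(t1$weight_g, t2$weight_g)
  expect_equal(t1$density_g_cm3, t1$weight_g / t1$volume_cm3, tolerance = 1e-15)
  # volumes inside the configured log range
  expect_true(all(t1$volume_cm3 >= 10 - 1e-9 & t1$volume_cm3 <= 4000 + 1e-9))
  noiseless <- gen_env_objects(env_gen_config(n_objects = 30, log_noise_sd = 0,
                                              seed = 1))
  expect_equal(log_log_correlation(noiseless)$r, -1, tolerance = 1e-12)
  fit <- fit_power_law(noiseless)
  expect_equal(fit$gamma, -0.387, tolerance = 1e-12)
  expect_equal(fit$c, 2, tolerance = 1e-9)
})

test_that("observer generator is deterministic and honors the generative equations", {
  cfg <- observer_gen_config(seed = 5)
  a <- gen_observer_trials(cfg)
  b <- gen_observer_trials(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 2 * 10 * 3 * 6 * 2 * 10)  # full factorial design
  # noiseless null observers: reports equal true ratios, group contrast null
  null_cfg <- observer_gen_config(compression_beta = 1,
                                  prior_line = ratio_line(0, 0, "density"),
                                  report_log_noise_sd = 0,
                                  subject_log_noise_sd = 0, seed = 2)
  tr <- gen_observer_trials(null_cfg)
  s <- subject_pair_means(tr)
  st <- stimulus_pair_table(stimulus_volumes()$Blobs)
  blob <- s[s$object_set == "Blobs" & s$subject == "EW01", ]
  expect_equal(blob$mean_log_ratio, st$VR[match(blob$pair, st$pair)],
               tolerance = 1e-12)
  ew <- s$mean_log_ratio[s$group == "EW"]
  pv <- s$mean_log_ratio[s$group == "PV"]
  expect_equal(ew, pv, tolerance = 1e-12)
  # quantized reports are integers
  qcfg <- observer_gen_config(quantize_reports = TRUE, seed = 3)
  expect_true(all(gen_observer_trials(qcfg)$report %% 1 == 0))
})

test_that("planted density prior makes EW exceed PV for every pair, and vanishes when the prior is null", {
  cfg <- observer_gen_config(seed = 8)
  s <- subject_pair_means(gen_observer_trials(cfg))
  agg <- aggregate(mean_log_ratio ~ group + pair, data = s, FUN = mean)
  for (pr in unique(agg$pair)) {
    ew <- agg$mean_log_ratio[agg$group == "EW" & agg$pair == pr]
    pv <- agg$mean_log_ratio[agg$group == "PV" & agg$pair == pr]
    expect_gt(ew, pv)   # "smaller is denser" prior raises EW log ratios
  }
  null_cfg <- observer_gen_config(prior_line = ratio_line(0, 0, "density"),
                                  report_log_noise_sd = 0,
                                  subject_log_noise_sd = 0, seed = 8)
  s0 <- subject_pair_means(gen_observer_trials(null_cfg))
  agg0 <- aggregate(mean_log_ratio ~ group + pair, data = s0, FUN = mean)
  diffs <- tapply(agg0$mean_log_ratio, agg0$pair, function(v) abs(diff(v)))
  expect_true(all(diffs < 1e-12))
})

test_that("subject-level means track the generative expectation within noise / sqrt(n)", {
  cfg <- observer_gen_config(seed = 14)
  s <- subject_pair_means(gen_observer_trials(cfg))
  st <- stimulus_pair_table(stimulus_volumes()$Cubes)
  pv <- s[s$group == "PV" & s$object_set == "Cubes", ]
  truth <- cfg$compression_beta * st$VR[match(pv$pair, st$pair)]
  # per-subject cell mean: subject bias (sd .6) dominates; 10 subjects x
  # 20 trials, so the across-subject mean sits within ~4 * .6/sqrt(10)
  cell_means <- tapply(pv$mean_log_ratio - truth, pv$pair, mean)
  expect_true(all(abs(cell_means) < 4 * 0.6 / sqrt(10)))
})

test_that("recovery_experiment reports near-zero bias, and zero bias exactly when noiseless", {
  env <- env_gen_config(n_objects = 195)
  obs <- observer_gen_config(n_per_group = 4, trials_per_cell = 2)
  rep <- recovery_experiment(env, obs, n_replicates = 20, seed = 42)
  expect_lt(abs(rep$gamma_bias), 0.03)
  expect_true(is.finite(rep$gamma_rmse) && rep$gamma_rmse < 0.1)
  # noiseless everything: zero bias exactly
  env0 <- env_gen_config(n_objects = 20, log_noise_sd = 0)
  obs0 <- observer_gen_config(n_per_group = 2, trials_per_cell = 1,
                              compression_beta = 1,
                              report_log_noise_sd = 0, subject_log_noise_sd = 0)
  rep0 <- recovery_experiment(env0, obs0, n_replicates = 3, seed = 9)
  expect_equal(rep0$gamma_bias, 0, tolerance = 1e-10)
  expect_equal(rep0$slope_bias, 0, tolerance = 1e-10)
})
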