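test_that("normalize_response maps reference-10 reports to canonical log ratios with order symmetry", {
  expect_equal(normalize_response(20, "S-L"), log(1 / 2), tolerance = 1e-12)
  expect_equal(normalize_response(5, "L-S"), log(1 / 2), tolerance = 1e-12)
  expect_equal(normalize_response(10, "S-L"), 0)
  # order/reciprocal symmetry: (S-L, r) == (L-S, 100/r) for all r > 0
  r <- c(0.5, 2, 7.3, 10, 25, 90)
  expect_equal(normalize_response(r, rep("S-L", 6)),
               normalize_response(100 / r, rep("L-S", 6)), tolerance = 1e-12)
  expect_error(normalize_response(-1, "S-L"), "positive")
  expect_error(normalize_response(10, "left-right"), "order")
})

test_that("subject_pair_means collapses orders into per-subject cell means", {
  trials <- fix_trials(ratio = 2, n_per_group = 2, trials_per_cell = 10)
  s <- subject_pair_means(trials)
  expect_s3_class(s, "subject_pair_summary")
  expect_true(all(abs(s$mean_log_ratio - log(1 / 2)) < 1e-12))
  expect_true(all(s$n_trials == 20))   # 10 S-L + 10 L-S pooled
  # asymmetric orders still agree: 10 S-L at 20 and 10 L-S at 5 both say "half"
  tr2 <- fix_trials(ratio = 2, trials_per_cell = 10)
  tr2$report[tr2$order == "L-S"] <- 5
  s2 <- subject_pair_means(tr2)
  expect_true(all(abs(s2$mean_log_ratio - log(1 / 2)) < 1e-12))
})

test_that("lilliefors test statistic and Monte-Carlo null behave like the literature values", {
  # perfectly normal-shaped sample: quantiles of the standard normal
  x <- qnorm(ppoints(20))
  res <- lilliefors_test(x, n_mc = 2000, seed = 9)
  expect_gt(res$p, 0.5)
  # strongly bimodal sample rejects
  bim <- rep(c(-1, 1), each = 10)
  expect_lt(lilliefors_test(bim, n_mc = 2000, seed = 9)$p, 0.05)
  # 95th percentile of the n = 20 null is near the tabulated 0.190
  null <- objdens:::with_seed(31, replicate(4000, objdens:::.lilliefors_D(rnorm(20))))
  expect_equal(unname(quantile(null, 0.95)), 0.190, tolerance = 0.04)
  expect_error(lilliefors_test(rep(1, 10)), "constant")
  expect_error(lilliefors_test(rnorm(3)), "at least 5")
})

test_that("one_sample_t matches the hand formula and stats::t.test", {
  res <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  x <- objdens:::with_seed(4, rnorm(15, 0.3))
  ours <- one_sample_t(x, 0.1)
  ref <- t.test(x, mu = 0.1)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  same <- one_sample_t(c(1, 2, 3), 2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(one_sample_t(c(1, 1, 1), 0), "zero variance")
})

test_that("split-plot ANOVA matches the aov() error-strata oracle on the full 2x3x6 design", {
  trials <- gen_observer_trials(observer_gen_config(seed = 21))
  s <- subject_pair_means(trials)
  ours <- mixed_anova(s)
  d <- as.data.frame(s)
  for (v in c("subject", "group", "object_set", "pair")) d[[v]] <- factor(d[[v]])
  fit <- summary(aov(mean_log_ratio ~ group * object_set * pair +
                       Error(subject / (object_set * pair)), data = d))
  ref <- do.call(rbind, lapply(fit, function(stratum) {
    tab <- stratum[[1]]
    tab <- tab[trimws(rownames(tab)) != "Residuals", , drop = FALSE]
    data.frame(term = trimws(rownames(tab)), F = tab[["F value"]],
               p = tab[["Pr(>F)"]])
  }))
  map <- c(group = "A", object_set = "B", "group:object_set" = "AB",
           pair = "C", "group:pair" = "AC", "object_set:pair" = "BC",
           "group:object_set:pair" = "ABC")
  for (term in names(map)) {
    i <- ours$effect == map[[term]]
    j <- ref$term == term
    expect_equal(ours$F[i], ref$F[j], tolerance = 1e-8, label = term)
    expect_equal(ours$p[i], ref$p[j], tolerance = 1e-8, label = term)
  }
  # declared dfs follow the classical split-plot decomposition
  expect_equal(ours$df_num[ours$effect == "A"], 1)
  expect_equal(ours$df_den[ours$effect == "A"], 18)
  expect_equal(ours$df_num[ours$effect == "C"], 5)
  expect_equal(ours$df_den[ours$effect == "C"], 90)
})

test_that("split-plot ANOVA matches aov() on a tiny 2x2x2 balanced design and handles degenerate groups", {
  grid <- expand.grid(subject = paste0("s", 1:8), B = c("b1", "b2"),
                      C = c("c1", "c2"), stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$subject %in% paste0("s", 1:4), "g1", "g2")
  grid$y <- objdens:::with_seed(5, rnorm(nrow(grid)))
  ours <- mixed_anova(grid, dv = "y", between = "group", within = c("B", "C"))
  d <- grid
  for (v in c("subject", "group", "B", "C")) d[[v]] <- factor(d[[v]])
  fit <- summary(aov(y ~ group * B * C + Error(subject / (B * C)), data = d))
  refF <- unlist(lapply(fit, function(st) {
    tab <- st[[1]]; setNames(tab[["F value"]], trimws(rownames(tab)))
  }))
  expect_equal(ours$F[ours$effect == "A"], unname(refF[grep("group$", names(refF))[1]]),
               tolerance = 1e-8)
  expect_equal(ours$F[ours$effect == "BC"],
               unname(refF[grep("B:C$", names(refF))[1]]), tolerance = 1e-8)
  # identical groups: condition F is exactly 0
  dup <- grid
  dup$y[dup$group == "g2"] <- dup$y[dup$group == "g1"]
  ours0 <- mixed_anova(dup, dv = "y", between = "group", within = c("B", "C"))
  expect_equal(ours0$F[ours0$effect == "A"], 0, tolerance = 1e-12)
  # unbalanced and incomplete designs are refused
  expect_error(mixed_anova(grid[grid$subject != "s1" | grid$B != "b1", ],
                           dv = "y", between = "group", within = c("B", "C")),
               "incomplete")
  expect_error(mixed_anova(grid[grid$subject != "s1", ], dv = "y",
                           between = "group", within = c("B", "C")),
               "unbalanced")
})

test_that("post-hoc per-pair ANOVAs give six condition tests matching per-pair aov()", {
  trials <- gen_observer_trials(observer_gen_config(seed = 33))
  s <- subject_pair_means(trials)
  anovas <- posthoc_pair_anovas(s)
  expect_length(anovas, 6)
  pr <- "A:D"
  sub <- as.data.frame(s[s$pair == pr, ])
  for (v in c("subject", "group", "object_set")) sub[[v]] <- factor(sub[[v]])
  fit <- summary(aov(mean_log_ratio ~ group * object_set +
                       Error(subject / object_set), data = sub))
  refF <- fit[[1]][[1]]["group", "F value"]
  expect_equal(anovas[[pr]]$F[anovas[[pr]]$effect == "A"], refF, tolerance = 1e-8)
  expect_equal(anovas[[pr]]$df_den[anovas[[pr]]$effect == "A"], 18)
  # identical groups: all six condition Fs collapse to 0
  null_trials <- fix_trials(ratio = 3, n_per_group = 3, trials_per_cell = 2,
                            sets = c("Blobs", "Greebles", "Cubes"),
                            pairs = c("A:B", "A:C", "A:D", "B:C", "B:D", "C:D"))
  s0 <- subject_pair_means(null_trials)
  s0$mean_log_ratio <- s0$mean_log_ratio +
    objdens:::with_seed(2, rep(rnorm(18 * 3), 2))  # same values in both groups
  a0 <- posthoc_pair_anovas(s0)
  expect_true(all(vapply(a0, function(at) at$F[at$effect == "A"], 0) < 1e-12))
})

test_that("fdr_correct implements textbook BH step-up (oracle: p.adjust)", {
  p_table <- c(0.025, 0.032, 0.009, 0.042, 0.031, 0.012)
  q <- fdr_correct(p_table)
  expect_equal(q, p.adjust(p_table, "BH"), tolerance = 1e-12)
  expect_equal(q, c(0.0384, 0.0384, 0.036, 0.042, 0.0384, 0.036),
               tolerance = 1e-12)   # hand step-up values
  expect_equal(fdr_correct(0.2), 0.2)
  expect_equal(fdr_correct(rep(0.3, 5)), rep(0.3, 5))
  # monotone in sorted p, never below raw p
  set.seed(8)
  p <- runif(25)
  q2 <- fdr_correct(p)
  expect_true(all(q2 >= p))
  o <- order(p)
  expect_true(all(diff(q2[o]) >= -1e-15))
  expect_error(fdr_correct(c(0.5, 0)), "0, 1")
})

test_that("cohens_d uses the pooled n-1 standard deviation and refuses degenerate groups", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  d <- cohens_d(a, b)
  expect_equal(d$statistic, -1 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(cohens_d(a, a)$statistic, 0)
  expect_error(cohens_d(c(0, 0), c(1, 1)), "zero pooled")
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
})

test_that("perceptual line fits recover a planted environmental line exactly (plant-and-recover)", {
  # noiseless observers whose EW equals the environmental line applied to
  # the true volume ratio: beta = 1, prior on true VR, no noise
  cfg <- observer_gen_config(compression_beta = 1,
                             prior_line = ratio_line(0.613 - 1, 0.114, "density"),
                             report_log_noise_sd = 0, subject_log_noise_sd = 0,
                             prior_on = "true", seed = 1)
  s <- subject_pair_means(gen_observer_trials(cfg))
  lines <- fit_perceptual_lines(s)
  for (set in names(lines)) {
    expect_equal(lines[[set]]$weight$slope, 0.613, tolerance = 1e-6)
    expect_equal(lines[[set]]$weight$intercept, 0.114, tolerance = 1e-6)
    # derived density line: slope - 1, same intercept
    expect_equal(lines[[set]]$density$slope, lines[[set]]$weight$slope - 1,
                 tolerance = 1e-12)
    expect_equal(lines[[set]]$density$intercept, lines[[set]]$weight$intercept,
                 tolerance = 1e-12)
  }
  expect_error(fit_perceptual_lines(s[s$pair != "A:B", ]), "missing pair")
})

test_that("volume_underestimation_tests flags compressed PV reports per object set", {
  # beta < 1 means PV log ratios are less extreme than the true ones:
  # mean log error is positive (reported small/large ratio too large)
  cfg <- observer_gen_config(compression_beta = 0.8,
                             report_log_noise_sd = 0.05,
                             subject_log_noise_sd = 0.05, seed = 12)
  s <- subject_pair_means(gen_observer_trials(cfg))
  tests <- volume_underestimation_tests(s)
  expect_length(tests, 3)
  for (res in tests) {
    expect_gt(res$statistic, 0)
    expect_lt(res$p, 0.001)
    expect_equal(res$df, 9)
  }
})
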