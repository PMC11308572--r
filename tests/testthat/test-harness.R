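test_that("randomization is balanced and independent of covariates", {
  params <- default_population_params()
  prof <- sample_population(params, 100000, seed = 70)
  arms <- randomize(prof, seed = 70, force_balance = FALSE)
  n_c <- sum(arms == "chemo_endocrine")
  ci <- qbinom(c(0.0005, 0.9995), 100000, 0.5)
  expect_gte(n_c, ci[1]); expect_lte(n_c, ci[2])
  # covariate balance: standardized mean differences < 3 SE
  for (x in list(prof$age_dx, prof$rs,
                 as.numeric(prof$grade == "high"),
                 as.numeric(prof$race_eth == "nh_black"))) {
    d <- mean(x[arms == "endocrine"]) - mean(x[arms == "chemo_endocrine"])
    se <- sd(x) * sqrt(4 / 100000)
    expect_lt(abs(d), 3 * se)
  }
  # forced balance: exact counts, n = 2 gives one per arm
  two <- randomize(prof[1:2, ], seed = 1, force_balance = TRUE)
  expect_setequal(two, c("endocrine", "chemo_endocrine"))
  exact <- randomize(prof, seed = 71, force_balance = TRUE)
  expect_equal(sum(exact == "chemo_endocrine"), 50000)
})

test_that("two-proportion power formula matches the textbook computation", {
  p1 <- 0.9; d <- 0.03; a <- 0.05; pw <- 0.8
  p2 <- p1 + d; pbar <- (p1 + p2) / 2
  n_hand <- ceiling((qnorm(1 - a / 2) * sqrt(2 * pbar * (1 - pbar)) +
                       qnorm(pw) * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / d^2)
  expect_equal(power_sample_size(p1, d, a, pw), as.integer(n_hand))
  # power 0.5 puts the z_power term at zero
  n_half <- power_sample_size(p1, d, a, 0.5)
  expect_equal(n_half,
               as.integer(ceiling(qnorm(1 - a / 2)^2 * 2 * pbar * (1 - pbar) / d^2)))
  # halving the detectable difference roughly quadruples n
  r <- power_sample_size(0.9, 0.015) / power_sample_size(0.9, 0.03)
  expect_gt(r, 3.5); expect_lt(r, 4.5)
  expect_error(power_sample_size(0.9, 0), "non-zero")
})

test_that("null model: every incremental outcome within 3 SE of zero", {
  config <- analysis_config(n_patients = 40000, seed = 72,
                            toxicity_prob = 0, use_prior_draw = FALSE,
                            strata = "menopausal")
  config$hazard$chemo_effect <- list(pre = rep(1, 4), post = rep(1, 4))
  res <- run_population_analysis(config, keep_histories = TRUE)
  inc <- res$outcomes[arm == "incremental" & level == "overall"]
  h <- res$histories
  n_arm <- sum(h$arm == "endocrine")
  se_ly <- sd(h$death_time) * sqrt(2 / n_arm)
  expect_lt(abs(inc$life_years), 3 * se_ly)
  p10 <- res$outcomes[arm == "endocrine" & level == "overall", drfs_10y] / 100
  expect_lt(abs(inc$drfs_10y), 3 * 100 * sqrt(2 * p10 * (1 - p10) / n_arm))
  q <- qaly(h, config$schedule, 0.03)
  expect_lt(abs(inc$qaly_disc_3), 3 * sd(q) * sqrt(2 / n_arm))
})

test_that("population analysis emits summaries, curves, manifest and warnings", {
  config <- analysis_config(n_patients = 5000, seed = 73)
  res <- run_population_analysis(config)
  expect_named(res, c("population_summary", "outcomes", "km_curves",
                      "manifest"))
  expect_true(all(c("overall", "menopausal", "race_eth") %in%
                    res$outcomes$stratum))
  expect_true(all(res$km_curves$surv >= 0 & res$km_curves$surv <= 1))
  expect_equal(res$manifest$seed, 73)
  # subgroups below 100 patients per arm are flagged in the manifest
  tiny <- analysis_config(n_patients = 600, seed = 74)
  expect_gt(length(run_population_analysis(tiny)$manifest$warnings), 0)
})

test_that("statistics are stable across simulation scale (3 MC SE)", {
  cfg_small <- analysis_config(n_patients = 50000, seed = 75,
                               use_prior_draw = FALSE, strata = NULL)
  cfg_big <- analysis_config(n_patients = 250000, seed = 76,
                             use_prior_draw = FALSE, strata = NULL)
  small <- run_population_analysis(cfg_small)$outcomes
  big <- run_population_analysis(cfg_big)$outcomes
  for (a in c("endocrine", "chemo_endocrine")) {
    s <- small[arm == a]; b <- big[arm == a]
    p <- b$drfs_10y / 100
    se <- 100 * sqrt(p * (1 - p) * (1 / (cfg_small$n_patients / 2) +
                                      1 / (cfg_big$n_patients / 2)))
    expect_lt(abs(s$drfs_10y - b$drfs_10y), 3 * se)
  }
})

test_that("virtual trial: structure, premenopausal mix and small-sample SE", {
  config <- analysis_config(seed = 77)
  config$trial_n <- 3000
  res <- run_trial_validation(config, n_replicates = 3)
  expect_equal(res$trial_n, 3000)
  expect_true(all(c("published_trial", "trial_simulation") %in%
                    res$comparison$source))
  expect_true(all(c("overall", "pre", "post") %in% res$comparison$stratum))
  # premenopausal enrollment share is forced by the trial mix
  one <- bcmicrosim:::sample_trial_population(config$pop_params, 2000,
                                              config$trial$pre_fraction,
                                              seed = 78)
  expect_equal(mean(one$menopausal == "pre"), config$trial$pre_fraction,
               tolerance = 0.001)
  # a small trial carries percent-scale Monte-Carlo noise
  config$trial_n <- 200
  tiny <- run_trial_validation(config, n_replicates = 8)
  expect_gt(max(tiny$mc_se$mc_se, na.rm = TRUE), 0.5)
  # default trial size comes from the power specification
  config$trial_n <- NULL
  ps <- config$trial$power_spec
  expect_equal(run_trial_validation(config, n_replicates = 1)$trial_n,
               2L * do.call(power_sample_size, ps))
})

test_that("sensitivity suite: CRN scenarios and monotone discounting", {
  config <- analysis_config(n_patients = 20000, seed = 79,
                            strata = "menopausal")
  res <- run_sensitivity_suite(config)
  expect_setequal(names(res$scenarios),
                  c("base", "age50_proxy", "toxicity_0.17", "toxicity_0.2"))
  base <- res$scenarios$base
  per_arm <- base[arm != "incremental"]
  # discounting at 5% is strictly below 1% for every stratum and arm
  expect_true(all(per_arm$qaly_disc_5 < per_arm$qaly_disc_1))
  # higher toxicity probability weakly decreases chemo-arm QALYs (CRN)
  lo <- res$scenarios$`toxicity_0.17`[arm == "chemo_endocrine"]
  hi <- res$scenarios$`toxicity_0.2`[arm == "chemo_endocrine"]
  expect_true(all(hi$qaly_disc_3 <= lo$qaly_disc_3 + 1e-12))
  # endocrine arm is untouched by the toxicity scenario (same random numbers)
  lo_e <- res$scenarios$`toxicity_0.17`[arm == "endocrine"]
  hi_e <- res$scenarios$`toxicity_0.2`[arm == "endocrine"]
  expect_equal(lo_e$qaly_disc_3, hi_e$qaly_disc_3, tolerance = 1e-12)
  # age-50 proxy leaves the premenopausal chemotherapy benefit sign unchanged
  sgn <- res$stability[level == "pre" & scenario %in% c("base", "age50_proxy")]
  expect_true(all(sgn$sign == sgn$sign[1]))
})
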