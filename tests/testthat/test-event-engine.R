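test_that("treatment-effect draws follow the empirical-Bayes prior", {
  m <- const_hazard_model(chemo_pre = 0.70, chemo_post = 1.0, prior_scale = 0)
  eff <- draw_treatment_effects(m, seed = 1)
  expect_equal(eff$pre, rep(0.70, 4))   # zero scale: location exactly
  expect_equal(eff$post, rep(1.0, 4))

  m2 <- const_hazard_model(chemo_pre = 0.70, chemo_post = 1.0,
                           prior_scale = 0.2)
  draws <- t(vapply(1:10000, function(s)
    c(draw_treatment_effects(m2, s)$pre[1],
      draw_treatment_effects(m2, s)$post[1]), numeric(2)))
  # normal-theory check on the log scale
  expect_lt(abs(mean(log(draws[, 1])) - log(0.70)), 3 * 0.2 / sqrt(10000))
  # symmetric prior at log(1): median draw ~ 1
  expect_lt(abs(median(draws[, 2]) - 1), 0.02)
})

test_that("dr_hazard composes baseline, sub-hazards and chemotherapy effect", {
  prof <- sample_population(toy_population_params(age = 60), 1, seed = 2)
  m <- const_hazard_model(h_post = 0.03, chemo_post = 1.0)
  h_e <- dr_hazard(prof, "endocrine", m)
  expect_equal(h_e$rates, rep(0.03, 4))  # zero log-shr: baseline exactly
  h_c <- dr_hazard(prof, "chemo_endocrine", m)
  expect_equal(h_c$rates, h_e$rates)     # chemo effect 1: arms identical

  shr <- zero_log_shr(); shr$grade["intermediate"] <- log(2)
  m2 <- const_hazard_model(h_post = 0.03, log_shr = shr)
  expect_equal(dr_hazard(prof, "endocrine", m2)$rates, rep(0.06, 4))

  m3 <- const_hazard_model(h_post = 0.03, chemo_post = 0.6)
  expect_equal(dr_hazard(prof, "chemo_endocrine", m3)$rates, rep(0.018, 4))

  bad <- const_hazard_model()
  bad$log_shr$grade <- bad$log_shr$grade[-2]
  expect_error(profile_multiplier(prof, bad), "configuration error")
})

test_that("piecewise inverse-CDF sampler matches closed forms", {
  h <- piecewise_hazard(c(0, 100), 0.25)
  x <- sample_time_piecewise(h, n = 100000, seed = 4)
  expect_lt(abs(mean(x) - 4), 3 * 4 / sqrt(100000))  # Exp(0.25) mean 1/h

  h0 <- piecewise_hazard(c(0, 100), 0)
  expect_true(all(sample_time_piecewise(h0, n = 1000, seed = 1) == Inf))

  # two-piece hazard: empirical S at the boundary within the binomial CI
  h2 <- piecewise_hazard(c(0, 2, 50), c(0.4, 0.05))
  x2 <- sample_time_piecewise(h2, n = 100000, seed = 6)
  s_emp <- mean(x2 > 2)
  s_true <- exp(-0.4 * 2)
  ci <- qbinom(c(0.0005, 0.9995), 100000, s_true) / 100000
  expect_gte(s_emp, ci[1]); expect_lte(s_emp, ci[2])
  # cumulative-hazard consistency: P(T > t) = exp(-H(t)) at several t
  for (t in c(0.5, 2, 6)) {
    expect_lt(abs(mean(x2 > t) - exp(-cumulative_hazard(h2, t))),
              4 * sqrt(exp(-cumulative_hazard(h2, t)) / 100000))
  }
})

test_that("other-cause death sampling follows the life table", {
  prof <- sample_population(toy_population_params(age = 40), 100000, seed = 8)
  # certain death within the first year
  t1 <- sample_other_cause_death(prof, flat_life_table(q = 1 - 1e-12), seed = 1)
  expect_true(all(t1 <= 1 + 1e-8))
  # constant annual probability q: piecewise-exponential mean -1/log(1-q)
  q <- 0.2
  t2 <- sample_other_cause_death(prof, flat_life_table(q), seed = 2)
  mu <- -1 / log(1 - q)
  expect_lt(abs(mean(t2) - mu), 3 * mu / sqrt(100000))
  # increasing rates: older diagnosis age stochastically shortens survival
  lt <- make_life_table(base_rate = 2e-5, gompertz_b = 0.1)
  old <- sample_population(toy_population_params(age = 75), 20000, seed = 3)
  yng <- sample_population(toy_population_params(age = 45), 20000, seed = 3)
  t_old <- sample_other_cause_death(old, lt, seed = 4)
  t_yng <- sample_other_cause_death(yng, lt, seed = 4)
  expect_lt(mean(t_old) + 3, mean(t_yng))
  expect_lt(quantile(t_old, 0.9), quantile(t_yng, 0.9))
})

test_that("simulate_cohort satisfies the event-history invariants", {
  params <- default_population_params()
  prof <- sample_population(params, 30000, seed = 10)
  arms <- randomize(prof, seed = 10)
  m <- const_hazard_model(h_pre = 0.03, h_post = 0.03, chemo_pre = 0.7,
                          chemo_post = 1.1)
  lt <- flat_life_table(0.03)
  h <- simulate_cohort(prof, arms, m, NULL, lt, toxicity_prob = 0.175,
                       seed = 10)
  expect_true(all(is.na(h$t_bc_death) | h$t_bc_death >= h$t_dr))
  expect_true(all(h$death_time ==
                    pmin(ifelse(is.na(h$t_bc_death), Inf, h$t_bc_death),
                         h$t_oc_death)))
  expect_true(all(!h$toxicity[h$arm == "endocrine"]))
  rec <- !is.na(h$t_dr)
  expect_identical(h$first_event[rec] == "distant_recurrence",
                   h$t_dr[rec] < h$t_oc_death[rec])
  expect_true(all(h$first_event[!rec] == "other_cause_death"))
  expect_true(all(h$death_cause %in% c("breast_cancer", "other")))
  # toxicity frequency in the chemo arm within the binomial 99.9% CI of 0.175
  nc <- sum(h$arm == "chemo_endocrine")
  tox <- sum(h$toxicity)
  ci <- qbinom(c(0.0005, 0.9995), nc, 0.175)
  expect_gte(tox, ci[1]); expect_lte(tox, ci[2])
})

test_that("degenerate pathways: no recurrence hazard; immediate breast cancer death", {
  prof <- sample_population(toy_population_params(age = 60), 5000, seed = 12)
  arms <- rep("endocrine", 5000)
  lt <- flat_life_table(0.05)
  m0 <- const_hazard_model(h_pre = 0, h_post = 0)
  h0 <- simulate_cohort(prof, arms, m0, NULL, lt, seed = 12)
  expect_true(all(h0$first_event == "other_cause_death"))
  expect_true(all(h0$death_cause == "other"))
  expect_true(all(is.na(h0$t_dr)))

  # post-recurrence survival ~ 0: death with distant recurrence as first
  # manifestation, at t_dr
  m1 <- const_hazard_model(h_post = 0.2, pr_meanlog = -30, pr_sdlog = 0)
  h1 <- simulate_cohort(prof, arms, m1, NULL, lt, seed = 13)
  rec <- !is.na(h1$t_dr)
  expect_gt(sum(rec), 0)
  expect_equal(h1$death_time[rec], h1$t_dr[rec], tolerance = 1e-9)
  expect_true(all(h1$death_cause[rec] == "breast_cancer"))
})

test_that("per-patient substreams make results order-invariant", {
  params <- default_population_params()
  prof <- sample_population(params, 500, seed = 20)
  arms <- randomize(prof, seed = 20)
  m <- const_hazard_model(h_pre = 0.05, h_post = 0.05, chemo_pre = 0.8)
  lt <- flat_life_table(0.02)
  full <- simulate_cohort(prof, arms, m, NULL, lt, seed = 20)
  # single-patient call reproduces the cohort row exactly
  for (k in c(1L, 137L, 500L)) {
    one <- simulate_patient(prof[k, ], arms[k], m, NULL, lt, seed = 20)
    expect_equal(as.list(one), as.list(full[k, ]))
  }
  # permuted input order: identical histories per patient id
  perm <- sample(500)
  shuffled <- simulate_cohort(prof[perm, ], arms[perm], m, NULL, lt, seed = 20)
  expect_equal(as.data.frame(shuffled[order(shuffled$patient_id), ]),
               as.data.frame(full), ignore_attr = TRUE)
})

test_that("competing-risk and treatment-effect structure is coherent", {
  # oracle equivalence: single stratum, constant hazards -> KM matches exp(-ht)
  prof <- sample_population(toy_population_params(age = 55), 200000, seed = 30)
  m <- const_hazard_model(h_pre = 0.04, h_post = 0.04)
  lt <- flat_life_table(0.03)
  h <- simulate_cohort(prof, rep("endocrine", nrow(prof)), m, NULL, lt,
                       seed = 30)
  ind <- drfs_indicator(h)
  km <- km_estimate(ind$time, ind$event)
  for (t in c(5, 10)) {
    s_true <- exp(-0.04 * t)
    expect_lt(abs(km_surv_at(km, t) - s_true),
              3 * sqrt(s_true * (1 - s_true) / 200000) / sqrt(exp(-0.03 * t)))
  }
  # cause-specific cumulative incidences sum to <= 1 at every horizon
  for (t in c(2, 5, 10, 20)) {
    ci_dr <- mean(!is.na(h$t_dr) & h$t_dr <= t)
    ci_oc <- mean(is.na(h$t_dr) & h$t_oc_death <= t |
                    (!is.na(h$t_dr) & h$t_oc_death <= pmin(h$t_dr, t)))
    expect_lte(ci_dr + ci_oc, 1)
  }

  # arm exchangeability: null effects -> equal DRFS distributions (KS)
  prof2 <- sample_population(default_population_params(), 40000, seed = 31)
  arms2 <- randomize(prof2, seed = 31)
  mnull <- const_hazard_model(h_pre = 0.03, h_post = 0.03, chemo_pre = 1,
                              chemo_post = 1)
  hn <- simulate_cohort(prof2, arms2, mnull, NULL, lt, toxicity_prob = 0,
                        seed = 31)
  indn <- drfs_indicator(hn)
  ks <- suppressWarnings(
    ks.test(indn$time[hn$arm == "endocrine"],
            indn$time[hn$arm == "chemo_endocrine"]))
  expect_gt(ks$p.value, 0.001)

  # monotone treatment effect: lower premenopausal HR raises 10-year DRFS
  prof3 <- sample_population(toy_population_params(age = 40), 30000, seed = 32)
  arms3 <- rep("chemo_endocrine", nrow(prof3))
  drfs10 <- sapply(c(0.9, 0.6), function(ce) {
    hh <- simulate_cohort(prof3, arms3,
                          const_hazard_model(h_pre = 0.04, chemo_pre = ce),
                          NULL, lt, seed = 33)
    ii <- drfs_indicator(hh)
    km_surv_at(km_estimate(ii$time, ii$event), 10)
  })
  expect_gt(drfs10[2], drfs10[1])
})
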