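test_that("drfs_indicator implements the endpoint definition", {
  # recurrence before other-cause death: event at t_dr
  h <- make_history(t_dr = 4, t_oc = 9)
  ind <- drfs_indicator(h)
  expect_equal(ind$time, 4); expect_true(ind$event)
  # no recurrence: censored at other-cause death
  ind2 <- drfs_indicator(make_history(t_oc = 7.2))
  expect_equal(ind2$time, 7.2); expect_false(ind2$event)
  # death as first manifestation (post-recurrence survival 0): event at t_dr
  ind3 <- drfs_indicator(make_history(t_dr = 3, t_oc = 9, post_rec = 0))
  expect_equal(ind3$time, 3); expect_true(ind3$event)
})

test_that("Kaplan-Meier estimator: closed forms and reference agreement", {
  # no censoring: equals the empirical survival function exactly
  tt <- c(1, 3, 3, 7, 2, 9)
  km <- km_estimate(tt, rep(TRUE, 6))
  for (t in c(0.5, 1, 3, 8, 9))
    expect_equal(km_surv_at(km, t), mean(tt > t))

  # hand-worked 6-observation product-limit oracle:
  # events at 1, 2, 4; censored at 3, 5, 6
  km2 <- km_estimate(c(1, 2, 3, 4, 5, 6),
                     c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(km_surv_at(km2, 1), 5 / 6)
  expect_equal(km_surv_at(km2, 2), 5 / 6 * 4 / 5)
  expect_equal(km_surv_at(km2, 4), 5 / 6 * 4 / 5 * 2 / 3)
  expect_equal(km2$n_risk, c(6, 5, 4, 3, 2, 1))

  # all censored at zero is an error
  expect_error(km_estimate(c(0, 0), c(FALSE, FALSE)), "censored at time zero")

  # 1000 random small censored datasets against the survival package
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    ti <- round(rexp(n, 0.3), 2)  # rounded to force ties
    ev <- runif(n) < 0.7
    if (all(ti == 0 & !ev)) next
    km3 <- km_estimate(ti, ev)
    sf <- survival::survfit(survival::Surv(ti, ev) ~ 1)
    ref <- summary(sf, times = km3$time)$surv
    expect_equal(km3$surv, ref, tolerance = 1e-12)
  }
})

test_that("life-years equal (truncated) death time", {
  h <- make_history(t_oc = 19.6)
  expect_equal(life_years(h), 19.6)
  expect_equal(life_years(make_history(t_oc = 14), horizon = 10), 10)
})

test_that("utility paths combine states multiplicatively", {
  sched <- default_utility_schedule()
  # all utilities 1 -> path identically 1
  u1 <- const_utility_schedule(1)
  p1 <- utility_path(make_history(t_dr = 4, t_oc = 20, arm = "chemo_endocrine",
                                  toxicity = TRUE), u1)
  expect_true(all(p1$utility == 1))

  # endocrine arm, no recurrence: cancer utility x age-band utility
  h <- make_history(t_oc = 20, age_dx = 55)
  p <- utility_path(h, sched)
  expect_equal(utility_path_at(p, 2), 0.731 * 0.837)    # age 57
  expect_equal(utility_path_at(p, 10), 0.731 * 0.811)   # age 65
  expect_equal(utility_path_at(p, 16), 0.731 * 0.771)   # age 71
  # age-band extension: held constant above 79
  h2 <- make_history(t_oc = 25, age_dx = 70)
  expect_equal(utility_path_at(utility_path(h2, sched), 20), 0.731 * 0.771)

  # chemo arm with toxicity: x 0.9 x 0.7 during the first 6 months only
  hc <- make_history(t_oc = 20, age_dx = 55, arm = "chemo_endocrine",
                     toxicity = TRUE)
  pc <- utility_path(hc, sched)
  expect_equal(utility_path_at(pc, 0.25), 0.731 * 0.837 * 0.9 * 0.7)
  expect_equal(utility_path_at(pc, 0.75), 0.731 * 0.837)

  # recurrence utility for 3 years, then pre-recurrence utility resumes
  hr <- make_history(t_dr = 6, t_oc = 20, post_rec = 10, age_dx = 55)
  pr <- utility_path(hr, sched)
  expect_equal(utility_path_at(pr, 7), 0.731 * 0.811 * 0.4)
  expect_equal(utility_path_at(pr, 9.5), 0.731 * 0.811)
  # config switch: recurrence disutility until death
  sched2 <- sched; sched2$recurrence_until_death <- TRUE
  pr2 <- utility_path(hr, sched2)
  expect_equal(utility_path_at(pr2, 9.5), 0.731 * 0.811 * 0.4)
})

test_that("QALY closed forms and discount monotonicity", {
  u1 <- const_utility_schedule(1)
  # utility 1, rate 0, death at T -> QALY = T
  h <- make_history(t_oc = 17.3)
  expect_equal(qaly(h, u1, 0), 17.3, tolerance = 1e-12)
  # utility 1, rate r: (1 - (1+r)^(-T)) / log(1+r), matched to 1e-9
  for (r in c(0.01, 0.03, 0.05)) {
    expect_equal(qaly(h, u1, r), (1 - (1 + r)^(-17.3)) / log(1 + r),
                 tolerance = 1e-9)
    expect_equal(qaly(h, u1, r, method = "segments"),
                 (1 - (1 + r)^(-17.3)) / log(1 + r), tolerance = 1e-9)
  }
})

test_that("analytic and segment QALY routes agree on randomized histories", {
  params <- default_population_params()
  prof <- sample_population(params, 2000, seed = 44)
  arms <- randomize(prof, seed = 44)
  m <- const_hazard_model(h_pre = 0.08, h_post = 0.08, chemo_pre = 0.7,
                          pr_meanlog = log(1.5), pr_sdlog = 1)
  h <- simulate_cohort(prof, arms, m, NULL, flat_life_table(0.04), seed = 44)
  sched <- default_utility_schedule()
  for (r in c(0, 0.03)) {
    expect_equal(qaly(h, sched, r), qaly(h, sched, r, method = "segments"),
                 tolerance = 1e-9)
  }
  sched2 <- sched; sched2$recurrence_until_death <- TRUE
  expect_equal(qaly(h, sched2, 0.03),
               qaly(h, sched2, 0.03, method = "segments"), tolerance = 1e-9)

  # discount monotonicity for every history; qaly bounded by life-years
  q <- sapply(c(0, 0.01, 0.03, 0.05), function(r) qaly(h, sched, r))
  expect_true(all(q[, 1] > q[, 2] & q[, 2] > q[, 3] & q[, 3] > q[, 4]))
  expect_true(all(q[, 1] <= life_years(h) + 1e-12))
})

test_that("summarize_outcomes: structure, symmetry and DRFS monotonicity", {
  params <- default_population_params()
  prof <- sample_population(params, 8000, seed = 50)
  m <- const_hazard_model(h_pre = 0.05, h_post = 0.05, chemo_pre = 1,
                          chemo_post = 1)
  lt <- flat_life_table(0.03)
  sched <- default_utility_schedule()

  # identical arms by construction (paired twins, null effects, no toxicity,
  # chemotherapy disutility switched off): every incremental value is zero
  sched$state_utilities$chemotherapy <- 1
  both <- rbind(prof, prof)
  arms <- rep(c("endocrine", "chemo_endocrine"), each = nrow(prof))
  h <- simulate_cohort(both, arms, m, NULL, lt, toxicity_prob = 0, seed = 50)
  out <- summarize_outcomes(h, sched, discount_rates = c(0.03),
                            strata = "menopausal")
  inc <- out[arm == "incremental"]
  expect_true(all(abs(inc$drfs_10y) < 1e-9))
  expect_true(all(abs(inc$life_years) < 1e-9))
  expect_true(all(abs(inc$qaly_disc_3) < 1e-9))

  # DRFS at 5 years never below DRFS at 10 years
  per_arm <- out[arm != "incremental"]
  expect_true(all(per_arm$drfs_5y >= per_arm$drfs_10y))
  expect_true(all(per_arm$qaly_disc_3 <= per_arm$qaly_undisc + 1e-9))
  expect_true(all(per_arm$qaly_undisc <= per_arm$life_years + 1e-9))

  # a stratum missing one arm is an explicit error
  expect_error(summarize_outcomes(h[h$arm == "endocrine", ], sched),
               "lacks arm")
})

test_that("chemo/toxicity disutilities alone drive a negative increment", {
  # recurrence utility 1 and long post-recurrence survival: with null
  # treatment effect the only arm difference is chemo + toxicity disutility
  params <- default_population_params()
  prof <- sample_population(params, 4000, seed = 51)
  sched <- default_utility_schedule()
  sched$state_utilities$distant_recurrence <- 1
  m <- const_hazard_model(h_pre = 0.03, h_post = 0.03, chemo_pre = 1,
                          chemo_post = 1, pr_meanlog = log(50), pr_sdlog = 0.1)
  both <- rbind(prof, prof)
  arms <- rep(c("endocrine", "chemo_endocrine"), each = nrow(prof))
  h <- simulate_cohort(both, arms, m, NULL, flat_life_table(0.03),
                       toxicity_prob = 0.175, seed = 51)
  out <- summarize_outcomes(h, sched, strata = NULL)
  inc <- out[arm == "incremental"]
  expect_lt(inc$qaly_disc_3, 0)
  expect_equal(inc$life_years, 0, tolerance = 1e-9)
})
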