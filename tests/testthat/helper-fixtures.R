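# Fixtures are built in code: small degenerate populations, constant-hazard
# models and flat life tables with closed-form behaviour.

RACES <- c("nh_black", "hispanic", "nh_white")

# single-cell population: one race, one (possibly zero-width) age bin,
# step menopause model, point-mass tumour characteristics
toy_population_params <- function(age = 60, age_width = 0,
                                  meno_midpoint = 50, meno_scale = 0,
                                  grade = "intermediate",
                                  p_erpr = 1, p_le2 = 1, rs_mu = 17) {
  gvec <- as.list(setNames(as.numeric(GRADE_LEVELS == grade), GRADE_LEVELS))
  gd <- lapply(RACES, function(r)
    setNames(rep(list(gvec), 3), c("18-49", "50-69", "70+")))
  names(gd) <- RACES
  hd <- lapply(RACES, function(r)
    as.list(setNames(rep(p_erpr, 3), GRADE_LEVELS)))
  names(hd) <- RACES
  sd_ <- lapply(RACES, function(r) {
    out <- lapply(GRADE_LEVELS, function(g)
      as.list(setNames(rep(p_le2, 3), c("18-49", "50-69", "70+"))))
    names(out) <- GRADE_LEVELS
    out
  })
  names(sd_) <- RACES
  # near point mass at round(rs_mu): cumulative logits jump from ~ -16 to ~ +9
  k0 <- round(rs_mu)
  cutpoints <- c(seq(-16, -9, length.out = k0),
                 seq(9, 16, length.out = 25 - k0))
  zero_eta <- list(grade = list(low = 0, intermediate = 0, high = 0),
                   size_class = list(le_2cm = 0, gt_2cm = 0),
                   hormone_sensitivity = list(er_and_pr_pos = 0,
                                              er_or_pr_pos = 0),
                   age_band = list(`18-49` = 0, `50-69` = 0, `70+` = 0),
                   race_eth = list(nh_black = 0, hispanic = 0, nh_white = 0))
  population_params(
    race_eth_weights = list(nh_black = 0, hispanic = 0, nh_white = 1),
    age_bins = list(lower = age, upper = age + age_width),
    age_dist_by_race = setNames(rep(list(1), 3), RACES),
    menopause = list(midpoint = as.list(setNames(rep(meno_midpoint, 3), RACES)),
                     scale = as.list(setNames(rep(meno_scale, 3), RACES))),
    grade_dist = gd, hormone_dist = hd, size_dist = sd_,
    rs_model = list(cutpoints = cutpoints, eta = zero_eta))
}

zero_log_shr <- function() {
  list(grade = c(low = 0, intermediate = 0, high = 0),
       size_class = c(le_2cm = 0, gt_2cm = 0),
       hormone_sensitivity = c(er_and_pr_pos = 0, er_or_pr_pos = 0),
       rs_band = c(`0-10` = 0, `11-15` = 0, `16-20` = 0, `21-25` = 0),
       race_eth = c(nh_black = 0, hispanic = 0, nh_white = 0))
}

# constant-hazard model: one rate per menopausal stratum over [0, horizon)
const_hazard_model <- function(h_pre = 0.02, h_post = 0.02,
                               chemo_pre = 1, chemo_post = 1,
                               prior_scale = 0,
                               pr_meanlog = log(2), pr_sdlog = 0.5,
                               breaks = c(0, 5, 10, 20, 100),
                               log_shr = zero_log_shr()) {
  np <- length(breaks) - 1L
  hazard_model(
    breaks = breaks,
    baseline_dr_hazard = list(pre = rep(h_pre, np), post = rep(h_post, np)),
    log_shr = log_shr,
    chemo_effect = list(pre = rep(chemo_pre, np), post = rep(chemo_post, np)),
    chemo_effect_prior = list(
      pre = list(location = log(rep(chemo_pre, np)), scale = prior_scale),
      post = list(location = log(rep(chemo_post, np)), scale = prior_scale)),
    post_recurrence_survival = list(
      pre = list(meanlog = pr_meanlog, sdlog = pr_sdlog),
      post = list(meanlog = pr_meanlog, sdlog = pr_sdlog)))
}

# flat life table: constant annual death probability at every age
flat_life_table <- function(q = 0.01, max_age = 110L) {
  ages <- 18:max_age
  df <- do.call(rbind, lapply(RACES, function(r)
    data.frame(age = ages, race_eth = r,
               rate = c(rep(q, length(ages) - 1L), 1))))
  life_table(df)
}

# utility schedule with every utility equal to u (duration defaults kept)
const_utility_schedule <- function(u = 1) {
  utility_schedule(
    age_band_utility = list(breaks = c(20, 30, 40, 50, 60, 70, 80),
                            values = rep(u, 6)),
    state_utilities = list(invasive_breast_cancer = u, chemotherapy = u,
                           toxicity = u, distant_recurrence = u),
    durations = list(chemotherapy = 0.5, toxicity = 0.5,
                     distant_recurrence = 3))
}

# hand-built event history rows for outcome-accounting tests
make_history <- function(t_dr = NA_real_, t_oc = 30, post_rec = 2,
                         arm = "endocrine", toxicity = FALSE, age_dx = 55,
                         menopausal = "post", race_eth = "nh_white",
                         patient_id = 1L) {
  recurred <- !is.na(t_dr) && t_dr < t_oc
  t_bc <- if (recurred) t_dr + post_rec else Inf
  data.table::data.table(
    patient_id = patient_id, arm = arm, age_dx = age_dx,
    menopausal = menopausal, race_eth = race_eth,
    t_dr = if (recurred) t_dr else NA_real_,
    t_bc_death = if (recurred && t_bc <= t_oc) t_bc else NA_real_,
    t_oc_death = t_oc, toxicity = toxicity,
    first_event = if (recurred) "distant_recurrence" else "other_cause_death",
    death_time = min(t_bc, t_oc),
    death_cause = if (recurred && t_bc <= t_oc) "breast_cancer" else "other")
}
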