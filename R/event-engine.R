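#' Simulate event histories for a cohort
#'
#' For every patient: a distant-recurrence time is drawn by inverting the
#' patient-specific piecewise cumulative hazard (baseline of the menopausal
#' stratum x covariate sub-hazard multiplier x chemotherapy effect in the
#' chemo-endocrine arm); an other-cause death time is drawn from the life
#' table; if recurrence precedes other-cause death, a lognormal
#' post-recurrence survival draw sets the breast cancer death time, and death
#' occurs at whichever of breast cancer or other-cause death comes first.
#' Grade 3--4 toxicity is drawn with probability `toxicity_prob` in the
#' chemo-endocrine arm only. Treatment adherence is 100% by construction.
#'
#' All randomness is a pure function of `(seed, patient_id)`
#' (see [substream_uniforms()]), so results do not depend on row order and
#' scenarios sharing a seed share their random numbers.
#'
#' @param profiles patient profiles from [sample_population()].
#' @param arms character vector per patient: `"endocrine"` or
#'   `"chemo_endocrine"`.
#' @param model `bc_hazard_model`.
#' @param effects realized chemotherapy effects from
#'   [draw_treatment_effects()]; `NULL` uses the model's configured
#'   `chemo_effect`.
#' @param lifetable `bc_life_table`.
#' @param toxicity_prob probability of grade 3--4 toxicity given
#'   chemotherapy (default 0.175).
#' @param seed master integer seed.
#' @return `data.table` (one row per patient) with the profile's
#'   stratification columns plus `t_dr` (years to distant recurrence, `NA`
#'   if none), `t_bc_death` (`NA` unless breast cancer death occurred),
#'   `t_oc_death`, `toxicity`, `first_event`
#'   (`"distant_recurrence"`/`"other_cause_death"`), `death_time`,
#'   `death_cause` (`"breast_cancer"`/`"other"`).
#' @export
simulate_cohort <- function(profiles, arms, model, effects = NULL,
                            lifetable, toxicity_prob = 0.175, seed) {
  stopifnot(toxicity_prob >= 0, toxicity_prob <= 1,
            length(arms) == nrow(profiles),
            all(arms %in% c("endocrine", "chemo_endocrine")))
  validate_hazard_model(model)
  n <- nrow(profiles)
  ids <- profiles$patient_id
  np <- length(model$breaks) - 1L
  widths <- diff(model$breaks)

  m <- profile_multiplier(profiles, model)
  is_pre <- profiles$menopausal == "pre"
  base <- rbind(model$baseline_dr_hazard$pre, model$baseline_dr_hazard$post)
  ce <- rbind(
    if (is.null(effects)) chemo_effect_periods(model$chemo_effect$pre, np)
    else chemo_effect_periods(effects$pre, np),
    if (is.null(effects)) chemo_effect_periods(model$chemo_effect$post, np)
    else chemo_effect_periods(effects$post, np))
  row <- ifelse(is_pre, 1L, 2L)
  chemo <- arms == "chemo_endocrine"

  # per-patient, per-period rates: n x np
  rates <- base[row, , drop = FALSE] * m
  rates[chemo, ] <- rates[chemo, , drop = FALSE] *
    ce[row[chemo], , drop = FALSE]

  # invert the cumulative hazard at the period boundaries
  e_dr <- -log(1 - substream_uniforms(seed, "dr_event", ids))
  cumh <- matrix(0, n, np + 1L)
  for (j in seq_len(np)) cumh[, j + 1L] <- cumh[, j] + rates[, j] * widths[j]
  idx <- rowSums(cumh < e_dr)          # period containing the event
  t_dr <- rep(Inf, n)
  hit <- idx <= np & e_dr > 0
  t_dr[hit] <- model$breaks[idx[hit]] +
    (e_dr[hit] - cumh[cbind(which(hit), idx[hit])]) /
    rates[cbind(which(hit), idx[hit])]
  t_dr[e_dr == 0] <- 0

  t_oc <- sample_other_cause_death(profiles, lifetable,
                                   u = substream_uniforms(seed, "oc_death", ids))

  recurred <- t_dr < t_oc
  u_pr <- substream_uniforms(seed, "post_recurrence", ids)
  prs <- model$post_recurrence_survival
  pr_time <- ifelse(is_pre,
                    qlnorm(u_pr, prs$pre$meanlog, prs$pre$sdlog),
                    qlnorm(u_pr, prs$post$meanlog, prs$post$sdlog))
  t_bc <- ifelse(recurred, t_dr + pr_time, Inf)

  death_time <- pmin(t_bc, t_oc)
  death_cause <- ifelse(t_bc <= t_oc, "breast_cancer", "other")
  toxicity <- chemo & (substream_uniforms(seed, "toxicity", ids) < toxicity_prob)

  out <- data.table(
    patient_id = ids,
    arm = arms,
    age_dx = profiles$age_dx,
    menopausal = profiles$menopausal,
    race_eth = profiles$race_eth,
    t_dr = ifelse(recurred, t_dr, NA_real_),
    t_bc_death = ifelse(recurred & t_bc <= t_oc, t_bc, NA_real_),
    t_oc_death = t_oc,
    toxicity = toxicity,
    first_event = ifelse(recurred, "distant_recurrence", "other_cause_death"),
    death_time = death_time,
    death_cause = ifelse(recurred & t_bc <= t_oc, "breast_cancer", "other"))
  out[]
}

#' Simulate a single patient
#'
#' One-row convenience wrapper around [simulate_cohort()]; because
#' randomness is keyed by patient id, simulating a patient alone reproduces
#' exactly the row the full-cohort call produces for that id.
#'
#' @inheritParams simulate_cohort
#' @param profile one-row patient profile.
#' @param arm treatment arm for this patient.
#' @return one-row `data.table` event history.
#' @export
simulate_patient <- function(profile, arm, model, effects = NULL, lifetable,
                             toxicity_prob = 0.175, seed) {
  simulate_cohort(as.data.table(profile), arm, model, effects, lifetable,
                  toxicity_prob, seed)
}
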