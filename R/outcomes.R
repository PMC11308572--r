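#' Utility schedule
#'
#' Health-state utilities combined multiplicatively: an age-band utility
#' (held at the boundary values outside the tabulated 20--79 range), the
#' invasive-breast-cancer state utility applied from diagnosis for life, a
#' chemotherapy disutility for the first 6 months of the chemo-endocrine arm,
#' a grade 3--4 toxicity disutility for the first 6 months when toxicity
#' occurred, and a distant-recurrence utility applied from recurrence for
#' `durations$distant_recurrence` years (or until death if sooner). With
#' `recurrence_until_death = TRUE` the recurrence utility instead persists to
#' death.
#'
#' @param age_band_utility list of `breaks` (lower bounds, years) and
#'   `values` (one fewer than... exactly `length(breaks) - 1` utilities).
#' @param state_utilities named list: `invasive_breast_cancer`,
#'   `chemotherapy`, `toxicity`, `distant_recurrence`, all in `[0, 1]`.
#' @param durations named list (years): `chemotherapy`, `toxicity`,
#'   `distant_recurrence`, all > 0.
#' @param recurrence_until_death logical config switch (default `FALSE`).
#' @return `bc_utility_schedule`.
#' @export
utility_schedule <- function(age_band_utility, state_utilities, durations,
                             recurrence_until_death = FALSE) {
  s <- structure(list(age_band_utility = age_band_utility,
                      state_utilities = state_utilities,
                      durations = durations,
                      combination_rule = "multiplicative",
                      recurrence_until_death = isTRUE(recurrence_until_death)),
                 class = "bc_utility_schedule")
  u <- c(unlist(age_band_utility$values), unlist(state_utilities))
  if (any(u < 0 | u > 1))
    stop("utility schedule: utilities must lie in [0, 1]", call. = FALSE)
  if (any(unlist(durations) <= 0))
    stop("utility schedule: durations must be > 0", call. = FALSE)
  if (length(age_band_utility$values) != length(age_band_utility$breaks) - 1L)
    stop("utility schedule: need one value per age band", call. = FALSE)
  s
}

#' @rdname utility_schedule
#' @param path JSON file path.
#' @export
load_utility_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  utility_schedule(x$age_band_utility, x$state_utilities, x$durations,
                   isTRUE(x$recurrence_until_death))
}

# age-band utility with constant extension below/above the tabulated range
age_band_utility_at <- function(schedule, age) {
  b <- schedule$age_band_utility$breaks
  v <- schedule$age_band_utility$values
  v[pmax(1L, pmin(findInterval(age, b), length(v)))]
}

#' DRFS indicator: event time and status per patient
#'
#' STEEP distant recurrence-free survival: the event is distant recurrence at
#' `t_dr` (death with distant recurrence as first manifestation is the
#' post-recurrence-survival-zero boundary case and still yields the event at
#' `t_dr`); other-cause death without prior recurrence censors at
#' `t_oc_death`.
#'
#' @param histories event histories from [simulate_cohort()].
#' @return `data.table` with `patient_id`, `time`, `event` (logical).
#' @export
drfs_indicator <- function(histories) {
  H <- as.data.table(histories)
  rec <- H$first_event == "distant_recurrence"
  data.table(patient_id = H$patient_id,
             time = ifelse(rec, H$t_dr, H$t_oc_death),
             event = rec)
}

# breast-cancer-specific survival indicator (supplemental endpoint): event is
# breast cancer death; death from other causes censors.
bcfs_indicator <- function(histories) {
  H <- as.data.table(histories)
  ev <- H$death_cause == "breast_cancer"
  data.table(patient_id = H$patient_id, time = H$death_time, event = ev)
}

#' Kaplan-Meier product-limit estimator
#'
#' Ties at a time are processed events-before-censorings (observations
#' censored at t remain in the risk set for an event at t, the standard
#' convention).
#'
#' @param times observation times (>= 0).
#' @param events logical event indicators (FALSE = censored).
#' @param horizon optional truncation of the reported grid (the estimate at
#'   `horizon` is still available via [km_surv_at()]).
#' @return `bc_km`: list with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` at each distinct observation time.
#' @export
km_estimate <- function(times, events, horizon = NULL) {
  stopifnot(length(times) == length(events), all(times >= 0))
  if (all(times == 0 & !events))
    stop("km_estimate: all observations censored at time zero", call. = FALSE)
  dt <- data.table(time = as.numeric(times), event = as.logical(events))
  agg <- dt[, .(n_event = sum(event), n_censor = sum(!event)), keyby = time]
  ntot <- nrow(dt)
  agg[, n_risk := ntot - c(0, cumsum(n_event + n_censor)[-.N])]
  agg[, surv := cumprod(1 - n_event / n_risk)]
  if (!is.null(horizon)) agg <- agg[time <= horizon]
  structure(list(time = agg$time, n_risk = agg$n_risk,
                 n_event = agg$n_event, n_censor = agg$n_censor,
                 surv = agg$surv),
            class = "bc_km")
}

#' @rdname km_estimate
#' @param km `bc_km` object.
#' @param t times at which to read the survival probability.
#' @export
km_surv_at <- function(km, t) {
  c(1, km$surv)[findInterval(t, km$time) + 1L]
}

#' Life-years of an event history
#'
#' @param histories event histories.
#' @param horizon optional finite horizon truncating survival time
#'   (default lifetime).
#' @return numeric vector of life-years per patient.
#' @export
life_years <- function(histories, horizon = Inf) {
  pmin(histories$death_time, horizon)
}

# Piecewise-constant utility segments for a set of histories: one row per
# (patient, segment) with start, end, and the multiplicative utility level.
utility_segments <- function(histories, schedule) {
  H <- as.data.table(histories)
  n <- nrow(H)
  chemo_dur <- schedule$durations$chemotherapy
  tox_dur <- schedule$durations$toxicity
  rec_end <- if (schedule$recurrence_until_death) H$death_time else
    pmin(H$t_dr + schedule$durations$distant_recurrence, H$death_time)
  bks <- schedule$age_band_utility$breaks
  cand <- cbind(0, H$death_time,
                ifelse(H$arm == "chemo_endocrine", chemo_dur, NA_real_),
                ifelse(H$toxicity, tox_dur, NA_real_),
                H$t_dr, rec_end,
                outer(-H$age_dx, bks, `+`))
  dt <- data.table(row = rep(seq_len(n), ncol(cand)), t = as.vector(cand))
  dt <- dt[!is.na(t)]
  dt <- dt[t >= 0 & t <= H$death_time[row]]
  setorder(dt, row, t)
  dt <- unique(dt)
  dt[, end := shift(t, -1L), by = row]
  seg <- dt[!is.na(end) & end > t]
  setnames(seg, "t", "start")
  mid <- (seg$start + seg$end) / 2
  r <- seg$row
  u <- age_band_utility_at(schedule, H$age_dx[r] + mid) *
    schedule$state_utilities$invasive_breast_cancer
  u <- u * ifelse(H$arm[r] == "chemo_endocrine" & mid < chemo_dur,
                  schedule$state_utilities$chemotherapy, 1)
  u <- u * ifelse(H$toxicity[r] & mid < tox_dur,
                  schedule$state_utilities$toxicity, 1)
  in_rec <- !is.na(H$t_dr[r]) & mid >= H$t_dr[r] & mid < rec_end[r]
  u <- u * ifelse(in_rec, schedule$state_utilities$distant_recurrence, 1)
  seg[, utility := u]
  seg[]
}

#' Utility path of a single event history
#'
#' The piecewise-constant utility function of time since diagnosis implied
#' by a schedule: at each instant the age-band utility (at current age), the
#' breast-cancer state utility, the chemotherapy and toxicity disutilities in
#' their first-6-month windows, and the distant-recurrence utility are
#' combined multiplicatively. Defined on `[0, death_time]`.
#'
#' @param history one-row event history.
#' @param schedule `bc_utility_schedule`.
#' @return `bc_utility_path`: data.table of `start`, `end`, `utility`
#'   segments; evaluate with [utility_path_at()].
#' @export
utility_path <- function(history, schedule) {
  stopifnot(nrow(history) == 1L)
  seg <- utility_segments(history, schedule)[, .(start, end, utility)]
  structure(seg, class = c("bc_utility_path", class(seg)))
}

#' @rdname utility_path
#' @param path `bc_utility_path`.
#' @param t times since diagnosis.
#' @export
utility_path_at <- function(path, t) {
  i <- findInterval(t, c(path$start, path$end[nrow(path)]),
                    rightmost.closed = TRUE)
  out <- rep(NA_real_, length(t))
  ok <- i >= 1 & i <= nrow(path)
  out[ok] <- path$utility[i[ok]]
  out
}

#' Quality-adjusted life-years
#'
#' Integrates the utility path against the annual-compounding discount
#' weight `(1 + rate)^(-t)`; rate 0 reproduces undiscounted QALYs. The
#' result never exceeds (discounted) life-years because utilities are <= 1.
#'
#' @param histories event histories (any number of rows).
#' @param schedule `bc_utility_schedule`.
#' @param discount_rate annual discount rate >= 0 (default 0.03).
#' @param method `"analytic"` (closed-form integration of the multiplicative
#'   path, the default) or `"segments"` (explicit piecewise enumeration via
#'   [utility_segments()]); the two agree to numerical precision and the
#'   test suite checks them against each other.
#' @param segments optional precomputed [utility_segments()] (implies
#'   `method = "segments"`), so several discount rates reuse one
#'   construction.
#' @return numeric QALYs per patient, in input row order.
#' @export
qaly <- function(histories, schedule, discount_rate = 0.03,
                 method = c("analytic", "segments"), segments = NULL) {
  stopifnot(discount_rate >= 0)
  method <- if (!is.null(segments)) "segments" else match.arg(method)
  if (method == "analytic") return(qaly_analytic(histories, schedule,
                                                 discount_rate))
  seg <- if (is.null(segments)) utility_segments(histories, schedule)
         else segments
  q <- if (discount_rate == 0) {
    seg$utility * (seg$end - seg$start)
  } else {
    lr <- log1p(discount_rate)
    seg$utility * (exp(-lr * seg$start) - exp(-lr * seg$end)) / lr
  }
  out <- numeric(nrow(histories))
  agg <- rowsum(q, seg$row)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Closed-form QALY: the age-band utility is piecewise constant in age, the
# discount weight is exponential in time, and the chemo/toxicity and
# recurrence disutilities are multiplicative factors on known windows, so
# the integral expands by inclusion-exclusion into age-band x discount
# primitives. Exact for the multiplicative combination rule.
qaly_analytic <- function(histories, schedule, discount_rate) {
  H <- as.data.table(histories)
  n <- nrow(H)
  lr <- log1p(discount_rate)
  disc_int <- function(x, y) {          # integral of (1+r)^(-t) over [x, y]
    y <- pmax(x, y)
    if (discount_rate == 0) y - x else (exp(-lr * x) - exp(-lr * y)) / lr
  }
  bks <- schedule$age_band_utility$breaks
  vals <- schedule$age_band_utility$values
  edges <- c(-Inf, bks[-1], Inf)        # constant extension outside the table
  ev <- c(vals, vals[length(vals)])
  age_int <- function(a, b) {           # integral of u_age(age_dx+t) disc(t)
    tot <- numeric(n)
    for (j in seq_along(ev)) {
      lo <- pmax(a, edges[j] - H$age_dx)
      hi <- pmin(b, edges[j + 1L] - H$age_dx)
      tot <- tot + ev[j] * disc_int(lo, pmax(lo, hi))
    }
    tot
  }
  su <- schedule$state_utilities
  fc <- ifelse(H$arm == "chemo_endocrine", su$chemotherapy, 1)
  ft <- ifelse(H$toxicity, su$toxicity, 1)
  wc <- pmin(schedule$durations$chemotherapy, H$death_time)
  wt <- pmin(schedule$durations$toxicity, H$death_time)
  rec <- !is.na(H$t_dr)
  ru <- ifelse(rec, su$distant_recurrence, 1)
  r_a <- ifelse(rec, H$t_dr, 0)
  r_b <- if (schedule$recurrence_until_death) ifelse(rec, H$death_time, 0)
         else ifelse(rec, pmin(H$t_dr + schedule$durations$distant_recurrence,
                               H$death_time), 0)
  zero <- rep(0, n)
  q <- age_int(zero, H$death_time) +
    (fc - 1) * age_int(zero, wc) +
    (ft - 1) * age_int(zero, wt) +
    (fc - 1) * (ft - 1) * age_int(zero, pmin(wc, wt)) +
    (ru - 1) * age_int(r_a, r_b) +
    (fc - 1) * (ru - 1) * age_int(pmin(r_a, wc), pmin(r_b, wc)) +
    (ft - 1) * (ru - 1) * age_int(pmin(r_a, wt), pmin(r_b, wt)) +
    (fc - 1) * (ft - 1) * (ru - 1) *
      age_int(pmin(r_a, wc, wt), pmin(r_b, wc, wt))
  q * su$invasive_breast_cancer
}

#' Summarize outcomes per arm and stratum
#'
#' Computes the per-arm Kaplan-Meier DRFS at 5 and 10 years (percent),
#' breast-cancer-specific survival at 5 and 10 years, mean lifetime
#' life-years, and mean undiscounted and discounted QALYs, for the overall
#' population and each level of the requested strata, plus an
#' `incremental` row per stratum (chemo-endocrine minus endocrine).
#'
#' @param histories event histories containing both arms.
#' @param schedule `bc_utility_schedule`.
#' @param discount_rates vector of annual discount rates (default 0.03).
#' @param strata stratification columns of `histories`
#'   (default menopausal status and race/ethnicity).
#' @return `data.table`, one row per (stratum level, arm) and per stratum an
#'   `arm = "incremental"` row.
#' @export
summarize_outcomes <- function(histories, schedule, discount_rates = 0.03,
                               strata = c("menopausal", "race_eth")) {
  H <- as.data.table(histories)
  drfs <- drfs_indicator(H)
  bcfs <- bcfs_indicator(H)
  ly <- life_years(H)
  seg <- utility_segments(H, schedule)
  qu <- qaly(H, schedule, 0, segments = seg)
  qd <- lapply(discount_rates, function(r) qaly(H, schedule, r, segments = seg))
  dnames <- sprintf("qaly_disc_%g", 100 * discount_rates)

  groups <- list(list(stratum = "overall", level = "overall",
                      sel = rep(TRUE, nrow(H))))
  for (s in strata) for (lev in sort(unique(H[[s]])))
    groups[[length(groups) + 1L]] <-
      list(stratum = s, level = lev, sel = H[[s]] == lev)

  one_arm <- function(sel, arm) {
    i <- which(sel & H$arm == arm)
    if (!length(i))
      stop("summarize_outcomes: stratum has no patients in arm ", arm,
           call. = FALSE)
    km_d <- km_estimate(drfs$time[i], drfs$event[i])
    km_b <- km_estimate(bcfs$time[i], bcfs$event[i])
    row <- data.table(arm = arm, n = length(i),
                      drfs_5y = 100 * km_surv_at(km_d, 5),
                      drfs_10y = 100 * km_surv_at(km_d, 10),
                      bcfs_5y = 100 * km_surv_at(km_b, 5),
                      bcfs_10y = 100 * km_surv_at(km_b, 10),
                      life_years = mean(ly[i]),
                      qaly_undisc = mean(qu[i]))
    for (j in seq_along(dnames)) row[[dnames[j]]] <- mean(qd[[j]][i])
    row
  }

  rbindlist(lapply(groups, function(g) {
    present <- unique(H$arm[g$sel])
    if (!all(c("endocrine", "chemo_endocrine") %in% present))
      stop("summarize_outcomes: stratum ", g$stratum, "=", g$level,
           " lacks arm(s) ",
           paste(setdiff(c("endocrine", "chemo_endocrine"), present),
                 collapse = ", "), call. = FALSE)
    e <- one_arm(g$sel, "endocrine")
    ch <- one_arm(g$sel, "chemo_endocrine")
    inc <- copy(ch)
    num <- setdiff(names(inc), c("arm", "n"))
    for (col in num) inc[[col]] <- ch[[col]] - e[[col]]
    inc$arm <- "incremental"
    inc$n <- e$n + ch$n
    cbind(data.table(stratum = g$stratum, level = g$level),
          rbindlist(list(e, ch, inc)))
  }))
}

#' Export Kaplan-Meier DRFS curves
#'
#' @param histories event histories.
#' @param by stratification column (default menopausal status).
#' @param horizon truncation for the exported grid (default 10 years).
#' @return `data.table` of (stratum, arm, time, surv, n_risk) suitable for
#'   CSV export and plotting.
#' @export
export_km_curves <- function(histories, by = "menopausal", horizon = 10) {
  H <- as.data.table(histories)
  ind <- drfs_indicator(H)
  out <- list()
  for (lev in c("overall", sort(unique(H[[by]])))) {
    sel <- if (lev == "overall") rep(TRUE, nrow(H)) else H[[by]] == lev
    for (arm in unique(H$arm)) {
      i <- which(sel & H$arm == arm)
      km <- km_estimate(ind$time[i], ind$event[i], horizon = horizon)
      out[[length(out) + 1L]] <- data.table(
        stratum = lev, arm = arm, time = km$time, surv = km$surv,
        n_risk = km$n_risk)
    }
  }
  rbindlist(out)
}
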