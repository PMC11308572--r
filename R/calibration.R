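#' Calibration targets
#'
#' A target is a summary statistic the simulator should reproduce: a
#' Kaplan-Meier DRFS rate, a mean life-year or QALY value, for a given
#' stratum and arm (or the `incremental` chemo-endocrine minus endocrine
#' difference), with a tolerance and a weight.
#'
#' @param statistic one of `drfs_5y`, `drfs_10y`, `life_years`,
#'   `qaly_undisc`, or `qaly_disc_<pct>` (e.g. `qaly_disc_3`).
#' @param stratum `"overall"` or `"<column>=<level>"`, e.g.
#'   `"menopausal=pre"`.
#' @param arm `"endocrine"`, `"chemo_endocrine"`, or `"incremental"`.
#' @param target numeric target value (percent for DRFS statistics).
#' @param tolerance acceptance half-width (> 0).
#' @param weight relative weight in the calibration objective.
#' @return `data.table` of class `bc_calibration_targets`.
#' @export
calibration_targets <- function(statistic, stratum, arm, target, tolerance,
                                weight = 1) {
  t <- data.table(statistic = statistic, stratum = stratum, arm = arm,
                  target = as.numeric(target),
                  tolerance = as.numeric(tolerance),
                  weight = as.numeric(weight))
  if (any(t$tolerance <= 0))
    stop("calibration targets: tolerance must be > 0", call. = FALSE)
  dup <- t[, .N, by = .(statistic, stratum, arm)][N > 1L]
  if (nrow(dup)) {
    key <- paste(dup$statistic, dup$stratum, dup$arm, sep = "/")
    conf <- t[paste(statistic, stratum, arm, sep = "/") %in% key]
    if (uniqueN(conf[, .(statistic, stratum, arm, target)]) > uniqueN(dup))
      stop("calibration targets: conflicting duplicate targets for ",
           paste(key, collapse = "; "), call. = FALSE)
  }
  structure(t, class = c("bc_calibration_targets", class(t)))
}

#' @rdname calibration_targets
#' @param path JSON file with an array of target objects.
#' @export
load_calibration_targets <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_targets(x$statistic, x$stratum, x$arm, x$target, x$tolerance,
                      if (is.null(x$weight)) 1 else x$weight)
}

# Evaluate the targeted statistics on a set of histories. Returns the
# targets table with a `value` column appended.
eval_targets <- function(histories, schedule, targets) {
  H <- as.data.table(histories)
  drfs <- drfs_indicator(H)
  need_q <- any(grepl("^qaly", targets$statistic))
  rates <- unique(as.numeric(sub("qaly_disc_", "",
    targets$statistic[grepl("^qaly_disc", targets$statistic)]))) / 100
  seg <- if (need_q) utility_segments(H, schedule)
  qu <- if (any(targets$statistic == "qaly_undisc"))
    qaly(H, schedule, 0, segments = seg)
  qd <- lapply(rates, function(r) qaly(H, schedule, r, segments = seg))
  names(qd) <- sprintf("qaly_disc_%g", 100 * rates)
  ly <- life_years(H)

  sel_stratum <- function(stratum) {
    if (stratum == "overall") return(rep(TRUE, nrow(H)))
    kv <- strsplit(stratum, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L || is.null(H[[kv[1]]]))
      stop("unknown stratum spec: ", stratum, call. = FALSE)
    H[[kv[1]]] == kv[2]
  }
  cache <- new.env(parent = emptyenv())
  stat_one <- function(statistic, stratum, arm) {
    key <- paste(statistic, stratum, arm, sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (arm == "incremental") {
      stat_one(statistic, stratum, "chemo_endocrine") -
        stat_one(statistic, stratum, "endocrine")
    } else {
      i <- which(sel_stratum(stratum) & H$arm == arm)
      if (!length(i)) stop("no patients in ", stratum, " arm ", arm,
                           call. = FALSE)
      switch(sub("_[0-9.]+y$", "", sub("qaly_disc_.*", "qaly_disc", statistic)),
        drfs = {
          km <- km_estimate(drfs$time[i], drfs$event[i])
          tpt <- as.numeric(sub("y$", "", sub("drfs_", "", statistic)))
          100 * km_surv_at(km, tpt)
        },
        life_years = mean(ly[i]),
        qaly_undisc = mean(qu[i]),
        qaly_disc = mean(qd[[statistic]][i]),
        stop("unknown statistic: ", statistic, call. = FALSE))
    }
    cache[[key]] <- val
    val
  }
  out <- as.data.table(targets)
  out[, value := mapply(stat_one, statistic, stratum, arm)]
  out[]
}

# One common-random-number simulation pass used by calibrate()/verify():
# identical (pop_params, sim_n, seed) reuse identical populations, arms and
# event uniforms across candidate hazard models. With `twins = TRUE` every
# patient is simulated under BOTH arms with the same uniforms (paired
# counterfactuals), which collapses the Monte-Carlo noise of incremental
# targets; production analyses instead randomize each patient to one arm.
crn_simulate <- function(model, pop_params, lifetable, sim_n, seed,
                         toxicity_prob = 0.175, twins = FALSE) {
  profiles <- sample_population(pop_params, sim_n, seed)
  if (twins) {
    both <- rbind(profiles, profiles)
    arms <- rep(c("endocrine", "chemo_endocrine"), each = nrow(profiles))
    simulate_cohort(both, arms, model, effects = NULL, lifetable,
                    toxicity_prob = toxicity_prob, seed = seed)
  } else {
    arms <- randomize(profiles, seed = seed, force_balance = TRUE)
    simulate_cohort(profiles, arms, model, effects = NULL, lifetable,
                    toxicity_prob = toxicity_prob, seed = seed)
  }
}

# get/set a free parameter (a numeric vector inside the model list) by path
param_get <- function(model, path, idx = NULL) {
  v <- model[[path]]
  if (is.null(idx)) v else v[idx]
}
param_set <- function(model, path, idx = NULL, value) {
  if (is.null(idx)) model[[path]] <- value else model[[path]][idx] <- value
  model
}
# move a free parameter by `delta`: multiplicative on the log scale for
# positive quantities (mode "log", the default), additive for location
# parameters such as lognormal meanlog (mode "shift")
param_move <- function(model, p, delta) {
  cur <- param_get(model, p$path, p$idx)
  new <- if (identical(p$mode, "shift")) cur + delta else cur * exp(delta)
  param_set(model, p$path, p$idx, new)
}

#' Default free-parameter set for calibration
#'
#' Stratum-level multiplicative scale factors: per-menopause baseline
#' hazards split into an early (trial follow-up) and late block, the two
#' menopause-specific chemotherapy effects (the postmenopausal one with a
#' separate late block), and the post-recurrence survival location per
#' stratum.
#'
#' @param model `bc_hazard_model` (for the number of baseline periods).
#' @return list of free-parameter descriptors (`name`, `path`, `idx`).
#' @export
default_free_parameters <- function(model) {
  np <- length(model$breaks) - 1L
  early <- which(model$breaks[-1] <= 10)
  late <- setdiff(seq_len(np), early)
  list(
    list(name = "base_pre_early", path = c("baseline_dr_hazard", "pre"), idx = early),
    list(name = "base_pre_late",  path = c("baseline_dr_hazard", "pre"), idx = late),
    list(name = "base_post_early", path = c("baseline_dr_hazard", "post"), idx = early),
    list(name = "base_post_late",  path = c("baseline_dr_hazard", "post"), idx = late),
    list(name = "chemo_pre",  path = c("chemo_effect", "pre"), idx = NULL),
    list(name = "chemo_post_early", path = c("chemo_effect", "post"), idx = early),
    list(name = "chemo_post_late",  path = c("chemo_effect", "post"), idx = late)
  )
}

#' Calibrate hazard parameters to aggregate targets
#'
#' Coordinate descent over log-scale multiplicative factors with
#' common-random-number simulation: each objective evaluation re-simulates
#' the same virtual population (same seed, hence identical covariates, arm
#' assignments and event-time uniforms) under the candidate hazard model and
#' scores the weighted squared deviations `((value - target)/tolerance)^2`.
#' Deterministic given `(model0, targets, sim_n, seed)`.
#'
#' Identifiability is the caller's responsibility: free parameters are
#' stratum-level scale factors, so the target set must pin each scaled block
#' (e.g. a 5- and a 10-year DRFS per menopausal stratum and arm);
#' directly conflicting duplicate targets are rejected by
#' [calibration_targets()].
#'
#' @param model0 starting `bc_hazard_model`.
#' @param targets `bc_calibration_targets`.
#' @param sim_n cohort size per objective evaluation.
#' @param seed master seed (also the CRN seed).
#' @param pop_params,lifetable,schedule simulation inputs.
#' @param free free-parameter descriptors
#'   (default [default_free_parameters()]).
#' @param control list: `max_sweeps` (default 6), `init_step` (log-scale,
#'   default 0.25), `min_step` (default 0.02), `toxicity_prob`.
#' @return calibrated `bc_hazard_model` whose `generated_by` block records
#'   targets, seed, sim_n, achieved objective, and date; the empirical-Bayes
#'   prior location is reset to the calibrated chemotherapy effects.
#' @export
calibrate <- function(model0, targets, sim_n, seed, pop_params, lifetable,
                      schedule, free = default_free_parameters(model0),
                      control = list()) {
  ctl <- utils::modifyList(list(max_sweeps = 6L, init_step = 0.25,
                                min_step = 0.02, toxicity_prob = 0.175,
                                twins = TRUE, verbose = FALSE), control)
  objective <- function(model) {
    hist <- crn_simulate(model, pop_params, lifetable, sim_n, seed,
                         ctl$toxicity_prob, twins = ctl$twins)
    ev <- eval_targets(hist, schedule, targets)
    sum(ev$weight * ((ev$value - ev$target) / ev$tolerance)^2)
  }
  model <- model0
  f_cur <- objective(model)
  step <- ctl$init_step
  for (sweep in seq_len(ctl$max_sweeps)) {
    moved <- FALSE
    for (p in free) {
      for (dir in c(1, -1)) {
        repeat {
          cand <- param_move(model, p, dir * step)
          f_new <- objective(cand)
          if (f_new < f_cur - 1e-12) {
            model <- cand; f_cur <- f_new; moved <- TRUE
            if (isTRUE(ctl$verbose))
              message(sprintf("sweep %d %s dir %+d -> %.4f", sweep, p$name,
                              dir, f_cur))
          } else break
        }
      }
    }
    if (!moved) {
      step <- step / 2
      if (step < ctl$min_step) break
    }
  }
  # keep the empirical-Bayes prior centred on the calibrated effects
  np <- length(model$breaks) - 1L
  for (s in MENO_LEVELS)
    model$chemo_effect_prior[[s]]$location <-
      log(chemo_effect_periods(model$chemo_effect[[s]], np))
  model$generated_by <- list(
    method = "coordinate descent on log scale factors, common random numbers",
    sim_n = sim_n, seed = seed, objective = f_cur,
    date = format(Sys.Date()),
    targets = as.data.frame(targets))
  model
}

#' Verify a hazard model against targets
#'
#' Simulates with a seed independent of calibration and reports, per target,
#' the achieved value, a Monte-Carlo standard error (Greenwood for
#' Kaplan-Meier statistics, `sd/sqrt(n)` for means, combined in quadrature
#' for incrementals), and pass/fail at the stated tolerance. A
#' zero-tolerance target always fails under stochastic simulation (by
#' design: [calibration_targets()] rejects it, but a hand-built targets
#' table with `tolerance = 0` fails here rather than erroring).
#'
#' @inheritParams calibrate
#' @param model `bc_hazard_model` to verify.
#' @return `data.table`: targets plus `value`, `mc_se`, `pass`.
#' @export
verify <- function(model, targets, sim_n, seed, pop_params, lifetable,
                   schedule, toxicity_prob = 0.175) {
  hist <- crn_simulate(model, pop_params, lifetable, sim_n, seed,
                       toxicity_prob)
  ev <- eval_targets(hist, schedule, targets)
  ev[, mc_se := mapply(function(statistic, stratum, arm)
    target_mc_se(hist, schedule, statistic, stratum, arm),
    statistic, stratum, arm)]
  ev[, pass := abs(value - target) <= tolerance & tolerance > 0]
  ev[]
}

target_mc_se <- function(H, schedule, statistic, stratum, arm) {
  H <- as.data.table(H)
  sel <- if (stratum == "overall") rep(TRUE, nrow(H)) else {
    kv <- strsplit(stratum, "=", fixed = TRUE)[[1]]
    H[[kv[1]]] == kv[2]
  }
  one <- function(a) {
    i <- which(sel & H$arm == a)
    if (grepl("^drfs", statistic)) {
      ind <- drfs_indicator(H[i])
      km <- km_estimate(ind$time, ind$event)
      tpt <- as.numeric(sub("y$", "", sub("drfs_", "", statistic)))
      100 * km_greenwood_se(km, tpt)
    } else {
      x <- if (statistic == "life_years") life_years(H[i])
      else if (statistic == "qaly_undisc") qaly(H[i], schedule, 0)
      else qaly(H[i], schedule,
                as.numeric(sub("qaly_disc_", "", statistic)) / 100)
      sd(x) / sqrt(length(x))
    }
  }
  if (arm == "incremental")
    sqrt(one("endocrine")^2 + one("chemo_endocrine")^2)
  else one(arm)
}

# Greenwood standard error of the KM estimate at time t
km_greenwood_se <- function(km, t) {
  keep <- km$time <= t & km$n_event > 0
  v <- sum(km$n_event[keep] /
             (km$n_risk[keep] * (km$n_risk[keep] - km$n_event[keep])))
  km_surv_at(km, t) * sqrt(v)
}

#' Expected distant-recurrence-free survival mixture
#'
#' Deterministic companion to the simulator used as a brute-force oracle and
#' by offline calibration: enumerates the analytic covariate-cell table of
#' the population ([population_cell_table()]) and returns the
#' population-mixture net survival `sum_x p(x) exp(-H(t) m(x))` for a
#' stratum and arm. Ignores the (small) Kaplan-Meier frailty-censoring
#' interaction, which simulation-based [verify()] picks up.
#'
#' @param model `bc_hazard_model`.
#' @param pop_params `bc_population_params`.
#' @param times evaluation times (years).
#' @param arm `"endocrine"` or `"chemo_endocrine"`.
#' @param menopausal optional `"pre"`/`"post"` restriction.
#' @param race_eth optional race restriction.
#' @return numeric survival probabilities at `times`.
#' @export
expected_drfs <- function(model, pop_params, times, arm = "endocrine",
                          menopausal = NULL, race_eth = NULL) {
  bands <- paste0(model$rs_bands, "-",
                  c(model$rs_bands[-1] - 1L, RS_MAX))
  cells <- population_cell_table(pop_params, rs_bands = model$rs_bands)
  if (!is.null(race_eth)) {
    keep <- cells$race_eth %in% race_eth  # resolve before [ to avoid
    cells <- cells[keep]                  # data.table column shadowing
  }
  lp <- model$log_shr$grade[cells$grade] +
    model$log_shr$size_class[cells$size_class] +
    model$log_shr$hormone_sensitivity[cells$hormone_sensitivity] +
    model$log_shr$rs_band[cells$rs_band] +
    model$log_shr$race_eth[cells$race_eth]
  m <- exp(unname(lp))
  np <- length(model$breaks) - 1L
  out <- numeric(length(times))
  for (s in MENO_LEVELS) {
    if (!is.null(menopausal) && s != menopausal) next
    w <- cells$prob * (if (s == "pre") cells$p_pre else 1 - cells$p_pre)
    rates <- model$baseline_dr_hazard[[s]]
    if (arm == "chemo_endocrine")
      rates <- rates * chemo_effect_periods(model$chemo_effect[[s]], np)
    h <- piecewise_hazard(model$breaks, rates)
    Ht <- cumulative_hazard(h, times)
    out <- out + vapply(Ht, function(H) sum(w * exp(-H * m)), numeric(1))
  }
  denom <- if (is.null(menopausal)) {
    wsel <- cells$prob
    sum(wsel)
  } else {
    sum(cells$prob * (if (menopausal == "pre") cells$p_pre else 1 - cells$p_pre))
  }
  out / denom
}
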