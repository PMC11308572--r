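#' Competing-risk hazard model
#'
#' Holds the piecewise-constant baseline distant-recurrence hazards per
#' menopausal stratum, log sub-hazard ratios for patient covariates, the
#' menopause-specific chemotherapy effect (a hazard ratio per baseline period,
#' so the effect may differ beyond trial follow-up), an empirical-Bayes prior
#' for the chemotherapy effects, and the post-recurrence survival
#' distribution (lognormal time from distant recurrence to breast cancer
#' death).
#'
#' @param breaks increasing numeric vector starting at 0; the piecewise
#'   intervals `[breaks[i], breaks[i+1])` partition `[0, max(breaks))`.
#' @param baseline_dr_hazard named list `pre`/`post`, each a non-negative
#'   hazard (events per person-year) per interval.
#' @param log_shr named list of named numeric vectors: log sub-hazard ratio
#'   per level of `grade`, `size_class`, `hormone_sensitivity`, `rs_band`,
#'   `race_eth`.
#' @param rs_bands lower bounds of the recurrence-score bands in `log_shr`.
#' @param chemo_effect named list `pre`/`post`: hazard ratio applied to the
#'   chemo-endocrine arm, scalar or one value per interval.
#' @param chemo_effect_prior named list `pre`/`post` of `location` (log
#'   hazard ratio, scalar or per interval) and `scale` (log-scale SD >= 0 of
#'   a single stratum-level draw shifting all intervals jointly).
#' @param post_recurrence_survival named list `pre`/`post` of `meanlog`,
#'   `sdlog` for the lognormal years from recurrence to breast cancer death.
#' @param generated_by optional provenance block (calibration targets, seed,
#'   date); carried verbatim so calibrated values are never mistaken for
#'   externally reported inputs.
#' @return object of class `bc_hazard_model`.
#' @export
hazard_model <- function(breaks, baseline_dr_hazard, log_shr,
                         chemo_effect, chemo_effect_prior,
                         post_recurrence_survival,
                         rs_bands = c(0, 11, 16, 21),
                         generated_by = NULL) {
  m <- structure(list(
    breaks = as.numeric(breaks),
    baseline_dr_hazard = baseline_dr_hazard,
    log_shr = log_shr,
    rs_bands = as.integer(rs_bands),
    chemo_effect = chemo_effect,
    chemo_effect_prior = chemo_effect_prior,
    post_recurrence_survival = post_recurrence_survival,
    generated_by = generated_by
  ), class = "bc_hazard_model")
  validate_hazard_model(m)
  m
}

#' @rdname hazard_model
#' @param model object to validate.
#' @export
validate_hazard_model <- function(model) {
  b <- model$breaks
  if (b[1] != 0 || any(diff(b) <= 0))
    stop("hazard model: breaks must start at 0 and be strictly increasing ",
         "(intervals may not overlap or leave gaps)", call. = FALSE)
  np <- length(b) - 1L
  for (s in MENO_LEVELS) {
    h <- model$baseline_dr_hazard[[s]]
    if (length(h) != np || any(h < 0))
      stop("hazard model: baseline_dr_hazard$", s,
           " needs ", np, " non-negative rates", call. = FALSE)
    ce <- chemo_effect_periods(model$chemo_effect[[s]], np)
    if (any(ce <= 0))
      stop("hazard model: chemo_effect$", s, " must be > 0", call. = FALSE)
    pr <- model$chemo_effect_prior[[s]]
    if (is.null(pr$scale) || pr$scale < 0)
      stop("hazard model: chemo_effect_prior$", s, "$scale must be >= 0",
           call. = FALSE)
    ps <- model$post_recurrence_survival[[s]]
    if (is.null(ps$meanlog) || is.null(ps$sdlog) || ps$sdlog < 0)
      stop("hazard model: post_recurrence_survival$", s, call. = FALSE)
  }
  for (cov in c("grade", "size_class", "hormone_sensitivity", "rs_band",
                "race_eth"))
    if (is.null(model$log_shr[[cov]]))
      stop("hazard model: log_shr$", cov, " missing", call. = FALSE)
  invisible(TRUE)
}

chemo_effect_periods <- function(x, np) {
  x <- as.numeric(unlist(x))
  if (length(x) == 1L) rep(x, np) else {
    stopifnot(length(x) == np)
    x
  }
}

rs_band_of <- function(rs, rs_bands = c(0, 11, 16, 21)) {
  bands <- c(rs_bands, RS_MAX + 1L)
  labs <- paste0(bands[-length(bands)], "-", bands[-1] - 1L)
  labs[findInterval(rs, rs_bands)]
}

#' Covariate sub-hazard multiplier for patient profiles
#'
#' `exp` of the summed log sub-hazard ratios of each profile's covariate
#' levels. A covariate level absent from the model's `log_shr` map is a
#' configuration error.
#'
#' @param profiles profile data (rows from [sample_population()]).
#' @param model `bc_hazard_model`.
#' @return numeric multiplier per profile (> 0).
#' @export
profile_multiplier <- function(profiles, model) {
  lookup <- function(cov, lev) {
    v <- model$log_shr[[cov]][lev]
    if (anyNA(v))
      stop("configuration error: level(s) ",
           paste(unique(lev[is.na(v)]), collapse = ", "),
           " missing from log_shr$", cov, call. = FALSE)
    unname(v)
  }
  lp <- lookup("grade", profiles$grade) +
    lookup("size_class", profiles$size_class) +
    lookup("hormone_sensitivity", profiles$hormone_sensitivity) +
    lookup("rs_band", rs_band_of(profiles$rs, model$rs_bands)) +
    lookup("race_eth", profiles$race_eth)
  exp(lp)
}

#' Draw realized chemotherapy treatment effects
#'
#' One lognormal draw per menopausal stratum from the configured empirical
#' Bayes prior: all baseline periods of a stratum are shifted by the same
#' draw, so a zero prior scale returns the prior location exactly.
#'
#' @param model `bc_hazard_model`.
#' @param seed integer seed.
#' @return named list `pre`/`post` of hazard-ratio vectors (one per baseline
#'   period).
#' @export
draw_treatment_effects <- function(model, seed) {
  np <- length(model$breaks) - 1L
  z <- with_preserved_rng({
    set.seed(substream_seed(seed, "treatment_effects"))
    stats::rnorm(length(MENO_LEVELS))
  })
  out <- lapply(seq_along(MENO_LEVELS), function(i) {
    pr <- model$chemo_effect_prior[[MENO_LEVELS[i]]]
    loc <- chemo_effect_periods(exp(unlist(pr$location)), np)
    loc * exp(pr$scale * z[i])
  })
  names(out) <- MENO_LEVELS
  out
}

#' Distant-recurrence hazard for one patient profile and arm
#'
#' Baseline piecewise hazard of the profile's menopausal stratum times the
#' covariate sub-hazard multiplier, times the realized chemotherapy effect in
#' the chemo-endocrine arm.
#'
#' @param profile single patient profile (one-row data.frame or list).
#' @param arm `"endocrine"` or `"chemo_endocrine"`.
#' @param model `bc_hazard_model`.
#' @param effects realized treatment effects from [draw_treatment_effects()];
#'   `NULL` uses the model's configured `chemo_effect`.
#' @return object of class `bc_piecewise_hazard`: list of `breaks` and
#'   `rates`, evaluable with [hazard_rate_at()].
#' @export
dr_hazard <- function(profile, arm = c("endocrine", "chemo_endocrine"),
                      model, effects = NULL) {
  arm <- match.arg(arm)
  np <- length(model$breaks) - 1L
  meno <- profile$menopausal
  base <- model$baseline_dr_hazard[[meno]]
  m <- profile_multiplier(profile, model)
  ce <- if (arm == "chemo_endocrine") {
    if (is.null(effects)) chemo_effect_periods(model$chemo_effect[[meno]], np)
    else chemo_effect_periods(effects[[meno]], np)
  } else rep(1, np)
  piecewise_hazard(model$breaks, base * m * ce)
}

#' Piecewise-constant hazard
#'
#' @param breaks increasing break points starting at 0.
#' @param rates non-negative rate per interval.
#' @return `bc_piecewise_hazard` object.
#' @export
piecewise_hazard <- function(breaks, rates) {
  stopifnot(breaks[1] == 0, all(diff(breaks) > 0),
            length(rates) == length(breaks) - 1L, all(rates >= 0))
  structure(list(breaks = as.numeric(breaks), rates = as.numeric(rates)),
            class = "bc_piecewise_hazard")
}

#' @rdname piecewise_hazard
#' @param h `bc_piecewise_hazard`.
#' @param t times (within `[0, max(breaks))`).
#' @export
hazard_rate_at <- function(h, t) {
  h$rates[pmin(findInterval(t, h$breaks), length(h$rates))]
}

#' Cumulative hazard of a piecewise-constant hazard
#'
#' @inheritParams hazard_rate_at
#' @return cumulative hazard at `t` (`t` beyond the last break extrapolates
#'   with the final rate equal to zero, i.e. the hazard is defined on the
#'   break span only).
#' @export
cumulative_hazard <- function(h, t) {
  widths <- diff(h$breaks)
  cum <- c(0, cumsum(widths * h$rates))
  i <- pmin(findInterval(t, h$breaks), length(h$rates))
  pmin_t <- pmin(t, max(h$breaks))
  cum[i] + (pmin_t - h$breaks[i]) * h$rates[i]
}

#' Inverse-CDF sampling from a piecewise-constant hazard
#'
#' Samples event times by inverting the cumulative hazard: with
#' E ~ Exponential(1), the event time solves H(T) = E, so
#' P(T > t) = exp(-H(t)). A draw whose exponential deviate exceeds the total
#' cumulative hazard over the break span is returned as `Inf`, meaning no
#' event within the modeled horizon.
#'
#' @param hazard `bc_piecewise_hazard`.
#' @param n number of draws (ignored when `u` given).
#' @param u optional uniforms (one per draw) for common-random-number reuse.
#' @param seed optional seed used when `u` is `NULL`.
#' @return numeric event times (possibly `Inf`).
#' @export
sample_time_piecewise <- function(hazard, n = 1L, u = NULL, seed = NULL) {
  if (is.null(u)) {
    u <- if (is.null(seed)) stats::runif(n)
         else substream_uniforms(seed, "piecewise", seq_len(n))
  }
  e <- -log(1 - u)  # Exp(1)
  widths <- diff(hazard$breaks)
  cum <- c(0, cumsum(widths * hazard$rates))
  # rightmost boundary strictly below e; with tied boundaries (zero-rate
  # intervals) findInterval automatically skips to the next positive rate
  idx <- findInterval(e, cum, left.open = TRUE)
  out <- rep(Inf, length(e))
  ii <- which(idx <= length(hazard$rates) & e > 0)
  if (length(ii))
    out[ii] <- hazard$breaks[idx[ii]] +
      (e[ii] - cum[idx[ii]]) / hazard$rates[idx[ii]]
  out[e == 0] <- hazard$breaks[1]
  out
}

#' Read/write a hazard model as JSON
#'
#' @param path file path.
#' @return `bc_hazard_model` for the loader; the path invisibly for the
#'   writer.
#' @export
load_hazard_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hazard_model(
    breaks = x$breaks,
    baseline_dr_hazard = lapply(x$baseline_dr_hazard, as.numeric),
    log_shr = lapply(x$log_shr, unlist),
    rs_bands = x$rs_bands,
    chemo_effect = lapply(x$chemo_effect, as.numeric),
    chemo_effect_prior = x$chemo_effect_prior,
    post_recurrence_survival = x$post_recurrence_survival,
    generated_by = x$generated_by
  )
}

#' @rdname load_hazard_model
#' @param model `bc_hazard_model`.
#' @export
write_hazard_model <- function(model, path) {
  x <- unclass(model)
  x$log_shr <- lapply(x$log_shr, as.list)  # keep level names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
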