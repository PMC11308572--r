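#' @import data.table
#' @importFrom stats plogis qlnorm qnorm quantile runif setNames uniroot median sd
NULL

# Canonical factor levels used throughout the package.
RACE_LEVELS    <- c("nh_black", "hispanic", "nh_white")
GRADE_LEVELS   <- c("low", "intermediate", "high")
HORMONE_LEVELS <- c("er_and_pr_pos", "er_or_pr_pos")
SIZE_LEVELS    <- c("le_2cm", "gt_2cm")
MENO_LEVELS    <- c("pre", "post")
RS_MAX         <- 25L

#' Population parameter set
#'
#' Container for the conditional distribution chain that generates virtual
#' patients: race/ethnicity weights, per-race age distributions (5-year bins,
#' uniform within bin), a logistic menopause model in age, and conditional
#' tables for tumor grade, hormone sensitivity (ER/PR), tumor size, and the
#' 21-gene recurrence score (proportional-odds model on 0--25).
#'
#' @param race_eth_weights named probability vector over
#'   `c("nh_black","hispanic","nh_white")`.
#' @param age_bins list with numeric `lower` and `upper` vectors (years).
#' @param age_dist_by_race named list, per race a probability vector over bins.
#' @param menopause named list: `midpoint` and `scale` per race. The
#'   probability of being postmenopausal at age a is
#'   `plogis((a - midpoint)/scale)`; `scale = 0` gives the step function
#'   1\{a >= midpoint\}. Monotone non-decreasing in age by construction.
#' @param age_band_breaks lower bounds of the coarse diagnosis-age bands used
#'   by the grade/size/recurrence-score conditionals (default 18, 50, 70).
#' @param grade_dist nested list `race -> age band -> probability vector` over
#'   grade levels.
#' @param hormone_dist nested list `race -> grade -> P(ER and PR positive)`.
#' @param size_dist nested list `race -> grade -> age band -> P(size <= 2cm)`.
#' @param rs_model list with `cutpoints` (baseline cumulative logits for
#'   RS <= k, k = 0..24) and `eta`, named lists of covariate shifts on the
#'   latent score (positive eta shifts the score upward).
#' @return object of class `bc_population_params`.
#' @export
population_params <- function(race_eth_weights, age_bins, age_dist_by_race,
                              menopause, grade_dist, hormone_dist, size_dist,
                              rs_model, age_band_breaks = c(18, 50, 70)) {
  p <- structure(list(
    race_eth_weights = race_eth_weights,
    age_bins         = age_bins,
    age_dist_by_race = age_dist_by_race,
    menopause        = menopause,
    age_band_breaks  = age_band_breaks,
    grade_dist       = grade_dist,
    hormone_dist     = hormone_dist,
    size_dist        = size_dist,
    rs_model         = rs_model
  ), class = "bc_population_params")
  validate_population_params(p)
  p
}

#' Validate a population parameter set
#'
#' Checks that every probability vector is non-negative and sums to one within
#' 1e-9, that all required stratum labels are present, and that the menopause
#' model is monotone (non-negative scale). Errors name the offending table.
#'
#' @param params a `bc_population_params` object.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_population_params <- function(params) {
  check_prob_vector <- function(x, what, levels = NULL) {
    if (!is.null(levels)) {
      if (!all(levels %in% names(x)))
        stop("configuration error in ", what, ": missing levels ",
             paste(setdiff(levels, names(x)), collapse = ", "), call. = FALSE)
      x <- unlist(x[levels])
    }
    x <- as.numeric(x)
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9)
      stop("configuration error in ", what,
           ": probabilities must be non-negative and sum to 1 (sum = ",
           format(sum(x), digits = 12), ")", call. = FALSE)
    invisible(TRUE)
  }
  check_prob_vector(params$race_eth_weights, "race_eth_weights", RACE_LEVELS)
  ab <- params$age_bins
  # zero-width bins are allowed: they are the degenerate point-mass case
  stopifnot(length(ab$lower) == length(ab$upper), all(ab$upper >= ab$lower))
  for (r in RACE_LEVELS) {
    check_prob_vector(params$age_dist_by_race[[r]],
                      paste0("age_dist_by_race$", r))
    if (length(params$age_dist_by_race[[r]]) != length(ab$lower))
      stop("configuration error in age_dist_by_race$", r,
           ": length must match age_bins", call. = FALSE)
    if (is.null(params$menopause$midpoint[[r]]) ||
        params$menopause$scale[[r]] < 0)
      stop("configuration error in menopause model for ", r, call. = FALSE)
    for (band in age_band_labels(params))
      check_prob_vector(params$grade_dist[[r]][[band]],
                        paste0("grade_dist$", r, "$", band), GRADE_LEVELS)
    for (g in GRADE_LEVELS) {
      ph <- params$hormone_dist[[r]][[g]]
      if (is.null(ph) || ph < 0 || ph > 1)
        stop("configuration error in hormone_dist$", r, "$", g, call. = FALSE)
      for (band in age_band_labels(params)) {
        ps <- params$size_dist[[r]][[g]][[band]]
        if (is.null(ps) || ps < 0 || ps > 1)
          stop("configuration error in size_dist$", r, "$", g, "$", band,
               call. = FALSE)
      }
    }
  }
  cp <- params$rs_model$cutpoints
  if (length(cp) != RS_MAX || any(diff(cp) <= 0))
    stop("configuration error in rs_model$cutpoints: need ", RS_MAX,
         " strictly increasing cumulative logits", call. = FALSE)
  invisible(TRUE)
}

age_band_labels <- function(params) {
  b <- params$age_band_breaks
  c(paste0(b[-length(b)], "-", c(b[-1] - 1)), paste0(b[length(b)], "+"))
}

age_band_of <- function(params, age) {
  age_band_labels(params)[findInterval(age, params$age_band_breaks)]
}

#' Probability of being postmenopausal at a given age
#'
#' @param params `bc_population_params`.
#' @param age ages in years.
#' @param race_eth race/ethnicity levels (recycled).
#' @return numeric vector of probabilities, non-decreasing in age.
#' @export
menopause_prob <- function(params, age, race_eth) {
  n <- max(length(age), length(race_eth))
  age <- rep_len(age, n)
  race_eth <- rep_len(race_eth, n)
  m <- unname(unlist(params$menopause$midpoint)[race_eth])
  s <- unname(unlist(params$menopause$scale)[race_eth])
  out <- plogis((age - m) / s)
  step <- s == 0
  if (any(step)) out[step] <- as.numeric(age[step] >= m[step])
  out
}

# Cumulative P(RS <= k | eta) for k = 0..24; column 26 is 1.
rs_cumprob <- function(params, eta) {
  cp <- params$rs_model$cutpoints
  out <- matrix(NA_real_, length(eta), RS_MAX + 1L)
  for (k in seq_len(RS_MAX)) out[, k] <- plogis(cp[k] - eta)
  out[, RS_MAX + 1L] <- 1
  out
}

rs_eta <- function(params, race_eth, age_band, grade, hormone, size) {
  e <- params$rs_model$eta
  pick <- function(tab, lev, what) {
    v <- unlist(tab)[lev]
    if (anyNA(v)) stop("configuration error in rs_model$eta$", what, call. = FALSE)
    unname(v)
  }
  pick(e$race_eth, race_eth, "race_eth") +
    pick(e$age_band, age_band, "age_band") +
    pick(e$grade, grade, "grade") +
    pick(e$hormone_sensitivity, hormone, "hormone_sensitivity") +
    pick(e$size_class, size, "size_class")
}

#' Read population parameters from a JSON configuration file
#'
#' @param path path to a JSON file produced by [write_population_params()].
#' @return validated `bc_population_params`.
#' @export
load_population_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  population_params(
    race_eth_weights = unlist(x$race_eth_weights),
    age_bins         = x$age_bins,
    age_dist_by_race = x$age_dist_by_race,
    menopause        = x$menopause,
    age_band_breaks  = x$age_band_breaks,
    grade_dist       = x$grade_dist,
    hormone_dist     = x$hormone_dist,
    size_dist        = x$size_dist,
    rs_model         = x$rs_model
  )
}

#' @rdname load_population_params
#' @param params `bc_population_params` to serialize.
#' @export
write_population_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
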