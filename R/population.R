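#' Sample a virtual patient population
#'
#' Draws `n` patient profiles by walking the conditional distribution chain
#' race -> age -> menopausal status -> tumor grade -> hormone sensitivity ->
#' tumor size -> 21-gene recurrence score. Ages are continuous (uniform within
#' 5-year bins); the recurrence score is an integer 0--25. Identical
#' `(params, n, seed)` give bitwise-identical output, independent of any
#' surrounding RNG state.
#'
#' @param params `bc_population_params` (see [population_params()]).
#' @param n number of patients (>= 1).
#' @param seed master integer seed.
#' @param menopause_mode `"probabilistic"` (Bernoulli from the logistic
#'   menopause model) or `"age50_proxy"` (premenopausal iff age < 50).
#' @return `data.table` with one row per patient: `patient_id`, `age_dx`,
#'   `menopausal`, `race_eth`, `grade`, `hormone_sensitivity`, `size_class`,
#'   `rs`. Attribute `seed` records the seed.
#' @export
sample_population <- function(params, n, seed,
                              menopause_mode = c("probabilistic", "age50_proxy")) {
  stopifnot(n >= 1)
  menopause_mode <- match.arg(menopause_mode)
  validate_population_params(params)
  ids <- seq_len(n)

  draw_cat <- function(u, prob_matrix) {
    # prob_matrix: one row per patient, columns = category probabilities
    cum <- prob_matrix
    for (j in seq_len(ncol(cum))[-1]) cum[, j] <- cum[, j] + cum[, j - 1L]
    1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
  }

  w <- unlist(params$race_eth_weights)[RACE_LEVELS]
  race_idx <- findInterval(substream_uniforms(seed, "race", ids),
                           cumsum(w), left.open = TRUE) + 1L
  race_idx <- pmin(race_idx, length(RACE_LEVELS))
  race <- RACE_LEVELS[race_idx]

  agemat <- do.call(rbind, params$age_dist_by_race[RACE_LEVELS])
  bin <- draw_cat(substream_uniforms(seed, "age_bin", ids),
                  agemat[race_idx, , drop = FALSE])
  lo <- params$age_bins$lower[bin]; hi <- params$age_bins$upper[bin]
  age <- lo + substream_uniforms(seed, "age_within", ids) * (hi - lo)

  meno <- assign_menopause(age, race, params, mode = menopause_mode,
                           u = substream_uniforms(seed, "menopause", ids))

  band <- age_band_of(params, age)
  gtab <- matrix(NA_real_, n, length(GRADE_LEVELS))
  for (r in RACE_LEVELS) for (b in age_band_labels(params)) {
    sel <- race == r & band == b
    if (any(sel))
      gtab[sel, ] <- matrix(unlist(params$grade_dist[[r]][[b]][GRADE_LEVELS]),
                            sum(sel), length(GRADE_LEVELS), byrow = TRUE)
  }
  grade <- GRADE_LEVELS[draw_cat(substream_uniforms(seed, "grade", ids), gtab)]

  p_erpr <- numeric(n)
  p_le2  <- numeric(n)
  for (r in RACE_LEVELS) for (g in GRADE_LEVELS) {
    sel <- race == r & grade == g
    if (!any(sel)) next
    p_erpr[sel] <- params$hormone_dist[[r]][[g]]
    for (b in age_band_labels(params)) {
      s2 <- sel & band == b
      if (any(s2)) p_le2[s2] <- params$size_dist[[r]][[g]][[b]]
    }
  }
  hormone <- ifelse(substream_uniforms(seed, "hormone", ids) < p_erpr,
                    "er_and_pr_pos", "er_or_pr_pos")
  size <- ifelse(substream_uniforms(seed, "size", ids) < p_le2,
                 "le_2cm", "gt_2cm")

  eta <- rs_eta(params, race, band, grade, hormone, size)
  cum <- rs_cumprob(params, eta)
  u_rs <- substream_uniforms(seed, "rs", ids)
  rs <- rowSums(cum < u_rs)  # smallest k with P(RS <= k) >= u

  out <- data.table(
    patient_id = ids, age_dx = age,
    menopausal = meno, race_eth = race, grade = grade,
    hormone_sensitivity = hormone, size_class = size, rs = as.integer(rs))
  setattr(out, "seed", seed)
  setattr(out, "menopause_mode", menopause_mode)
  out[]
}

#' Assign menopausal status
#'
#' @param age ages at diagnosis (years, >= 18).
#' @param race_eth race/ethnicity levels.
#' @param params `bc_population_params`.
#' @param mode `"probabilistic"` draws Bernoulli(`menopause_prob`);
#'   `"age50_proxy"` returns `"pre"` iff age < 50, deterministically.
#' @param u uniforms for the probabilistic draw (one per patient); if `NULL`,
#'   drawn from `seed`.
#' @param seed used only when `u` is `NULL` in probabilistic mode.
#' @return character vector in `c("pre","post")`.
#' @export
assign_menopause <- function(age, race_eth, params,
                             mode = c("probabilistic", "age50_proxy"),
                             u = NULL, seed = NULL) {
  stopifnot(all(age >= 18))
  mode <- match.arg(mode)
  if (mode == "age50_proxy") return(ifelse(age < 50, "pre", "post"))
  p_post <- menopause_prob(params, age, race_eth)
  if (is.null(u)) {
    if (is.null(seed)) stop("probabilistic mode needs `u` or `seed`")
    u <- substream_uniforms(seed, "menopause", seq_along(age))
  }
  ifelse(u < p_post, "post", "pre")
}

#' Summarize a simulated population
#'
#' Tabulates the characteristic frequencies of Table-2 style reports: column
#' percentages per stratum (overall and, when an `arm` column is present, per
#' arm) plus median age and median recurrence score.
#'
#' @param profiles output of [sample_population()] (optionally with an `arm`
#'   column from [randomize()]).
#' @param by extra stratification columns (default `"menopausal"` in addition
#'   to the overall column).
#' @return list with `frequencies` (data.table: stratum, characteristic,
#'   level, n, pct) and `medians` (median `age_dx` and `rs` per stratum).
#' @export
summarize_population <- function(profiles, by = "menopausal") {
  if (!is.data.frame(profiles) || nrow(profiles) == 0L)
    stop("summarize_population: empty input")
  profiles <- as.data.table(profiles)
  chars <- c("menopausal", "race_eth", "grade", "hormone_sensitivity",
             "size_class")
  strata <- list(overall = rep(TRUE, nrow(profiles)))
  for (col in intersect(c(by, "arm"), names(profiles)))
    for (lev in sort(unique(profiles[[col]])))
      strata[[paste0(col, "=", lev)]] <- profiles[[col]] == lev

  freq <- rbindlist(lapply(names(strata), function(s) {
    sub <- profiles[strata[[s]]]
    rbindlist(lapply(chars, function(ch) {
      tab <- sub[, .N, by = ch]
      setnames(tab, ch, "level")
      tab[, .(stratum = s, characteristic = ch, level = as.character(level),
              n = N, pct = 100 * N / nrow(sub))]
    }))
  }))
  med <- rbindlist(lapply(names(strata), function(s) {
    sub <- profiles[strata[[s]]]
    data.table(stratum = s, median_age = median(sub$age_dx),
               median_rs = median(as.numeric(sub$rs)))
  }))
  list(frequencies = freq[], medians = med[])
}

#' Analytic joint cell probabilities implied by a population parameter set
#'
#' Expands the conditional chain into the full joint distribution over
#' (race, age bin, grade, hormone sensitivity, size class, recurrence-score
#' band) with the premenopausal probability integrated over the uniform
#' within-bin age. This is the deterministic companion to
#' [sample_population()]: sampled marginals converge to marginals of this
#' table, which tests use as the goodness-of-fit oracle and calibration uses
#' to compute expected survival mixtures.
#'
#' @param params `bc_population_params`.
#' @param rs_bands lower bounds of recurrence-score bands (default the hazard
#'   model's bands).
#' @return `data.table` with one row per cell and columns `prob` (joint
#'   probability) and `p_pre` (probability premenopausal within the cell).
#' @export
population_cell_table <- function(params, rs_bands = c(0, 11, 16, 21)) {
  nb <- length(params$age_bins$lower)
  cells <- CJ(race_eth = RACE_LEVELS, bin = seq_len(nb),
              grade = GRADE_LEVELS, hormone_sensitivity = HORMONE_LEVELS,
              size_class = SIZE_LEVELS)
  cells[, lo := params$age_bins$lower[bin]]
  cells[, hi := params$age_bins$upper[bin]]
  cells[, age_band := age_band_of(params, (lo + hi) / 2)]
  w <- unlist(params$race_eth_weights)
  cells[, p_race := w[race_eth]]
  cells[, p_age := mapply(function(r, b) params$age_dist_by_race[[r]][b],
                          race_eth, bin)]
  cells[, p_grade := mapply(function(r, b, g) params$grade_dist[[r]][[b]][[g]],
                            race_eth, age_band, grade)]
  cells[, p_horm := mapply(function(r, g, h) {
    p <- params$hormone_dist[[r]][[g]]
    if (h == "er_and_pr_pos") p else 1 - p
  }, race_eth, grade, hormone_sensitivity)]
  cells[, p_size := mapply(function(r, g, b, s) {
    p <- params$size_dist[[r]][[g]][[b]]
    if (s == "le_2cm") p else 1 - p
  }, race_eth, grade, age_band, size_class)]
  # mean premenopausal probability over the uniform within-bin age (11-point
  # midpoint rule; the logistic is smooth so this is plenty)
  grid <- (seq_len(11) - 0.5) / 11
  cells[, p_pre := {
    vapply(seq_len(.N), function(i) {
      a <- lo[i] + grid * (hi[i] - lo[i])
      mean(1 - menopause_prob(params, a, race_eth[i]))
    }, numeric(1))
  }]
  cells[, prob := p_race * p_age * p_grade * p_horm * p_size]
  cells <- cells[prob > 0]

  # attach recurrence-score band probabilities
  eta <- rs_eta(params, cells$race_eth, cells$age_band, cells$grade,
                cells$hormone_sensitivity, cells$size_class)
  cum <- rs_cumprob(params, eta)
  bands <- c(rs_bands, RS_MAX + 1L)
  out <- rbindlist(lapply(seq_len(length(rs_bands)), function(j) {
    lo_k <- bands[j]; hi_k <- bands[j + 1L] - 1L
    p_lo <- if (lo_k == 0) 0 else cum[, lo_k]  # P(RS <= lo_k - 1)
    p_hi <- cum[, hi_k + 1L]                   # P(RS <= hi_k), col k+1
    cbind(cells, data.table(rs_band = paste0(lo_k, "-", hi_k),
                            p_rs = p_hi - p_lo))
  }))
  out[, prob := prob * p_rs]
  out[, c("p_race", "p_age", "p_grade", "p_horm", "p_size", "p_rs") := NULL]
  out[]
}

#' Marginal distributions implied by a population parameter set
#'
#' @param params `bc_population_params`.
#' @return named list of probability vectors over the levels of each sampled
#'   characteristic (plus `menopausal`), computed analytically from the
#'   conditional chain. Used as the chi-square goodness-of-fit oracle.
#' @export
population_marginals <- function(params) {
  cells <- population_cell_table(params)
  m <- function(col) {
    agg <- cells[, .(p = sum(prob)), by = col]
    setNames(agg$p, agg[[col]])
  }
  rs_full <- {
    eta_cells <- population_cell_table(params, rs_bands = 0:RS_MAX)
    agg <- eta_cells[, .(p = sum(prob)), by = rs_band]
    agg[, k := as.integer(sub("-.*", "", rs_band))]
    setNames(agg[order(k)]$p, 0:RS_MAX)
  }
  list(
    race_eth = m("race_eth")[RACE_LEVELS],
    grade = m("grade")[GRADE_LEVELS],
    hormone_sensitivity = m("hormone_sensitivity")[HORMONE_LEVELS],
    size_class = m("size_class")[SIZE_LEVELS],
    menopausal = c(pre = cells[, sum(prob * p_pre)],
                   post = cells[, sum(prob * (1 - p_pre))]),
    rs = rs_full
  )
}
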