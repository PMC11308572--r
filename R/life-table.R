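#' Synthetic other-cause mortality life table
#'
#' Annual probability of other-cause death by single year of age and
#' race/ethnicity. The shipped default is *synthetic*: a Gompertz curve with
#' race-specific multipliers calibrated so that simulated life-year levels
#' match the published aggregate tables; it is life-table-shaped but is not a
#' CDC WONDER extract. Rates are clamped to `[0, 1]` and the terminal age
#' carries rate 1, so sampled survival is always finite.
#'
#' @param base_rate Gompertz scale at age 0 (annual rate).
#' @param gompertz_b Gompertz log-slope per year of age.
#' @param race_multipliers named multipliers per race/ethnicity.
#' @param floor_rate minimum annual rate (background/accident mortality).
#' @param min_age,max_age age range covered; the rate at `max_age` is 1.
#' @return `bc_life_table`: data.table with columns `age`, `race_eth`,
#'   `rate`.
#' @export
make_life_table <- function(base_rate = 2.0e-5, gompertz_b = 0.094,
                            race_multipliers = c(nh_black = 1, hispanic = 1,
                                                 nh_white = 1),
                            floor_rate = 5e-4, min_age = 18L, max_age = 110L) {
  ages <- min_age:max_age
  lt <- CJ(race_eth = RACE_LEVELS, age = ages)
  lt[, rate := pmin(1, pmax(floor_rate,
    base_rate * race_multipliers[race_eth] * exp(gompertz_b * age)))]
  lt[age == max_age, rate := 1]
  life_table(lt)
}

#' @rdname make_life_table
#' @param x data.frame with columns `age`, `race_eth`, `rate`.
#' @export
life_table <- function(x) {
  x <- as.data.table(x)[, .(age = as.integer(age),
                            race_eth = as.character(race_eth),
                            rate = as.numeric(rate))]
  if (any(x$rate < 0 | x$rate > 1))
    stop("life table: rates must lie in [0, 1]", call. = FALSE)
  for (r in RACE_LEVELS) {
    sub <- x[race_eth == r][order(age)]
    if (nrow(sub) == 0L)
      stop("life table: race ", r, " missing", call. = FALSE)
    if (!identical(sub$age, seq(min(sub$age), max(sub$age))))
      stop("life table: ages for ", r, " must be consecutive single years",
           call. = FALSE)
    if (sub[.N, rate] != 1)
      stop("life table: terminal-age rate must be 1 for ", r, call. = FALSE)
  }
  setkey(x, race_eth, age)
  structure(x, class = c("bc_life_table", class(x)))
}

#' Read/write a life table as CSV
#'
#' Comment lines starting with `#` carry provenance and are preserved on
#' write via a `provenance` attribute.
#'
#' @param path CSV file path.
#' @export
load_life_table <- function(path) {
  lines <- readLines(path)
  prov <- grep("^#", lines, value = TRUE)
  lt <- life_table(utils::read.csv(text = lines[!grepl("^#", lines)]))
  setattr(lt, "provenance", prov)
  lt
}

#' @rdname load_life_table
#' @param lt `bc_life_table`.
#' @param provenance character comment lines written atop the file.
#' @export
write_life_table <- function(lt, path, provenance = attr(lt, "provenance")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(provenance, con)
  utils::write.csv(as.data.frame(lt), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Piecewise-linear cumulative other-cause hazard per race, anchored at the
# youngest tabulated age. Annual probability q maps to a constant hazard
# -log(1 - q) across that year of age.
oc_cumhaz_table <- function(lt) {
  out <- lapply(RACE_LEVELS, function(r) {
    sub <- lt[list(r)][order(age)]
    lam <- -log(pmax(1e-12, 1 - sub$rate))
    lam[sub$rate >= 1] <- 1e9  # terminal age: certain death within the year
    list(age0 = sub$age[1],
         ages = c(sub$age, max(sub$age) + 1L),
         cum = c(0, cumsum(lam)), lam = lam)
  })
  names(out) <- RACE_LEVELS
  out
}

#' Sample time from diagnosis to other-cause death
#'
#' Piecewise-exponential draw walking the annual life-table rates upward from
#' the (continuous) age at diagnosis. Always finite because the terminal age
#' has rate 1.
#'
#' @param profiles patient profiles (uses `age_dx`, `race_eth`).
#' @param lifetable `bc_life_table`.
#' @param u uniforms (one per patient) or `NULL` to draw from `seed`.
#' @param seed master seed used when `u` is `NULL`.
#' @return years from diagnosis to other-cause death.
#' @export
sample_other_cause_death <- function(profiles, lifetable, u = NULL,
                                     seed = NULL) {
  n <- nrow(profiles)
  if (is.null(u)) {
    if (is.null(seed)) stop("sample_other_cause_death needs `u` or `seed`")
    u <- substream_uniforms(seed, "oc_death", profiles$patient_id)
  }
  e <- -log(1 - u)
  tab <- oc_cumhaz_table(lifetable)
  t_oc <- numeric(n)
  for (r in RACE_LEVELS) {
    sel <- which(profiles$race_eth == r)
    if (!length(sel)) next
    tr <- tab[[r]]
    age <- profiles$age_dx[sel]
    if (any(age < tr$age0 | age >= max(tr$ages)))
      stop("age_dx outside life-table range for ", r, call. = FALSE)
    i0 <- findInterval(age, tr$ages)
    c_start <- tr$cum[i0] + (age - tr$ages[i0]) * tr$lam[i0]
    target <- c_start + e[sel]
    i1 <- pmin(findInterval(target, tr$cum, left.open = TRUE),
               length(tr$lam))
    age_death <- tr$ages[i1] + (target - tr$cum[i1]) / tr$lam[i1]
    age_death <- pmin(age_death, max(tr$ages))
    t_oc[sel] <- pmax(age_death - age, 0)
  }
  t_oc
}
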