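# Construct the shipped population_params.json.
# Targets (printed population characteristics): overall median age 57.4,
# premenopausal 28.6%, grade low/int/high 27.0/57.8/15.2 with race-specific
# high-grade excess (NH Black ~26.3%), ER&PR+ 85.4% overall (NH Black ~78.2%),
# size <=2cm 53.2%, median RS 17 (pre 18, post 17).
# Race mixture (0.83/0.07/0.10 white/black/hispanic) solved from internal
# consistency of the published race-stratified and overall tables.
suppressMessages(devtools::load_all("/root/pkg", quiet = TRUE))
suppressMessages(library(data.table))

races <- c("nh_black", "hispanic", "nh_white")
w <- c(nh_black = 0.07, hispanic = 0.10, nh_white = 0.83)

lowers <- c(18, seq(25, 95, 5)); uppers <- c(seq(25, 100, 5))
bins <- list(lower = lowers, upper = uppers)

age_probs <- function(mu, sd = 12.5) {
  p <- pnorm(uppers, mu, sd) - pnorm(lowers, mu, sd)
  p / sum(p)
}
# continuous CDF of the binned (uniform-within-bin) mixture
mix_age_cdf <- function(x, mus) {
  sapply(x, function(xx) {
    tot <- 0
    for (r in races) {
      p <- age_probs(mus[r])
      frac <- pmin(pmax((xx - lowers) / (uppers - lowers), 0), 1)
      tot <- tot + w[r] * sum(p * frac)
    }
    tot
  })
}
mus <- c(nh_black = 56.3, hispanic = 53.6, nh_white = NA)
f <- function(mw) { m <- mus; m["nh_white"] <- mw; mix_age_cdf(57.4, m) - 0.5 }
mus["nh_white"] <- uniroot(f, c(54, 62), tol = 1e-7)$root
cat("solved white age mean:", round(mus["nh_white"], 3), "\n")
age_dist <- lapply(races, function(r) age_probs(mus[r])); names(age_dist) <- races

# menopause: shared logistic midpoint solved for 28.6% premenopausal
meno_scale <- 2.2
pre_frac <- function(mid) {
  tot <- 0
  for (r in races) {
    p <- age_probs(mus[r])
    # integrate within bins (11-point midpoint rule)
    g <- (seq_len(11) - 0.5) / 11
    pb <- sapply(seq_along(lowers), function(i) {
      a <- lowers[i] + g * (uppers[i] - lowers[i])
      mean(1 - plogis((a - mid) / meno_scale))
    })
    tot <- tot + w[r] * sum(p * pb)
  }
  tot
}
mid <- uniroot(function(m) pre_frac(m) - 0.286, c(45, 55), tol = 1e-7)$root
cat("solved menopause midpoint:", round(mid, 3), " pre frac:", pre_frac(mid), "\n")

# grade: race-level targets; white solved from the overall row
g_black <- c(low = 0.200, intermediate = 0.537, high = 0.263)
g_hisp  <- c(low = 0.250, intermediate = 0.580, high = 0.170)
g_white <- (c(low = .270, intermediate = .578, high = .152) -
              0.07 * g_black - 0.10 * g_hisp) / 0.83
cat("white grade:", round(g_white, 4), "sum", sum(g_white), "\n")
g_race <- list(nh_black = g_black, hispanic = g_hisp, nh_white = g_white)

bands <- c("18-49", "50-69", "70+")
tilt <- list(`18-49` = c(low = -0.030, intermediate = -0.005, high = 0.035),
             `50-69` = c(low = 0.005, intermediate = 0.002, high = -0.007),
             `70+`  = c(low = 0.020, intermediate = 0.000, high = -0.020))
band_probs <- function(r) {  # P(age band | race)
  p <- age_probs(mus[r])
  cuts <- findInterval((lowers + uppers) / 2, c(18, 50, 70))
  sapply(1:3, function(b) sum(p[cuts == b]))
}
grade_dist <- lapply(races, function(r) {
  pb <- band_probs(r)
  base <- g_race[[r]] - Reduce(`+`, Map(function(t, p) t * p, tilt, pb))
  out <- lapply(bands, function(b) {
    v <- base + tilt[[b]]
    stopifnot(all(v > 0)); as.list(v / sum(v))
  })
  names(out) <- bands; out
})
names(grade_dist) <- races

# hormone sensitivity: P(ER & PR positive | grade, race)
h_eff <- c(low = 0.055, intermediate = 0.010, high = -0.170)
h_race_target <- c(nh_black = 0.782, hispanic = 0.840, nh_white = NA)
h_race_target["nh_white"] <- (0.854 - 0.07 * 0.782 - 0.10 * 0.840) / 0.83
hormone_dist <- lapply(races, function(r) {
  base <- h_race_target[r] - sum(g_race[[r]] * h_eff)
  v <- setNames(pmin(0.99, pmax(0.01, base + h_eff)), names(h_eff))
  as.list(v)
})
names(hormone_dist) <- races

# tumor size: P(<= 2cm | grade, age band, race)
s_g <- c(low = 0.100, intermediate = 0.010, high = -0.140)
s_b <- c(`18-49` = -0.020, `50-69` = 0.005, `70+` = 0.010)
s_race_target <- c(nh_black = 0.470, hispanic = 0.505, nh_white = NA)
s_race_target["nh_white"] <- (0.532 - 0.07 * 0.470 - 0.10 * 0.505) / 0.83
size_dist <- lapply(races, function(r) {
  pb <- band_probs(r); names(pb) <- bands
  base <- s_race_target[r] - sum(g_race[[r]] * s_g) - sum(pb * s_b)
  out <- lapply(GRADE_LEVELS, function(g) {
    v <- pmin(0.99, pmax(0.01, base + s_g[g] + s_b))
    as.list(setNames(v, bands))
  })
  names(out) <- GRADE_LEVELS; out
})
names(size_dist) <- races

# recurrence score: proportional-odds cutpoints from a discretized normal
eta <- list(
  grade = list(low = -0.25, intermediate = 0, high = 0.45),
  size_class = list(le_2cm = 0, gt_2cm = 0.10),
  hormone_sensitivity = list(er_and_pr_pos = 0, er_or_pr_pos = 0.35),
  age_band = list(`18-49` = 0.28, `50-69` = 0, `70+` = -0.05),
  race_eth = list(nh_black = 0.05, hispanic = 0, nh_white = 0)
)
build_params <- function(mu_rs, sd_rs = 6.0, age_pre_coef = eta$age_band$`18-49`) {
  e <- eta; e$age_band$`18-49` <- age_pre_coef
  Fk <- pnorm((0:24) + 0.5, mu_rs, sd_rs) / pnorm(25.5, mu_rs, sd_rs)
  population_params(
    race_eth_weights = as.list(w),
    age_bins = bins,
    age_dist_by_race = age_dist,
    menopause = list(midpoint = as.list(setNames(rep(mid, 3), races)),
                     scale = as.list(setNames(rep(meno_scale, 3), races))),
    grade_dist = grade_dist, hormone_dist = hormone_dist,
    size_dist = size_dist,
    rs_model = list(cutpoints = qlogis(pmin(Fk, 1 - 1e-12)), eta = e))
}
# RS CDF at k overall / by menopause from the analytic cell table
rs_cdf <- function(params, k, meno = NULL) {
  cells <- population_cell_table(params, rs_bands = 0:25)
  cells[, k_rs := as.integer(sub("-.*", "", rs_band))]
  wgt <- if (is.null(meno)) cells$prob else if (meno == "pre")
    cells$prob * cells$p_pre else cells$prob * (1 - cells$p_pre)
  sum(wgt[cells$k_rs <= k]) / sum(wgt)
}
mu_rs <- uniroot(function(m) rs_cdf(build_params(m), 16) - 0.465,
                 c(10, 24), tol = 1e-5)$root
cat("solved RS latent mean:", round(mu_rs, 3), "\n")
p <- build_params(mu_rs)
# nudge the young-age shift until the premenopausal median is 18
ac <- uniroot(function(a) rs_cdf(build_params(mu_rs, age_pre_coef = a), 17,
                                 "pre") - 0.468, c(0.0, 1.2), tol = 1e-4)$root
p <- build_params(mu_rs, age_pre_coef = ac)
cat("age 18-49 RS shift:", round(ac, 3), "\n")

marg <- population_marginals(p)
cat("\n-- analytic marginals --\n")
cat("pre:", round(100 * marg$menopausal["pre"], 2), "\n")
cat("grade:", round(100 * marg$grade, 2), "\n")
cat("ER&PR:", round(100 * marg$hormone_sensitivity["er_and_pr_pos"], 2), "\n")
cat("le_2cm:", round(100 * marg$size_class["le_2cm"], 2), "\n")
rs_cum <- cumsum(marg$rs)
cat("RS CDF 15,16,17,18:", round(rs_cum[c("15", "16", "17", "18")], 3), "\n")
cat("pre RS CDF 16,17,18:", round(sapply(16:18, rs_cdf, params = p, meno = "pre"), 3), "\n")
cat("post RS CDF 15,16,17:", round(sapply(15:17, rs_cdf, params = p, meno = "post"), 3), "\n")
cat("age CDF at 57.4:", mix_age_cdf(57.4, mus), "\n")

write_population_params(p, "/root/pkg/inst/extdata/population_params.json")
cat("written.\n")
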