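# Baseline (no-extended-therapy) breast-cancer mortality. Each stratum
# carries a lifetime cumulative hazard Lambda_total spread over the first 25
# years post-diagnosis by a truncated-Weibull time shape; no breast-cancer
# death can occur after year 25. Lambda is calibrated so the simulated
# 5-year-arm lifetime breast-cancer mortality (with competing mortality on)
# hits the published target; the Weibull scale is calibrated so the share of
# the 10-vs-5 mortality difference accrued by year 15 matches the published
# 15-year/25-year ratio.

AGE_GROUPS <- c("age2549", "age5079")

group_of_age <- function(age) ifelse(age < 50, "age2549", "age5079")

# Weibull CDF truncated to (0, tmax]
weib_trunc_cdf <- function(t, k, lambda, tmax = 25) {
  if (any(t < 0)) stop("t must be >= 0")
  C <- 1 - exp(-(tmax / lambda)^k)
  q <- (1 - exp(-(pmin(t, tmax) / lambda)^k)) / C
  pmin(q, 1)
}

weib_trunc_quantile <- function(q, k, lambda, tmax = 25) {
  stopifnot(all(q >= 0), all(q <= 1))
  C <- 1 - exp(-(tmax / lambda)^k)
  lambda * (-log1p(-q * C))^(1 / k)
}

# density of the truncated Weibull on (0, tmax]
weib_trunc_pdf <- function(t, k, lambda, tmax = 25) {
  C <- 1 - exp(-(tmax / lambda)^k)
  out <- (k / lambda) * (t / lambda)^(k - 1) * exp(-(t / lambda)^k) / C
  out[t > tmax | t < 0] <- 0
  out
}

#' Baseline cumulative breast-cancer mortality hazard
#'
#' `Lambda(t) = Lambda_total * F(t)` where `F` is the truncated-Weibull CDF
#' on (0, 25]; flat at `Lambda_total` for `t >= 25`.
#'
#' @param t Years since diagnosis (vectorized, `>= 0`).
#' @param Lambda_total Lifetime cumulative hazard for the stratum.
#' @param shape list with elements `k`, `lambda` (Weibull shape and scale).
#' @param tmax Year after which no breast-cancer death occurs (default 25).
#' @export
bc_cumulative_hazard <- function(t, Lambda_total, shape, tmax = 25) {
  if (any(t < 0)) stop("t must be >= 0")
  Lambda_total * weib_trunc_cdf(t, shape$k, shape$lambda, tmax)
}

#' Closed-form calibration initializer (no competing mortality)
#'
#' With competing mortality switched off and a single stratum, the lifetime
#' breast-cancer mortality in the 5-year arm is `1 - exp(-hr5 * Lambda)`,
#' so `Lambda = -ln(1 - target) / hr5`.
#' @param target_p5 Lifetime probability of breast-cancer death in the
#'   5-year arm.
#' @param hr5 5-year strategy hazard ratio.
#' @export
closed_form_lambda <- function(target_p5, hr5) {
  stopifnot(target_p5 >= 0, target_p5 < 1, hr5 > 0)
  -log(1 - target_p5) / hr5
}

# ---- stratum bookkeeping ----------------------------------------------------

# Hazard-ratio strata for an age group with their cohort weights and
# node-positive Lambda multipliers.
strata_for_group <- function(config, group) {
  p <- config$cohort$stage_distribution / sum(config$cohort$stage_distribution)
  npm <- config$node_pos_multiplier
  if (group == "age2549") {
    h1 <- config$hazard_ratios$age2549_stage1
    h23 <- config$hazard_ratios$age2549_stage23
    data.frame(
      w = c(p[["stage1"]], p[["stage2a"]], p[["stage2b"]] + p[["stage3"]]),
      hr5 = c(h1$hr5, h23$hr5, h23$hr5),
      hr10 = c(h1$hr10, h23$hr10, h23$hr10),
      mult = c(1, 1, npm)
    )
  } else {
    h <- config$hazard_ratios$age5079
    data.frame(
      w = c(p[["stage1"]] + p[["stage2a"]], p[["stage2b"]] + p[["stage3"]]),
      hr5 = c(h$hr5, h$hr5),
      hr10 = c(h$hr10, h$hr10),
      mult = c(1, npm)
    )
  }
}

# Restrict the cohort specification to one calibration age group.
restrict_age_group <- function(config, group) {
  ar <- config$cohort$age_range
  gr <- if (group == "age2549") c(25, 50) else c(50, 79)
  lo <- max(ar[1], gr[1]); hi <- min(ar[2], gr[2])
  if (lo >= hi) stop("config age range does not overlap group ", group)
  config$cohort$age_range <- c(lo, hi)
  config
}

config_age_groups <- function(config) {
  ar <- config$cohort$age_range
  out <- character(0)
  if (ar[1] < 50) out <- c(out, "age2549")
  if (ar[2] > 50) out <- c(out, "age5079")
  if (ar[2] == 50 && length(out) == 0) out <- "age5079"
  out
}

# ---- expected mortality curves by quadrature --------------------------------

# Mean other-cause survival S(a + x | a) over the group's age-at-diagnosis
# distribution, evaluated on the time grid x.
mean_oc_survival <- function(config, group, xgrid) {
  cfg <- restrict_age_group(config, group)
  ar <- cfg$cohort$age_range
  lt <- life_table_from_config(config)
  agrid <- seq(ar[1], ar[2], length.out = 60)
  w <- dnorm(agrid, cfg$cohort$age_mean, cfg$cohort$age_sd)
  w <- w / sum(w)
  H0 <- lt_cumhaz(lt, agrid)
  sapply(xgrid, function(x) sum(w * exp(-(lt_cumhaz(lt, agrid + x) - H0))))
}

# Expected cumulative probability of breast-cancer death by time t under one
# arm, with competing mortality folded in:
#   P(t) = int_0^t  Sbar_oc(x) * lam_arm(x) * exp(-Lambda_arm(x)) dx
# computed by trapezoid on a fine grid, per stratum, then mixed.
expected_bc_mortality_curve <- function(config, group, Lambda_base, shape,
                                        t_eval, soc = NULL, xgrid = NULL) {
  if (is.null(xgrid)) xgrid <- seq(1e-6, 25, length.out = 1001)
  if (is.null(soc)) soc <- mean_oc_survival(config, group, xgrid)
  st <- strata_for_group(config, group)
  F5 <- weib_trunc_cdf(5, shape$k, shape$lambda, config$max_bc_death_year)
  fF <- weib_trunc_pdf(xgrid, shape$k, shape$lambda, config$max_bc_death_year)
  FF <- weib_trunc_cdf(xgrid, shape$k, shape$lambda, config$max_bc_death_year)
  dx <- diff(xgrid)
  out <- matrix(0, nrow = length(t_eval), ncol = 2,
                dimnames = list(NULL, c("five_year", "ten_year")))
  for (s in seq_len(nrow(st))) {
    Ltot <- Lambda_base * st$mult[s]
    mt10 <- tail_multiplier(st$hr5[s], st$hr10[s], Ltot * F5, Ltot)
    for (arm in c("five_year", "ten_year")) {
      m <- if (arm == "five_year") c(st$hr5[s], st$hr5[s])
           else c(st$hr5[s], mt10)
      mx <- ifelse(xgrid <= 5, m[1], m[2])
      Larm <- Ltot * ifelse(xgrid <= 5, m[1] * FF,
                            m[1] * F5 + m[2] * (FF - F5))
      g <- soc * mx * Ltot * fF * exp(-Larm)
      cum <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * dx))
      P <- approx(xgrid, cum, xout = pmin(t_eval, max(xgrid)), rule = 2)$y
      out[, arm] <- out[, arm] + st$w[s] * P
    }
  }
  out
}

# share of the 10-vs-5 mortality difference accrued by year 15
expected_share_15 <- function(config, group, Lambda_base, shape, soc = NULL,
                              xgrid = NULL) {
  P <- expected_bc_mortality_curve(config, group, Lambda_base, shape,
                                   t_eval = c(15, 25), soc = soc,
                                   xgrid = xgrid)
  D <- P[, "five_year"] - P[, "ten_year"]
  D[1] / D[2]
}

# ---- calibration ------------------------------------------------------------

#' Calibrate the time shape of baseline breast-cancer mortality
#'
#' Finds the truncated-Weibull scale (shape `k` held fixed) such that the
#' expected share of the 10-vs-5 between-arm mortality difference accrued by
#' year 15 matches the target. The expectation folds in competing mortality
#' via a deterministic quadrature of the breast-cancer death sub-density
#' against the cohort-mean other-cause survival; with `k = 1` and competing
#' mortality off this reduces to the closed-form truncated-exponential
#' share, which brackets the solution. Deterministic.
#'
#' @param config An `eet_config`.
#' @param group `"age2549"` or `"age5079"`.
#' @param target_share Target share in (0, 1); defaults to the configured
#'   calibration target for the group.
#' @param k Weibull shape; defaults to `config$calibration$weibull_k`.
#' @param Lambda_base Baseline lifetime cumulative hazard; defaults to the
#'   closed-form initializer for the group's target mortality.
#' @return list with `k`, `lambda`, `achieved_share`, `iterations`.
#' @export
calibrate_time_shape <- function(config, group, target_share = NULL, k = NULL,
                                 Lambda_base = NULL) {
  if (is.null(target_share))
    target_share <- config$calibration$share_15y[[group]]
  stopifnot(target_share > 0, target_share < 1)
  if (is.null(k)) k <- config$calibration$weibull_k
  if (is.null(Lambda_base)) {
    st <- strata_for_group(config, group)
    hr5bar <- sum(st$w * st$hr5)
    Lambda_base <- closed_form_lambda(config$calibration$target_p5[[group]],
                                      hr5bar)
  }
  xgrid <- seq(1e-6, 25, length.out = 1001)
  soc <- mean_oc_survival(config, group, xgrid)
  f <- function(loglam) {
    expected_share_15(config, group, Lambda_base,
                      list(k = k, lambda = exp(loglam)),
                      soc = soc, xgrid = xgrid) - target_share
  }
  # the piecewise model is feasible only while F(5) < min(hr10/hr5): below
  # that scale all baseline hazard sits before year 5 and no tail multiplier
  # can reproduce the lifetime hazard ratio
  st <- strata_for_group(config, group)
  rmin <- min(st$hr10 / st$hr5)
  tmaxy <- config$max_bc_death_year
  lam_hi <- 300
  if (weib_trunc_cdf(5, k, lam_hi, tmaxy) >= rmin)
    stop("no feasible time-shape scale for k = ", k)
  lam_min <- uniroot(function(l) weib_trunc_cdf(5, k, l, tmaxy) - 0.999 * rmin,
                     lower = 0.01, upper = lam_hi)$root
  lo <- log(max(lam_min, 0.05)); hi <- log(lam_hi)
  flo <- f(lo); fhi <- f(hi)   # share decreases with lambda: flo > 0 > fhi
  if (flo < 0 || fhi > 0) {
    stop(sprintf(paste0("target share %.3f is outside the achievable ",
                        "interval [%.3f, %.3f] for k = %g"),
                 target_share, target_share + fhi, target_share + flo, k))
  }
  it <- 0L
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm > 0) lo <- mid else hi <- mid
    it <- i
    if (abs(fm) < 1e-10 || (hi - lo) < 1e-12) break
  }
  lambda <- exp((lo + hi) / 2)
  list(k = k, lambda = lambda,
       achieved_share = target_share + f(log(lambda)), iterations = it)
}

#' Calibrate the lifetime baseline hazard to a 5-year-arm mortality target
#'
#' Bisection on the node-negative lifetime cumulative hazard `Lambda_base`
#' (node-positive strata use `Lambda_base * node_pos_multiplier`) so that the
#' simulated lifetime probability of breast-cancer death in the 5-year arm,
#' with competing mortality on, matches `target_p5`. The simulation reuses
#' one fixed set of draws across all bisection steps (common random
#' numbers), making the objective monotone in `Lambda_base`; the search is
#' initialized at the closed-form no-competing-mortality solution.
#'
#' @inheritParams calibrate_time_shape
#' @param shape Time-shape list (`k`, `lambda`), e.g. from
#'   [calibrate_time_shape()].
#' @param target_p5 Target lifetime P(BC death) in the 5-year arm; defaults
#'   to the configured group target.
#' @param n_sim Calibration sample size; defaults to
#'   `config$calibration$n_sim`.
#' @param seed Seed for the calibration draws; defaults to
#'   `config$calibration$calib_seed`.
#' @return list with `Lambda_base`, `achieved_p5`, `target_p5`, `mc_se`,
#'   `iterations`, `n_sim`.
#' @export
calibrate_lambda <- function(config, group, shape, target_p5 = NULL,
                             n_sim = NULL, seed = NULL) {
  if (is.null(target_p5)) target_p5 <- config$calibration$target_p5[[group]]
  stopifnot(target_p5 > 0, target_p5 < 1)
  if (is.null(n_sim)) n_sim <- config$calibration$n_sim
  if (is.null(seed)) seed <- config$calibration$calib_seed

  gcfg <- restrict_age_group(config, group)
  # calibration is always run at 100% completion (the published base case)
  gcfg$completion <- list(c1 = 1, c2 = 1)
  prof <- sample_cohort(gcfg, n = n_sim, seed = seed, stream_tag = "_calib")
  prof <- assign_regimen(prof, gcfg)
  lt <- life_table_from_config(gcfg)
  E <- -log(substream_runif(seed, "latent_bc_calib", n_sim))
  u_oc <- substream_runif(seed, "other_cause_calib", n_sim)
  oc_age <- sample_other_cause_death_age(prof$age_dx, lt, u_oc,
                                         prof$birth_year)
  t_oc <- oc_age - prof$age_dx
  mult <- ifelse(prof$nodal == "positive", gcfg$node_pos_multiplier, 1)

  p5_of <- function(Lb) {
    bc <- bc_death_time(E, m_early = prof$hr5, m_tail = prof$hr5,
                        Lambda_total = Lb * mult, shape = shape,
                        tmax = gcfg$max_bc_death_year)
    mean(bc$death & bc$time <= t_oc)
  }

  st <- strata_for_group(config, group)
  L0 <- closed_form_lambda(target_p5, sum(st$w * st$hr5)) / sum(st$w * st$mult)
  lo <- L0 / 3; hi <- L0 * 3
  widen <- 0L
  while (p5_of(hi) < target_p5 && widen < 2) { hi <- hi * 3; widen <- widen + 1L }
  while (p5_of(lo) > target_p5 && widen < 4) { lo <- lo / 3; widen <- widen + 1L }
  if (p5_of(lo) > target_p5 || p5_of(hi) < target_p5) {
    stop(sprintf(paste0("calibration failed to bracket target %.4f after ",
                        "widening: p5(%.4g) = %.4f, p5(%.4g) = %.4f"),
                 target_p5, lo, p5_of(lo), hi, p5_of(hi)))
  }
  it <- 0L
  for (i in 1:45) {
    mid <- (lo + hi) / 2
    if (p5_of(mid) < target_p5) lo <- mid else hi <- mid
    it <- i
    if ((hi - lo) / mid < 1e-6) break
  }
  Lb <- (lo + hi) / 2
  achieved <- p5_of(Lb)
  list(Lambda_base = Lb, achieved_p5 = achieved, target_p5 = target_p5,
       mc_se = sqrt(achieved * (1 - achieved) / n_sim),
       iterations = it, n_sim = n_sim)
}

# Try the configured Weibull shape k first; if the target share lies outside
# the achievable interval (a truncated exponential cannot defer enough of the
# between-arm difference past year 15 once competing mortality is folded in,
# as happens for the ages 50-79 share target), escalate k so the
# time-to-death mode moves later until the target becomes attainable.
fit_shape_escalating_k <- function(config, group, k = NULL,
                                   Lambda_base = NULL) {
  k0 <- if (is.null(k)) config$calibration$weibull_k else k
  for (kk in unique(c(k0, 1.5, 2, 2.5, 3, 4))) {
    sh <- tryCatch(
      calibrate_time_shape(config, group, k = kk, Lambda_base = Lambda_base),
      error = function(e) e)
    if (!inherits(sh, "error")) return(sh)
  }
  stop("time-shape calibration failed for group ", group, ": ",
       conditionMessage(sh))
}

#' Calibrate the full baseline model for every age group in a scenario
#'
#' For each age group covered by the configured cohort age range, alternates
#' the time-shape fit and the lifetime-hazard fit (shape, Lambda, shape,
#' Lambda) so both the lifetime 5-year-arm mortality target and the 15-year
#' difference-share target hold simultaneously.
#'
#' @param config An `eet_config`.
#' @param n_sim,seed Passed to [calibrate_lambda()].
#' @return An `eet_calibration`: named list (per group) with `Lambda_base`,
#'   `shape`, `node_pos_multiplier`, `lambda_report`, `shape_report`.
#' @export
calibrate_model <- function(config, n_sim = NULL, seed = NULL) {
  out <- list()
  for (group in config_age_groups(config)) {
    sh <- fit_shape_escalating_k(config, group)
    lam <- calibrate_lambda(config, group, shape = sh, n_sim = n_sim,
                            seed = seed)
    sh <- fit_shape_escalating_k(config, group, k = sh$k,
                                 Lambda_base = lam$Lambda_base)
    lam <- calibrate_lambda(config, group,
                            shape = list(k = sh$k, lambda = sh$lambda),
                            n_sim = n_sim, seed = seed)
    out[[group]] <- list(
      Lambda_base = lam$Lambda_base,
      shape = list(k = sh$k, lambda = sh$lambda),
      node_pos_multiplier = config$node_pos_multiplier,
      lambda_report = lam,
      shape_report = sh
    )
  }
  class(out) <- c("eet_calibration", "list")
  out
}

#' Write a calibration report CSV
#' @param calib An `eet_calibration`.
#' @param path Output CSV path.
#' @export
calibration_report <- function(calib, path = NULL) {
  rows <- lapply(names(calib), function(g) {
    cc <- calib[[g]]
    data.frame(group = g, target_p5 = cc$lambda_report$target_p5,
               achieved_p5 = cc$lambda_report$achieved_p5,
               mc_se = cc$lambda_report$mc_se,
               Lambda_base = cc$Lambda_base,
               node_pos_multiplier = cc$node_pos_multiplier,
               weibull_k = cc$shape$k, weibull_lambda = cc$shape$lambda,
               achieved_share_15y = cc$shape_report$achieved_share,
               lambda_iterations = cc$lambda_report$iterations,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(rep, path, row.names = FALSE)
  rep
}
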