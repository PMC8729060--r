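# Regimen assignment and treatment effect. Strategy-level hazard ratios
# (5-year or 10-year strategy vs none) are converted into piecewise-constant
# hazard multipliers on the baseline breast-cancer mortality hazard: both
# arms share the 5-year-strategy multiplier on (0, 5]; the 10-year arm's
# tail multiplier on (5, 25] is solved so that its lifetime cumulative
# hazard equals hr10 * Lambda_total, which makes the two arms identical over
# the first five years and reproduces the strategy-level hazard ratios over
# a lifetime.

#' Assign the endocrine regimen and hazard-ratio pair for each woman
#'
#' Women under 50 receive tamoxifen (with ovarian suppression when
#' node-positive, i.e. stages 2b/3); women 50 and older receive an aromatase
#' inhibitor. Chemotherapy is given for stages 2a-3 (carried as a flag; its
#' mortality effect is absorbed in the calibrated baseline). The
#' hazard-ratio pair is selected by age band and stage group.
#'
#' @param profiles data.frame from [sample_cohort()].
#' @param config An `eet_config`.
#' @return `profiles` with columns `regimen`, `chemo`, `hr_key`, `hr5`,
#'   `hr10` appended.
#' @export
assign_regimen <- function(profiles, config) {
  age <- profiles$age_dx
  if (any(age < 25 | age > 79)) stop("age at diagnosis must lie in [25, 79]")
  young <- age < 50
  nodal_pos <- profiles$nodal == "positive"
  regimen <- ifelse(young,
                    ifelse(nodal_pos, "tamoxifen_os", "tamoxifen"),
                    "aromatase_inhibitor")
  hr_key <- ifelse(young,
                   ifelse(profiles$stage == "stage1",
                          "age2549_stage1", "age2549_stage23"),
                   "age5079")
  hr <- config$hazard_ratios
  hr5 <- vapply(hr, `[[`, numeric(1), "hr5")[hr_key]
  hr10 <- vapply(hr, `[[`, numeric(1), "hr10")[hr_key]
  profiles$regimen <- regimen
  profiles$chemo <- profiles$stage != "stage1"
  profiles$hr_key <- hr_key
  profiles$hr5 <- unname(hr5)
  profiles$hr10 <- unname(hr10)
  profiles
}

#' Tail hazard multiplier for the 10-year strategy
#'
#' Solves `hr5 * Lambda5 + m_tail * (Lambda25 - Lambda5) = hr10 * Lambda25`
#' so the 10-year strategy reproduces its lifetime hazard ratio while both
#' arms share the 5-year-strategy multiplier over the first five years.
#'
#' @param hr5,hr10 Strategy-level hazard ratios.
#' @param Lambda5 Baseline cumulative hazard at year 5.
#' @param Lambda25 Baseline lifetime cumulative hazard.
#' @return `m_tail` for the ten-year arm (the five-year arm's tail
#'   multiplier is `hr5` itself).
#' @export
tail_multiplier <- function(hr5, hr10, Lambda5, Lambda25) {
  if (any(Lambda25 <= Lambda5) || any(Lambda5 < 0))
    stop("need Lambda25 > Lambda5 >= 0")
  m <- (hr10 * Lambda25 - hr5 * Lambda5) / (Lambda25 - Lambda5)
  if (any(m <= 0))
    stop("infeasible piecewise model: tail multiplier would be <= 0 ",
         "(hr10 too small relative to the hazard already accrued by year 5)")
  m
}

#' Effective hazard ratio under partial treatment completion
#'
#' Linear scaling on the hazard-reduction scale:
#' `hr_eff = 1 - c * (1 - hr)`; continuous and monotone in `c`, with
#' `c = 1` the published 100%-use base case and `hr_eff -> 1` as `c -> 0`.
#' @param hr Hazard ratio at full completion.
#' @param completion Completion fraction in (0, 1].
#' @export
hr_effective <- function(hr, completion) {
  if (any(completion <= 0 | completion > 1))
    stop("completion fraction must lie in (0, 1]")
  1 - completion * (1 - hr)
}

# Per-arm piecewise multipliers for given hazard-ratio vectors and the
# group's baseline F(5), honouring the completion schedule: c1 scales the
# shared early (and carried-over) hazard reduction, c2 scales the 10-year
# arm's incremental tail reduction.
arm_multiplier_set <- function(hr5, hr10, F5, completion) {
  c1 <- completion$c1; c2 <- completion$c2
  m_early <- hr_effective(hr5, c1)
  m_tail_base <- tail_multiplier(hr5, hr10, F5, 1)  # Lambda-free form
  m_tail_10 <- m_early + c2 * (m_tail_base - hr5)
  list(five_year = list(m_early = m_early, m_tail = m_early),
       ten_year = list(m_early = m_early, m_tail = m_tail_10))
}

# Vectorized piecewise inverse: given latent standard-exponential draws E,
# return whether a breast-cancer death occurs (E below the arm's lifetime
# cumulative hazard) and its time. Lower multipliers never give an earlier
# death for the same E (monotone coupling).
bc_death_time <- function(E, m_early, m_tail, Lambda_total, shape, tmax = 25) {
  stopifnot(all(E > 0))
  F5 <- weib_trunc_cdf(5, shape$k, shape$lambda, tmax)
  thr5 <- m_early * Lambda_total * F5
  thr25 <- thr5 + m_tail * Lambda_total * (1 - F5)
  death <- E < thr25
  q <- ifelse(E < thr5,
              E / (m_early * Lambda_total),
              F5 + (E - thr5) / (m_tail * Lambda_total))
  # shape$lambda may be per-woman; keep everything elementwise
  q <- pmin(pmax(q, 0), 1)
  t <- ifelse(death, weib_trunc_quantile(q, shape$k, shape$lambda, tmax), Inf)
  list(death = death, time = t)
}

#' Evaluate breast-cancer death under one arm's multipliers
#'
#' A woman dies of breast cancer (absent competing death) iff her latent
#' standard-exponential draw `E` falls below the arm's lifetime cumulative
#' hazard; the death time is the inverse of the piecewise-scaled cumulative
#' hazard at `E`. Sharing `E` across arms couples them monotonically.
#'
#' @param E Latent standard-exponential draw(s), `> 0`.
#' @param m_early Hazard multiplier on (0, 5].
#' @param m_tail Hazard multiplier on (5, `tmax`].
#' @param Lambda_total Baseline lifetime cumulative hazard (stratum level).
#' @param shape Time-shape list (`k`, `lambda`).
#' @param tmax No breast-cancer death after this many years (default 25).
#' @return list with logical `death` and numeric `time` (`Inf` when no
#'   breast-cancer death occurs).
#' @export
evaluate_bc_death <- function(E, m_early, m_tail, Lambda_total, shape,
                              tmax = 25) {
  bc_death_time(E, m_early, m_tail, Lambda_total, shape, tmax)
}

#' Scale adverse-event probabilities for a completion schedule
#'
#' The 5-year-window cumulative probability scales by `c1`; the 10-year
#' cumulative probability decomposes into the 0-5 window (scaled by `c1`)
#' plus the 5-10 increment (scaled by `c2`). Where the published 10-year
#' probability is below the 5-year one the increment is negative and is
#' scaled the same way.
#'
#' @param p5,p10 Cumulative probabilities (any common scale).
#' @param completion list with `c1`, `c2` in (0, 1].
#' @return list with `p5`, `p10` effective probabilities.
#' @export
apply_completion <- function(p5, p10, completion) {
  c1 <- completion$c1; c2 <- completion$c2
  if (any(c(c1, c2) <= 0) || any(c(c1, c2) > 1))
    stop("completion fractions must lie in (0, 1]")
  list(p5 = p5 * c1, p10 = pmax(p5 * c1 + (p10 - p5) * c2, 0))
}
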