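# Competing (other-cause) mortality. The default is a Gompertz-Makeham
# hazard mu(a) = alpha + beta * exp(gamma * a) with closed-form cumulative
# hazard H(a) = alpha*a + (beta/gamma) * (exp(gamma*a) - 1); a tabulated
# (age, annual hazard) table read from CSV can stand in for it. An optional
# multiplicative cohort shift per birth decade scales the whole hazard.

#' Build a competing-mortality life table
#'
#' Either a Gompertz-Makeham parametric table (the default parameters give a
#' remaining life expectancy of about 39 years at age 40 and 14 years at age
#' 70, approximating U.S. women; this is a synthetic stand-in, not a
#' published life table) or a tabulated table from a 2-column CSV
#' (integer age, annual hazard) with piecewise-constant hazards.
#'
#' @param alpha,beta,gamma Makeham parameters; `alpha`, `beta >= 0`,
#'   `gamma > 0`.
#' @param table Optional data.frame with columns `age`, `hazard` overriding
#'   the parametric form.
#' @param cohort_shift Optional named numeric vector of multiplicative hazard
#'   factors keyed by birth decade (e.g. `c("1940" = 1.1)`); unlisted decades
#'   use 1.
#' @return An object of class `eet_life_table`.
#' @export
build_life_table <- function(alpha = 5e-4, beta = 3e-5, gamma = 0.095,
                             table = NULL, cohort_shift = NULL) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (!is.null(table)) {
    stopifnot(all(c("age", "hazard") %in% names(table)))
    tab <- table[order(table$age), ]
    if (any(tab$hazard < 0)) stop("tabulated hazards must be >= 0")
    ages <- c(tab$age, 200)
    # cumulative hazard at the tabulated ages; last hazard extends beyond
    Hgrid <- c(0, cumsum(tab$hazard * diff(ages)))
    lt <- list(kind = "tabulated", ages = ages, hazard = tab$hazard,
               Hgrid = Hgrid, cohort_shift = cohort_shift)
  } else {
    lt <- list(kind = "makeham", alpha = alpha, beta = beta, gamma = gamma,
               cohort_shift = cohort_shift)
  }
  class(lt) <- "eet_life_table"
  lt
}

#' Read a life table from a 2-column CSV (age, annual hazard)
#' @param path CSV path with columns `age`, `hazard`.
#' @param ... Passed to [build_life_table()].
#' @export
read_life_table_csv <- function(path, ...) {
  build_life_table(table = read.csv(path), ...)
}

cohort_factor <- function(lt, birth_year = NULL) {
  cs <- lt$cohort_shift
  if (is.null(cs) || length(cs) == 0 || is.null(birth_year)) {
    return(rep(1, max(1, length(birth_year))))
  }
  dec <- as.character(10 * (birth_year %/% 10))
  f <- unname(cs[dec])
  f[is.na(f)] <- 1
  f
}

#' Cumulative other-cause mortality hazard at age `a`
#' @param lt An `eet_life_table`.
#' @param age Age in years (vectorized).
#' @param birth_year Optional birth years for the cohort shift.
#' @export
lt_cumhaz <- function(lt, age, birth_year = NULL) {
  f <- cohort_factor(lt, birth_year)
  if (lt$kind == "makeham") {
    H <- lt$alpha * age + lt$beta / lt$gamma * (exp(lt$gamma * age) - 1)
  } else {
    last <- length(lt$ages) - 1L
    i <- pmin(pmax(findInterval(age, lt$ages), 1L), last)
    H <- lt$Hgrid[i] + lt$hazard[i] * (age - lt$ages[i])
  }
  f * H
}

#' Other-cause survival to age `a`
#' @inheritParams lt_cumhaz
#' @export
lt_survival <- function(lt, age, birth_year = NULL) {
  exp(-lt_cumhaz(lt, age, birth_year))
}

# Invert H(a) = target (target on the unshifted scale). Vectorized; Makeham
# inversion by safeguarded Newton on the convex increasing cumulative hazard.
lt_inverse_cumhaz <- function(lt, target) {
  if (lt$kind == "tabulated") {
    last <- length(lt$ages) - 1L
    i <- pmin(pmax(findInterval(target, lt$Hgrid), 1L), last)
    h <- lt$hazard[i]
    a <- lt$ages[i] + ifelse(h > 0, (target - lt$Hgrid[i]) / h, Inf)
    return(pmin(a, 200))
  }
  al <- lt$alpha; be <- lt$beta; ga <- lt$gamma
  if (be == 0 && al == 0) return(rep(Inf, length(target)))
  if (be == 0) return(target / al)
  # initialize from the Gompertz part alone, then Newton
  a <- log(pmax(target * ga / be, 1e-12) + 1) / ga
  if (al > 0) a <- pmin(a, target / al)
  a <- pmin(pmax(a, 0), 200)
  for (i in 1:50) {
    f <- al * a + be / ga * (exp(ga * a) - 1) - target
    fp <- al + be * exp(ga * a)
    step <- f / fp
    a <- pmin(pmax(a - step, 0), 200)
    if (max(abs(step)) < 1e-12) break
  }
  a
}

#' Remaining life expectancy at a given age
#'
#' Numerical integration (trapezoid, 0.05-year grid) of the conditional
#' survival `S(a + t) / S(a)`.
#' @inheritParams lt_cumhaz
#' @export
lt_remaining_life_expectancy <- function(lt, age, birth_year = NULL) {
  vapply(seq_along(age), function(k) {
    tt <- seq(0, 120, by = 0.05)
    s <- exp(-(lt_cumhaz(lt, age[k] + tt, birth_year[k]) -
                 lt_cumhaz(lt, age[k], birth_year[k])))
    sum((s[-1] + s[-length(s)]) / 2) * 0.05
  }, numeric(1))
}

#' Sample an other-cause death age by inverse transform
#'
#' Draws from the distribution of death age conditional on being alive at
#' `age_dx`: the returned age `a` solves
#' `H(a) = H(age_dx) - ln(1 - u) / shift`. Monotone increasing in `u`;
#' capped at 120 years.
#'
#' @param age_dx Age(s) at diagnosis.
#' @param lt An `eet_life_table`.
#' @param u Uniform(0,1) draw(s), strictly inside the unit interval.
#' @param birth_year Optional birth years for the cohort shift.
#' @return Death age(s), `> age_dx`, `<= 120`.
#' @export
sample_other_cause_death_age <- function(age_dx, lt, u, birth_year = NULL) {
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly inside (0, 1)")
  f <- cohort_factor(lt, birth_year)
  target <- lt_cumhaz(lt, age_dx) + (-log(1 - u)) / f
  a <- lt_inverse_cumhaz(lt, target)
  pmax(pmin(a, 120), age_dx + 1e-9)
}

life_table_from_config <- function(config) {
  ltc <- config$life_table
  cs <- if (length(ltc$cohort_shift) > 0) ltc$cohort_shift else NULL
  if (!is.null(ltc$csv_path) && nzchar(ltc$csv_path)) {
    read_life_table_csv(ltc$csv_path, cohort_shift = cs)
  } else {
    build_life_table(ltc$alpha, ltc$beta, ltc$gamma, cohort_shift = cs)
  }
}
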