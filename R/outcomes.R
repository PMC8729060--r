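# Paired life histories and outcome integration. Each woman's two arms
# share every random draw (latent breast-cancer exponential, other-cause
# uniform, adverse-event occurrence and onset uniforms), so between-arm
# contrasts are paired. Quality-adjusted survival integrates a
# piecewise-constant utility: age-band utility at current age x stage
# utility x the product of active toxicity multipliers, discounted
# continuously from diagnosis.

AGE_BAND_BREAKS <- seq(30, 80, by = 10)

disc_integral <- function(t1, t2, r) {
  if (r == 0) return(t2 - t1)
  (exp(-r * t1) - exp(-r * t2)) / r
}

horizon_years <- function(config) {
  if (identical(config$horizon, "15y")) 15 else Inf
}

# ---- vectorized paired simulation ------------------------------------------

# Simulate both arms for a chunk of profiles under shared draws.
simulate_pair_chunk <- function(profiles, calib, config, seed, stream_tag = "",
                                mortality_only = FALSE) {
  n <- nrow(profiles)
  prof <- assign_regimen(profiles, config)
  grp <- group_of_age(prof$age_dx)
  if (!all(unique(grp) %in% names(calib)))
    stop("missing calibration for age group(s): ",
         paste(setdiff(unique(grp), names(calib)), collapse = ", "))

  Lb <- vapply(calib, `[[`, numeric(1), "Lambda_base")[grp]
  lamv <- vapply(calib, function(cc) cc$shape$lambda, numeric(1))[grp]
  kv <- vapply(calib, function(cc) cc$shape$k, numeric(1))[grp]
  shape_v <- list(k = unname(kv), lambda = unname(lamv))
  npm <- ifelse(prof$nodal == "positive", config$node_pos_multiplier, 1)
  Ltot <- unname(Lb) * npm
  tmax <- config$max_bc_death_year

  F5 <- weib_trunc_cdf(5, shape_v$k, shape_v$lambda, tmax)
  m_tail_base <- tail_multiplier(prof$hr5, prof$hr10, F5, 1)
  c1 <- config$completion$c1; c2 <- config$completion$c2
  m_early <- hr_effective(prof$hr5, c1)
  m_tail_10 <- m_early + c2 * (m_tail_base - prof$hr5)

  E <- -log(substream_runif(seed, paste0("latent_bc", stream_tag), n))
  u_oc <- substream_runif(seed, paste0("other_cause", stream_tag), n)
  lt <- life_table_from_config(config)
  oc_age <- sample_other_cause_death_age(prof$age_dx, lt, u_oc,
                                         prof$birth_year)
  t_oc <- oc_age - prof$age_dx
  hz <- horizon_years(config)

  one_arm <- function(arm) {
    m_tail <- if (arm == "five_year") m_early else m_tail_10
    bc <- bc_death_time(E, m_early, m_tail, Ltot, shape_v, tmax)
    cause_bc <- bc$death & bc$time <= t_oc
    t_death <- pmin(ifelse(bc$death, bc$time, Inf), t_oc)
    T_int <- pmin(t_death, hz)
    bc_ind <- cause_bc & bc$time <= hz
    rec <- data.table::data.table(
      id = prof$id, arm = arm,
      bc_time = ifelse(bc$death, bc$time, NA_real_),
      oc_death_age = oc_age,
      t_death = t_death,
      cause = ifelse(cause_bc, "breast_cancer", "other"),
      bc_death = bc_ind, ly = T_int)
    if (mortality_only) return(list(records = rec, ae = NULL))
    ae <- sample_adverse_events(prof, config, arm, seed, stream_tag)
    out <- integrate_outcomes_vec(T_int, prof$age_dx, prof$stage, ae, config)
    rec[, c("ly_disc", "qaly", "qaly_disc") :=
          list(out$ly_disc, out$qaly, out$qaly_disc)]
    list(records = rec, ae = ae)
  }

  five <- one_arm("five_year")
  ten <- one_arm("ten_year")
  list(profiles = prof, five = five, ten = ten)
}

# Vectorized integration of (discounted) quality-adjusted survival.
# T_int: integration endpoint per woman (death clipped at horizon);
# ae: data.table from sample_adverse_events (idx indexes rows here).
integrate_outcomes_vec <- function(T_int, age_dx, stage, ae, config) {
  if (!identical(config$discounting, "continuous"))
    stop("the vectorized cohort integrator supports continuous discounting ",
         "only; use compute_outcomes() for annual-step discounting")
  r <- config$discount_rate
  n <- length(T_int)
  ub <- unname(config$utilities$age_band)
  ustage <- unname(config$utilities$stage[stage])

  ly <- T_int
  ly_disc <- if (r == 0) T_int else (1 - exp(-r * T_int)) / r

  # base (no-toxicity) quality-adjusted survival, by age band
  lo_edges <- c(0, AGE_BAND_BREAKS)
  hi_edges <- c(AGE_BAND_BREAKS, Inf)
  qaly <- numeric(n); qaly_disc <- numeric(n)
  for (b in seq_along(ub)) {
    t1 <- pmax(0, lo_edges[b] - age_dx)
    t2 <- pmin(T_int, hi_edges[b] - age_dx)
    keep <- t2 > t1
    if (!any(keep)) next
    t1 <- t1[keep]; t2 <- t2[keep]
    qaly[keep] <- qaly[keep] + ub[b] * (t2 - t1)
    qaly_disc[keep] <- qaly_disc[keep] + ub[b] * disc_integral(t1, t2, r)
  }
  qaly <- qaly * ustage
  qaly_disc <- qaly_disc * ustage

  if (!is.null(ae) && nrow(ae) > 0) {
    seg <- data.table::copy(ae)
    seg[, Ti := T_int[idx]]
    seg <- seg[start < Ti & mult < 1]
    if (nrow(seg) > 0) {
      seg[, e := pmin(end, Ti)]
      widx <- unique(seg$idx)
      bp <- data.table::rbindlist(list(
        seg[, .(idx, t = start, dlog = log(mult))],
        seg[, .(idx, t = e, dlog = -log(mult))],
        data.table::data.table(idx = widx, t = 0, dlog = 0),
        data.table::data.table(idx = widx, t = T_int[widx], dlog = 0)
      ))
      # age-band crossing times inside (0, T) for affected women
      for (b in AGE_BAND_BREAKS) {
        tc <- b - age_dx[widx]
        k <- tc > 0 & tc < T_int[widx]
        if (any(k)) bp <- rbind(bp, data.table::data.table(
          idx = widx[k], t = tc[k], dlog = 0))
      }
      data.table::setorder(bp, idx, t)
      bp[, lvl := pmin(cumsum(dlog), 0), by = idx]
      bp[, t2 := data.table::shift(t, -1L), by = idx]
      bp <- bp[!is.na(t2) & t2 > t]
      band <- findInterval(age_dx[bp$idx] + bp$t, AGE_BAND_BREAKS) + 1L
      u <- ustage[bp$idx] * ub[band] * exp(bp$lvl)
      und <- u * (bp$t2 - bp$t)
      dsc <- u * disc_integral(bp$t, bp$t2, r)
      agg <- data.table::data.table(idx = bp$idx, und = und, dsc = dsc)
      agg <- agg[, .(und = sum(und), dsc = sum(dsc)), by = idx]
      qaly[agg$idx] <- agg$und
      qaly_disc[agg$idx] <- agg$dsc
    }
  }
  list(ly = ly, ly_disc = ly_disc, qaly = qaly, qaly_disc = qaly_disc)
}

# ---- scalar reference path --------------------------------------------------

#' Simulate one woman's life history under one arm
#'
#' Scalar wrapper around the paired-cohort machinery: the same substreams
#' are used, so the returned history for one arm is identical whether or not
#' the other arm is also realized.
#'
#' @param profile One-row data.frame from [sample_cohort()].
#' @param arm `"five_year"` or `"ten_year"`.
#' @param calib An `eet_calibration`.
#' @param config An `eet_config`.
#' @param seed Master seed (defaults to `config$master_seed`).
#' @return A `LifeHistory` list: `profile`, `arm`, `bc_death_time` (`NA`
#'   when no breast-cancer death), `oc_death_age`, `realized_death_age`,
#'   `cause`, `events` (data.frame of dated utility decrements).
#' @export
simulate_life_history <- function(profile, arm, calib, config, seed = NULL) {
  if (is.null(seed)) seed <- config$master_seed
  stopifnot(nrow(profile) == 1)
  sim <- simulate_pair_chunk(profile, calib, config, seed,
                             stream_tag = "_single")
  res <- if (arm == "five_year") sim$five else sim$ten
  rec <- res$records
  ev <- as.data.frame(res$ae[, .(event, onset, start, end, mult)])
  structure(list(
    profile = sim$profiles,
    arm = arm,
    bc_death_time = rec$bc_time,
    oc_death_age = rec$oc_death_age,
    realized_death_age = sim$profiles$age_dx + rec$t_death,
    t_death = rec$t_death,
    cause = rec$cause,
    events = ev
  ), class = "eet_life_history")
}

#' Piecewise-constant utility trajectory for one life history
#'
#' At time `t` since diagnosis the utility is the age-band utility at the
#' woman's current age times her stage utility times the product of all
#' active toxicity multipliers. Breakpoints occur at age-band boundaries and
#' event starts/ends; the trajectory ends at death (or the horizon).
#'
#' @param history An `eet_life_history` (or a list with `profile`, `t_death`,
#'   `events`).
#' @param config An `eet_config`.
#' @param horizon_end Optional integration end; defaults to time of death
#'   clipped at the configured horizon.
#' @return data.frame with columns `start`, `end`, `utility`.
#' @export
utility_trajectory <- function(history, config, horizon_end = NULL) {
  Tend <- min(history$t_death, horizon_years(config))
  if (!is.null(horizon_end)) Tend <- min(Tend, horizon_end)
  age_dx <- history$profile$age_dx
  ustage <- unname(config$utilities$stage[history$profile$stage])
  ub <- unname(config$utilities$age_band)
  ev <- history$events
  bps <- c(0, Tend, AGE_BAND_BREAKS - age_dx)
  if (!is.null(ev) && nrow(ev) > 0) {
    bps <- c(bps, ev$start, pmin(ev$end, Tend))
  }
  bps <- sort(unique(bps[bps >= 0 & bps <= Tend]))
  if (length(bps) < 2) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      utility = numeric(0)))
  }
  s <- bps[-length(bps)]; e <- bps[-1]
  u <- vapply(seq_along(s), function(i) {
    tm <- (s[i] + e[i]) / 2
    band <- findInterval(age_dx + tm, AGE_BAND_BREAKS) + 1L
    tox <- 1
    if (!is.null(ev) && nrow(ev) > 0) {
      act <- ev$start <= tm & ev$end > tm
      if (any(act)) tox <- prod(ev$mult[act])
    }
    ustage * ub[band] * tox
  }, numeric(1))
  data.frame(start = s, end = e, utility = u)
}

#' Integrate outcomes for one life history
#'
#' Life-years are the survival time from diagnosis (clipped at the horizon);
#' QALYs integrate the utility trajectory; discounted variants weight by
#' `exp(-r t)` (continuous, from diagnosis) or, with
#' `config$discounting = "annual"`, by `(1 + r)^{-floor(t)}` per year lived.
#' With a 15-year horizon both the integration and the breast-cancer death
#' attribution are clipped at `t = 15`.
#'
#' @param history An `eet_life_history`.
#' @param config An `eet_config`.
#' @return list with `ly`, `ly_disc`, `qaly`, `qaly_disc`, `bc_death`,
#'   `horizon`.
#' @export
compute_outcomes <- function(history, config) {
  r <- config$discount_rate
  hz <- horizon_years(config)
  Tend <- min(history$t_death, hz)
  traj <- utility_trajectory(history, config)
  annual <- identical(config$discounting, "annual")

  seg_disc <- function(a, b) {
    if (!annual) return(disc_integral(a, b, r))
    # split [a, b) at integer years; weight each piece by (1+r)^(-year)
    if (r == 0) return(b - a)
    cuts <- unique(c(a, seq(ceiling(a), floor(b)), b))
    cuts <- cuts[cuts >= a & cuts <= b]
    if (length(cuts) < 2) cuts <- c(a, b)
    sum(vapply(seq_len(length(cuts) - 1), function(i) {
      (cuts[i + 1] - cuts[i]) * (1 + r)^(-floor(cuts[i]))
    }, numeric(1)))
  }

  ly <- Tend
  ly_disc <- seg_disc(0, Tend)
  qaly <- sum(traj$utility * (traj$end - traj$start))
  qaly_disc <- sum(vapply(seq_len(nrow(traj)), function(i) {
    traj$utility[i] * seg_disc(traj$start[i], traj$end[i])
  }, numeric(1)))
  bc_death <- identical(history$cause, "breast_cancer") &&
    !is.na(history$bc_death_time) && history$bc_death_time <= hz
  list(ly = ly, ly_disc = ly_disc, qaly = qaly, qaly_disc = qaly_disc,
       bc_death = bc_death, horizon = config$horizon)
}

# ---- aggregation ------------------------------------------------------------

OUTCOME_METRICS <- c("bc_death", "ly", "ly_disc", "qaly", "qaly_disc")

# per-cell sufficient statistics for one simulated chunk
chunk_cell_stats <- function(sim, mortality_only = FALSE) {
  metrics <- if (mortality_only) "bc_death" else OUTCOME_METRICS
  prof <- sim$profiles
  f <- sim$five$records; t <- sim$ten$records
  dt <- data.table::data.table(band = prof$age_band, nodal = prof$nodal)
  for (m in metrics) {
    a5 <- as.numeric(f[[m]]); a10 <- as.numeric(t[[m]])
    dt[, paste0(m, "_5") := a5]
    dt[, paste0(m, "_10") := a10]
    dt[, paste0(m, "_d") := a10 - a5]
    dt[, paste0(m, "_d2") := (a10 - a5)^2]
    dt[, paste0(m, "_s52") := a5^2]
    dt[, paste0(m, "_s102") := a10^2]
  }
  cols <- setdiff(names(dt), c("band", "nodal"))
  out <- dt[, c(lapply(.SD, sum), .N), by = .(band, nodal), .SDcols = cols]
  data.table::setnames(out, "N", "n")
  out
}

combine_cell_stats <- function(stats_list) {
  all_ <- data.table::rbindlist(stats_list)
  cols <- setdiff(names(all_), c("band", "nodal"))
  all_[, lapply(.SD, sum), by = .(band, nodal), .SDcols = cols]
}

# expand cells to the reporting strata and finalize means / paired SEs
finalize_summary <- function(cells, mortality_only = FALSE) {
  metrics <- if (mortality_only) "bc_death" else OUTCOME_METRICS
  young_bands <- c("b20", "b30", "b40")
  strata <- list(
    all = cells,
    age2549 = cells[band %in% young_bands],
    age5079 = cells[!band %in% young_bands],
    age2549_node_negative = cells[band %in% young_bands & nodal == "negative"],
    age2549_node_positive = cells[band %in% young_bands & nodal == "positive"]
  )
  for (b in c("b50", "b60", "b70")) {
    strata[[paste0("age", sub("b", "", b), "s")]] <- cells[band == b]
    strata[[paste0("age", sub("b", "", b), "s_node_negative")]] <-
      cells[band == b & nodal == "negative"]
    strata[[paste0("age", sub("b", "", b), "s_node_positive")]] <-
      cells[band == b & nodal == "positive"]
  }
  rows <- list()
  for (snm in names(strata)) {
    cc <- strata[[snm]]
    if (nrow(cc) == 0) next
    n <- sum(cc$n)
    for (m in metrics) {
      s5 <- sum(cc[[paste0(m, "_5")]]); s10 <- sum(cc[[paste0(m, "_10")]])
      sdiff <- sum(cc[[paste0(m, "_d")]]); sd2 <- sum(cc[[paste0(m, "_d2")]])
      s52 <- sum(cc[[paste0(m, "_s52")]]); s102 <- sum(cc[[paste0(m, "_s102")]])
      vard <- pmax(sd2 / n - (sdiff / n)^2, 0)
      var5 <- pmax(s52 / n - (s5 / n)^2, 0)
      var10 <- pmax(s102 / n - (s10 / n)^2, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = snm, metric = m, n = n,
        mean_5y = s5 / n, mean_10y = s10 / n,
        diff = sdiff / n,
        se_diff = sqrt(vard / n),
        se_unpaired = sqrt((var5 + var10) / n),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate paired records into a cohort summary
#'
#' @param sim Output of the internal paired simulation (list with
#'   `profiles`, `five`, `ten`) — exposed for testing on small cohorts.
#' @param mortality_only Aggregate only the mortality metric.
#' @return data.frame with per-stratum per-metric means, paired differences
#'   (10-year minus 5-year), Monte-Carlo paired and unpaired SEs.
#' @export
aggregate_outcomes <- function(sim, mortality_only = FALSE) {
  finalize_summary(chunk_cell_stats(sim, mortality_only), mortality_only)
}

#' Compare 5 versus 10 years of endocrine therapy on a simulated cohort
#'
#' Calibrates the baseline model (unless a calibration is supplied), then
#' simulates the configured cohort in chunks with both treatment durations
#' realized per woman under common random numbers, and aggregates lifetime
#' (or 15-year) outcomes overall and by age band and nodal status.
#'
#' @param config An `eet_config`.
#' @param calib Optional `eet_calibration`; computed from `config` when
#'   `NULL`.
#' @param n Number of women (defaults to `config$n_women`).
#' @param mortality_only Skip adverse events and QALY integration (faster).
#' @param keep_records Also return the per-woman record tables (only
#'   sensible for small `n`).
#' @return An `eet_comparison`: list with `summary` (see
#'   [aggregate_outcomes()]), `n`, `calib`, and optionally `records`.
#' @export
compare_durations <- function(config, calib = NULL, n = NULL,
                              mortality_only = FALSE, keep_records = FALSE) {
  if (is.null(n)) n <- config$n_women
  if (is.null(calib)) calib <- calibrate_model(config)
  seed <- config$master_seed
  chunk <- max(1, min(config$chunk_size, n))
  starts <- seq(0, n - 1, by = chunk)
  stats <- vector("list", length(starts))
  recs <- if (keep_records) vector("list", length(starts)) else NULL
  for (i in seq_along(starts)) {
    ni <- min(chunk, n - starts[i])
    prof <- sample_cohort(config, n = ni, seed = seed,
                          id_offset = starts[i],
                          stream_tag = paste0("#", i))
    sim <- simulate_pair_chunk(prof, calib, config, seed,
                               stream_tag = paste0("#", i),
                               mortality_only = mortality_only)
    stats[[i]] <- chunk_cell_stats(sim, mortality_only)
    if (keep_records) recs[[i]] <- sim
  }
  summary_ <- finalize_summary(combine_cell_stats(stats), mortality_only)
  out <- list(summary = summary_, n = n, calib = calib,
              horizon = config$horizon)
  if (keep_records) out$records <- recs
  class(out) <- c("eet_comparison", "list")
  out
}

#' @export
print.eet_comparison <- function(x, ...) {
  cat("Endocrine therapy duration comparison (10-year minus 5-year), n =",
      format(x$n, big.mark = ","), "women, horizon:", x$horizon, "\n\n")
  s <- x$summary
  s$mean_5y <- ifelse(s$metric == "bc_death",
                      sprintf("%.2f%%", 100 * s$mean_5y),
                      sprintf("%.2f", s$mean_5y))
  s$mean_10y <- ifelse(s$metric == "bc_death",
                       sprintf("%.2f%%", 100 * as.numeric(s$mean_10y)),
                       sprintf("%.2f", as.numeric(s$mean_10y)))
  s$diff <- ifelse(s$metric == "bc_death",
                   sprintf("%.2f%%", 100 * as.numeric(s$diff)),
                   sprintf("%.2f", as.numeric(s$diff)))
  print(s[, c("stratum", "metric", "mean_5y", "mean_10y", "diff", "n")],
        row.names = FALSE)
  invisible(x)
}

#' Extract one summary value from a comparison
#' @param comparison An `eet_comparison`.
#' @param metric One of `bc_death`, `ly`, `ly_disc`, `qaly`, `qaly_disc`.
#' @param stratum Stratum name (default `"all"`).
#' @param what `"diff"`, `"mean_5y"`, `"mean_10y"`, or `"se_diff"`.
#' @export
comparison_value <- function(comparison, metric, stratum = "all",
                             what = "diff") {
  s <- comparison$summary
  row <- s[s$stratum == stratum & s$metric == metric, ]
  if (nrow(row) != 1) stop("no unique row for ", stratum, "/", metric)
  row[[what]]
}
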