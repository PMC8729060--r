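# Sensitivity machinery. One-way sweeps move one parameter family across its
# published range (adverse-event utilities, durations, or probabilities —
# the latter scaled proportionally across events so the column total tracks
# its published range); two-way best/worst combine the duration and utility
# extremes; completion scenarios rescale efficacy and adverse-event
# probabilities together. All runs share the same seeds and the same
# calibration, so the base-case point of every sweep is bit-identical and
# between-scenario contrasts carry no extra Monte-Carlo noise from cohort
# resampling.

at_value <- function(base, range, at) {
  if (is.character(at) && !at %in% c("low", "base", "high")) {
    num <- suppressWarnings(as.numeric(at))
    if (!is.na(num)) at <- num
  }
  if (identical(at, "base")) return(base)
  if (identical(at, "low")) return(range[1])
  if (identical(at, "high")) return(range[2])
  if (is.numeric(at) && at >= 0 && at <= 1)
    return(range[1] + at * (range[2] - range[1]))
  stop("sweep point must be 'low', 'base', 'high' or a fraction in [0, 1]")
}

#' Build a perturbed configuration for a sensitivity point
#'
#' @param config An `eet_config`.
#' @param param One of `"ae_utility"`, `"ae_duration"`, `"ae_probability"`.
#' @param at `"low"`, `"base"`, `"high"`, or a fraction in `[0, 1]`
#'   interpolating low to high (utilities/probabilities only).
#' @return A modified `eet_config`.
#' @export
sweep_config <- function(config, param, at) {
  if (identical(at, "base")) return(config)
  cfg <- config
  if (param == "ae_utility") {
    for (ev in names(cfg$adverse_events$grade34)) {
      spec <- cfg$adverse_events$grade34[[ev]]
      spec$utility <- at_value(spec$utility, spec$utility_range, at)
      if (!is.na(spec$utility_continuing)) {
        spec$utility_continuing <- at_value(spec$utility_continuing,
                                            spec$utility_continuing_range, at)
      }
      cfg$adverse_events$grade34[[ev]] <- spec
    }
    g12 <- cfg$adverse_events$grade12
    g12$utility_grade1 <- at_value(g12$utility_grade1,
                                   g12$utility_grade1_range, at)
    g12$utility_grade2 <- at_value(g12$utility_grade2,
                                   g12$utility_grade2_range, at)
    cfg$adverse_events$grade12 <- g12
  } else if (param == "ae_duration") {
    if (!at %in% c("low", "high"))
      stop("duration sweeps support 'low', 'base' or 'high' only")
    for (ev in names(cfg$adverse_events$grade34)) {
      spec <- cfg$adverse_events$grade34[[ev]]
      if (identical(spec$duration$kind, "fixed") &&
          is.finite(spec$duration$range_low)) {
        spec$duration$years <- if (at == "low") spec$duration$range_low
                               else spec$duration$range_high
        cfg$adverse_events$grade34[[ev]] <- spec
      }
    }
    g12 <- cfg$adverse_events$grade12
    if (at == "low") {
      g12$duration$kind <- "fixed"
      g12$duration$years <- as.numeric(g12$duration$range_low)
    } else {
      # published upper bound: the full treatment duration
      g12$duration$kind <- "span_treatment_duration"
    }
    cfg$adverse_events$grade12 <- g12
  } else if (param == "ae_probability") {
    tot <- cfg$adverse_events$grade34_printed_total
    for (rg in REGIMENS) {
      f5 <- at_value(tot[[rg]]$p5, tot[[rg]]$p5_range, at) / tot[[rg]]$p5
      f10 <- at_value(tot[[rg]]$p10, tot[[rg]]$p10_range, at) / tot[[rg]]$p10
      for (ev in names(cfg$adverse_events$grade34)) {
        p <- cfg$adverse_events$grade34[[ev]]$prob[[rg]]
        p$p5 <- min(p$p5 * f5, 100)
        p$p10 <- min(p$p10 * f10, 100)
        cfg$adverse_events$grade34[[ev]]$prob[[rg]] <- p
      }
      q <- cfg$adverse_events$grade12$prob[[rg]]
      q$p5 <- at_value(q$p5, q$p5_range, at)
      q$p10 <- at_value(q$p10, q$p10_range, at)
      cfg$adverse_events$grade12$prob[[rg]] <- q
    }
  } else {
    stop("unknown sweep parameter: '", param, "'")
  }
  cfg
}

run_increment <- function(config, calib, n) {
  cmp <- compare_durations(config, calib = calib, n = n)
  comparison_value(cmp, "qaly_disc", "all", "diff")
}

#' One-way sensitivity sweep
#'
#' Re-simulates the paired comparison at each sweep point under identical
#' seeds and the base-case calibration, varying only the named parameter
#' family.
#'
#' @param config An `eet_config`.
#' @param spec list with `param` (see [sweep_config()]), optional `points`
#'   (default `c("low", "base", "high")`) and `label`.
#' @param calib Optional `eet_calibration` (computed once when `NULL`).
#' @param n Cohort size per point (defaults to `config$n_women`).
#' @return An `eet_sensitivity` data.frame: `label`, `point`, `increment`
#'   (10-vs-5-year discounted QALYs), with attributes `base_increment` and
#'   `sign_flip`.
#' @export
one_way_sweep <- function(config, spec, calib = NULL, n = NULL) {
  if (is.null(calib)) calib <- calibrate_model(config)
  if (is.null(n)) n <- config$n_women
  points <- if (!is.null(spec$points)) spec$points else c("low", "base", "high")
  label <- if (!is.null(spec$label)) spec$label else spec$param
  inc <- vapply(points, function(at) {
    run_increment(sweep_config(config, spec$param, at), calib, n)
  }, numeric(1))
  base_inc <- if ("base" %in% points) inc[[which(points == "base")[1]]]
              else run_increment(config, calib, n)
  out <- data.frame(label = label, point = as.character(points),
                    increment = unname(inc), stringsAsFactors = FALSE)
  attr(out, "base_increment") <- base_inc
  attr(out, "sign_flip") <- any(sign(inc[inc != 0]) != sign(base_inc))
  class(out) <- c("eet_sensitivity", "data.frame")
  out
}

#' Two-way best/worst-case sensitivity analysis
#'
#' Worst case: longest adverse-event durations combined with lowest utility
#' values; best case: shortest durations with highest utilities. Run under
#' the same seeds as the base case, which they bracket by construction.
#'
#' @inheritParams one_way_sweep
#' @return list of `eet_sensitivity` rows: `worst`, `base`, `best`
#'   increments (discounted QALYs, 10-year minus 5-year).
#' @export
two_way_best_worst <- function(config, calib = NULL, n = NULL) {
  if (is.null(calib)) calib <- calibrate_model(config)
  if (is.null(n)) n <- config$n_women
  worst_cfg <- sweep_config(sweep_config(config, "ae_duration", "high"),
                            "ae_utility", "low")
  best_cfg <- sweep_config(sweep_config(config, "ae_duration", "low"),
                           "ae_utility", "high")
  list(
    worst = run_increment(worst_cfg, calib, n),
    base = run_increment(config, calib, n),
    best = run_increment(best_cfg, calib, n)
  )
}

#' Completion-rate scenarios
#'
#' Each schedule `(c1, c2)` scales the hazard reduction and adverse-event
#' probabilities of the 0-5 and 5-10-year windows respectively.
#'
#' @param config An `eet_config`.
#' @param schedules list of length-2 numeric vectors `(c1, c2)`.
#' @inheritParams one_way_sweep
#' @return An `eet_sensitivity` data.frame with one row per schedule.
#' @export
completion_scenarios <- function(config, schedules, calib = NULL, n = NULL) {
  if (is.null(calib)) calib <- calibrate_model(config)
  if (is.null(n)) n <- config$n_women
  rows <- lapply(schedules, function(sc) {
    cfg <- config
    cfg$completion <- list(c1 = sc[1], c2 = sc[2])
    data.frame(label = sprintf("completion_%g_%g", sc[1], sc[2]),
               point = sprintf("(%g, %g)", sc[1], sc[2]),
               increment = run_increment(cfg, calib, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "base_increment") <- run_increment(config, calib, n)
  class(out) <- c("eet_sensitivity", "data.frame")
  out
}

#' Tornado table
#'
#' Orders scenarios by the largest absolute deviation of their incremental
#' discounted QALYs from the base case, descending; ties broken
#' alphabetically by label.
#'
#' @param results list of `eet_sensitivity` objects (each sharing a
#'   `base_increment` attribute).
#' @param path Optional CSV output path.
#' @return data.frame: `label`, `inc_low`, `inc_high`, `base_increment`,
#'   `max_abs_deviation`, sorted.
#' @export
tornado_table <- function(results, path = NULL) {
  if (length(results) == 0) {
    out <- data.frame(label = character(0), inc_low = numeric(0),
                      inc_high = numeric(0), base_increment = numeric(0),
                      max_abs_deviation = numeric(0))
    if (!is.null(path)) write.csv(out, path, row.names = FALSE)
    return(out)
  }
  rows <- lapply(results, function(res) {
    base <- attr(res, "base_increment")
    inc <- res$increment
    data.frame(label = res$label[1],
               inc_low = inc[which.min(inc)],
               inc_high = inc[which.max(inc)],
               base_increment = base,
               max_abs_deviation = max(abs(inc - base)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$max_abs_deviation, out$label), ]
  rownames(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
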