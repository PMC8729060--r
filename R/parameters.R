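# Model inputs: treatment-effect hazard ratios by age band and stage group,
# adverse-event probabilities by regimen and treatment duration (cumulative
# over the 0-5 or 0-10 year window, in percent as published), toxicity
# utilities with sensitivity ranges, age-band and stage utilities, cohort and
# run-time settings. Probabilities are stored in percent and converted to
# fractions at the point of use.

AE_EVENTS_G34 <- c("stroke", "pulmonary_embolus", "new_cardiac_condition",
                   "fracture", "endometrial_cancer", "osteoporosis")
REGIMENS <- c("tamoxifen", "tamoxifen_os", "aromatase_inhibitor")

ae_prob_entry <- function(p5, p5r, p10, p10r) {
  list(p5 = p5, p5_range = p5r, p10 = p10, p10_range = p10r)
}

#' Bundled default scenario configuration
#'
#' Returns the full set of model inputs: hazard-ratio pairs for the 5- and
#' 10-year strategies by age band and stage group, grade 3-4 and pooled
#' grade 1-2 adverse-event probabilities per regimen and duration (cumulative
#' percent, with sensitivity ranges), toxicity utilities and durations,
#' age-band and stage utilities, the synthetic cohort specification, the
#' Gompertz-Makeham competing-mortality parameters, calibration targets
#' (lifetime breast-cancer mortality in the 5-year arm and the 15-year share
#' of the between-arm mortality difference), discounting and horizon settings.
#'
#' @return A nested named list of class `eet_config`.
#' @export
default_config <- function() {
  cfg <- list(
    n_women = 100000,
    master_seed = 1L,
    discount_rate = 0.03,
    discounting = "continuous",      # "annual" supported in compute_outcomes()
    horizon = "lifetime",            # or "15y"
    max_bc_death_year = 25,
    completion = list(c1 = 1.0, c2 = 1.0),
    node_pos_multiplier = 2.5,
    grade12_events_per_affected = 2,
    chunk_size = 500000,
    cohort = list(
      age_range = c(25, 79),
      age_mean = 61,
      age_sd = 13,
      birth_cohort_range = c(1935, 2009),
      stage_distribution = c(stage1 = 0.45, stage2a = 0.25,
                             stage2b = 0.18, stage3 = 0.12)
    ),
    life_table = list(alpha = 5e-4, beta = 3e-5, gamma = 0.095,
                      csv_path = "", cohort_shift = numeric(0)),
    hazard_ratios = list(
      age2549_stage1 = list(hr5 = 0.70, hr5_range = c(0.66, 0.88),
                            hr10 = 0.54, hr10_range = c(0.51, 0.68)),
      age2549_stage23 = list(hr5 = 0.66, hr5_range = c(0.62, 0.84),
                             hr10 = 0.50, hr10_range = c(0.47, 0.64)),
      age5079 = list(hr5 = 0.55, hr5_range = c(0.46, 0.72),
                     hr10 = 0.54, hr10_range = c(NA_real_, NA_real_))
    ),
    calibration = list(
      target_p5 = c(age2549 = 0.1191, age5079 = 0.1020),
      share_15y = c(age2549 = 2.13 / 2.63, age5079 = 0.10 / 0.16),
      weibull_k = 1,
      n_sim = 500000,
      calib_seed = 104729L
    ),
    utilities = list(
      age_band = c(b20 = 0.913, b30 = 0.893, b40 = 0.863, b50 = 0.837,
                   b60 = 0.811, b70 = 0.771, b80 = 0.724),
      stage = c(stage1 = 0.9, stage2a = 0.85, stage2b = 0.85,
                stage3 = 0.8, stage4 = 0.4)
    ),
    adverse_events = list(
      grade34 = list(
        stroke = list(
          prob = list(
            tamoxifen = ae_prob_entry(1.85, c(1.75, 2.17), 2.01, c(1.67, 2.48)),
            tamoxifen_os = ae_prob_entry(1.85, c(1.68, 2.02), 2.01, c(1.84, 2.21)),
            aromatase_inhibitor = ae_prob_entry(1.85, c(1.69, 1.98), 2.01, c(1.85, 2.13))
          ),
          utility = 0.7, utility_range = c(0.6, 0.8),
          utility_continuing = 0.85, utility_continuing_range = c(0.75, 0.95),
          duration = list(kind = "first_year_then_lifetime", years = 1,
                          range_low = 1, range_high = 1)
        ),
        pulmonary_embolus = list(
          prob = list(
            tamoxifen = ae_prob_entry(3.03, c(2.86, 3.56), 5.87, c(4.89, 7.26)),
            tamoxifen_os = ae_prob_entry(2.30, c(2.09, 2.51), 4.46, c(4.08, 4.90)),
            aromatase_inhibitor = ae_prob_entry(0.83, c(0.76, 0.89), 0.80, c(0.74, 0.85))
          ),
          utility = 0.65, utility_range = c(0.6, 0.7),
          utility_continuing = NA_real_,
          utility_continuing_range = c(NA_real_, NA_real_),
          duration = list(kind = "fixed", years = 0.75,
                          range_low = 0.5, range_high = 1)
        ),
        new_cardiac_condition = list(
          prob = list(
            tamoxifen = ae_prob_entry(2.53, c(2.39, 2.97), 1.97, c(1.64, 2.44)),
            tamoxifen_os = ae_prob_entry(2.53, c(2.30, 2.77), 1.97, c(1.80, 2.16)),
            aromatase_inhibitor = ae_prob_entry(5.06, c(4.62, 5.41), 5.06, c(4.65, 5.37))
          ),
          utility = 0.8, utility_range = c(0.7, 0.9),
          utility_continuing = NA_real_,
          utility_continuing_range = c(NA_real_, NA_real_),
          duration = list(kind = "lifetime", years = NA_real_,
                          range_low = NA_real_, range_high = NA_real_)
        ),
        fracture = list(
          prob = list(
            tamoxifen = ae_prob_entry(1.09, c(1.03, 1.28), 0.96, c(0.80, 1.19)),
            tamoxifen_os = ae_prob_entry(1.74, c(1.59, 1.90), 1.74, c(1.59, 1.91)),
            aromatase_inhibitor = ae_prob_entry(2.80, c(2.56, 2.99), 5.00, c(4.59, 5.31))
          ),
          utility = 0.8, utility_range = c(0.7, 0.9),
          utility_continuing = NA_real_,
          utility_continuing_range = c(NA_real_, NA_real_),
          duration = list(kind = "fixed", years = 1, range_low = 1, range_high = 1)
        ),
        endometrial_cancer = list(
          prob = list(
            tamoxifen = ae_prob_entry(0.98, c(0.93, 1.15), 1.80, c(1.50, 2.23)),
            tamoxifen_os = ae_prob_entry(0.98, c(0.89, 1.07), 1.80, c(1.65, 1.98)),
            aromatase_inhibitor = ae_prob_entry(0.32, c(0.30, 0.35), 0.59, c(0.55, 0.63))
          ),
          utility = 0.85, utility_range = c(0.75, 0.95),
          utility_continuing = 0.9, utility_continuing_range = c(0.85, 0.95),
          duration = list(kind = "first_year_then_lifetime", years = 1,
                          range_low = 1, range_high = 1)
        ),
        osteoporosis = list(
          prob = list(
            tamoxifen = ae_prob_entry(13.70, c(12.96, 16.10), 12.07, c(10.04, 14.92)),
            tamoxifen_os = ae_prob_entry(21.90, c(19.93, 23.93), 22.90, c(20.94, 25.15)),
            aromatase_inhibitor = ae_prob_entry(13.71, c(12.52, 14.66), 14.48, c(13.31, 15.37))
          ),
          utility = 0.9, utility_range = c(0.85, 0.95),
          utility_continuing = NA_real_,
          utility_continuing_range = c(NA_real_, NA_real_),
          # decrement runs from onset to the end of the arm's treatment window
          duration = list(kind = "treatment_window", years = NA_real_,
                          range_low = NA_real_, range_high = NA_real_)
        )
      ),
      # published column totals; derived quantities, revalidated against the
      # component sums (the aromatase-inhibitor columns differ by 0.01 from
      # the component sum, a rounding artifact in the source inputs)
      grade34_printed_total = list(
        tamoxifen = ae_prob_entry(23.18, c(21.92, 27.24), 24.68, c(20.54, 30.51)),
        tamoxifen_os = ae_prob_entry(31.30, c(28.48, 34.21), 34.88, c(31.90, 38.31)),
        aromatase_inhibitor = ae_prob_entry(24.58, c(22.45, 26.28), 27.95, c(25.68, 29.66))
      ),
      grade12 = list(
        prob = list(
          tamoxifen = ae_prob_entry(71.67, c(68.89, 74.45), 86.43, c(82.52, 92.90)),
          tamoxifen_os = ae_prob_entry(67.06, c(64.16, 69.97), 80.88, c(77.47, 84.49)),
          aromatase_inhibitor = ae_prob_entry(53.40, c(51.64, 55.15), 64.40, c(61.30, 67.51))
        ),
        utility_grade1 = 0.9, utility_grade1_range = c(0.85, 0.95),
        utility_grade2 = 0.85, utility_grade2_range = c(0.75, 0.95),
        # 1 year per event; sensitivity range runs from 6 months to the full
        # treatment duration ("treatment_duration" sentinel)
        duration = list(kind = "fixed", years = 1,
                        range_low = 0.5, range_high = "treatment_duration")
      )
    )
  )
  class(cfg) <- c("eet_config", "list")
  cfg
}

# ---- config merging / load / save ------------------------------------------

# Recursively merge `override` into `defaults`, erroring on unknown keys and
# coercing leaves to the default's storage type so that YAML round-trips are
# canonical.
merge_config <- function(defaults, override, path = "") {
  for (nm in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      stop("unknown configuration key: '", here, "'", call. = FALSE)
    }
    d <- defaults[[nm]]
    v <- override[[nm]]
    if (is.list(d) && !is.null(names(d)) && length(d) > 0) {
      if (!is.list(v)) stop("configuration key '", here, "' must be a section",
                            call. = FALSE)
      defaults[[nm]] <- merge_config(d, v, here)
    } else {
      defaults[[nm]] <- coerce_leaf(d, v, here)
    }
  }
  defaults
}

coerce_leaf <- function(d, v, path) {
  v <- unlist(v, use.names = FALSE)
  if (is.integer(d)) {
    v <- as.integer(v)
  } else if (is.numeric(d)) {
    if (is.null(v)) v <- numeric(0) else v <- as.numeric(v)
  } else if (is.character(d)) {
    v <- as.character(v)
  }
  if (length(d) > 0 && length(v) != length(d) && !is.null(names(d))) {
    stop("configuration key '", path, "' expects length ", length(d),
         call. = FALSE)
  }
  if (!is.null(names(d)) && length(v) == length(d)) names(v) <- names(d)
  v
}

#' Load a scenario configuration
#'
#' Reads a YAML configuration file (any subset of the keys in
#' [default_config()]), merges it over the bundled defaults, then applies
#' `overrides` given as dotted paths (e.g. `"cohort.age_range"`). An empty or
#' absent file yields the bundled defaults.
#'
#' @param path Path to a YAML file, or `NULL` for defaults only.
#' @param overrides Named list; names are dotted key paths into the config.
#' @return An `eet_config` list.
#' @export
load_scenario_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    parsed <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("malformed configuration file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
    if (!is.null(parsed)) cfg <- merge_config(cfg, parsed)
  }
  for (nm in names(overrides)) {
    cfg <- set_config_value(cfg, nm, overrides[[nm]])
  }
  class(cfg) <- c("eet_config", "list")
  cfg
}

#' Set a single configuration value by dotted path
#' @param config An `eet_config`.
#' @param key Dotted path, e.g. `"discount_rate"` or `"completion.c2"`.
#' @param value Replacement value (coerced to the default's storage type).
#' @export
set_config_value <- function(config, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- list(structure(list(), names = character(0)))
  # build nested override list then merge for type-checking
  ov <- value
  for (p in rev(parts)) ov <- setNames(list(ov), p)
  out <- merge_config(config, ov)
  class(out) <- c("eet_config", "list")
  out
}

#' Save a configuration in canonical YAML form
#'
#' The serialization is canonical: `save(load(x))` is byte-identical to
#' `save(x)` once `x` has passed through the loader.
#' @param config An `eet_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_scenario_config <- function(config, path) {
  txt <- yaml::as.yaml(unclass(config), precision = 15)
  writeLines(txt, path, sep = "")
  invisible(path)
}

# ---- accessors --------------------------------------------------------------

#' Adverse-event probability table
#'
#' Flattens the configured adverse-event probabilities into a data frame
#' mirroring the published panel layout: one row per event x regimen, with
#' cumulative percent columns for the 5- and 10-year windows and their
#' sensitivity bounds.
#' @param config An `eet_config`.
#' @return A data.frame.
#' @export
ae_probability_table <- function(config) {
  g34 <- config$adverse_events$grade34
  rows <- list()
  for (ev in names(g34)) {
    for (rg in REGIMENS) {
      p <- g34[[ev]]$prob[[rg]]
      rows[[length(rows) + 1L]] <- data.frame(
        event = ev, grade_class = "grade34", regimen = rg,
        prob_5y = p$p5, prob_5y_lo = p$p5_range[1], prob_5y_hi = p$p5_range[2],
        prob_10y = p$p10, prob_10y_lo = p$p10_range[1],
        prob_10y_hi = p$p10_range[2], stringsAsFactors = FALSE)
    }
  }
  for (rg in REGIMENS) {
    p <- config$adverse_events$grade12$prob[[rg]]
    rows[[length(rows) + 1L]] <- data.frame(
      event = "grade12_pooled", grade_class = "grade12", regimen = rg,
      prob_5y = p$p5, prob_5y_lo = p$p5_range[1], prob_5y_hi = p$p5_range[2],
      prob_10y = p$p10, prob_10y_lo = p$p10_range[1],
      prob_10y_hi = p$p10_range[2], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Export the parameter tables as CSV
#' @param config An `eet_config`.
#' @param path Output CSV path.
#' @export
export_parameters_csv <- function(config, path) {
  write.csv(ae_probability_table(config), path, row.names = FALSE)
  invisible(path)
}

# grade 3-4 component sums per regimen/duration, in percent
grade34_component_sums <- function(config) {
  tab <- ae_probability_table(config)
  tab <- tab[tab$grade_class == "grade34", ]
  list(
    p5 = tapply(tab$prob_5y, tab$regimen, sum),
    p10 = tapply(tab$prob_10y, tab$regimen, sum)
  )
}

# ---- validation -------------------------------------------------------------

violation <- function(field, value, rule) {
  data.frame(field = field, value = as.character(value)[1], rule = rule,
             stringsAsFactors = FALSE)
}

#' Validate a scenario configuration
#'
#' Checks every structural invariant of the inputs (probability ranges,
#' utility ranges and orderings, hazard-ratio orderings, stage-distribution
#' normalization, completion fractions, recomputed adverse-event totals).
#' Never raises; returns a report with one row per violation, empty when the
#' configuration is valid.
#'
#' @param config An `eet_config`.
#' @return data.frame with columns `field`, `value`, `rule`.
#' @export
validate_parameters <- function(config) {
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x

  if (config$discount_rate < 0)
    add(violation("discount_rate", config$discount_rate, "must be >= 0"))
  if (config$n_women < 1)
    add(violation("n_women", config$n_women, "must be >= 1"))
  for (cc in c("c1", "c2")) {
    x <- config$completion[[cc]]
    if (!is.finite(x) || x <= 0 || x > 1)
      add(violation(paste0("completion.", cc), x, "must lie in (0, 1]"))
  }
  if (config$node_pos_multiplier < 1)
    add(violation("node_pos_multiplier", config$node_pos_multiplier,
                  "must be >= 1"))
  if (config$grade12_events_per_affected < 1)
    add(violation("grade12_events_per_affected",
                  config$grade12_events_per_affected, "must be >= 1"))

  sd_ <- config$cohort$stage_distribution
  if (abs(sum(sd_) - 1) > 1e-12)
    add(violation("cohort.stage_distribution", sum(sd_), "must sum to 1"))
  if (any(sd_ < 0))
    add(violation("cohort.stage_distribution", min(sd_),
                  "entries must be >= 0"))
  ar <- config$cohort$age_range
  if (ar[1] < 25 || ar[2] > 79 || ar[1] >= ar[2])
    add(violation("cohort.age_range", paste(ar, collapse = "-"),
                  "must be a sub-interval of [25, 79]"))

  # hazard ratios
  for (nm in names(config$hazard_ratios)) {
    hp <- config$hazard_ratios[[nm]]
    if (hp$hr5 <= 0 || hp$hr5 > 1)
      add(violation(paste0("hazard_ratios.", nm, ".hr5"), hp$hr5,
                    "must lie in (0, 1]"))
    if (hp$hr10 <= 0 || hp$hr10 > 1)
      add(violation(paste0("hazard_ratios.", nm, ".hr10"), hp$hr10,
                    "must lie in (0, 1]"))
    if (startsWith(nm, "age2549") && hp$hr10 > hp$hr5)
      add(violation(paste0("hazard_ratios.", nm), paste(hp$hr5, hp$hr10),
                    "hr10 must not exceed hr5 for tamoxifen strata"))
  }

  # utilities
  ab <- config$utilities$age_band
  if (any(ab <= 0 | ab > 1))
    add(violation("utilities.age_band", paste(range(ab), collapse = "-"),
                  "must lie in (0, 1]"))
  if (any(diff(ab) > 1e-12))
    add(violation("utilities.age_band", paste(ab, collapse = ","),
                  "must be non-increasing with age band"))
  st <- config$utilities$stage
  if (any(st <= 0 | st > 1))
    add(violation("utilities.stage", paste(range(st), collapse = "-"),
                  "must lie in (0, 1]"))
  if (any(diff(st) > 1e-12))
    add(violation("utilities.stage", paste(st, collapse = ","),
                  "must be non-increasing from stage 1 to stage 4"))

  # adverse events
  g34 <- config$adverse_events$grade34
  for (ev in names(g34)) {
    spec <- g34[[ev]]
    for (rg in REGIMENS) {
      p <- spec$prob[[rg]]
      for (fld in c("p5", "p10")) {
        x <- p[[fld]]
        if (!is.finite(x) || x < 0 || x > 100)
          add(violation(paste0("adverse_events.grade34.", ev, ".prob.", rg,
                               ".", fld), x, "percent must lie in [0, 100]"))
      }
    }
    if (spec$utility <= 0 || spec$utility > 1)
      add(violation(paste0("adverse_events.grade34.", ev, ".utility"),
                    spec$utility, "must lie in (0, 1]"))
    if (!is.na(spec$utility_continuing) &&
        (spec$utility_continuing <= 0 || spec$utility_continuing > 1))
      add(violation(paste0("adverse_events.grade34.", ev,
                           ".utility_continuing"),
                    spec$utility_continuing, "must lie in (0, 1]"))
    if (identical(spec$duration$kind, "fixed") &&
        (!is.finite(spec$duration$years) || spec$duration$years <= 0))
      add(violation(paste0("adverse_events.grade34.", ev, ".duration.years"),
                    spec$duration$years, "fixed duration must be > 0"))
  }
  g12 <- config$adverse_events$grade12
  for (rg in REGIMENS) {
    p <- g12$prob[[rg]]
    for (fld in c("p5", "p10")) {
      x <- p[[fld]]
      if (!is.finite(x) || x < 0 || x > 100)
        add(violation(paste0("adverse_events.grade12.prob.", rg, ".", fld),
                      x, "percent must lie in [0, 100]"))
    }
  }
  for (u in c("utility_grade1", "utility_grade2")) {
    if (g12[[u]] <= 0 || g12[[u]] > 1)
      add(violation(paste0("adverse_events.grade12.", u), g12[[u]],
                    "must lie in (0, 1]"))
  }

  # printed totals are derived quantities: recompute from components.
  # 0.0105 absorbs the 0.01 rounding discrepancy in the published
  # aromatase-inhibitor columns.
  sums <- grade34_component_sums(config)
  for (rg in REGIMENS) {
    tot <- config$adverse_events$grade34_printed_total[[rg]]
    if (abs(sums$p5[[rg]] - tot$p5) > 0.0105)
      add(violation(paste0("adverse_events.grade34_printed_total.", rg, ".p5"),
                    tot$p5, sprintf("component sum %.4f differs by > 0.0105",
                                    sums$p5[[rg]])))
    if (abs(sums$p10[[rg]] - tot$p10) > 0.0105)
      add(violation(paste0("adverse_events.grade34_printed_total.", rg,
                           ".p10"), tot$p10,
                    sprintf("component sum %.4f differs by > 0.0105",
                            sums$p10[[rg]])))
  }

  lt <- config$life_table
  if (lt$gamma <= 0)
    add(violation("life_table.gamma", lt$gamma, "must be > 0"))
  if (lt$alpha < 0 || lt$beta < 0)
    add(violation("life_table", paste(lt$alpha, lt$beta),
                  "alpha and beta must be >= 0"))

  if (length(v) == 0) {
    data.frame(field = character(0), value = character(0),
               rule = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}

# ---- trial-count hazard arithmetic ------------------------------------------

#' Convert trial death counts to exponential hazards and their ratio
#'
#' Under an exponential (constant-hazard) survival model over the follow-up
#' window, a survival proportion `1 - deaths/n` corresponds to a hazard
#' `-ln(1 - deaths/n) / followup_years`. The ratio of two such hazards does
#' not depend on the follow-up length. The default follow-up of 7 years is
#' the value under which the per-arm hazards print as 0.00335 and 0.00343 for
#' the 46/1983 vs 47/1983 death counts used to extend the aromatase-inhibitor
#' strategy.
#'
#' @param deaths_a,n_a Deaths and sample size in arm A.
#' @param deaths_b,n_b Deaths and sample size in arm B.
#' @param followup_years Follow-up window length in years.
#' @return list with `hazard_a`, `hazard_b`, `ratio` (= hazard_a / hazard_b).
#' @export
trial_counts_to_hazards <- function(deaths_a, n_a, deaths_b, n_b,
                                    followup_years = 7) {
  if (n_a <= 0 || n_b <= 0) stop("sample sizes must be positive")
  if (deaths_a < 0 || deaths_b < 0 || deaths_a > n_a || deaths_b > n_b)
    stop("death counts must lie in [0, n]")
  if (followup_years <= 0) stop("followup_years must be positive")
  if (deaths_a == n_a || deaths_b == n_b)
    stop("all subjects died: exponential hazard is infinite")
  ha <- -log(1 - deaths_a / n_a) / followup_years
  hb <- -log(1 - deaths_b / n_b) / followup_years
  list(hazard_a = ha, hazard_b = hb, ratio = ha / hb)
}

#' Extend a 5-year hazard ratio by an incremental ratio
#'
#' The 10-year strategy hazard ratio is the 5-year strategy HR multiplied by
#' the incremental ratio estimated from extension-trial death counts.
#' @param hr5 5-year strategy hazard ratio.
#' @param incremental_ratio Hazard ratio of extended vs placebo continuation.
#' @return hr10 = hr5 * incremental_ratio.
#' @export
extend_hr <- function(hr5, incremental_ratio) {
  stopifnot(hr5 > 0, incremental_ratio > 0)
  hr5 * incremental_ratio
}
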