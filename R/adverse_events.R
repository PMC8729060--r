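# Adverse events. Each grade 3-4 event type is sampled independently per
# woman with the cumulative probability of the arm's duration column
# (0-5 or 0-10 years); the pooled grade 1-2 row is one Bernoulli, and an
# affected woman receives exactly `grade12_events_per_affected` instances.
# Occurrence and onset draws are keyed by event type but not by arm, so the
# two arms share them (common random numbers): where the 10-year column
# probability exceeds the 5-year one, every woman affected in the 5-year arm
# is also affected in the 10-year arm, and vice versa where the ordering is
# reversed (e.g. new cardiac events on tamoxifen).
#
# Duration semantics ("kind"):
#   fixed                    decrement for `years` from onset
#   treatment_window         decrement from onset to the end of the arm's
#                            treatment window (osteoporosis)
#   span_treatment_duration  decrement for the full treatment duration from
#                            onset (sensitivity-range upper bound)
#   lifetime                 decrement from onset to death
#   first_year_then_lifetime initial utility for 1 year from onset, then the
#                            continuing-care utility to death (stroke,
#                            endometrial cancer)

arm_duration <- function(arm) {
  switch(arm, five_year = 5, ten_year = 10,
         stop("unknown arm: ", arm))
}

# segments for one instance; returns list of (start, end, utility) triples
duration_segments <- function(kind, years, onset, D, utility,
                              utility_continuing = NA_real_) {
  switch(kind,
    fixed = list(c(onset, onset + years, utility)),
    treatment_window = list(c(onset, D, utility)),
    span_treatment_duration = list(c(onset, onset + D, utility)),
    lifetime = list(c(onset, Inf, utility)),
    first_year_then_lifetime = list(c(onset, onset + 1, utility),
                                    c(onset + 1, Inf, utility_continuing)),
    stop("unknown duration kind: ", kind)
  )
}

#' Utility-decrement segments for one adverse-event instance
#'
#' Translates an event instance (event type + onset) into dated
#' multiplicative utility decrements under the configured duration
#' semantics, clipped at `horizon_end`. `event` is a grade 3-4 event name or
#' `"grade12_grade1"` / `"grade12_grade2"` for the two pooled mild-toxicity
#' instances.
#'
#' @param event Event name.
#' @param onset Years post-diagnosis, `<= horizon_end`.
#' @param config An `eet_config`.
#' @param arm `"five_year"` or `"ten_year"` (sets the treatment window).
#' @param horizon_end Clip segments at this time (death or horizon).
#' @return data.frame with columns `start`, `end`, `utility`; zero rows when
#'   the instance is entirely beyond the horizon.
#' @export
event_utility_segments <- function(event, onset, config, arm = "five_year",
                                   horizon_end = Inf) {
  if (onset > horizon_end) stop("onset must not exceed horizon_end")
  D <- arm_duration(arm)
  g12 <- config$adverse_events$grade12
  if (event %in% c("grade12_grade1", "grade12_grade2")) {
    utility <- if (event == "grade12_grade1") g12$utility_grade1
               else g12$utility_grade2
    dur <- g12$duration
    segs <- duration_segments(dur$kind, dur$years, onset, D, utility)
  } else {
    spec <- config$adverse_events$grade34[[event]]
    if (is.null(spec)) stop("unknown adverse event: ", event)
    segs <- duration_segments(spec$duration$kind, spec$duration$years, onset,
                              D, spec$utility, spec$utility_continuing)
  }
  out <- do.call(rbind, lapply(segs, function(s) {
    data.frame(start = s[1], end = min(s[2], horizon_end), utility = s[3])
  }))
  out[out$end > out$start, , drop = FALSE]
}

# effective occurrence probability (fraction) for one event, per woman,
# honouring regimen, arm and completion schedule
ae_effective_prob <- function(prob_entry_by_regimen, regimen, arm,
                              completion) {
  p5 <- vapply(prob_entry_by_regimen, `[[`, numeric(1), "p5")[regimen] / 100
  p10 <- vapply(prob_entry_by_regimen, `[[`, numeric(1), "p10")[regimen] / 100
  eff <- apply_completion(unname(p5), unname(p10), completion)
  if (arm == "five_year") eff$p5 else eff$p10
}

#' Sample adverse events for a cohort under one arm
#'
#' Vectorized over the cohort. Occurrence and onset uniforms are substreams
#' keyed by event type (not arm), so calling this for each arm yields
#' coupled event sets. Onsets are uniform over the arm's treatment window;
#' the two grade 1-2 instances of an affected woman sit at the window start
#' (grade 1 utility) and midpoint (grade 2 utility).
#'
#' @param profiles data.frame with `regimen` (from [assign_regimen()]).
#' @param config An `eet_config`.
#' @param arm `"five_year"` or `"ten_year"`.
#' @param seed Master seed (defaults to `config$master_seed`).
#' @param stream_tag Substream suffix for chunked runs.
#' @return data.table with one row per utility segment: `idx` (row index
#'   into `profiles`), `id`, `event`, `onset`, `start`, `end`, `mult`.
#' @export
sample_adverse_events <- function(profiles, config, arm, seed = NULL,
                                  stream_tag = "") {
  if (is.null(seed)) seed <- config$master_seed
  n <- nrow(profiles)
  D <- arm_duration(arm)
  comp <- config$completion
  g34 <- config$adverse_events$grade34
  out <- vector("list", length(g34) + 1L)

  for (j in seq_along(g34)) {
    ev <- names(g34)[j]
    spec <- g34[[ev]]
    p5e <- ae_effective_prob(spec$prob, profiles$regimen, "five_year", comp)
    p10e <- ae_effective_prob(spec$prob, profiles$regimen, "ten_year", comp)
    p <- if (arm == "five_year") p5e else p10e
    u <- substream_runif(seed, paste0("ae_occ_", ev, stream_tag), n)
    v <- substream_runif(seed, paste0("ae_onset_", ev, stream_tag), n)
    hit <- which(u < p)
    if (length(hit) == 0) next
    # the two arms are the same treatment through year 5, so events shared
    # by both arms (u below both column probabilities) occur at the same
    # time in (0, 5]; only the 10-year arm's incremental cases fall in
    # (5, 10]
    if (arm == "five_year") {
      onset <- v[hit] * 5
    } else {
      shared <- u[hit] < pmin(p5e, p10e)[hit]
      onset <- ifelse(shared, v[hit] * 5, 5 + v[hit] * 5)
    }
    kind <- spec$duration$kind
    if (kind == "first_year_then_lifetime") {
      seg <- data.table::data.table(
        idx = c(hit, hit), id = c(profiles$id[hit], profiles$id[hit]),
        event = ev, onset = c(onset, onset),
        start = c(onset, onset + 1),
        end = c(onset + 1, rep(Inf, length(hit))),
        mult = c(rep(spec$utility, length(hit)),
                 rep(spec$utility_continuing, length(hit))))
    } else {
      end <- switch(kind,
                    fixed = onset + spec$duration$years,
                    treatment_window = rep(D, length(hit)),
                    span_treatment_duration = onset + D,
                    lifetime = rep(Inf, length(hit)),
                    stop("unknown duration kind: ", kind))
      seg <- data.table::data.table(
        idx = hit, id = profiles$id[hit], event = ev, onset = onset,
        start = onset, end = pmax(end, onset), mult = spec$utility)
    }
    out[[j]] <- seg
  }

  # pooled grade 1-2 row: one Bernoulli, fixed number of dated instances
  g12 <- config$adverse_events$grade12
  p <- ae_effective_prob(g12$prob, profiles$regimen, arm, comp)
  u <- substream_runif(seed, paste0("ae_occ_grade12", stream_tag), n)
  hit <- which(u < p)
  if (length(hit) > 0) {
    k_inst <- config$grade12_events_per_affected
    onsets <- (seq_len(k_inst) - 1) / k_inst * D
    utils_ <- rep(c(g12$utility_grade1, g12$utility_grade2),
                  length.out = k_inst)
    dur <- g12$duration
    segs <- lapply(seq_len(k_inst), function(i) {
      on <- rep(onsets[i], length(hit))
      end <- switch(dur$kind,
                    fixed = on + dur$years,
                    span_treatment_duration = on + D,
                    treatment_window = rep(D, length(hit)),
                    stop("unsupported grade 1-2 duration kind: ", dur$kind))
      data.table::data.table(
        idx = hit, id = profiles$id[hit],
        event = paste0("grade12_", ifelse(i %% 2 == 1, "grade1", "grade2")),
        onset = on, start = on, end = pmax(end, on), mult = utils_[i])
    })
    out[[length(g34) + 1L]] <- data.table::rbindlist(segs)
  }

  res <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(res) == 0) {
    res <- data.table::data.table(idx = integer(0), id = integer(0),
                                  event = character(0), onset = numeric(0),
                                  start = numeric(0), end = numeric(0),
                                  mult = numeric(0))
  }
  res[]
}
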