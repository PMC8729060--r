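# Synthetic diagnosed cohort: age at diagnosis from a truncated normal
# (mean 61, sd 13, restricted to the configured age window inside [25, 79];
# an approximately SEER-like shape, configurable), a categorical stage mix
# over stages 1/2a/2b/3, and the deterministic stage -> nodal mapping
# (stages 1 and 2a node-negative, 2b and 3 node-positive).

STAGES <- c("stage1", "stage2a", "stage2b", "stage3")

#' Nodal status implied by stage
#'
#' Stages 1 and 2a map to node-negative, stages 2b and 3 to node-positive;
#' a pure function of stage.
#' @param stage Character vector in `c("stage1","stage2a","stage2b","stage3")`.
#' @return Character vector `"negative"` / `"positive"`.
#' @export
nodal_from_stage <- function(stage) {
  if (!all(stage %in% STAGES)) stop("unknown stage value")
  ifelse(stage %in% c("stage2b", "stage3"), "positive", "negative")
}

age_band_label <- function(age) {
  b <- pmin(pmax(10 * (floor(age) %/% 10), 20), 80)
  paste0("b", b)
}

# inverse-CDF draw from a normal truncated to [lo, hi]
rtruncnorm_inv <- function(u, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

#' Sample a diagnosed cohort
#'
#' Draws `n` woman profiles: continuous age at diagnosis, birth year, stage,
#' nodal status (deterministic from stage) and utility age band. Draws come
#' from purpose-keyed substreams of `seed`, so the same `(seed, id)` always
#' yields the same woman regardless of how many others are sampled after her.
#'
#' @param config An `eet_config` (uses the `cohort` section).
#' @param n Number of women; defaults to `config$n_women`.
#' @param seed Master seed; defaults to `config$master_seed`.
#' @param id_offset Added to the 1-based ids (used for chunked runs).
#' @param stream_tag Substream suffix letting chunked runs draw disjoint
#'   streams.
#' @return data.frame with columns `id`, `age_dx`, `birth_year`, `stage`,
#'   `nodal`, `age_band`.
#' @export
sample_cohort <- function(config, n = NULL, seed = NULL, id_offset = 0,
                          stream_tag = "") {
  if (is.null(n)) n <- config$n_women
  if (is.null(seed)) seed <- config$master_seed
  spec <- config$cohort
  if (n == 0) {
    return(data.frame(id = integer(0), age_dx = numeric(0),
                      birth_year = integer(0), stage = character(0),
                      nodal = character(0), age_band = character(0),
                      stringsAsFactors = FALSE))
  }
  u_age <- substream_runif(seed, paste0("cohort_age", stream_tag), n)
  u_stage <- substream_runif(seed, paste0("cohort_stage", stream_tag), n)
  u_birth <- substream_runif(seed, paste0("cohort_birth", stream_tag), n)

  ar <- spec$age_range
  age <- rtruncnorm_inv(u_age, spec$age_mean, spec$age_sd, ar[1], ar[2])
  age <- pmin(pmax(age, ar[1]), ar[2])

  p <- spec$stage_distribution / sum(spec$stage_distribution)
  stage <- STAGES[findInterval(u_stage, cumsum(p), left.open = TRUE) + 1L]

  br <- spec$birth_cohort_range
  birth <- as.integer(br[1] + floor(u_birth * (br[2] - br[1] + 1)))

  data.frame(
    id = seq_len(n) + as.integer(id_offset),
    age_dx = age,
    birth_year = birth,
    stage = stage,
    nodal = nodal_from_stage(stage),
    age_band = age_band_label(age),
    stringsAsFactors = FALSE
  )
}
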