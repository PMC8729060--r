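# Shared test scaffolding: reduced-size configurations and a calibration
# cache so multiple test files reuse the same fitted baselines.

small_config <- function(age_range = c(25, 49), n = 20000, n_sim = 50000,
                         seed = 1L) {
  cfg <- default_config()
  cfg$cohort$age_range <- age_range
  cfg$n_women <- n
  cfg$calibration$n_sim <- n_sim
  cfg$master_seed <- as.integer(seed)
  cfg
}

# a hand-built calibration for tests that pin the baseline directly
manual_calib <- function(Lambda_base, k = 1, lambda = 7, groups = "age2549",
                         npm = 2.5) {
  out <- lapply(groups, function(g) {
    list(Lambda_base = Lambda_base, shape = list(k = k, lambda = lambda),
         node_pos_multiplier = npm)
  })
  names(out) <- groups
  structure(out, class = c("eet_calibration", "list"))
}

.eet_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .eet_test_cache)) {
    assign(key, force(expr), envir = .eet_test_cache)
  }
  get(key, envir = .eet_test_cache)
}

calib_2549_small <- function() {
  cached("calib_2549_small", calibrate_model(small_config()))
}

calib_5079_small <- function() {
  cached("calib_5079_small", calibrate_model(small_config(c(50, 79))))
}

# zero out every adverse-event probability (isolates mortality/QALY paths)
zero_ae_config <- function(cfg) {
  for (ev in names(cfg$adverse_events$grade34)) {
    for (rg in names(cfg$adverse_events$grade34[[ev]]$prob)) {
      cfg$adverse_events$grade34[[ev]]$prob[[rg]]$p5 <- 0
      cfg$adverse_events$grade34[[ev]]$prob[[rg]]$p10 <- 0
    }
  }
  for (rg in names(cfg$adverse_events$grade12$prob)) {
    cfg$adverse_events$grade12$prob[[rg]]$p5 <- 0
    cfg$adverse_events$grade12$prob[[rg]]$p10 <- 0
  }
  cfg
}

# all-ones utilities (so quality-adjusted survival equals survival)
unit_utility_config <- function(cfg) {
  cfg$utilities$age_band[] <- 1
  cfg$utilities$stage[] <- 1
  cfg
}
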