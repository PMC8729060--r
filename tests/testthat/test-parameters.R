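test_that("trial death counts convert to exponential hazards with a follow-up-independent ratio", {
  h <- trial_counts_to_hazards(46, 1983, 47, 1983, followup_years = 7)
  # oracle: ratio = ln(1 - 46/1983) / ln(1 - 47/1983), follow-up cancels
  expect_equal(h$ratio, log(1 - 46 / 1983) / log(1 - 47 / 1983),
               tolerance = 1e-12)
  expect_identical(signif(h$ratio, 3), 0.978)
  # per-arm hazards at the 7-year default print as published
  expect_identical(round(h$hazard_a, 5), 0.00335)
  expect_identical(round(h$hazard_b, 5), 0.00343)

  followups <- c(0.5, 1, 2, 3.7, 5, 7, 10, 12.5, 20, 40)
  ratios <- vapply(followups, function(t)
    trial_counts_to_hazards(46, 1983, 47, 1983, t)$ratio, numeric(1))
  expect_true(all(abs(ratios - ratios[1]) < 1e-12))

  sym <- trial_counts_to_hazards(30, 1000, 30, 1000, 5)
  expect_identical(sym$ratio, 1)
})

test_that("extending the aromatase-inhibitor HR by the trial ratio reproduces the published 10-year value", {
  ratio <- trial_counts_to_hazards(46, 1983, 47, 1983)$ratio
  hr10 <- extend_hr(0.55, ratio)
  expect_equal(hr10, 0.5381595, tolerance = 1e-6)
  expect_identical(round(hr10, 2), 0.54)
})

test_that("trial-count conversion rejects degenerate inputs", {
  expect_error(trial_counts_to_hazards(1000, 1000, 5, 100, 5), "died")
  expect_error(trial_counts_to_hazards(5, 0, 5, 100, 5), "positive")
  expect_error(trial_counts_to_hazards(5, 100, 5, 100, -1), "positive")
  expect_error(trial_counts_to_hazards(101, 100, 5, 100, 5))
})

test_that("grade 3-4 component probabilities sum to the published totals", {
  tab <- ae_probability_table(default_config())
  g34 <- tab[tab$grade_class == "grade34", ]
  s5 <- tapply(g34$prob_5y, g34$regimen, sum)
  s10 <- tapply(g34$prob_10y, g34$regimen, sum)
  expect_equal(unname(s5[["tamoxifen"]]), 23.18, tolerance = 1e-9)
  expect_equal(unname(s5[["tamoxifen_os"]]), 31.30, tolerance = 1e-9)
  expect_equal(unname(s10[["tamoxifen"]]), 24.68, tolerance = 1e-9)
  expect_equal(unname(s10[["tamoxifen_os"]]), 34.88, tolerance = 1e-9)
  # published aromatase-inhibitor totals carry a 0.01 rounding discrepancy
  expect_lt(abs(s5[["aromatase_inhibitor"]] - 24.58), 0.0105)
  expect_lt(abs(s10[["aromatase_inhibitor"]] - 27.95), 0.0105)
})

test_that("the bundled defaults validate cleanly", {
  expect_identical(nrow(validate_parameters(default_config())), 0L)
})

test_that("validation reports out-of-range probabilities and HR ordering breaches by field", {
  cfg <- default_config()
  cfg$adverse_events$grade34$stroke$prob$tamoxifen$p5 <- 120
  rep <- validate_parameters(cfg)
  # flags the out-of-range probability and the broken recomputed column total
  expect_true(any(grepl("stroke.*p5", rep$field)))
  expect_true(any(grepl("printed_total", rep$field)))

  cfg2 <- default_config()
  cfg2$hazard_ratios$age2549_stage1$hr10 <- 0.8  # > hr5 = 0.70
  rep2 <- validate_parameters(cfg2)
  expect_identical(nrow(rep2), 1L)
  expect_match(rep2$field, "age2549_stage1")
  expect_match(rep2$rule, "hr10")

  cfg3 <- default_config()
  cfg3$completion$c2 <- 0
  expect_gt(nrow(validate_parameters(cfg3)), 0)
})

test_that("configuration loading merges, overrides, and round-trips canonically", {
  # empty file -> bundled defaults
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_identical(load_scenario_config(empty), default_config())

  # single-field override leaves everything else at default
  cfg <- load_scenario_config(NULL, overrides = list(discount_rate = 0))
  ref <- default_config()
  ref$discount_rate <- 0
  expect_identical(cfg, ref)

  # dotted-path override
  cfg2 <- set_config_value(default_config(), "completion.c2", 0.5)
  expect_identical(cfg2$completion$c2, 0.5)

  # save -> load -> save is byte-identical
  p1 <- withr::local_tempfile(fileext = ".yaml")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  save_scenario_config(cfg2, p1)
  save_scenario_config(load_scenario_config(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- load_scenario_config(p1)
  expect_equal(back, cfg2)  # values equal to serialization precision
  expect_identical(back$master_seed, cfg2$master_seed)  # types preserved
  expect_identical(names(back$cohort$stage_distribution),
                   names(cfg2$cohort$stage_distribution))
})

test_that("unknown configuration keys are rejected by name", {
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("nonsense_key: 3", bad)
  expect_error(load_scenario_config(bad), "nonsense_key")
  expect_error(set_config_value(default_config(), "cohort.not_a_field", 1),
               "cohort.not_a_field")
  expect_error(load_scenario_config("/no/such/file.yaml"), "not found")
})

test_that("parameter export mirrors the event x regimen x duration panel", {
  path <- withr::local_tempfile(fileext = ".csv")
  export_parameters_csv(default_config(), path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), 7L * 3L)  # 6 grade 3-4 events + pooled grade 1-2
  expect_true(all(c("event", "regimen", "prob_5y", "prob_10y") %in% names(tab)))
  expect_equal(tab$prob_5y[tab$event == "stroke" &
                             tab$regimen == "tamoxifen"], 1.85)
})
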