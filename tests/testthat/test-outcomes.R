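mk_history <- function(age_dx = 55, stage = "stage2a", t_death = 20,
                       cause = "other", bc_time = NA_real_, events = NULL) {
  structure(list(
    profile = data.frame(age_dx = age_dx, stage = stage,
                         stringsAsFactors = FALSE),
    arm = "five_year",
    bc_death_time = bc_time,
    oc_death_age = age_dx + t_death,
    realized_death_age = age_dx + t_death,
    t_death = t_death,
    cause = cause,
    events = events
  ), class = "eet_life_history")
}

test_that("discounted survival integrals match their closed forms", {
  cfg <- unit_utility_config(default_config())
  cfg$discount_rate <- 0
  out <- compute_outcomes(mk_history(t_death = 10), cfg)
  expect_equal(out$ly, 10)
  expect_equal(out$qaly, 10, tolerance = 1e-12)
  expect_equal(out$ly_disc, 10, tolerance = 1e-12)

  cfg$discount_rate <- 0.03
  out1 <- compute_outcomes(mk_history(t_death = 1), cfg)
  expect_equal(out1$ly_disc, (1 - exp(-0.03)) / 0.03, tolerance = 1e-10)
  expect_equal(out1$ly_disc, 0.9851489, tolerance = 1e-6)

  # constant utility 0.7 over 40 years at 3%
  cfg2 <- unit_utility_config(default_config())
  cfg2$utilities$stage[] <- 0.7
  out40 <- compute_outcomes(mk_history(t_death = 40), cfg2)
  expect_equal(out40$qaly_disc, 0.7 * (1 - exp(-1.2)) / 0.03,
               tolerance = 1e-10)
  expect_equal(out40$qaly_disc, 0.7 * 23.29353, tolerance = 1e-4)
})

test_that("annual-step discounting weights each year lived by (1+r)^-year", {
  cfg <- unit_utility_config(default_config())
  cfg$discounting <- "annual"
  out <- compute_outcomes(mk_history(t_death = 2.5), cfg)
  expect_equal(out$ly_disc, 1 + 1 / 1.03 + 0.5 / 1.03^2, tolerance = 1e-10)
  expect_equal(out$qaly_disc, out$ly_disc, tolerance = 1e-10)
})

test_that("utility trajectory multiplies age-band, stage and toxicity weights", {
  cfg <- default_config()
  h <- mk_history(age_dx = 55, stage = "stage2a", t_death = 20)
  traj <- utility_trajectory(h, cfg)
  # 0.837 (ages 50-59) x 0.85 (stage 2a) until she turns 60 at t = 5
  expect_equal(traj$utility[1], 0.837 * 0.85, tolerance = 1e-12)
  expect_equal(traj$utility[1], 0.71145, tolerance = 1e-12)
  expect_equal(traj$end[1], 5)
  expect_equal(traj$utility[2], 0.811 * 0.85, tolerance = 1e-12)

  # an active pulmonary embolus multiplies in over its 9-month span
  ev <- data.frame(event = "pulmonary_embolus", onset = 1, start = 1,
                   end = 1.75, mult = 0.65)
  traj2 <- utility_trajectory(mk_history(events = ev), cfg)
  seg <- traj2[traj2$start == 1, ]
  expect_equal(seg$utility, 0.71145 * 0.65, tolerance = 1e-12)
  expect_equal(seg$end, 1.75)

  cfg1 <- unit_utility_config(cfg)
  traj3 <- utility_trajectory(mk_history(), cfg1)
  expect_true(all(traj3$utility == 1))
})

test_that("cause of death follows min() semantics", {
  # BC death scheduled at year 10 but other-cause death at year 8
  h <- mk_history(t_death = 8, cause = "other", bc_time = 10)
  out <- compute_outcomes(h, default_config())
  expect_false(out$bc_death)
  expect_equal(out$ly, 8)
})

test_that("vectorized cohort integration agrees with the scalar reference", {
  cfg <- small_config()
  calib <- calib_2549_small()
  n <- 150
  prof <- sample_cohort(cfg, n = n, seed = 17L, stream_tag = "#1")
  sim <- eetsim:::simulate_pair_chunk(prof, calib, cfg, 17L,
                                      stream_tag = "#1")
  for (armname in c("five", "ten")) {
    arm <- if (armname == "five") "five_year" else "ten_year"
    rec <- sim[[armname]]$records
    ae <- sim[[armname]]$ae
    for (i in seq_len(n)) {
      evi <- as.data.frame(ae[ae$idx == i, ])
      h <- mk_history(age_dx = prof$age_dx[i], stage = prof$stage[i],
                      t_death = rec$t_death[i], cause = rec$cause[i],
                      bc_time = rec$bc_time[i],
                      events = if (nrow(evi)) evi else NULL)
      out <- compute_outcomes(h, cfg)
      expect_equal(rec$qaly[i], out$qaly, tolerance = 1e-8)
      expect_equal(rec$qaly_disc[i], out$qaly_disc, tolerance = 1e-8)
      expect_equal(rec$ly_disc[i], out$ly_disc, tolerance = 1e-10)
    }
  }
})

test_that("outcome orderings hold for every simulated woman", {
  cfg <- small_config()
  cmp <- compare_durations(cfg, calib = calib_2549_small(), n = 30000,
                           keep_records = TRUE)
  for (ch in cmp$records) {
    for (armname in c("five", "ten")) {
      r <- ch[[armname]]$records
      expect_true(all(r$qaly <= r$ly + 1e-9))
      expect_true(all(r$ly_disc <= r$ly + 1e-9))
      expect_true(all(r$qaly_disc <= pmin(r$qaly, r$ly_disc) + 1e-9))
      expect_true(all(r$qaly >= 0 & r$qaly_disc >= 0))
    }
  }
})

test_that("zero discount rate makes discounted and undiscounted outcomes identical", {
  cfg <- small_config()
  cfg$discount_rate <- 0
  cmp <- compare_durations(cfg, calib = calib_2549_small(), n = 20000,
                           keep_records = TRUE)
  r <- cmp$records[[1]]$five$records
  expect_equal(r$ly, r$ly_disc, tolerance = 1e-12)
  expect_equal(r$qaly, r$qaly_disc, tolerance = 1e-12)
})

test_that("the 15-year horizon clips outcomes and mortality attribution", {
  cfg <- small_config()
  calib <- calib_2549_small()
  cfg15 <- cfg
  cfg15$horizon <- "15y"
  life <- compare_durations(cfg, calib = calib, n = 100000,
                            mortality_only = TRUE)
  clip <- compare_durations(cfg15, calib = calib, n = 100000,
                            mortality_only = TRUE, keep_records = TRUE)
  red_life <- -comparison_value(life, "bc_death")
  red_15 <- -comparison_value(clip, "bc_death")
  expect_lt(red_15, red_life)
  expect_gt(red_15, 0)
  expect_true(all(clip$records[[1]]$five$records$ly <= 15))
})

test_that("simulate_life_history is arm-consistent and reproducible", {
  cfg <- small_config()
  calib <- calib_2549_small()
  prof <- sample_cohort(cfg, n = 1, seed = 23L)
  h5 <- simulate_life_history(prof, "five_year", calib, cfg, seed = 23L)
  h5b <- simulate_life_history(prof, "five_year", calib, cfg, seed = 23L)
  expect_identical(h5[names(h5) != "events"], h5b[names(h5b) != "events"])
  expect_identical(h5$events, h5b$events)
  h10 <- simulate_life_history(prof, "ten_year", calib, cfg, seed = 23L)
  expect_identical(h5$oc_death_age, h10$oc_death_age)
  expect_gte(h5$realized_death_age, prof$age_dx)
})

test_that("aggregation is exact on degenerate input and paired SEs beat unpaired ones", {
  cfg <- small_config()
  for (key in names(cfg$hazard_ratios))
    cfg$hazard_ratios[[key]]$hr10 <- cfg$hazard_ratios[[key]]$hr5
  cmp_same <- compare_durations(cfg, calib = calib_2549_small(), n = 5000,
                                mortality_only = TRUE)
  s <- cmp_same$summary
  expect_true(all(s$diff == 0))
  expect_true(all(s$se_diff == 0))

  cmp <- compare_durations(small_config(), calib = calib_2549_small(),
                           n = 50000)
  s2 <- cmp$summary
  expect_true(all(s2$se_diff <= s2$se_unpaired + 1e-12))
  # strata cover the Table-3 layout
  expect_true(all(c("all", "age2549", "age2549_node_negative",
                    "age2549_node_positive") %in% s2$stratum))
})
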