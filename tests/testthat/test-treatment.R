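test_that("regimen assignment follows the age/stage/nodal rules", {
  cfg <- default_config()
  prof <- data.frame(
    id = 1:3,
    age_dx = c(45, 62, 45),
    birth_year = 1960L,
    stage = c("stage2b", "stage1", "stage2a"),
    nodal = nodal_from_stage(c("stage2b", "stage1", "stage2a")),
    age_band = c("b40", "b60", "b40"),
    stringsAsFactors = FALSE)
  out <- assign_regimen(prof, cfg)
  # age 45, stage 2b: tamoxifen + ovarian suppression, chemo, stages-2/3 HRs
  expect_identical(out$regimen[1], "tamoxifen_os")
  expect_true(out$chemo[1])
  expect_identical(c(out$hr5[1], out$hr10[1]), c(0.66, 0.50))
  # age 62, stage 1: aromatase inhibitor, no chemo
  expect_identical(out$regimen[2], "aromatase_inhibitor")
  expect_false(out$chemo[2])
  expect_identical(c(out$hr5[2], out$hr10[2]), c(0.55, 0.54))
  # age 45, stage 2a: node-negative -> plain tamoxifen, with chemo
  expect_identical(out$regimen[3], "tamoxifen")
  expect_true(out$chemo[3])
  expect_identical(c(out$hr5[3], out$hr10[3]), c(0.66, 0.50))

  bad <- prof; bad$age_dx[1] <- 80.5
  expect_error(assign_regimen(bad, cfg), "\\[25, 79\\]")
})

test_that("tail multiplier solves the lifetime hazard-ratio identity", {
  # arithmetic oracle: (0.54 - 0.70*0.3) / (1 - 0.3) = 0.33/0.7
  expect_equal(tail_multiplier(0.70, 0.54, 0.3, 1), 0.33 / 0.7,
               tolerance = 1e-12)
  expect_equal(tail_multiplier(0.70, 0.70, 0.3, 1), 0.70, tolerance = 1e-12)
  expect_equal(tail_multiplier(0.70, 0.54, 0, 1), 0.54, tolerance = 1e-12)
  expect_error(tail_multiplier(0.9, 0.1, 0.9, 1), "infeasible")
  expect_error(tail_multiplier(0.7, 0.54, 1, 1), "Lambda25 > Lambda5")
})

test_that("coupled arms reproduce the closed-form power identity without competing mortality", {
  cfg <- small_config()
  cfg$cohort$stage_distribution <- c(stage1 = 1, stage2a = 0,
                                     stage2b = 0, stage3 = 0)
  cfg$life_table$alpha <- 0
  cfg$life_table$beta <- 0
  L <- closed_form_lambda(0.1191, 0.70)
  calib <- manual_calib(L, k = 1, lambda = 7)
  n <- 400000
  cmp <- compare_durations(cfg, calib = calib, n = n, mortality_only = TRUE)
  p5 <- comparison_value(cmp, "bc_death", "all", "mean_5y")
  p10 <- comparison_value(cmp, "bc_death", "all", "mean_10y")
  # oracle: p10 = 1 - (1 - p5)^(hr10/hr5)
  expect_lt(abs(p5 - 0.1191), 3 * sqrt(0.1191 * 0.8809 / n))
  expect_lt(abs(p10 - 0.09319311), 3 * sqrt(0.0932 * 0.9068 / n))
})

test_that("monotone coupling: the ten-year arm never dies of breast cancer earlier", {
  cfg <- small_config()
  cmp <- compare_durations(cfg, calib = calib_2549_small(), n = 50000,
                           mortality_only = TRUE, keep_records = TRUE)
  for (ch in cmp$records) {
    t5 <- ch$five$records$bc_time
    t10 <- ch$ten$records$bc_time
    # women with a BC death in the 10-year arm also die in the 5-year arm,
    # and never later
    expect_true(all(is.na(t10) | (!is.na(t5) & t10 >= t5 - 1e-12)))
  }
})

test_that("between-arm mortality difference is exactly zero in the first five years", {
  cfg <- small_config()
  cmp <- compare_durations(cfg, calib = calib_2549_small(), n = 50000,
                           mortality_only = TRUE, keep_records = TRUE)
  for (ch in cmp$records) {
    f <- ch$five$records; t <- ch$ten$records
    early5 <- !is.na(f$bc_time) & f$bc_time <= 5
    early10 <- !is.na(t$bc_time) & t$bc_time <= 5
    expect_identical(early5, early10)
    expect_identical(f$bc_time[early5], t$bc_time[early10])
  }
})

test_that("identical multipliers and shared draws give identical death times", {
  cfg <- small_config()
  for (key in names(cfg$hazard_ratios))
    cfg$hazard_ratios[[key]]$hr10 <- cfg$hazard_ratios[[key]]$hr5
  cmp <- compare_durations(cfg, calib = calib_2549_small(), n = 20000,
                           mortality_only = TRUE, keep_records = TRUE)
  for (ch in cmp$records) {
    expect_identical(ch$five$records$t_death, ch$ten$records$t_death)
    expect_identical(ch$five$records$bc_death, ch$ten$records$bc_death)
  }
})

test_that("completion scaling is continuous, monotone, and identity at full completion", {
  expect_identical(hr_effective(0.54, 1), 0.54)
  expect_equal(hr_effective(0.54, 0.7), 1 - 0.7 * 0.46, tolerance = 1e-12)
  cc <- seq(0.05, 1, by = 0.05)
  he <- hr_effective(0.54, cc)
  expect_true(all(diff(he) < 0))
  expect_lt(abs(hr_effective(0.54, 1e-9) - 1), 1e-8)
  expect_error(hr_effective(0.54, 0), "\\(0, 1\\]")

  sc <- apply_completion(23.18, 24.68, list(c1 = 0.7, c2 = 0.7))
  expect_equal(sc$p5, 16.226, tolerance = 1e-9)
  idem <- apply_completion(23.18, 24.68, list(c1 = 1, c2 = 1))
  expect_identical(c(idem$p5, idem$p10), c(23.18, 24.68))
})

test_that("halving second-window completion leaves years 0-5 untouched and shrinks the benefit", {
  cfg <- small_config()
  calib <- calib_2549_small()
  cfg_half <- cfg
  cfg_half$completion$c2 <- 0.5
  base <- compare_durations(cfg, calib = calib, n = 100000,
                            mortality_only = TRUE, keep_records = TRUE)
  half <- compare_durations(cfg_half, calib = calib, n = 100000,
                            mortality_only = TRUE, keep_records = TRUE)
  # five-year arm and both arms' first five years are bit-identical
  expect_identical(base$records[[1]]$five$records$t_death,
                   half$records[[1]]$five$records$t_death)
  e_base <- base$records[[1]]$ten$records$bc_time
  e_half <- half$records[[1]]$ten$records$bc_time
  expect_identical(e_base[!is.na(e_base) & e_base <= 5],
                   e_half[!is.na(e_half) & e_half <= 5])
  # lifetime mortality reduction strictly smaller than base
  red_base <- -comparison_value(base, "bc_death")
  red_half <- -comparison_value(half, "bc_death")
  expect_lt(red_half, red_base)
  expect_gt(red_half, 0)
})
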