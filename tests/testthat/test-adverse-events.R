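make_profiles <- function(n, regimen = "tamoxifen") {
  data.frame(id = seq_len(n), regimen = regimen, stringsAsFactors = FALSE)
}

test_that("segment semantics follow the published durations and utilities", {
  cfg <- default_config()
  pe <- event_utility_segments("pulmonary_embolus", 3.0, cfg, "five_year", 40)
  expect_equal(unlist(pe), c(start = 3.0, end = 3.75, utility = 0.65))

  cardiac <- event_utility_segments("new_cardiac_condition", 2.0, cfg,
                                    "five_year", 40)
  expect_equal(unlist(cardiac), c(start = 2.0, end = 40, utility = 0.8))

  stroke <- event_utility_segments("stroke", 4.0, cfg, "five_year", 40)
  expect_equal(stroke$start, c(4, 5))
  expect_equal(stroke$end, c(5, 40))
  expect_equal(stroke$utility, c(0.7, 0.85))

  osteo5 <- event_utility_segments("osteoporosis", 2.0, cfg, "five_year", 40)
  expect_equal(unlist(osteo5), c(start = 2, end = 5, utility = 0.9))
  osteo10 <- event_utility_segments("osteoporosis", 2.0, cfg, "ten_year", 40)
  expect_equal(osteo10$end, 10)

  frac <- event_utility_segments("fracture", 1.5, cfg, "five_year", 40)
  expect_equal(unlist(frac), c(start = 1.5, end = 2.5, utility = 0.8))

  endo <- event_utility_segments("endometrial_cancer", 1.0, cfg,
                                 "five_year", 40)
  expect_equal(endo$utility, c(0.85, 0.9))

  # clipping at an early horizon
  stroke_clip <- event_utility_segments("stroke", 4.0, cfg, "five_year", 4.5)
  expect_equal(nrow(stroke_clip), 1L)
  expect_equal(stroke_clip$end, 4.5)

  expect_error(event_utility_segments("not_an_event", 1, cfg), "unknown")
  expect_error(event_utility_segments("stroke", 5, cfg, horizon_end = 4))
})

test_that("zero probabilities yield an empty event list", {
  cfg <- zero_ae_config(default_config())
  ae <- sample_adverse_events(make_profiles(1000), cfg, "five_year", seed = 1L)
  expect_identical(nrow(ae), 0L)
})

test_that("empirical event frequencies match the published probabilities within 3 binomial SEs", {
  cfg <- default_config()
  n <- 100000
  prof <- make_profiles(n)
  ae <- sample_adverse_events(prof, cfg, "five_year", seed = 3L)
  expected <- c(stroke = 0.0185, pulmonary_embolus = 0.0303,
                new_cardiac_condition = 0.0253, fracture = 0.0109,
                endometrial_cancer = 0.0098, osteoporosis = 0.137)
  for (ev in names(expected)) {
    p <- expected[[ev]]
    freq <- length(unique(ae$idx[ae$event == ev])) / n
    expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / n))
  }
  pg12 <- 0.7167
  n12 <- length(unique(ae$idx[grepl("^grade12", ae$event)]))
  expect_lt(abs(n12 / n - pg12), 3 * sqrt(pg12 * (1 - pg12) / n))
})

test_that("every woman with grade 1-2 toxicity carries exactly two dated instances", {
  cfg <- default_config()
  ae <- sample_adverse_events(make_profiles(20000), cfg, "ten_year", seed = 5L)
  g12 <- ae[grepl("^grade12", ae$event)]
  counts <- table(g12$idx)
  expect_true(all(counts == 2))
  # window start and midpoint of the 10-year window
  expect_setequal(unique(g12$onset), c(0, 5))
  expect_setequal(unique(g12$mult), c(0.9, 0.85))
})

test_that("arm coupling matches the Table-1 orderings event by event", {
  cfg <- default_config()
  n <- 100000
  prof <- make_profiles(n)
  ae5 <- sample_adverse_events(prof, cfg, "five_year", seed = 7L)
  ae10 <- sample_adverse_events(prof, cfg, "ten_year", seed = 7L)
  ids <- function(ae, ev) unique(ae$idx[ae$event == ev])
  # p10 >= p5 on tamoxifen: stroke, pulmonary embolus, endometrial cancer ->
  # the 5-year-arm cases are a subset of the 10-year-arm cases
  for (ev in c("stroke", "pulmonary_embolus", "endometrial_cancer")) {
    expect_length(setdiff(ids(ae5, ev), ids(ae10, ev)), 0)
  }
  # reversed ordering where p10 < p5 (new cardiac condition, fracture,
  # osteoporosis on tamoxifen)
  for (ev in c("new_cardiac_condition", "fracture", "osteoporosis")) {
    expect_length(setdiff(ids(ae10, ev), ids(ae5, ev)), 0)
  }
})

test_that("shared events occur at the same time in both arms; incremental cases fall in years 5-10", {
  cfg <- default_config()
  prof <- make_profiles(50000)
  ae5 <- sample_adverse_events(prof, cfg, "five_year", seed = 9L)
  ae10 <- sample_adverse_events(prof, cfg, "ten_year", seed = 9L)
  s5 <- ae5[event == "stroke" & start == onset]
  s10 <- ae10[event == "stroke" & start == onset]
  shared <- intersect(s5$idx, s10$idx)
  expect_identical(s5[idx %in% shared][order(idx)]$onset,
                   s10[idx %in% shared][order(idx)]$onset)
  extra <- setdiff(s10$idx, s5$idx)
  expect_true(all(s10[idx %in% extra]$onset > 5))
  expect_true(all(s5$onset <= 5))
})

test_that("an arm's event set does not depend on whether the other arm is sampled", {
  cfg <- default_config()
  prof <- make_profiles(5000)
  a <- sample_adverse_events(prof, cfg, "five_year", seed = 11L)
  invisible(sample_adverse_events(prof, cfg, "ten_year", seed = 11L))
  b <- sample_adverse_events(prof, cfg, "five_year", seed = 11L)
  expect_identical(a, b)
})

test_that("sampled segments agree with the scalar segment builder", {
  cfg <- default_config()
  prof <- make_profiles(5000, regimen = "aromatase_inhibitor")
  ae <- sample_adverse_events(prof, cfg, "ten_year", seed = 13L)
  pick <- ae[!grepl("^grade12", event), .SD[1], by = event]
  for (i in seq_len(nrow(pick))) {
    ref <- event_utility_segments(pick$event[i], pick$onset[i], cfg,
                                  "ten_year", Inf)
    got <- ae[idx == pick$idx[i] & event == pick$event[i]]
    expect_equal(got$start, ref$start)
    expect_equal(got$end, ref$end)
    expect_equal(got$mult, ref$utility)
  }
})
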