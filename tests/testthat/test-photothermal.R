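test_that("daily PTU contribution is lambda * (mu - base) above base, zero otherwise", {
  cfg <- ptu_config(base_temp = 3)
  expect_equal(daily_ptu(13, 0.5, cfg), 5.0)
  # days at or below the base temperature contribute nothing (strict inequality)
  expect_equal(daily_ptu(2, 0.7, cfg), 0)
  expect_equal(daily_ptu(3, 0.5, cfg), 0)
  expect_equal(daily_ptu(c(13, 2, 3, 23), c(0.5, 1, 1, 0.25), cfg),
               c(5, 0, 0, 5))
  expect_error(daily_ptu(10, 1.2), "\\[0, 1\\]")
  expect_error(daily_ptu(10, -0.1), "\\[0, 1\\]")
})

test_that("accumulation matches a brute-force day loop on random series", {
  set.seed(101)
  cfg <- ptu_config()
  for (i in 1:25) {
    env <- random_env(60)
    ends <- sort(sample(0:60, 2))
    expect_equal(as.numeric(accumulate_ptu(env, ends[1], ends[2], cfg)),
                 brute_ptu(env, ends[1], ends[2]), tolerance = 1e-12)
  }
})

test_that("half-open intervals are empty at start == end and additive over a split", {
  set.seed(202)
  cfg <- ptu_config()
  env <- random_env(60)
  expect_equal(as.numeric(accumulate_ptu(env, 17, 17, cfg)), 0)
  for (i in 1:20) {
    pts <- sort(sample(0:60, 3))
    expect_equal(as.numeric(accumulate_ptu(env, pts[1], pts[2], cfg)) +
                   as.numeric(accumulate_ptu(env, pts[2], pts[3], cfg)),
                 as.numeric(accumulate_ptu(env, pts[1], pts[3], cfg)),
                 tolerance = 1e-12)
  }
  # three days contributing 5.0 each sum to 15
  env5 <- flat_env(10, temp = 13, photoperiod = 12)
  expect_equal(as.numeric(accumulate_ptu(env5, 2, 5, cfg)), 15)
})

test_that("accumulation is monotone in the end day and zero on cold series", {
  set.seed(303)
  env <- random_env(40)
  cfg <- ptu_config()
  vals <- vapply(0:40, function(e) as.numeric(accumulate_ptu(env, 0, e, cfg)),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  cold <- flat_env(30, temp = 2.5)
  expect_equal(as.numeric(accumulate_ptu(cold, 0, 30)), 0)
  at_base <- flat_env(30, temp = 3)
  expect_equal(as.numeric(accumulate_ptu(at_base, 5, 25)), 0)
})

test_that("intervals outside environment coverage are rejected naming the range", {
  env <- flat_env(10, start = 5)   # covers days 5..14
  expect_error(accumulate_ptu(env, 0, 8), "not covered")
  expect_error(accumulate_ptu(env, 10, 20), "not covered")
  # closed convention needs the end day itself
  expect_error(accumulate_ptu(env, 10, 14, ptu_config(convention = "closed")), NA)
  expect_error(accumulate_ptu(env, 10, 15, ptu_config(convention = "closed")),
               "not covered")
})

test_that("closed convention includes both endpoint days", {
  env <- flat_env(10, temp = 13, photoperiod = 12)
  expect_equal(as.numeric(accumulate_ptu(env, 2, 5, ptu_config(convention = "closed"))),
               20)
})

test_that("logger aggregation averages daylight readings and flags gap days", {
  pp <- data.frame(day = 0:2, sunrise = 6, sunset = 18)
  log <- data.frame(
    day = c(rep(0, 4), rep(1, 2), rep(2, 4)),
    hour = c(7, 10, 13, 16,  2, 22,  7, 10, 13, 16),    # day 1: night only
    temp = c(10, 10, 10, 10,  30, 30,  8, 12, 8, 12))
  expect_warning(env <- daylight_mean_from_log(log, pp), "day\\(s\\) 1")
  expect_equal(env$temp_daylight[c(1, 3)], c(10, 10))
  expect_true(is.na(env$temp_daylight[2]))
  expect_equal(attr(env, "gap_days"), 1)
  expect_equal(env$photoperiod, rep(12, 3))
  # the gap is a hard error inside an accumulation interval...
  expect_error(accumulate_ptu(env, 0, 3), "missing daylight temperature")
  # ...unless gap filling is explicitly enabled
  filled <- suppressMessages(
    accumulate_ptu(env, 0, 3, ptu_config(gap_fill = TRUE, max_gap = 1)))
  expect_equal(as.numeric(filled), 0.5 * (10 - 3) * 3, tolerance = 1e-12)
})

test_that("per-plant vegetative and flowering PTU are computed and flagged", {
  env <- flat_env(100, temp = 13, photoperiod = 12)
  rec <- data.frame(plant_id = c("p1", "p2"), accession = "a", regime = "only",
                    cohort = c(1L, 2L),
                    germination = c(0L, 7L), bolting = c(30L, NA),
                    flowering_init = c(40L, NA), flowering_term = c(70L, 60L),
                    senescence = c(90L, 90L))
  out <- ptu_for_records(rec, list(only = env))
  expect_equal(out$vegetative_ptu[1], 40 * 5)
  expect_equal(out$flowering_ptu[1], 30 * 5)
  expect_true(is.na(out$vegetative_ptu[2]) && out$flagged[2])
  expect_false(out$flagged[1])
  expect_error(ptu_for_records(rec, list(other = env)), "regime")
})

test_that("environment series validation rejects gaps and bad photoperiods", {
  expect_error(env_series(c(0, 1, 3), c(1, 2, 3), c(12, 12, 12)), "contiguous")
  expect_error(env_series(0:2, c(1, 2, 3), c(12, 25, 12)), "photoperiod")
  expect_s3_class(env_series(0:2, c(1, 2, 3), c(0, 12, 24)), "env_series")
})
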