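test_that("SIg matches the direct variance-ratio computation", {
  g <- c(0, 7, 14, 21, 28)
  e <- c(30, 30.5, 31, 31.5, 32)
  s <- sig_index(g, e)
  expect_equal(s$sig, log2(var(g) / var(e)))
  expect_equal(s$var_germination, var(g))
  expect_equal(s$var_event, var(e))
  expect_identical(s$classification, "synchronized")
})

test_that("SIg sign convention: halved variance is +1, doubled is -1", {
  g <- c(0, 7, 14, 21, 28)
  expect_equal(sig_index(g, g / sqrt(2))$sig, 1)
  expect_equal(sig_index(g, g * sqrt(2))$sig, -1)
  expect_equal(sig_index(g, g)$sig, 0)
  expect_identical(sig_index(g, g)$classification, "neutral")
})

test_that("zero event variance gives +Inf with an exactness flag; zero germination variance is undefined", {
  g <- c(0, 7, 14, 21, 28)
  s <- sig_index(g, rep(42, 5))
  expect_identical(s$sig, Inf)
  expect_identical(s$classification, "synchronized")
  expect_true(s$exact)
  u <- sig_index(rep(3, 4), c(1, 2, 3, 4))
  expect_identical(u$classification, "undefined")
  expect_true(is.na(u$sig))
})

test_that("SIg input contracts: cohort sets must match, >= 2 cohorts", {
  expect_error(sig_index(c(a = 1, b = 2), c(a = 1, c = 2)), "cohort sets differ")
  expect_error(sig_index(1, 2), "at least two")
  expect_error(sig_index(c(1, 2), c(1, NA)), "NA")
})

test_that("SIg shift-invariance, scale property and antisymmetry hold on random cohorts", {
  set.seed(11)
  for (i in 1:20) {
    g <- rnorm(5, sd = 10)
    e <- rnorm(5, sd = 3)
    s <- sig_index(g, e)$sig
    expect_equal(sig_index(g, e + 100)$sig, s)
    k <- runif(1, 0.2, 5)
    em <- mean(e) + k * (e - mean(e))
    expect_equal(sig_index(g, em)$sig, s - 2 * log2(k), tolerance = 1e-12)
    expect_equal(sig_index(e, g)$sig, -s, tolerance = 1e-12)
  }
})

test_that("cohort means exclude missing values and drop under-recorded cohorts", {
  rec <- data.frame(
    plant_id = sprintf("p%d", 1:5), accession = "a", regime = "r",
    cohort = c(1, 1, 2, 3, 3),
    germination = c(0, 0, 7, 14, 14),
    flowering_init = c(10, 12, 20, NA, NA))
  expect_warning(m <- cohort_event_means(rec, "flowering_init"), "dropped")
  expect_equal(m$cohort, c(1, 2))
  expect_equal(m$mean_day, c(11, 20))
  expect_equal(m$n, c(2, 1))
  # cohort 3 (0/2 recorded) can never contribute
  expect_false(3 %in% m$cohort)
  # the 50% policy drops a cohort where only 1 of 3 plants is recorded
  rec2 <- data.frame(
    plant_id = sprintf("q%d", 1:6), accession = "a", regime = "r",
    cohort = rep(c(1, 2), each = 3), germination = rep(c(0, 7), each = 3),
    flowering_init = c(10, 12, 20, 20, NA, NA))
  expect_warning(m2 <- cohort_event_means(rec2, "flowering_init"), "dropped")
  expect_equal(m2$cohort, 1)
})

test_that("classify_all_events reproduces deterministic zero-noise signs and flags single cohorts", {
  cfg <- sse_config(event_noise_sd = 0, temp_noise_sd = 0, rng_seed = 5)
  env <- simulate_environment(cfg, n_days = 170)
  rec <- simulate_cohort_phenology(cfg, env)
  tab <- classify_all_events(rec)
  expect_equal(nrow(tab), 2 * 4)   # two regimes x four events
  for (rg in c("colder", "warmer")) {
    sub <- tab[tab$regime == rg, ]
    expect_true(all(sub$sig[sub$event %in% c("bolting", "flowering_init")] < 0))
    # fixed-date termination/senescence with zero noise has zero variance
    ft <- sub[sub$event %in% c("flowering_term", "senescence"), ]
    expect_true(all(ft$sig == Inf))
    expect_true(all(ft$classification == "synchronized"))
  }
  # duplicate run on the same input is identical
  expect_identical(tab, classify_all_events(rec))
  # single cohort: everything undefined
  one <- rec[rec$cohort == 1, ]
  tab1 <- classify_all_events(one)
  expect_true(all(tab1$classification == "undefined"))
})

test_that("period lengths difference the event days and propagate missingness", {
  rec <- data.frame(germination = c(0, 0, 5), flowering_init = c(40, NA, 5),
                    flowering_term = c(70, 60, 5))
  out <- period_lengths(rec)
  expect_equal(out$vegetative_period, c(40, NA, 0))
  expect_equal(out$flowering_period, c(30, NA, 0))
})

test_that("correlation returns exact coefficients, labels and constant-input flags", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, -x + 10)$r, -1)
  expect_identical(correlate(x, rep(2, 5))$flagged, TRUE)
  expect_error(correlate(1:2, 1:2), "3 complete pairs")
  expect_error(correlate(1:4, 1:5), "equal length")
  set.seed(2)
  r <- correlate(rnorm(30), rnorm(30))
  expect_true(abs(r$r) <= 1)
  expect_identical(r$significance %in% c("***", "**", "*", "N.S."), TRUE)
})

test_that("zero-noise staggered initiation with synchronized termination gives r = -1", {
  cfg <- sse_config(event_noise_sd = 0, temp_noise_sd = 0, rng_seed = 5)
  env <- simulate_environment(cfg, n_days = 170)
  rec <- period_lengths(simulate_cohort_phenology(cfg, env))
  sub <- rec[rec$regime == "colder", ]
  veg <- tapply(sub$vegetative_period, sub$cohort, mean)
  flw <- tapply(sub$flowering_period, sub$cohort, mean)
  # fixed termination forces flowering = const - (g + vegetative): exact anti-linearity
  expect_equal(correlate(as.numeric(veg + 7 * (0:4)), as.numeric(flw))$r, -1,
               tolerance = 1e-12)
})
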