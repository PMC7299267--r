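test_that("simulated maps respect endpoints, ordering, uniqueness and marker counts", {
  # two markers on a 100 cM chromosome sit at the endpoints
  m2 <- simulate_genetic_map(ril_map_spec(lengths = 100, n_markers = 2))
  expect_equal(m2$pos, c(0, 100))
  # paper-scale default: 5 chromosomes, 144 markers
  mp <- simulate_genetic_map(ril_map_spec(), rng_seed = 7)
  expect_equal(nrow(mp), 144)
  expect_equal(length(unique(mp$chr)), 5)
  for (ch in 1:5) {
    p <- mp$pos[mp$chr == ch]
    expect_equal(p[1], 0)
    expect_true(all(diff(p) > 0))
  }
  # determinism contract
  expect_identical(mp, simulate_genetic_map(ril_map_spec(), rng_seed = 7))
  # too many markers for the length is rejected
  expect_error(simulate_genetic_map(ril_map_spec(lengths = 10, n_markers = 50)),
               "cannot fit")
})

test_that("RIL genotypes follow the Haldane chain: r = 0 is identity, large distance is independence", {
  # zero distance: identical alleles at both markers
  map0 <- toy_map(c(0, 0))
  cfg <- ril_config(n_lines = 200, rng_seed = 3)
  g0 <- simulate_ril_genotypes(map0, cfg)
  expect_identical(g0[, 1], g0[, 2])
  # 1000 cM: discordance ~ 0.5 within 3 binomial SDs
  n <- 10000
  map_far <- toy_map(c(0, 1000))
  gf <- simulate_ril_genotypes(map_far, ril_config(n_lines = n, rng_seed = 4))
  disc <- mean(gf[, 1] != gf[, 2])
  expect_lt(abs(disc - 0.5), 3 * sqrt(0.25 / n))
  # marginal allele frequency ~ 0.5 per marker
  freq <- colMeans(gf == "B")
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / n)))
})

test_that("adjacent-marker discordance converges to the Haldane fraction of the map distance", {
  d <- 25
  map <- toy_map(c(0, d))
  n <- 10000
  g <- simulate_ril_genotypes(map, ril_config(n_lines = n, rng_seed = 8))
  r <- haldane_r(d)
  disc <- mean(g[, 1] != g[, 2])
  expect_lt(abs(disc - r), 3 * sqrt(r * (1 - r) / n))
})

test_that("phenotypes follow the configured architecture exactly in degenerate cases", {
  map <- toy_map(c(0, 50, 100))
  # zero effects: line means are grand mean + noise that vanishes as sd -> 0
  cfg <- ril_config(n_lines = 20, residual_sd = 1e-9, grand_mean = 7,
                    rng_seed = 5)
  g <- simulate_ril_genotypes(map, cfg)
  ph <- simulate_ril_phenotypes(g, map, cfg)
  expect_equal(unname(ph$line_means), rep(7, 20), tolerance = 1e-6)
  # one additive QTL, (near) zero noise: exactly two classes split by allele
  cfgq <- ril_config(n_lines = 50, residual_sd = 1e-9,
                     qtl_effects = data.frame(chr = 1, pos = 50, effect = 2),
                     rng_seed = 6)
  gq <- simulate_ril_genotypes(map, cfgq)
  phq <- simulate_ril_phenotypes(gq, map, cfgq)
  classes <- round(phq$line_means, 3)
  expect_setequal(unique(classes), c(0, 2))
  expect_equal(unname(classes == 2), unname(gq[, 2] == "B"))
  # replicate table has the configured shape and line means are replicate means
  expect_equal(nrow(phq$replicates), 50 * 8)
  expect_equal(unname(phq$line_means["RIL001"]),
               mean(phq$replicates$value[phq$replicates$line == "RIL001"]))
})

test_that("a QTL configured for a 25% variance share lands near 25% at n = 500", {
  map <- simulate_genetic_map(ril_map_spec(), rng_seed = 7)
  eff <- qtl_effect_for_share(0.25, residual_sd = 1, n_replicates = 8)
  cfg <- ril_config(n_lines = 500,
                    qtl_effects = data.frame(chr = 2, pos = map$pos[match("M2.15", map$marker)],
                                             effect = eff),
                    rng_seed = 13)
  g <- simulate_ril_genotypes(map, cfg)
  ph <- simulate_ril_phenotypes(g, map, cfg)
  # least-squares oracle on the simulated table
  x <- as.integer(g[, "M2.15"] == "B")
  r2 <- summary(lm(ph$line_means ~ x))$r.squared
  expect_gte(r2, 0.20)
  expect_lte(r2, 0.30)
})

test_that("epistatic terms have no marginal effect under the product coding", {
  map <- structure(data.frame(marker = c("M1.01", "M2.01"), chr = c(1, 2),
                              pos = c(0, 0)),
                   class = c("genetic_map", "data.frame"))
  cfg <- ril_config(n_lines = 4000, residual_sd = 1e-6,
                    epistatic_pairs = data.frame(chr1 = 1, pos1 = 0,
                                                 chr2 = 2, pos2 = 0, effect = 1),
                    rng_seed = 17)
  g <- simulate_ril_genotypes(map, cfg)
  ph <- simulate_ril_phenotypes(g, map, cfg)
  x1 <- as.integer(g[, 1] == "B"); x2 <- as.integer(g[, 2] == "B")
  # marginal regressions see (almost) nothing; the product sees everything
  expect_lt(summary(lm(ph$line_means ~ x1))$r.squared, 0.01)
  expect_lt(summary(lm(ph$line_means ~ x2))$r.squared, 0.01)
  expect_gt(summary(lm(ph$line_means ~ I((2 * x1 - 1) * (2 * x2 - 1))))$r.squared,
            0.99)
})

test_that("config invariants: QTL inside the map, positive residual sd", {
  expect_error(ril_config(qtl_effects = data.frame(chr = 1, pos = 999, effect = 1)),
               "outside")
  expect_error(ril_config(residual_sd = 0), "> 0")
  expect_error(ril_config(n_lines = 1), ">= 2")
})
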