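test_that("scan LOD at fully typed markers equals the least-squares oracle", {
  set.seed(41)
  map <- toy_map(c(0, 15, 30, 45, 60))
  cfg <- ril_config(n_lines = 60, rng_seed = 14)
  g <- simulate_ril_genotypes(map, cfg)
  y <- rnorm(60) + 0.8 * (g[, 3] == "B")
  names(y) <- rownames(g)
  pr <- genotype_probabilities(map, g, step = 5)
  sc <- hk_scan(pr, y)
  at <- match(map$marker, sc$name)
  for (j in seq_along(at)) {
    x <- as.integer(g[, j] == "B")
    expect_equal(sc$lod[at[j]], lm_lod(unname(y), x), tolerance = 1e-8)
  }
})

test_that("a constant phenotype gives LOD zero everywhere and zero thresholds", {
  map <- toy_map(c(0, 20, 40))
  g <- simulate_ril_genotypes(map, ril_config(n_lines = 30, rng_seed = 1))
  pr <- genotype_probabilities(map, g, step = 10)
  y <- setNames(rep(5, 30), rownames(g))
  expect_true(all(hk_scan(pr, y)$lod == 0))
  pt <- permutation_thresholds(pr, y, n_perm = 100, seed = 2)
  expect_true(all(pt$maxima == 0))
  expect_true(all(pt$thresholds == 0))
})

test_that("a strong simulated QTL is located on the right chromosome near its true position", {
  dat <- make_ril_dataset(
    n_lines = 200, seed = 31, step = 2,
    qtl = data.frame(chr = 3, pos = 50, effect = qtl_effect_for_share(0.25)))
  sc <- hk_scan(dat$pr, dat$ph$line_means)
  top <- sc[which.max(sc$lod), ]
  expect_equal(top$chr, 3)
  expect_lt(abs(top$pos - 50), 10)
})

test_that("covariates increase power at a second QTL and obey the exclusion window", {
  map <- simulate_genetic_map(ril_map_spec(), rng_seed = 7)
  eff <- qtl_effect_for_share(0.20)
  qtl <- data.frame(chr = c(1, 4), pos = c(40, 60), effect = c(eff, eff))
  gain <- 0
  for (s in 1:12) {
    cfg <- ril_config(n_lines = 105, qtl_effects = qtl, rng_seed = 100 + s)
    g <- simulate_ril_genotypes(map, cfg)
    ph <- simulate_ril_phenotypes(g, map, cfg)
    pr <- genotype_probabilities(map, g, step = 1000)
    sc0 <- hk_scan(pr, ph$line_means)
    # covariate: marker nearest the chromosome-4 QTL
    m4 <- map[map$chr == 4, ]
    cov_mk <- m4$marker[which.min(abs(m4$pos - 60))]
    sc1 <- hk_scan(pr, ph$line_means, covariates = cov_mk, window = 2)
    i1 <- which(sc0$chr == 1)
    at <- i1[which.min(abs(sc0$pos[i1] - 40))]
    gain <- gain + (sc1$lod[at] - sc0$lod[at])
    # window contract: the covariate is excluded at its own position,
    # where the scan therefore equals the covariate-free scan
    at_cov <- which(sc0$name == cov_mk)
    expect_equal(sc1$lod[at_cov], sc0$lod[at_cov], tolerance = 1e-10)
  }
  expect_gt(gain / 12, 0)   # residual-variance reduction in expectation
})

test_that("CIM with zero covariates reduces to the plain scan, and covariate count is bounded", {
  dat <- make_ril_dataset(n_lines = 60, seed = 8,
                          qtl = data.frame(chr = 2, pos = 30, effect = 1))
  sc_hk <- hk_scan(dat$pr, dat$ph$line_means)
  sc_cim0 <- cim_scan(dat$pr, dat$ph$line_means, n_covariates = 0)
  expect_equal(sc_cim0$lod, sc_hk$lod, tolerance = 1e-12)
  expect_error(cim_scan(dat$pr, dat$ph$line_means, n_covariates = 60),
               "smaller than the number of lines")
  # with covariates allowed, the true QTL's marker region is picked first
  sc_cim <- cim_scan(dat$pr, dat$ph$line_means, n_covariates = 3)
  cov_sel <- attr(sc_cim, "covariates")
  expect_gte(length(cov_sel), 1)
  first <- dat$pr$grid[match(cov_sel[1], dat$pr$grid$name), ]
  expect_equal(first$chr, 2)
  expect_lt(abs(first$pos - 30), 15)
})

test_that("permutation thresholds are reproducible under a fixed seed and ordered by alpha", {
  dat <- make_ril_dataset(n_lines = 105, seed = 9)
  p1 <- permutation_thresholds(dat$pr, dat$ph$line_means, n_perm = 200, seed = 77)
  p2 <- permutation_thresholds(dat$pr, dat$ph$line_means, n_perm = 200, seed = 77)
  expect_identical(p1$thresholds, p2$thresholds)
  expect_lt(p1$thresholds["0.63"], p1$thresholds["0.05"])
  expect_error(permutation_thresholds(dat$pr, dat$ph$line_means, n_perm = 50),
               ">= 100")
})

test_that("Bayes credible interval matches hand-normalised posteriors", {
  # two-point grid, LOD {0, 3}: posterior {1/1001, 1000/1001}; the 95%
  # interval is the high point alone
  sc <- fake_scan(chr = 1, pos = c(0, 10), lod = c(0, 3))
  ci <- bayes_interval(sc, 1, 0.95)
  expect_equal(as.numeric(ci), c(10, 10))
  expect_equal(attr(ci, "covered_mass"), 1000 / 1001, tolerance = 1e-12)
  # flat LOD: interval spans >= 95% of the grid mass, flagged
  scf <- fake_scan(chr = 2, pos = seq(0, 100, by = 5), lod = rep(0, 21))
  cif <- bayes_interval(scf, 2, 0.95)
  expect_true(attr(cif, "flat"))
  expect_gte(attr(cif, "covered_mass"), 0.95)
  expect_gte(diff(cif), 0.94 * 100)
  # a single dominant sharp peak contains the peak position
  scp <- fake_scan(chr = 3, pos = 0:20, lod = c(rep(0, 10), 6, rep(0, 10)))
  cip <- bayes_interval(scp, 3)
  expect_true(cip["lo"] <= 10 && cip["hi"] >= 10)
  expect_error(bayes_interval(scp, 9), "cover")
})

test_that("peak calling respects thresholds, tiers and leftmost tie-break", {
  sc <- rbind(fake_scan(1, 0:10, c(rep(0, 4), 4, 4, rep(0, 5))),
              fake_scan(2, 0:10, c(rep(0, 5), 2, rep(0, 5))),
              fake_scan(3, 0:10, rep(0.1, 11)))
  attr(sc, "n") <- 100
  class(sc) <- c("qtl_scan", "data.frame")
  pk <- call_peaks(sc, thresholds = c(3, 1.5))
  expect_equal(nrow(pk), 2)
  expect_equal(pk$tier, c("significant", "suggestive"))
  expect_equal(pk$pos[pk$chr == 1], 4)   # leftmost of the tied maxima
  expect_equal(pk$r2[pk$chr == 1], 100 * (1 - 10^(-2 * 4 / 100)))
  # all-below-suggestive: empty
  expect_equal(nrow(call_peaks(sc, thresholds = c(10, 5))), 0)
})

test_that("multi-QTL fit decomposes variance and rejects collinear peaks", {
  dat <- make_ril_dataset(
    n_lines = 300, seed = 23, step = 2,
    qtl = data.frame(chr = c(1, 3), pos = c(40, 60),
                     effect = c(qtl_effect_for_share(0.2), qtl_effect_for_share(0.2))))
  fit <- fit_multi_qtl(dat$pr, dat$ph$line_means,
                       peaks = data.frame(chr = c(1, 3), pos = c(40, 60)))
  expect_equal(nrow(fit$terms), 2)
  expect_true(fit$total_r2 <= 100)
  expect_true(all(fit$terms$r2 > 5))
  # single peak: drop-one R2 equals the single-regression R2
  fit1 <- fit_multi_qtl(dat$pr, dat$ph$line_means,
                        peaks = data.frame(chr = 1, pos = 40))
  expect_equal(fit1$terms$r2[1], fit1$total_r2, tolerance = 1e-12)
  # zero-effect phenotype: all R2 near zero
  set.seed(99)
  ynull <- setNames(rnorm(length(dat$ph$line_means)), names(dat$ph$line_means))
  fit0 <- fit_multi_qtl(dat$pr, ynull, peaks = data.frame(chr = c(1, 3), pos = c(40, 60)))
  expect_lt(fit0$total_r2, 5)
  # duplicated peak position is collinear
  expect_error(fit_multi_qtl(dat$pr, dat$ph$line_means,
                             peaks = data.frame(chr = c(1, 1), pos = c(40, 40))),
               "collinear")
})
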