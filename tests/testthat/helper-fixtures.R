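# shared fixture builders; everything is generated in code, no stored data

# flat environment: constant daylight temperature and photoperiod
flat_env <- function(n_days = 60, temp = 13, photoperiod = 12, start = 0) {
  env_series(seq.int(start, start + n_days - 1), rep(temp, n_days),
             rep(photoperiod, n_days))
}

# environment with per-day random temperature/photoperiod
random_env <- function(n_days = 60, start = 0) {
  env_series(seq.int(start, start + n_days - 1),
             runif(n_days, -2, 25), runif(n_days, 6, 18))
}

# small one-chromosome map with markers at given positions
toy_map <- function(pos = c(0, 10, 20, 30, 40), chr = 1) {
  structure(data.frame(marker = sprintf("M%d.%02d", chr, seq_along(pos)),
                       chr = chr, pos = pos),
            class = c("genetic_map", "data.frame"))
}

# independent per-day PTU accumulation oracle (plain loop, half-open)
brute_ptu <- function(env, start, end, base = 3) {
  total <- 0
  d <- start
  while (d < end) {
    i <- which(env$day == d)
    mu <- env$temp_daylight[i]; lam <- env$photoperiod[i] / 24
    if (!is.na(mu) && mu > base) total <- total + lam * (mu - base)
    d <- d + 1
  }
  total
}

# independent single-marker regression LOD oracle via lm()
lm_lod <- function(y, x) {
  n <- length(y)
  rss0 <- sum(resid(lm(y ~ 1))^2)
  rss1 <- sum(resid(lm(y ~ x))^2)
  (n / 2) * log10(rss0 / rss1)
}

# minimal hand-built scan object
fake_scan <- function(chr, pos, lod, n = 100) {
  out <- data.frame(chr = chr, pos = pos, marker = NA_character_,
                    name = sprintf("c%s.loc%g", chr, pos), lod = lod)
  attr(out, "n") <- n
  class(out) <- c("qtl_scan", "data.frame")
  out
}

# a fast paper-scale RIL dataset with an optional additive QTL
make_ril_dataset <- function(n_lines = 105, seed = 1, qtl = NULL, step = 1000,
                             residual_sd = 1, map_seed = 7) {
  map <- simulate_genetic_map(ril_map_spec(), rng_seed = map_seed)
  cfg <- ril_config(n_lines = n_lines, qtl_effects = qtl,
                    residual_sd = residual_sd, rng_seed = seed)
  geno <- simulate_ril_genotypes(map, cfg)
  ph <- simulate_ril_phenotypes(geno, map, cfg)
  pr <- genotype_probabilities(map, geno, step = step)
  list(map = map, cfg = cfg, geno = geno, ph = ph, pr = pr)
}
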