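#' Configuration of a simulated sequential-seeding experiment
#'
#' Describes the stated world of the cohort simulator: five cohorts sown at
#' 7-day intervals, eight replicate plants per cohort, grown under two
#' temperature regimes about 3 C apart. Flowering is ruled by a
#' photothermal-unit threshold (plants flower once their accumulated
#' vegetative PTU reaches a constant amount), bolting by a fixed PTU lead
#' below that threshold, and flowering termination / whole-plant senescence
#' by a seasonal cue: a fixed calendar day per regime.
#'
#' The default environment is a late-autumn decline: daylight temperature
#' starting at 20 C and cooling by 0.14 C per day, photoperiod following a
#' seasonal cosine with its minimum near the winter solstice. Under this
#' world later cohorts need progressively more calendar days to collect the
#' same PTU, which stretches bolting/flowering initiation apart
#' (desynchrony) while the fixed seasonal end dates pull termination and
#' senescence together (synchrony).
#'
#' @param n_cohorts Number of cohorts (>= 2); default 5.
#' @param seeding_interval Days between successive sowings (> 0); default 7.
#' @param replicates_per_cohort Plants per cohort per regime (>= 1); default 8.
#' @param regimes Named list; each element a list with `offset` (degrees C
#'   added to the shared base temperature series), `flowering_term_day` and
#'   `senescence_day` (fixed seasonal event days for the regime).
#' @param ptu_flowering_threshold Vegetative PTU at which flowering
#'   initiates (degree C * daylight-days); default 200.
#' @param bolting_lead PTU lead of bolting below the flowering threshold;
#'   default 40.
#' @param event_noise_sd Gaussian day-jitter SD applied independently to
#'   each post-germination event (>= 0); default 1.5 days.
#' @param temp_start,temp_slope,temp_min Daylight temperature profile:
#'   `temp_start + temp_slope * day`, floored at `temp_min`.
#' @param temp_noise_sd Day-to-day temperature jitter SD, shared between
#'   regimes so the configured offset holds exactly on every day.
#' @param photoperiod_mean,photoperiod_amplitude,solstice_day Photoperiod
#'   seasonal curve `mean - amplitude * cos(2*pi*(day - solstice)/365)`,
#'   clamped to `[0, 24]` hours.
#' @param base_temp Base temperature for the PTU rule (degrees C); default 3.
#' @param rng_seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A list of class `"sse_config"`.
#' @export
sse_config <- function(n_cohorts = 5L, seeding_interval = 7L,
                       replicates_per_cohort = 8L,
                       regimes = list(
                         colder = list(offset = 0, flowering_term_day = 115L,
                                       senescence_day = 130L),
                         warmer = list(offset = 3, flowering_term_day = 105L,
                                       senescence_day = 120L)),
                       ptu_flowering_threshold = 200,
                       bolting_lead = 40,
                       event_noise_sd = 1.5,
                       temp_start = 20, temp_slope = -0.14, temp_min = 0,
                       temp_noise_sd = 0.5,
                       photoperiod_mean = 12, photoperiod_amplitude = 2.2,
                       solstice_day = 19,
                       base_temp = 3,
                       rng_seed = 1L) {
  if (n_cohorts < 2L) stop("`n_cohorts` must be >= 2", call. = FALSE)
  if (seeding_interval <= 0) stop("`seeding_interval` must be > 0", call. = FALSE)
  if (replicates_per_cohort < 1L) stop("`replicates_per_cohort` must be >= 1", call. = FALSE)
  if (event_noise_sd < 0) stop("`event_noise_sd` must be >= 0", call. = FALSE)
  if (is.null(names(regimes)) || any(names(regimes) == ""))
    stop("`regimes` must be a named list", call. = FALSE)
  for (nm in names(regimes)) {
    r <- regimes[[nm]]
    if (!all(c("offset", "flowering_term_day", "senescence_day") %in% names(r)))
      stop("regime '", nm, "' needs offset, flowering_term_day, senescence_day",
           call. = FALSE)
    if (r$senescence_day < r$flowering_term_day)
      stop("regime '", nm, "': senescence before flowering termination", call. = FALSE)
  }
  if (bolting_lead < 0 || bolting_lead > ptu_flowering_threshold)
    stop("`bolting_lead` must lie in [0, ptu_flowering_threshold]", call. = FALSE)
  structure(list(n_cohorts = as.integer(n_cohorts),
                 seeding_interval = as.numeric(seeding_interval),
                 replicates_per_cohort = as.integer(replicates_per_cohort),
                 regimes = regimes,
                 ptu_flowering_threshold = ptu_flowering_threshold,
                 bolting_lead = bolting_lead,
                 event_noise_sd = event_noise_sd,
                 temp_start = temp_start, temp_slope = temp_slope,
                 temp_min = temp_min, temp_noise_sd = temp_noise_sd,
                 photoperiod_mean = photoperiod_mean,
                 photoperiod_amplitude = photoperiod_amplitude,
                 solstice_day = solstice_day,
                 base_temp = base_temp,
                 rng_seed = as.integer(rng_seed)),
            class = "sse_config")
}

#' Simulate the daily environment of each regime
#'
#' Generates one daily environment series per regime. All regimes share one
#' realisation of the base temperature profile (including its day-to-day
#' weather jitter); a regime's series is the base plus its configured
#' offset, so the warmer regime exceeds the colder one by exactly the offset
#' on every day.
#'
#' @param config An [sse_config()].
#' @param start_day First day offset (default 0 = first sowing).
#' @param n_days Number of days to generate (>= 1).
#'
#' @return Named list of [env_series()], one per regime.
#' @export
simulate_environment <- function(config, start_day = 0L, n_days = 170L) {
  stopifnot(inherits(config, "sse_config"))
  if (n_days < 1L) stop("`n_days` must be >= 1", call. = FALSE)
  set.seed(config$rng_seed)
  day <- seq.int(start_day, start_day + n_days - 1L)
  base <- config$temp_start + config$temp_slope * day +
    stats::rnorm(n_days, 0, config$temp_noise_sd)
  pp <- config$photoperiod_mean - config$photoperiod_amplitude *
    cos(2 * pi * (day - config$solstice_day) / 365)
  pp <- pmin(24, pmax(0, pp))
  lapply(config$regimes, function(r)
    env_series(day, pmax(config$temp_min, base + r$offset), pp))
}

# first day f (> g) at which PTU accumulated over [g, f) reaches `target`;
# NA if never reached within the series
ptu_crossing_day <- function(env, g, target, pconf) {
  idx <- which(env$day >= g)
  if (!length(idx)) return(NA_integer_)
  contrib <- daily_ptu(env$temp_daylight[idx], env$photoperiod[idx] / 24, pconf)
  cum <- cumsum(contrib)
  k <- which(cum >= target)
  if (!length(k)) return(NA_integer_)
  env$day[idx[k[1]]] + 1L   # event day excluded under half-open convention
}

#' Simulate cohort phenology under the PTU-threshold / seasonal-cue rules
#'
#' Each plant germinates at its cohort's seeding offset (no germination
#' noise: sowing dates are controlled). It bolts on the first day its
#' accumulated PTU (from germination, half-open) reaches
#' `threshold - bolting_lead`, initiates flowering at the threshold, and
#' terminates flowering / senesces on the regime's fixed seasonal days.
#' Independent Gaussian day-jitter (rounded to whole days) is added to every
#' post-germination event; jitters are re-drawn (up to 100 times, then the
#' events are sorted) so the life-cycle ordering g <= bolting <= fi <= ft <=
#' senescence holds in every record. Plants whose threshold is never reached
#' within the environment horizon are flagged (`censored = TRUE`) with
#' missing flowering dates.
#'
#' @param config An [sse_config()].
#' @param env Named list of [env_series()] per regime, e.g. from
#'   [simulate_environment()] (must cover every cohort's lifespan).
#' @param accession Accession label stamped on the records (default "simA").
#'
#' @return A plant-record data frame (one row per plant) with the standard
#'   phenology columns plus `censored`.
#' @export
simulate_cohort_phenology <- function(config, env, accession = "simA") {
  stopifnot(inherits(config, "sse_config"))
  if (!setequal(names(env), names(config$regimes)))
    stop("`env` must contain one series per configured regime", call. = FALSE)
  pconf <- ptu_config(base_temp = config$base_temp)
  horizon <- max(vapply(config$regimes, function(r) r$senescence_day, numeric(1)))
  for (nm in names(env)) {
    if (max(env[[nm]]$day) < horizon ||
        min(env[[nm]]$day) > 0)
      stop("environment for regime '", nm,
           "' does not cover the simulated lifespan [0, ", horizon, "]",
           call. = FALSE)
  }
  set.seed(config$rng_seed + 1L)
  rows <- list()
  for (rg in names(config$regimes)) {
    e <- env[[rg]]; rcfg <- config$regimes[[rg]]
    for (co in seq_len(config$n_cohorts)) {
      g <- as.integer(round((co - 1L) * config$seeding_interval))
      b0 <- ptu_crossing_day(e, g, config$ptu_flowering_threshold - config$bolting_lead, pconf)
      fi0 <- ptu_crossing_day(e, g, config$ptu_flowering_threshold, pconf)
      ft0 <- as.integer(rcfg$flowering_term_day)
      sn0 <- as.integer(rcfg$senescence_day)
      for (rep_i in seq_len(config$replicates_per_cohort)) {
        censored <- is.na(fi0)
        ev <- jitter_events(g, b0, fi0, ft0, sn0, config$event_noise_sd)
        if (censored) { ev["fi"] <- NA_integer_; ev["ft"] <- NA_integer_ }
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = sprintf("%s_%s_c%d_r%d", accession, rg, co, rep_i),
          accession = accession, regime = rg, cohort = co,
          germination = g,
          bolting = ev[["b"]], flowering_init = ev[["fi"]],
          flowering_term = ev[["ft"]], senescence = ev[["sn"]],
          leaves_at_bolting = max(0L, as.integer(round(stats::rnorm(1, 12, 1.2)))),
          rosette_diameter_mm = round(stats::rnorm(1, 50, 4), 1),
          fruit_count = stats::rpois(1, 60),
          censored = censored)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# add independent rounded Gaussian jitter to the post-germination events,
# resampling until the life-cycle ordering holds (sort as a last resort)
jitter_events <- function(g, b, fi, ft, sn, sd) {
  base <- c(b = b, fi = fi, ft = ft, sn = sn)
  if (sd == 0) return(base)
  present <- !is.na(base)
  for (try in 1:100) {
    ev <- base
    ev[present] <- as.integer(round(base[present] + stats::rnorm(sum(present), 0, sd)))
    ev[present] <- pmax(ev[present], g)
    if (!is.unsorted(ev[present])) return(ev)
  }
  ev[present] <- sort(ev[present])
  ev
}
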