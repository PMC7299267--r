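#' Photothermal accumulation settings
#'
#' Bundles the base temperature and interval conventions used by the PTU
#' engine. Photothermal units (PTU, degree C * daylight-days) accumulate
#' daily as `lambda_i * (mu_Li - mu_b)`, where `lambda_i` is the photoperiod
#' as a fraction of 24 h and `mu_Li` the mean daylight temperature, counting
#' only days with `mu_Li` strictly greater than the base temperature `mu_b`.
#'
#' @param base_temp Base temperature `mu_b` in degrees C. The default, 3 C,
#'   is the optimised base temperature for modelling Arabidopsis (Col-0)
#'   developmental rate.
#' @param convention Which endpoint days an accumulation interval includes.
#'   `"half_open"` (default) counts the start day but not the end day, so
#'   vegetative PTU (germination to flowering initiation) and flowering PTU
#'   (initiation to termination) add up exactly to the whole-life PTU.
#'   `"closed"` includes both endpoints.
#' @param gap_fill Fill missing daylight-temperature days by linear
#'   interpolation? Off by default: a gap inside an accumulation interval is
#'   a hard error.
#' @param max_gap Longest run of consecutive missing days the gap filler is
#'   allowed to bridge (ignored unless `gap_fill = TRUE`).
#'
#' @return A list of class `"ptu_config"`.
#' @export
ptu_config <- function(base_temp = 3, convention = c("half_open", "closed"),
                       gap_fill = FALSE, max_gap = 2L) {
  convention <- match.arg(convention)
  if (!is.numeric(base_temp) || length(base_temp) != 1L || !is.finite(base_temp))
    stop("`base_temp` must be a single finite number", call. = FALSE)
  if (!is.logical(gap_fill) || length(gap_fill) != 1L)
    stop("`gap_fill` must be TRUE or FALSE", call. = FALSE)
  structure(list(base_temp = base_temp, convention = convention,
                 gap_fill = isTRUE(gap_fill), max_gap = as.integer(max_gap)),
            class = "ptu_config")
}

#' Daily environment series
#'
#' Constructs and validates the per-day environment table the PTU engine
#' consumes: one row per calendar day (stored as an integer day offset from
#' a run-level reference date), with the mean daylight temperature and the
#' photoperiod in hours.
#'
#' @param day Integer day offsets, contiguous and strictly increasing.
#' @param temp_daylight Mean daylight temperature per day (degrees C). `NA`
#'   marks a logger gap; gaps are tolerated here but rejected later by
#'   [accumulate_ptu()] unless gap filling is enabled.
#' @param photoperiod Hours of daylight per day, in `[0, 24]`.
#'
#' @return A data frame of class `"env_series"` with columns `day`,
#'   `temp_daylight`, `photoperiod`.
#' @export
env_series <- function(day, temp_daylight, photoperiod) {
  day <- as.integer(day)
  n <- length(day)
  if (n < 1L) stop("environment series must contain at least one day", call. = FALSE)
  if (length(temp_daylight) != n || length(photoperiod) != n)
    stop("`day`, `temp_daylight` and `photoperiod` must have equal length", call. = FALSE)
  if (anyNA(day)) stop("`day` must not contain NA", call. = FALSE)
  if (n > 1L && !all(diff(day) == 1L))
    stop("days must be contiguous and strictly increasing; gaps at day(s) ",
         paste(day[which(diff(day) != 1L)] + 1L, collapse = ", "), call. = FALSE)
  bad_pp <- which(!is.na(photoperiod) & (photoperiod < 0 | photoperiod > 24))
  if (length(bad_pp))
    stop("photoperiod outside [0, 24] at day(s) ",
         paste(day[bad_pp], collapse = ", "), call. = FALSE)
  out <- data.frame(day = day,
                    temp_daylight = as.numeric(temp_daylight),
                    photoperiod = as.numeric(photoperiod))
  class(out) <- c("env_series", "data.frame")
  out
}

#' Daily PTU contribution
#'
#' `lambda * (mu_L - mu_b)` when the mean daylight temperature exceeds the
#' base temperature, zero otherwise (strict inequality). Vectorised over
#' days.
#'
#' @param temp_daylight Mean daylight temperature(s) `mu_Li`, degrees C.
#' @param photoperiod_fraction Photoperiod(s) as a fraction of 24 h,
#'   `lambda_i` in `[0, 1]`.
#' @param config A [ptu_config()].
#'
#' @return Numeric vector of daily PTU contributions (degree C * daylight-days).
#' @export
daily_ptu <- function(temp_daylight, photoperiod_fraction, config = ptu_config()) {
  lam <- photoperiod_fraction
  bad <- which(!is.na(lam) & (lam < 0 | lam > 1))
  if (length(bad))
    stop("photoperiod fraction outside [0, 1] at position(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  contrib <- ifelse(!is.na(temp_daylight) & temp_daylight > config$base_temp,
                    lam * (temp_daylight - config$base_temp), 0)
  contrib[is.na(temp_daylight)] <- NA_real_
  contrib
}

#' Accumulate PTU over a day interval
#'
#' Sums daily PTU contributions between two day offsets under the configured
#' endpoint convention. Under the default half-open convention the interval
#' `[start, end)` includes `start` but not `end`, which makes abutting
#' intervals exactly additive.
#'
#' @param env An [env_series()].
#' @param start,end Integer day offsets, `start <= end`, both inside the
#'   series coverage.
#' @param config A [ptu_config()].
#'
#' @return A single numeric PTU value of class `"ptu_value"`, with
#'   attributes `interval` (start, end) and `n_contributing_days` (days with
#'   a positive contribution).
#' @export
accumulate_ptu <- function(env, start, end, config = ptu_config()) {
  stopifnot(inherits(env, "env_series"))
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1L || length(end) != 1L)
    stop("`start` and `end` must be single day offsets", call. = FALSE)
  if (is.na(start) || is.na(end)) stop("`start`/`end` must not be NA", call. = FALSE)
  if (start > end) stop("`start` must be <= `end`", call. = FALSE)
  last_needed <- if (config$convention == "half_open") end - 1L else end
  if (start < min(env$day) || (last_needed >= start && last_needed > max(env$day)))
    stop(sprintf("interval [%s, %s] not covered by environment series [%s, %s]",
                 start, end, min(env$day), max(env$day)), call. = FALSE)
  days <- if (config$convention == "half_open") {
    if (end == start) integer(0) else seq.int(start, end - 1L)
  } else seq.int(start, end)
  idx <- match(days, env$day)
  temp <- env$temp_daylight[idx]
  if (anyNA(temp)) {
    if (config$gap_fill) {
      temp_all <- fill_gaps(env$temp_daylight, config$max_gap)
      temp <- temp_all[idx]
      if (anyNA(temp))
        stop("environment gap longer than `max_gap` inside interval at day(s) ",
             paste(days[is.na(temp)], collapse = ", "), call. = FALSE)
      message("gap-filled ", sum(is.na(env$temp_daylight[idx])),
              " missing environment day(s) by linear interpolation")
    } else {
      stop("missing daylight temperature inside interval at day(s) ",
           paste(days[is.na(temp)], collapse = ", "),
           "; enable gap_fill in ptu_config() to interpolate", call. = FALSE)
    }
  }
  contrib <- daily_ptu(temp, env$photoperiod[idx] / 24, config)
  structure(sum(contrib),
            interval = c(start = start, end = end),
            n_contributing_days = sum(contrib > 0),
            class = "ptu_value")
}

# linear interpolation across NA runs no longer than max_gap
fill_gaps <- function(x, max_gap) {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- x
  for (k in which(r$values)) {
    if (r$lengths[k] > max_gap) next
    i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
    if (i0 < 1L || i1 > length(x)) next       # cannot anchor at series edge
    out[starts[k]:ends[k]] <-
      x[i0] + (x[i1] - x[i0]) * (seq_len(r$lengths[k])) / (r$lengths[k] + 1L)
  }
  out
}

#' Aggregate a sub-daily temperature log to a daily environment series
#'
#' Averages logger readings whose time of day falls inside the daylight
#' window `[sunrise, sunset)` of each day; the photoperiod is
#' `sunset - sunrise` in hours. Days without any daylight reading are
#' flagged as gaps (temperature `NA`), never silently interpolated.
#'
#' @param log Data frame with columns `day` (integer offset), `hour`
#'   (time of day, decimal hours in `[0, 24)`) and `temp` (degrees C).
#' @param photoperiod Data frame with columns `day`, `sunrise`, `sunset`
#'   (decimal hours), one row per day, contiguous.
#'
#' @return An [env_series()]; gap days carry `NA` temperature and are listed
#'   in the `gap_days` attribute (with a warning).
#' @export
daylight_mean_from_log <- function(log, photoperiod) {
  need_log <- c("day", "hour", "temp")
  need_pp <- c("day", "sunrise", "sunset")
  if (!all(need_log %in% names(log)))
    stop("`log` must have columns ", paste(need_log, collapse = ", "), call. = FALSE)
  if (!all(need_pp %in% names(photoperiod)))
    stop("`photoperiod` must have columns ", paste(need_pp, collapse = ", "), call. = FALSE)
  pp <- photoperiod[order(photoperiod$day), , drop = FALSE]
  if (any(pp$sunset < pp$sunrise))
    stop("sunset before sunrise at day(s) ",
         paste(pp$day[pp$sunset < pp$sunrise], collapse = ", "), call. = FALSE)
  mu <- rep(NA_real_, nrow(pp))
  for (i in seq_len(nrow(pp))) {
    sel <- log$day == pp$day[i] & log$hour >= pp$sunrise[i] & log$hour < pp$sunset[i]
    if (any(sel)) mu[i] <- mean(log$temp[sel])
  }
  gaps <- pp$day[is.na(mu)]
  if (length(gaps))
    warning("no daylight readings on day(s) ", paste(gaps, collapse = ", "),
            "; flagged as gaps", call. = FALSE)
  out <- env_series(pp$day, mu, pp$sunset - pp$sunrise)
  attr(out, "gap_days") <- gaps
  out
}

#' Per-plant vegetative and flowering PTU
#'
#' Computes, for every plant record, the PTU accumulated over the vegetative
#' period (germination to flowering initiation) and the flowering period
#' (initiation to termination), using the environment series of the plant's
#' regime.
#'
#' @param records Plant-record data frame (see [read_phenology()] for the
#'   column contract); must carry `germination`, `flowering_init`,
#'   `flowering_term` and `regime`.
#' @param env A single [env_series()] (applied to all plants) or a named
#'   list of series keyed by regime label.
#' @param config A [ptu_config()].
#'
#' @return A data frame with one row per plant: `plant_id`, `regime`,
#'   `cohort`, `vegetative_ptu`, `flowering_ptu`, and a logical `flagged`
#'   column marking plants with a missing event (their PTUs are `NA`).
#' @export
ptu_for_records <- function(records, env, config = ptu_config()) {
  if (inherits(env, "env_series")) {
    env <- stats::setNames(list(env), unique(as.character(records$regime))[1])
    if (length(unique(records$regime)) > 1L)
      stop("records span several regimes; supply a named list of environment series",
           call. = FALSE)
  }
  missing_regimes <- setdiff(unique(as.character(records$regime)), names(env))
  if (length(missing_regimes))
    stop("no environment series for regime(s): ",
         paste(missing_regimes, collapse = ", "), call. = FALSE)
  n <- nrow(records)
  veg <- flow <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    e <- env[[as.character(records$regime[i])]]
    g <- records$germination[i]; fi <- records$flowering_init[i]
    ft <- records$flowering_term[i]
    if (!is.na(g) && !is.na(fi)) veg[i] <- as.numeric(accumulate_ptu(e, g, fi, config))
    if (!is.na(fi) && !is.na(ft)) flow[i] <- as.numeric(accumulate_ptu(e, fi, ft, config))
  }
  data.frame(plant_id = records$plant_id,
             regime = records$regime,
             cohort = records$cohort,
             vegetative_ptu = veg,
             flowering_ptu = flow,
             flagged = is.na(veg) | is.na(flow))
}
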