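#' Per-cohort means of a phenological event
#'
#' First step of the SIg computation: within each accession x regime group,
#' average the event day over the plants of each cohort. A cohort
#' contributes only if at least `min_prop` of its plants have the event
#' recorded, so a mean is never driven by one or two survivors.
#'
#' @param records Plant-record data frame (internal columns; see
#'   [read_phenology()]).
#' @param event Event column name: one of `"germination"`, `"bolting"`,
#'   `"flowering_init"`, `"flowering_term"`, `"senescence"`.
#' @param by Grouping columns, default accession and regime.
#' @param min_prop Minimum proportion of non-missing plants for a cohort to
#'   contribute (default 0.5).
#'
#' @return Data frame with columns `by...`, `cohort`, `mean_day`, `n`,
#'   `n_total`. Cohorts failing the missing-data policy are dropped with a
#'   warning.
#' @export
cohort_event_means <- function(records, event,
                               by = c("accession", "regime"),
                               min_prop = 0.5) {
  if (!event %in% names(records))
    stop("unknown event column: ", event, call. = FALSE)
  sp <- split(records, interaction(records[by], drop = TRUE, lex.order = TRUE))
  out <- lapply(sp, function(grp) {
    co <- split(grp[[event]], grp$cohort)
    rows <- lapply(names(co), function(cname) {
      v <- co[[cname]]
      data.frame(cohort = as.integer(cname),
                 mean_day = if (sum(!is.na(v)) >= 1L) mean(v, na.rm = TRUE) else NA_real_,
                 n = sum(!is.na(v)), n_total = length(v))
    })
    res <- do.call(rbind, rows)
    drop <- res$n < pmax(1, ceiling(min_prop * res$n_total))
    if (any(drop))
      warning(sprintf("event '%s': cohort(s) %s dropped (%s) — fewer than %.0f%% plants recorded",
                      event, paste(res$cohort[drop], collapse = ", "),
                      paste(unlist(grp[1, by]), collapse = "/"), 100 * min_prop),
              call. = FALSE)
    res <- res[!drop, , drop = FALSE]
    for (b in by) res[[b]] <- grp[[b]][1]
    res[, c(by, "cohort", "mean_day", "n", "n_total")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res[[by[1]]], res[[by[length(by)]]], res$cohort), , drop = FALSE]
}

#' SIg synchronization index
#'
#' `SIg = log2( Var(germination cohort means) / Var(event cohort means) )`.
#' Positive values mean the event is more synchronized across cohorts than
#' germination was (SIg = 1 and 2 correspond to halved and quartered
#' variance); negative values mean desynchronization (SIg = -1 and -2 to
#' doubled and quadrupled variance). Variances are sample variances (n - 1)
#' across cohort means; the estimator choice cancels in the ratio because
#' both inputs must cover the same cohorts.
#'
#' @param germination_means Per-cohort mean germination days. If named, the
#'   names (cohort labels) must match `event_means`.
#' @param event_means Per-cohort mean event days, same cohorts.
#' @param event Optional event label carried into the result.
#'
#' @return A list of class `"sig_result"`: `event`, `var_germination`,
#'   `var_event`, `sig`, `classification` (one of `"synchronized"`,
#'   `"desynchronized"`, `"neutral"`, `"undefined"`), `exact` (TRUE when the
#'   event variance is exactly zero, making SIg `+Inf`), `n_cohorts`.
#' @export
sig_index <- function(germination_means, event_means, event = NA_character_) {
  g <- germination_means; e <- event_means
  if (length(g) != length(e))
    stop("germination and event means must cover the same cohorts", call. = FALSE)
  if (!is.null(names(g)) && !is.null(names(e)) && !identical(names(g), names(e)))
    stop("cohort sets differ between germination and event means: ",
         paste(union(setdiff(names(g), names(e)), setdiff(names(e), names(g))),
               collapse = ", "), call. = FALSE)
  if (length(g) < 2L)
    stop("at least two cohorts are required", call. = FALSE)
  if (anyNA(g) || anyNA(e))
    stop("cohort means must not contain NA", call. = FALSE)
  vg <- stats::var(g); ve <- stats::var(e)
  exact <- FALSE
  if (vg == 0) {
    sig <- NA_real_; cls <- "undefined"
  } else if (ve == 0) {
    sig <- Inf; cls <- "synchronized"; exact <- TRUE
  } else {
    sig <- log2(vg / ve)
    cls <- if (sig > 0) "synchronized" else if (sig < 0) "desynchronized" else "neutral"
  }
  structure(list(event = event, var_germination = vg, var_event = ve,
                 sig = sig, classification = cls, exact = exact,
                 n_cohorts = length(g)),
            class = "sig_result")
}

#' @export
print.sig_result <- function(x, ...) {
  cat(sprintf("SIg[%s] = %.4g (%s%s; var germ = %.4g, var event = %.4g, %d cohorts)\n",
              x$event, x$sig, x$classification, if (x$exact) ", exact" else "",
              x$var_germination, x$var_event, x$n_cohorts))
  invisible(x)
}

#' SIg table for the four reproductive events
#'
#' Computes the SIg index for bolting, flowering initiation, flowering
#' termination and whole-plant senescence in every accession x regime group.
#' Germination-timing variance is computed across the cohort means of
#' germination day of the same cohorts that contribute to the event.
#'
#' @inheritParams cohort_event_means
#' @param events Event columns to classify (default the four reproductive
#'   events, in life-cycle order).
#' @param strong_band Absolute SIg magnitude labelled "strong" in the output
#'   (reporting annotation only; classification is by sign). Default 4.
#'
#' @return A data frame sorted by accession, regime and event order, one row
#'   per group x event, with columns `accession`, `regime`, `event`,
#'   `n_cohorts`, `var_germination`, `var_event`, `sig`, `classification`,
#'   `strong`.
#' @export
classify_all_events <- function(records,
                                events = c("bolting", "flowering_init",
                                           "flowering_term", "senescence"),
                                by = c("accession", "regime"),
                                min_prop = 0.5, strong_band = 4) {
  groups <- unique(records[by])
  groups <- groups[do.call(order, groups), , drop = FALSE]
  rows <- list()
  for (gi in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(records))
    for (b in by) sel <- sel & records[[b]] == groups[[b]][gi]
    grp <- records[sel, , drop = FALSE]
    for (ev in events) {
      em <- suppressWarnings(
        cohort_event_means(grp, ev, by = by, min_prop = min_prop))
      row <- groups[gi, , drop = FALSE]
      row$event <- ev
      if (nrow(em) < 2L) {
        row$n_cohorts <- nrow(em)
        row$var_germination <- NA_real_; row$var_event <- NA_real_
        row$sig <- NA_real_; row$classification <- "undefined"; row$strong <- NA
      } else {
        gm <- suppressWarnings(
          cohort_event_means(grp[grp$cohort %in% em$cohort, , drop = FALSE],
                             "germination", by = by, min_prop = 0))
        gm <- gm[match(em$cohort, gm$cohort), , drop = FALSE]
        s <- sig_index(stats::setNames(gm$mean_day, gm$cohort),
                       stats::setNames(em$mean_day, em$cohort), event = ev)
        row$n_cohorts <- s$n_cohorts
        row$var_germination <- s$var_germination; row$var_event <- s$var_event
        row$sig <- s$sig; row$classification <- s$classification
        row$strong <- is.finite(s$sig) && abs(s$sig) > strong_band || s$exact
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$event <- factor(out$event, levels = events)
  out <- out[do.call(order, out[c(by, "event")]), , drop = FALSE]
  out$event <- as.character(out$event)
  rownames(out) <- NULL
  out
}

#' Vegetative and flowering period lengths
#'
#' Vegetative period = flowering initiation - germination; flowering period
#' = flowering termination - initiation, in days. Missing events propagate
#' as `NA`.
#'
#' @param records Plant-record data frame.
#' @return The records with `vegetative_period` and `flowering_period`
#'   columns appended.
#' @export
period_lengths <- function(records) {
  records$vegetative_period <- records$flowering_init - records$germination
  records$flowering_period <- records$flowering_term - records$flowering_init
  records
}

#' Pearson correlation with a significance label
#'
#' The correlation statistic used for the cohort-level relationships (e.g.
#' vegetative vs. flowering period length). Constant input yields an
#' undefined, flagged result rather than an error.
#'
#' @param x,y Numeric vectors of equal length; pairs with any `NA` are
#'   dropped. At least 3 complete pairs required.
#' @return A list of class `"correlation_result"`: `r`, `n`, `p_value`,
#'   `significance` (`"***"` p<0.001, `"**"` p<0.01, `"*"` p<0.05, `"N.S."`),
#'   `flagged` (TRUE when undefined because an input is constant).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, n = n, p_value = NA_real_,
                          significance = NA_character_, flagged = TRUE),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- ct$p.value
  lab <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "N.S."
  structure(list(r = unname(ct$estimate), n = n, p_value = p,
                 significance = lab, flagged = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$flagged) cat("r undefined (constant input), n =", x$n, "\n")
  else cat(sprintf("r = %.3f (n = %d, %s)\n", x$r, x$n, x$significance))
  invisible(x)
}
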