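#' Single-QTL genome scan by Haley-Knott regression
#'
#' At every grid position, regresses the line phenotype on the expected
#' allele dosage (the probability of the B allele) and converts the fit to a
#' LOD score: `LOD = (n/2) * log10(RSS_reduced / RSS_full)`, where the
#' reduced model omits the position term but keeps any covariates. With no
#' covariates the reduced model is the intercept-only fit.
#'
#' @param probs A [genotype_probabilities()] result.
#' @param phenotype Named numeric vector of line means (names = line ids),
#'   or a data frame with columns `line` and `value`.
#' @param covariates Optional character vector of grid-position names whose
#'   dosages enter both models (a marker covariate set, as in composite
#'   interval mapping).
#' @param window Exclusion window in cM: a covariate on the same chromosome
#'   within `window` of the tested position (or numerically collinear with
#'   it) is dropped for that position. Default 0 (only exact collinearity
#'   is dropped).
#'
#' @return A data frame of class `"qtl_scan"` with columns `chr`, `pos`,
#'   `marker`, `name`, `lod`, and attributes `n`, `method`, `covariates`,
#'   `window`.
#' @export
hk_scan <- function(probs, phenotype, covariates = NULL, window = 0) {
  al <- align_phenotype(probs, phenotype)
  y <- al$y; X <- probs$pB[al$lines, , drop = FALSE]
  n <- length(y)
  if (n < 10L) stop("need at least 10 lines with phenotype and probabilities",
                    call. = FALSE)
  grid <- probs$grid
  if (is.null(covariates) || length(covariates) == 0L) {
    lod <- lod_fast(X, y)
    method <- "single-QTL HK"
  } else {
    miss <- setdiff(covariates, grid$name)
    if (length(miss)) stop("unknown covariate position(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    ci <- match(covariates, grid$name)
    C <- X[, ci, drop = FALSE]
    lod <- numeric(nrow(grid))
    for (j in seq_len(nrow(grid))) {
      drop <- grid$chr[ci] == grid$chr[j] & abs(grid$pos[ci] - grid$pos[j]) <= window
      Cj <- C[, !drop, drop = FALSE]
      # drop covariates numerically collinear with the tested dosage
      if (ncol(Cj)) {
        x_sd <- stats::sd(X[, j])
        if (x_sd > 0) {
          cc <- suppressWarnings(abs(stats::cor(X[, j], Cj)))
          cc[is.na(cc)] <- 0
          Cj <- Cj[, cc < 0.9999, drop = FALSE]
        }
      }
      lod[j] <- lod_qr(cbind(1, Cj), X[, j], y)
    }
    method <- "single-QTL HK + covariates"
  }
  out <- data.frame(chr = grid$chr, pos = grid$pos, marker = grid$marker,
                    name = grid$name, lod = lod)
  attr(out, "n") <- n
  attr(out, "method") <- method
  attr(out, "covariates") <- covariates
  attr(out, "window") <- window
  class(out) <- c("qtl_scan", "data.frame")
  out
}

# LOD for every column of X against y, intercept-only reduced model.
# Equivalent to the RSS-ratio form via r^2: LOD = -(n/2) log10(1 - r^2).
lod_fast <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy == 0) return(numeric(ncol(X)))
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- as.numeric(crossprod(Xc, yc))
  r2 <- ifelse(sxx > 0, sxy^2 / (sxx * syy), 0)
  r2 <- pmin(r2, 1 - 1e-15)
  -(n / 2) * log10(1 - r2)
}

# LOD from explicit reduced design R and position dosage x
lod_qr <- function(R, x, y) {
  n <- length(y)
  rss_red <- sum(stats::lm.fit(R, y)$residuals^2)
  if (stats::sd(x) == 0) return(0)
  rss_full <- sum(stats::lm.fit(cbind(R, x), y)$residuals^2)
  if (rss_red <= 0) return(0)
  max(0, (n / 2) * log10(rss_red / max(rss_full, 1e-300)))
}

align_phenotype <- function(probs, phenotype) {
  if (is.data.frame(phenotype)) {
    stopifnot(all(c("line", "value") %in% names(phenotype)))
    phenotype <- stats::setNames(phenotype$value, phenotype$line)
  }
  if (is.null(names(phenotype)))
    stop("phenotype must carry line ids as names (or a line/value data frame)",
         call. = FALSE)
  phenotype <- phenotype[!is.na(phenotype)]
  common <- intersect(probs$lines, names(phenotype))
  if (length(common) < 2L)
    stop("phenotype line ids do not match genotype probability lines", call. = FALSE)
  list(y = as.numeric(phenotype[common]), lines = common)
}

#' Composite interval mapping scan
#'
#' Selects up to `n_covariates` marker covariates by forward stepwise
#' regression of the phenotype on the typed-marker dosages (largest
#' residual-sum-of-squares reduction first, partial-F entry test at
#' `entry_alpha`, ties broken by genome order), then runs the Haley-Knott
#' scan with those covariates, excluding any covariate within `window` cM
#' of the tested position.
#'
#' @inheritParams hk_scan
#' @param window Covariate exclusion window in cM (default 2).
#' @param n_covariates Maximum number of marker covariates (default 3; must
#'   be smaller than the number of lines).
#' @param entry_alpha Partial-F significance required for a covariate to
#'   enter (default 0.05).
#' @return A `"qtl_scan"` data frame (see [hk_scan()]); the selected
#'   covariates are in `attr(, "covariates")`. With `n_covariates = 0` the
#'   result is identical to [hk_scan()].
#' @export
cim_scan <- function(probs, phenotype, window = 2, n_covariates = 3,
                     entry_alpha = 0.05) {
  al <- align_phenotype(probs, phenotype)
  if (n_covariates >= length(al$y))
    stop("`n_covariates` must be smaller than the number of lines", call. = FALSE)
  sel <- character(0)
  if (n_covariates > 0) {
    marker_idx <- which(!is.na(probs$grid$marker))   # genome order
    M <- probs$pB[al$lines, marker_idx, drop = FALSE]
    y <- al$y; n <- length(y)
    design <- matrix(1, n, 1)
    res <- stats::lm.fit(design, y)$residuals
    rss <- sum(res^2)
    for (k in seq_len(n_covariates)) {
      # residualize candidates against current design; RSS drop is
      # (x_r . y_r)^2 / (x_r . x_r)
      Q <- qr.Q(qr(design))
      Mr <- M - Q %*% crossprod(Q, M)
      yr <- res
      sxx <- colSums(Mr^2)
      sxy <- as.numeric(crossprod(Mr, yr))
      gain <- ifelse(sxx > 1e-10, sxy^2 / sxx, 0)
      gain[colnames(M) %in% sel] <- 0
      best <- which.max(gain)   # first max = genome order tie-break
      rss_new <- rss - gain[best]
      df2 <- n - ncol(design) - 1L
      if (df2 <= 0) break
      Fstat <- (rss - rss_new) / (rss_new / df2)
      if (stats::pf(Fstat, 1, df2, lower.tail = FALSE) > entry_alpha) break
      sel <- c(sel, colnames(M)[best])
      design <- cbind(design, M[, best])
      res <- stats::lm.fit(design, y)$residuals
      rss <- sum(res^2)
    }
  }
  out <- hk_scan(probs, phenotype, covariates = if (length(sel)) sel else NULL,
                 window = window)
  attr(out, "method") <- "CIM"
  attr(out, "covariates") <- sel
  out
}

#' Genome-wide LOD thresholds by permutation
#'
#' Shuffles the phenotype against the genotyped lines, records the
#' genome-wide maximum LOD of each permuted scan, and returns the empirical
#' `1 - alpha` quantiles of those maxima. The conventional alphas are 0.05
#' (significant) and 0.63 (suggestive).
#'
#' @inheritParams hk_scan
#' @param n_perm Number of permutations (>= 100).
#' @param alphas Genome-wide error rates; default `c(0.05, 0.63)`.
#' @param seed Integer seed; fixed seed gives identical thresholds.
#' @param batch Permutations processed per matrix block (memory control).
#'
#' @return A list of class `"perm_thresholds"`: `thresholds` (named by
#'   alpha), `maxima`, `n_perm`, `alphas`, `seed`.
#' @export
permutation_thresholds <- function(probs, phenotype, n_perm = 1000L,
                                   alphas = c(0.05, 0.63), seed = 1L,
                                   batch = 250L) {
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  al <- align_phenotype(probs, phenotype)
  y <- al$y; n <- length(y)
  X <- probs$pB[al$lines, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  sx <- sqrt(colSums(Xc^2))
  keep <- sx > 0
  set.seed(seed)
  maxima <- numeric(n_perm)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  if (sy == 0 || !any(keep)) {
    maxima[] <- 0
  } else {
    Xs <- sweep(Xc[, keep, drop = FALSE], 2, sx[keep], `/`)
    ys <- yc / sy
    done <- 0L
    while (done < n_perm) {
      b <- min(batch, n_perm - done)
      Y <- vapply(seq_len(b), function(i) ys[sample.int(n)], numeric(n))
      R2 <- pmin(crossprod(Xs, Y)^2, 1 - 1e-15)
      lod <- -(n / 2) * log10(1 - R2)
      maxima[done + seq_len(b)] <- apply(lod, 2, max)
      done <- done + b
    }
  }
  thr <- stats::quantile(maxima, 1 - alphas, names = FALSE, type = 7)
  structure(list(thresholds = stats::setNames(thr, format(alphas)),
                 maxima = maxima, n_perm = as.integer(n_perm),
                 alphas = alphas, seed = as.integer(seed)),
            class = "perm_thresholds")
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf("genome-wide LOD thresholds (%d permutations, seed %d):\n",
              x$n_perm, x$seed))
  for (i in seq_along(x$alphas))
    cat(sprintf("  alpha = %-5s -> LOD %.3f\n", format(x$alphas[i]), x$thresholds[i]))
  invisible(x)
}

#' Bayesian credible interval for a QTL peak
#'
#' Treats `10^LOD` as the likelihood and the position prior as uniform along
#' the chromosome: the posterior at each grid point is `10^LOD` normalised
#' over the chromosome. The interval is the smallest contiguous grid span
#' containing the peak whose posterior mass reaches `prob`, grown greedily
#' from the peak towards the neighbouring point with the larger posterior.
#'
#' @param scan A `"qtl_scan"` data frame.
#' @param chromosome Chromosome identifier present in the scan.
#' @param prob Target posterior mass (default 0.95).
#' @return Numeric `c(lo, hi)` in cM with attributes `covered_mass`,
#'   `peak_pos`, and `flat` (TRUE when the LOD profile is flat-zero, in
#'   which case the interval spans the whole chromosome).
#' @export
bayes_interval <- function(scan, chromosome, prob = 0.95) {
  sub <- scan[scan$chr == chromosome, , drop = FALSE]
  if (!nrow(sub)) stop("scan does not cover chromosome ", chromosome, call. = FALSE)
  sub <- sub[order(sub$pos), , drop = FALSE]
  lod <- sub$lod
  flat <- max(lod) - min(lod) < 1e-8
  post <- 10^(lod - max(lod))
  post <- post / sum(post)
  peak <- which(lod == max(lod))[1]   # leftmost tie
  lo <- hi <- peak
  mass <- post[peak]
  while (mass < prob && (lo > 1L || hi < length(post))) {
    left <- if (lo > 1L) post[lo - 1L] else -Inf
    right <- if (hi < length(post)) post[hi + 1L] else -Inf
    if (left >= right) { lo <- lo - 1L; mass <- mass + post[lo] }
    else { hi <- hi + 1L; mass <- mass + post[hi] }
  }
  structure(c(lo = sub$pos[lo], hi = sub$pos[hi]),
            covered_mass = mass, peak_pos = sub$pos[peak], flat = flat)
}

#' Call QTL peaks against permutation thresholds
#'
#' One peak per chromosome whose maximum LOD reaches the suggestive
#' threshold; peaks at or above the significant threshold are tiered
#' `"significant"`, the rest `"suggestive"`. Ties at the maximum go to the
#' lowest cM position. Each peak carries its nearest typed marker, the 95%
#' Bayesian credible interval, and the single-locus variance share
#' `R^2 = 100 * (1 - 10^(-2 LOD / n))`.
#'
#' @param scan A `"qtl_scan"` data frame.
#' @param thresholds A [permutation_thresholds()] result, or a numeric
#'   vector of length 2: `c(significant, suggestive)`.
#' @param prob Credible-interval mass (default 0.95).
#' @return A data frame of class `"qtl_peaks"`: `chr`, `pos`, `lod`,
#'   `nearest_marker`, `ci_lo`, `ci_hi`, `r2`, `tier`. Empty when nothing
#'   reaches the suggestive threshold.
#' @export
call_peaks <- function(scan, thresholds, prob = 0.95) {
  if (inherits(thresholds, "perm_thresholds")) {
    sig <- thresholds$thresholds[format(0.05)]
    sug <- thresholds$thresholds[format(0.63)]
    if (anyNA(c(sig, sug)))
      stop("thresholds must include alphas 0.05 and 0.63", call. = FALSE)
  } else {
    sig <- thresholds[1]; sug <- thresholds[2]
  }
  n <- attr(scan, "n")
  rows <- list()
  for (ch in unique(scan$chr)) {
    sub <- scan[scan$chr == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    i <- which(sub$lod == max(sub$lod))[1]
    if (sub$lod[i] < sug) next
    ci <- bayes_interval(scan, ch, prob)
    mk <- sub[!is.na(sub$marker), , drop = FALSE]
    nearest <- if (nrow(mk)) mk$marker[which.min(abs(mk$pos - sub$pos[i]))] else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      chr = ch, pos = sub$pos[i], lod = sub$lod[i], nearest_marker = nearest,
      ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
      r2 = if (!is.null(n)) 100 * (1 - 10^(-2 * sub$lod[i] / n)) else NA_real_,
      tier = if (sub$lod[i] >= sig) "significant" else "suggestive")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chr = integer(0), pos = numeric(0), lod = numeric(0),
               nearest_marker = character(0), ci_lo = numeric(0),
               ci_hi = numeric(0), r2 = numeric(0), tier = character(0))
  rownames(out) <- NULL
  class(out) <- c("qtl_peaks", "data.frame")
  out
}

#' Multi-QTL model fit and variance decomposition
#'
#' Jointly regresses the phenotype on the expected dosages at a set of QTL
#' peaks (plus optional pairwise interaction products) and reports the
#' percent phenotypic variance of each term by drop-one comparison:
#' `100 * (RSS_without - RSS_full) / TSS`, with the total
#' `100 * (1 - RSS_full / TSS)`.
#'
#' @inheritParams hk_scan
#' @param peaks Data frame with columns `chr` and `pos` (a
#'   [call_peaks()] result works); dosages are taken at the nearest grid
#'   position.
#' @param interactions `NULL`, or a two-column matrix/data frame of peak
#'   indices whose dosage products enter the model.
#' @return A list of class `"multi_qtl_fit"`: `total_r2`, `terms` (data
#'   frame `term`, `r2`), `coefficients`, `n`.
#' @export
fit_multi_qtl <- function(probs, phenotype, peaks, interactions = NULL) {
  al <- align_phenotype(probs, phenotype)
  y <- al$y; n <- length(y)
  if (!nrow(peaks)) stop("`peaks` is empty", call. = FALSE)
  cols <- integer(nrow(peaks))
  for (q in seq_len(nrow(peaks))) {
    on_chr <- which(probs$grid$chr == peaks$chr[q])
    if (!length(on_chr)) stop("no grid positions on chromosome ", peaks$chr[q],
                              call. = FALSE)
    cols[q] <- on_chr[which.min(abs(probs$grid$pos[on_chr] - peaks$pos[q]))]
  }
  X <- probs$pB[al$lines, cols, drop = FALSE]
  labels <- sprintf("q%d_c%s@%.4g", seq_len(nrow(peaks)), peaks$chr, peaks$pos)
  colnames(X) <- labels
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    cc <- abs(stats::cor(X))
    diag(cc) <- 0
    bad <- which(cc >= 0.9999, arr.ind = TRUE)
    pair <- if (nrow(bad)) paste(labels[bad[1, 1]], "and", labels[bad[1, 2]]) else "unknown pair"
    stop("collinear peaks: ", pair, call. = FALSE)
  }
  terms_list <- as.list(as.data.frame(X))
  names(terms_list) <- labels
  if (!is.null(interactions)) {
    interactions <- as.matrix(interactions)
    for (k in seq_len(nrow(interactions))) {
      i <- interactions[k, 1]; j <- interactions[k, 2]
      terms_list[[paste0(labels[i], ":", labels[j])]] <- X[, i] * X[, j]
    }
  }
  D <- do.call(cbind, terms_list)
  full <- stats::lm.fit(cbind(1, D), y)
  rss_full <- sum(full$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2_terms <- vapply(seq_len(ncol(D)), function(k) {
    red <- stats::lm.fit(cbind(1, D[, -k, drop = FALSE]), y)
    100 * (sum(red$residuals^2) - rss_full) / tss
  }, numeric(1))
  structure(list(total_r2 = 100 * (1 - rss_full / tss),
                 terms = data.frame(term = names(terms_list), r2 = r2_terms),
                 coefficients = stats::setNames(full$coefficients,
                                                c("(Intercept)", names(terms_list))),
                 n = n),
            class = "multi_qtl_fit")
}

#' @export
print.multi_qtl_fit <- function(x, ...) {
  cat(sprintf("multi-QTL fit (n = %d): total R^2 = %.2f%%\n", x$n, x$total_r2))
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("  %-24s %.2f%%\n", x$terms$term[i], x$terms$r2[i]))
  invisible(x)
}
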