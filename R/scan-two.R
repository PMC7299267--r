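#' Two-locus genome scan (additive and epistatic LOD decomposition)
#'
#' For every pair of grid positions (thinned to roughly `step` cM for
#' tractability), fits the full two-locus model with an interaction term
#' (`y ~ x1 + x2 + x1:x2`) and the additive model (`y ~ x1 + x2`) against
#' the null, giving `LOD_full`, `LOD_add` and their difference
#' `LOD_int = LOD_full - LOD_add`, the evidence for epistasis. Same-
#' chromosome pairs closer than `min_sep` are skipped to avoid collinear
#' dosages.
#'
#' @inheritParams hk_scan
#' @param step Pair-grid spacing in cM (default 10; coarser than the
#'   single-locus grid).
#' @param min_sep Minimum same-chromosome separation; default `2 * step`.
#' @param max_pairs Pair budget; a finer grid than the budget allows is
#'   rejected with a suggested step.
#' @return A data frame of class `"qtl_scan2"` in long format: `chr1`,
#'   `pos1`, `name1`, `chr2`, `pos2`, `name2`, `lod_full`, `lod_add`,
#'   `lod_int`; attribute `n`.
#' @export
scan_two <- function(probs, phenotype, step = 10, min_sep = NULL,
                     max_pairs = 50000L) {
  if (is.null(min_sep)) min_sep <- 2 * step
  al <- align_phenotype(probs, phenotype)
  y <- al$y; n <- length(y)
  if (n < 10L) stop("need at least 10 lines with phenotype and probabilities",
                    call. = FALSE)
  grid <- probs$grid
  keep <- integer(0)
  for (ch in unique(grid$chr)) {
    gi <- which(grid$chr == ch)
    gi <- gi[order(grid$pos[gi])]
    last <- -Inf
    for (j in gi) {
      if (grid$pos[j] - last >= step - 1e-9) {
        keep <- c(keep, j); last <- grid$pos[j]
      }
    }
  }
  sub <- grid[keep, , drop = FALSE]
  X <- probs$pB[al$lines, keep, drop = FALSE]
  K <- nrow(sub)
  pair_ok <- function(i, j)
    sub$chr[i] != sub$chr[j] || abs(sub$pos[i] - sub$pos[j]) >= min_sep
  n_pairs <- sum(vapply(seq_len(K - 1L), function(i)
    sum(vapply((i + 1L):K, function(j) pair_ok(i, j), logical(1))), integer(1)))
  if (n_pairs > max_pairs)
    stop(sprintf("%d position pairs exceed the budget of %d; increase `step` to about %.0f cM",
                 n_pairs, max_pairs, step * sqrt(n_pairs / max_pairs)), call. = FALSE)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  rows <- vector("list", n_pairs)
  k <- 0L
  one <- rep(1, n)
  for (i in seq_len(K - 1L)) {
    x1 <- X[, i]
    for (j in (i + 1L):K) {
      if (!pair_ok(i, j)) next
      x2 <- X[, j]
      if (rss0 == 0) {
        lod_add <- lod_full <- 0
      } else {
        rss_add <- sum(stats::lm.fit(cbind(one, x1, x2), y)$residuals^2)
        rss_full <- sum(stats::lm.fit(cbind(one, x1, x2, x1 * x2), y)$residuals^2)
        lod_add <- (n / 2) * log10(rss0 / max(rss_add, 1e-300))
        lod_full <- (n / 2) * log10(rss0 / max(rss_full, 1e-300))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(chr1 = sub$chr[i], pos1 = sub$pos[i],
                              name1 = sub$name[i],
                              chr2 = sub$chr[j], pos2 = sub$pos[j],
                              name2 = sub$name[j],
                              lod_full = lod_full, lod_add = lod_add,
                              lod_int = lod_full - lod_add)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "step") <- step
  class(out) <- c("qtl_scan2", "data.frame")
  out
}
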