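#' Conditional genotype probabilities on a pseudomarker grid
#'
#' Computes, for every line and every position on an evaluation grid
#' (markers plus pseudomarkers inserted so no gap exceeds `step` cM), the
#' probability of each parental allele given the typed markers. The
#' genotype along a chromosome is modelled as a two-state hidden Markov
#' chain with transition probabilities from the Haldane map function on the
#' inter-position distances; a forward-backward pass gives the posteriors.
#' Typed markers emit the observed allele with probability
#' `1 - error_rate`; missing genotypes and pseudomarkers are uninformative.
#'
#' @param map Genetic map data frame (`marker`, `chr`, `pos`).
#' @param genotypes Lines x markers character matrix of `"A"`/`"B"`/`NA`.
#' @param step Maximum pseudomarker spacing in cM (> 0); default 2.
#' @param error_rate Genotyping error probability (default 0: probabilities
#'   collapse to the observed allele at typed markers).
#'
#' @return A list of class `"geno_probs"`: `grid` (data frame `chr`, `pos`,
#'   `marker` — `NA` for pseudomarkers — and `name`), `pA` and `pB`
#'   (lines x grid-position probability matrices summing to 1), plus the
#'   call parameters. Lines with no typed marker on a chromosome get a flat
#'   0.5/0.5 posterior there and are listed in `uninformative`.
#' @export
genotype_probabilities <- function(map, genotypes, step = 2, error_rate = 0) {
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5)
    stop("`error_rate` must lie in [0, 0.5)", call. = FALSE)
  stopifnot(all(map$marker %in% colnames(genotypes)))
  n <- nrow(genotypes)
  lines <- rownames(genotypes)
  if (is.null(lines)) lines <- sprintf("line%03d", seq_len(n))

  grid_list <- list()
  for (ch in unique(map$chr)) {
    sub <- map[map$chr == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    pos <- sub$pos[1]; mk <- sub$marker[1]
    if (nrow(sub) > 1L) {
      for (j in seq_len(nrow(sub) - 1L)) {
        gap <- sub$pos[j + 1L] - sub$pos[j]
        n_ins <- max(0L, ceiling(gap / step) - 1L)
        if (n_ins > 0L) {
          ins <- sub$pos[j] + gap * seq_len(n_ins) / (n_ins + 1L)
          pos <- c(pos, ins); mk <- c(mk, rep(NA_character_, n_ins))
        }
        pos <- c(pos, sub$pos[j + 1L]); mk <- c(mk, sub$marker[j + 1L])
      }
    }
    nm <- ifelse(is.na(mk), sprintf("c%s.loc%g", ch, round(pos, 3)), mk)
    grid_list[[as.character(ch)]] <- data.frame(chr = ch, pos = pos, marker = mk,
                                                name = make.unique(nm))
  }
  grid <- do.call(rbind, grid_list)
  rownames(grid) <- NULL

  G <- nrow(grid)
  pA <- pB <- matrix(NA_real_, n, G, dimnames = list(lines, grid$name))
  uninformative <- character(0)

  for (ch in unique(grid$chr)) {
    gi <- which(grid$chr == ch)
    K <- length(gi)
    # emission likelihoods (n x K per state)
    eA <- matrix(1, n, K); eB <- matrix(1, n, K)
    for (k in seq_len(K)) {
      mkname <- grid$marker[gi[k]]
      if (!is.na(mkname)) {
        obs <- genotypes[, mkname]
        isA <- !is.na(obs) & obs == "A"
        isB <- !is.na(obs) & obs == "B"
        eA[isA, k] <- 1 - error_rate; eA[isB, k] <- error_rate
        eB[isB, k] <- 1 - error_rate; eB[isA, k] <- error_rate
      }
    }
    typed_any <- rowSums(eA != 1 | eB != 1) > 0
    uninformative <- c(uninformative,
                       lines[!typed_any][!(lines[!typed_any] %in% uninformative)])
    r <- if (K > 1L) haldane_r(diff(grid$pos[gi])) else numeric(0)
    # forward
    fA <- matrix(0, n, K); fB <- matrix(0, n, K)
    a <- 0.5 * eA[, 1]; b <- 0.5 * eB[, 1]
    s <- a + b; fA[, 1] <- a / s; fB[, 1] <- b / s
    if (K > 1L) for (k in 2:K) {
      a <- (fA[, k - 1] * (1 - r[k - 1]) + fB[, k - 1] * r[k - 1]) * eA[, k]
      b <- (fB[, k - 1] * (1 - r[k - 1]) + fA[, k - 1] * r[k - 1]) * eB[, k]
      s <- a + b; fA[, k] <- a / s; fB[, k] <- b / s
    }
    # backward
    bA <- matrix(1, n, K); bB <- matrix(1, n, K)
    if (K > 1L) for (k in (K - 1L):1L) {
      a <- (1 - r[k]) * eA[, k + 1] * bA[, k + 1] + r[k] * eB[, k + 1] * bB[, k + 1]
      b <- (1 - r[k]) * eB[, k + 1] * bB[, k + 1] + r[k] * eA[, k + 1] * bA[, k + 1]
      s <- a + b; bA[, k] <- a / s; bB[, k] <- b / s
    }
    num_a <- fA * bA; num_b <- fB * bB
    tot <- num_a + num_b
    pA[, gi] <- num_a / tot
    pB[, gi] <- num_b / tot
  }
  if (length(uninformative))
    warning("line(s) with no typed marker on some chromosome (flat posterior): ",
            paste(uninformative, collapse = ", "), call. = FALSE)
  structure(list(grid = grid, pA = pA, pB = pB, lines = lines,
                 step = step, error_rate = error_rate,
                 uninformative = uninformative),
            class = "geno_probs")
}

#' @export
print.geno_probs <- function(x, ...) {
  cat(sprintf("genotype probabilities: %d lines x %d grid positions (%d chromosomes, step %g cM, error rate %g)\n",
              length(x$lines), nrow(x$grid), length(unique(x$grid$chr)),
              x$step, x$error_rate))
  invisible(x)
}
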