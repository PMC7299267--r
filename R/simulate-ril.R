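#' Map specification for a simulated RIL population
#'
#' Chromosome lengths (cM) and marker counts. The default emulates the scale
#' of the published Arabidopsis Ler/Cvi RIL map: five chromosomes and 144
#' markers in total.
#'
#' @param lengths Chromosome lengths in cM (> 0).
#' @param n_markers Marker count per chromosome (>= 1), same length.
#' @return A list of class `"map_spec"`.
#' @export
ril_map_spec <- function(lengths = c(135, 98, 99, 104, 123),
                         n_markers = c(29, 29, 29, 29, 28)) {
  if (length(lengths) != length(n_markers))
    stop("`lengths` and `n_markers` must have equal length", call. = FALSE)
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (any(n_markers < 1)) stop("each chromosome needs >= 1 marker", call. = FALSE)
  structure(list(lengths = as.numeric(lengths), n_markers = as.integer(n_markers)),
            class = "map_spec")
}

#' Configuration of a simulated RIL mapping population
#'
#' The stated world: 105 recombinant inbred lines, eight replicate plants
#' per line, genotyped at a 144-marker / 5-chromosome map. Trait replicates
#' are `grand_mean + sum(additive effects) + sum(epistatic terms) + Gaussian
#' noise`; the line phenotype is the mean of its replicates.
#'
#' Additive effects are allelic-substitution effects: a QTL with effect `a`
#' adds `a` to carriers of the B allele (dosage coding 0/1). An epistatic
#' pair with effect `w` adds `w * (2*x1 - 1) * (2*x2 - 1)`, which has no
#' marginal effect when allele frequencies are 1/2.
#'
#' @param n_lines Number of RILs (>= 2); default 105.
#' @param replicates_per_line Plants per line (>= 1); default 8.
#' @param map_spec A [ril_map_spec()].
#' @param qtl_effects `NULL` or a data frame with columns `chr`, `pos`
#'   (cM, inside the chromosome), `effect` (trait units).
#' @param epistatic_pairs `NULL` or a data frame with columns `chr1`,
#'   `pos1`, `chr2`, `pos2`, `effect`.
#' @param residual_sd Replicate-level Gaussian noise SD (> 0); default 1.
#' @param grand_mean Trait grand mean; default 0.
#' @param rng_seed Integer seed.
#' @return A list of class `"ril_config"`.
#' @export
ril_config <- function(n_lines = 105L, replicates_per_line = 8L,
                       map_spec = ril_map_spec(),
                       qtl_effects = NULL, epistatic_pairs = NULL,
                       residual_sd = 1, grand_mean = 0, rng_seed = 1L) {
  if (n_lines < 2L) stop("`n_lines` must be >= 2", call. = FALSE)
  if (replicates_per_line < 1L) stop("`replicates_per_line` must be >= 1", call. = FALSE)
  if (residual_sd <= 0) stop("`residual_sd` must be > 0", call. = FALSE)
  if (!is.null(qtl_effects)) {
    stopifnot(all(c("chr", "pos", "effect") %in% names(qtl_effects)))
    for (i in seq_len(nrow(qtl_effects))) {
      ch <- qtl_effects$chr[i]
      if (ch < 1 || ch > length(map_spec$lengths) ||
          qtl_effects$pos[i] < 0 || qtl_effects$pos[i] > map_spec$lengths[ch])
        stop("QTL ", i, " lies outside its chromosome's map", call. = FALSE)
    }
  }
  if (!is.null(epistatic_pairs))
    stopifnot(all(c("chr1", "pos1", "chr2", "pos2", "effect") %in% names(epistatic_pairs)))
  structure(list(n_lines = as.integer(n_lines),
                 replicates_per_line = as.integer(replicates_per_line),
                 map_spec = map_spec, qtl_effects = qtl_effects,
                 epistatic_pairs = epistatic_pairs,
                 residual_sd = residual_sd, grand_mean = grand_mean,
                 rng_seed = as.integer(rng_seed)),
            class = "ril_config")
}

#' Simulate a genetic map
#'
#' Marker positions per chromosome: the first marker at 0 cM, the last at
#' the chromosome length, interior markers at jittered equal spacing
#' (deterministic under a fixed seed). Positions are sorted and unique.
#'
#' @param spec A [ril_map_spec()].
#' @param rng_seed Integer seed for the spacing jitter.
#' @param min_spacing Smallest admissible inter-marker gap in cM; a marker
#'   count that cannot fit at this spacing is rejected.
#' @return A data frame of class `"genetic_map"` with columns `marker`,
#'   `chr`, `pos` (cM).
#' @export
simulate_genetic_map <- function(spec, rng_seed = 1L, min_spacing = 1) {
  stopifnot(inherits(spec, "map_spec"))
  set.seed(rng_seed)
  rows <- list()
  for (ch in seq_along(spec$lengths)) {
    L <- spec$lengths[ch]; m <- spec$n_markers[ch]
    if (m > 1L && (m - 1L) * min_spacing > L)
      stop(sprintf("chromosome %d: %d markers cannot fit in %.4g cM at %.4g cM minimum spacing",
                   ch, m, L, min_spacing), call. = FALSE)
    if (m == 1L) {
      pos <- 0
    } else {
      pos <- seq(0, L, length.out = m)
      if (m > 2L) {
        gap <- L / (m - 1L)
        # jitter interior markers by < 40% of a gap: order and spacing survive
        pos[2:(m - 1L)] <- pos[2:(m - 1L)] +
          stats::runif(m - 2L, -0.4, 0.4) * min(gap, gap - min_spacing + gap * 0.01)
      }
      pos <- round(pos, 2)
    }
    rows[[ch]] <- data.frame(marker = sprintf("M%d.%02d", ch, seq_len(m)),
                             chr = ch, pos = pos)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$marker)) stop("internal error: duplicate marker names")
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Haldane map function
#'
#' Converts genetic distance to recombination fraction assuming no crossover
#' interference: `r = (1 - exp(-2 d / 100)) / 2` for `d` in cM.
#'
#' @param distance Genetic distance(s) in cM, >= 0.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(distance) {
  if (any(distance < 0)) stop("`distance` must be >= 0", call. = FALSE)
  (1 - exp(-2 * distance / 100)) / 2
}

#' Simulate RIL genotypes along a map
#'
#' Each line is a two-state mosaic of the parental alleles A and B. Along
#' each chromosome the genotype follows a Markov chain: the allele at the
#' first marker is drawn uniformly, and the allele switches between adjacent
#' markers with the Haldane recombination fraction of their cM distance.
#' Map distances are used as given (a published RIL map already embeds the
#' map expansion of the selfing generations).
#'
#' @param map A [simulate_genetic_map()] result (or any data frame with
#'   `marker`, `chr`, `pos`).
#' @param config A [ril_config()].
#' @return Character matrix of `"A"`/`"B"`, lines x markers, with line ids
#'   as row names and marker names as column names.
#' @export
simulate_ril_genotypes <- function(map, config) {
  stopifnot(inherits(config, "ril_config"))
  set.seed(config$rng_seed)
  n <- config$n_lines
  geno <- matrix(NA_integer_, n, nrow(map),
                 dimnames = list(sprintf("RIL%03d", seq_len(n)), map$marker))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    idx <- idx[order(map$pos[idx])]
    cur <- sample(c(0L, 1L), n, replace = TRUE)
    geno[, idx[1]] <- cur
    if (length(idx) > 1L) {
      r <- haldane_r(diff(map$pos[idx]))
      for (j in seq_along(r)) {
        flip <- stats::runif(n) < r[j]
        cur <- ifelse(flip, 1L - cur, cur)
        geno[, idx[j + 1L]] <- cur
      }
    }
  }
  mode(geno) <- "integer"
  out <- matrix(c("A", "B")[geno + 1L], n, ncol(geno), dimnames = dimnames(geno))
  out
}

# P(B at position pos | flanking marker genotypes), two-point Haldane chain
flank_prob_B <- function(map, geno_row, chr, pos) {
  idx <- which(map$chr == chr)
  idx <- idx[order(map$pos[idx])]
  p <- map$pos[idx]
  hit <- idx[abs(p - pos) < 1e-8]
  if (length(hit)) return(as.numeric(geno_row[hit[1]] == "B"))
  left <- idx[p < pos]; right <- idx[p > pos]
  pr <- 0.5
  if (length(left) && length(right)) {
    l <- left[length(left)]; r <- right[1]
    rl <- haldane_r(pos - map$pos[l]); rr <- haldane_r(map$pos[r] - pos)
    gl <- geno_row[l] == "B"; gr <- geno_row[r] == "B"
    pB <- (if (gl) 1 - rl else rl) * (if (gr) 1 - rr else rr)
    pA <- (if (gl) rl else 1 - rl) * (if (gr) rr else 1 - rr)
    pr <- pB / (pA + pB)
  } else if (length(left)) {
    l <- left[length(left)]; rl <- haldane_r(pos - map$pos[l])
    pr <- if (geno_row[l] == "B") 1 - rl else rl
  } else if (length(right)) {
    r <- right[1]; rr <- haldane_r(map$pos[r] - pos)
    pr <- if (geno_row[r] == "B") 1 - rr else rr
  }
  pr
}

#' Simulate RIL phenotypes with known genetic architecture
#'
#' Draws replicate trait values per line from the configured additive and
#' epistatic architecture plus Gaussian residual noise, and returns line
#' means (the quantity a QTL scan consumes) together with the replicate
#' table and the true QTL dosages.
#'
#' QTL not coinciding with a typed marker get their allele sampled from the
#' Haldane chain conditional on the flanking markers.
#'
#' @param genotypes Matrix from [simulate_ril_genotypes()].
#' @param map The matching genetic map.
#' @param config A [ril_config()] (its `qtl_effects`/`epistatic_pairs`
#'   define the architecture).
#' @return A list of class `"ril_phenotypes"`: `line_means` (named numeric),
#'   `replicates` (data frame `line`, `replicate`, `value`), `qtl_dosage`
#'   (lines x QTL matrix of 0/1 dosages, NULL if no QTL).
#' @export
simulate_ril_phenotypes <- function(genotypes, map, config) {
  stopifnot(inherits(config, "ril_config"))
  set.seed(config$rng_seed + 1L)
  n <- nrow(genotypes)
  m <- config$replicates_per_line
  genetic <- rep(config$grand_mean, n)
  dos <- NULL
  qtl <- config$qtl_effects
  if (!is.null(qtl) && nrow(qtl)) {
    dos <- matrix(0, n, nrow(qtl),
                  dimnames = list(rownames(genotypes),
                                  sprintf("q%d_c%s@%.4g", seq_len(nrow(qtl)),
                                          qtl$chr, qtl$pos)))
    for (q in seq_len(nrow(qtl))) {
      pB <- vapply(seq_len(n), function(i)
        flank_prob_B(map, genotypes[i, ], qtl$chr[q], qtl$pos[q]), numeric(1))
      dos[, q] <- ifelse(pB %in% c(0, 1), pB, stats::rbinom(n, 1, pB))
      genetic <- genetic + qtl$effect[q] * dos[, q]
    }
  }
  ep <- config$epistatic_pairs
  if (!is.null(ep) && nrow(ep)) {
    for (k in seq_len(nrow(ep))) {
      x1 <- vapply(seq_len(n), function(i) {
        p <- flank_prob_B(map, genotypes[i, ], ep$chr1[k], ep$pos1[k])
        if (p %in% c(0, 1)) p else stats::rbinom(1, 1, p)
      }, numeric(1))
      x2 <- vapply(seq_len(n), function(i) {
        p <- flank_prob_B(map, genotypes[i, ], ep$chr2[k], ep$pos2[k])
        if (p %in% c(0, 1)) p else stats::rbinom(1, 1, p)
      }, numeric(1))
      genetic <- genetic + ep$effect[k] * (2 * x1 - 1) * (2 * x2 - 1)
    }
  }
  values <- rep(genetic, each = m) + stats::rnorm(n * m, 0, config$residual_sd)
  replicates <- data.frame(line = rep(rownames(genotypes), each = m),
                           replicate = rep(seq_len(m), n),
                           value = values)
  lm_arr <- tapply(replicates$value, replicates$line, mean)
  line_means <- stats::setNames(as.vector(lm_arr), dimnames(lm_arr)[[1]])
  line_means <- line_means[rownames(genotypes)]   # keep genotype order
  structure(list(line_means = line_means, replicates = replicates,
                 qtl_dosage = dos),
            class = "ril_phenotypes")
}

#' Additive effect achieving a target variance share
#'
#' For a biallelic RIL QTL with allele frequency 1/2 (dosage variance 1/4),
#' the allelic-substitution effect `a` that makes the QTL explain the
#' fraction `share` of the variance of line means (the rest being
#' residual noise averaged over replicates) is
#' `a = 2 * residual_sd * sqrt(share / ((1 - share) * n_replicates))`.
#' The relation assumes a single-QTL architecture.
#'
#' @param share Target variance share in (0, 1).
#' @param residual_sd Replicate-level noise SD.
#' @param n_replicates Replicates averaged per line.
#' @return The additive effect in trait units.
#' @export
qtl_effect_for_share <- function(share, residual_sd = 1, n_replicates = 8L) {
  if (share <= 0 || share >= 1) stop("`share` must lie in (0, 1)", call. = FALSE)
  2 * residual_sd * sqrt(share / ((1 - share) * n_replicates))
}
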