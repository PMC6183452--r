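#' Alternate-allele frequencies
#' @param G Genotype matrix (samples x loci, calls 0/1/2).
#' @return Numeric vector of per-locus alternate-allele frequencies.
#' @export
allele_freqs <- function(G) colMeans(G) / 2

#' Per-locus diversity and inbreeding summary
#'
#' Expected heterozygosity `He = 2 p (1 - p)`, observed heterozygote
#' fraction `Ho`, and the inbreeding coefficient `Fis = 1 - Ho / He`
#' (defined only for polymorphic loci; the number of monomorphic loci
#' excluded from `Fis` is reported with a message). The summary gives
#' per-locus means with `SE = sd / sqrt(n_loci)`, and reports the
#' inbreeding coefficient both ways it is computed in practice: as the
#' mean of per-locus values and as the ratio-of-means
#' `1 - mean(Ho) / mean(He)`.
#'
#' @param G Genotype matrix (samples x loci).
#' @return Object of class `diversity_summary` with `loci` (per-locus
#'   tibble) and `summary` (one-row tibble).
#' @export
diversity <- function(G) {
  stopifnot(nrow(G) >= 2)
  if (anyNA(G)) stop("missing calls not allowed")
  p <- allele_freqs(G)
  he <- 2 * p * (1 - p)
  ho <- colMeans(G == 1)
  fis <- ifelse(he > 0, 1 - ho / he, NA_real_)
  n_mono <- sum(he == 0)
  if (n_mono > 0) {
    message(n_mono, " monomorphic locus(i) excluded from Fis")
  }
  loci <- tibble::tibble(
    locus = colnames(G) %||% paste0("loc", seq_along(p)),
    p = unname(p), He = unname(he), Ho = unname(ho), Fis = unname(fis)
  )
  se <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  summary <- tibble::tibble(
    n_loci = length(p), n_monomorphic = n_mono,
    He_mean = mean(he), He_se = se(he),
    Ho_mean = mean(ho), Ho_se = se(ho),
    Fis_mean = mean(fis, na.rm = TRUE), Fis_se = se(fis),
    Fis_ratio = 1 - mean(ho) / mean(he)
  )
  structure(list(loci = loci, summary = summary),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<diversity_summary> %d loci: He %.3f +/- %.3f, Ho %.3f +/- %.3f, Fis %.3f (ratio-of-means %.3f)\n",
              s$n_loci, s$He_mean, s$He_se, s$Ho_mean, s$Ho_se,
              s$Fis_mean, s$Fis_ratio))
  invisible(x)
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window` loci (advancing by `step`); within each
#' window, for every pair with squared genotype correlation `>= r2_max`
#' the later locus is dropped. The surviving set has no within-window pair
#' at or above the threshold.
#'
#' @param G Genotype matrix.
#' @param r2_max Squared-correlation threshold in `(0, 1]`.
#' @param window,step Window size and stride in loci.
#' @return Pruned genotype matrix.
#' @export
ld_prune <- function(G, r2_max = 0.9, window = 100, step = window %/% 2) {
  stopifnot(r2_max > 0, r2_max <= 1, window >= 2)
  step <- max(1, step)
  keep <- rep(TRUE, ncol(G))
  starts <- seq(1, max(1, ncol(G) - 1), by = step)
  for (s in starts) {
    idx <- which(keep)[which(keep) >= s & which(keep) < s + window]
    if (length(idx) < 2) next
    sub <- G[, idx, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    r2 <- suppressWarnings(stats::cor(sub))^2
    r2[is.na(r2)] <- 0
    # treat exact duplicates of constant columns as correlated
    if (any(sds == 0)) {
      const <- which(sds == 0)
      for (a in const) for (bb in seq_along(idx)) {
        if (a != bb && identical(sub[, a], sub[, bb])) r2[a, bb] <- 1
      }
    }
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (bb in seq_len(a - 1)) {
        if (keep[idx[bb]] && r2[a, bb] >= r2_max) {
          keep[idx[a]] <- FALSE
          break
        }
      }
    }
  }
  G[, keep, drop = FALSE]
}

# genotype-pair log-probability tables under 0/1/2 shared alleles IBD,
# HWE with alt frequency p; rows indexed by 3*g_i + g_j + 1
pair_prob_tables <- function(p) {
  q <- 1 - p
  P0g <- rbind(q^2, 2 * p * q, p^2)          # genotype probs, 3 x L
  T0 <- matrix(0, 9, length(p))
  T1 <- matrix(0, 9, length(p))
  T2 <- matrix(0, 9, length(p))
  for (gi in 0:2) for (gj in 0:2) {
    row <- 3 * gi + gj + 1
    T0[row, ] <- P0g[gi + 1, ] * P0g[gj + 1, ]
    T2[row, ] <- if (gi == gj) P0g[gi + 1, ] else 0
  }
  T1[1, ] <- q^3          # (0,0)
  T1[2, ] <- q^2 * p      # (0,1)
  T1[4, ] <- q^2 * p      # (1,0)
  T1[5, ] <- p * q        # (1,1)
  T1[6, ] <- p^2 * q      # (1,2)
  T1[8, ] <- p^2 * q      # (2,1)
  T1[9, ] <- p^3          # (2,2)
  list(T0 = T0, T1 = T1, T2 = T2)
}

#' Maximum-likelihood pairwise relatedness
#'
#' For every unordered pair of individuals, estimates the probabilities
#' `(k0, k1, k2)` of sharing 0/1/2 alleles identical by descent by
#' maximizing the multilocus likelihood
#' `sum_l log(k0 P0 + k1 P1 + k2 P2)` over the probability simplex
#' (no-inbreeding model; genotype-pair probabilities from Hardy--Weinberg
#' with the supplied or sample allele frequencies). Relatedness is
#' `r = k1/2 + k2`. The simplex maximization runs EM to a log-likelihood
#' change below `tol`. Pairs with fewer than `min_loci` informative
#' (polymorphic) loci are flagged low-confidence.
#'
#' @param G Genotype matrix.
#' @param freqs Optional allele frequencies (default: estimated from `G`).
#' @param min_loci Informative-locus threshold for the confidence flag.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @return Object of class `relatedness_matrix`: `pairs` tibble
#'   (`id1, id2, k0, k1, k2, r, logLik, n_informative, low_confidence`)
#'   and symmetric matrix `r`.
#' @export
relatedness_ml <- function(G, freqs = NULL, min_loci = 20, tol = 1e-8) {
  n <- nrow(G)
  stopifnot(n >= 2)
  ids <- rownames(G) %||% paste0("ind", seq_len(n))
  p <- freqs %||% allele_freqs(G)
  poly <- p > 0 & p < 1
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  tabs <- pair_prob_tables(p[poly])
  Gp <- G[, poly, drop = FALSE]
  storage.mode(Gp) <- "integer"
  L <- ncol(Gp)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- .em_relatedness_pairs(Gp, pair, tabs$T0, tabs$T1, tabs$T2,
                               tol, 2000L)
  pairs <- tibble::tibble(
    id1 = ids[pair[, 1]], id2 = ids[pair[, 2]],
    k0 = res[, 1], k1 = res[, 2], k2 = res[, 3],
    r = res[, 2] / 2 + res[, 3], logLik = res[, 4],
    n_informative = L,
    low_confidence = L < min_loci
  )
  R <- matrix(0, n, n, dimnames = list(ids, ids))
  R[pair] <- pairs$r
  R <- R + t(R)
  diag(R) <- 1
  structure(list(pairs = pairs, r = R), class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat(sprintf("<relatedness_matrix> %d individuals, %d pairs; r in [%.4f, %.4f], mean %.4f\n",
              nrow(x$r), nrow(x$pairs), min(x$pairs$r), max(x$pairs$r),
              mean(x$pairs$r)))
  invisible(x)
}

#' Flag and thin close kin
#'
#' Lists pairs above the relatedness threshold and builds a greedy removal
#' set: pairs are scanned in order, and whenever both members are still
#' present the first-listed member is kept and the other removed. For
#' disjoint pairs this removes exactly one individual per pair; chains
#' collapse onto their shared members.
#'
#' @param rel A [relatedness_ml()] result.
#' @param threshold Relatedness cutoff (default 0.10).
#' @return List with `pairs` (tibble of flagged pairs), `flagged`
#'   (ids in any flagged pair) and `removed` (greedy removal set).
#' @export
kin_filter <- function(rel, threshold = 0.10) {
  kp <- dplyr::filter(rel$pairs, .data$r > threshold)
  removed <- character(0)
  for (k in seq_len(nrow(kp))) {
    a <- kp$id1[k]; b <- kp$id2[k]
    if (!(a %in% removed) && !(b %in% removed)) removed <- c(removed, b)
  }
  list(pairs = kp, flagged = unique(c(kp$id1, kp$id2)), removed = removed)
}

#' Multilocus squared genotypic distance
#'
#' The codominant-genotypic squared distance for biallelic loci: per locus
#' 0 between identical genotypes, 1 between a homozygote and the
#' heterozygote, 4 between opposite homozygotes — i.e. the squared
#' difference of allele counts — summed over loci.
#'
#' @param G Genotype matrix without missing calls.
#' @return Symmetric matrix of squared distances with zero diagonal.
#' @export
genotypic_distance <- function(G) {
  if (anyNA(G)) stop("missing calls not allowed")
  D <- as.matrix(stats::dist(G))^2
  dimnames(D) <- list(rownames(G), rownames(G))
  D
}

#' Principal component analysis of genotypes
#'
#' Centers each locus on twice its allele frequency and (by default)
#' scales by `sqrt(p (1 - p))`, then eigendecomposes the sample covariance
#' via SVD. Coordinates are deterministic up to sign.
#'
#' @param G Genotype matrix.
#' @param drop Character vector of sample ids to exclude (e.g. the
#'   `removed` set from [kin_filter()]).
#' @param scale Scale loci by the binomial SD (`TRUE`, standard practice)
#'   or just center (`FALSE`).
#' @param n_pcs Number of components to return.
#' @return Object of class `gen_pca`: `scores` tibble (`id, PC1, ...`)
#'   and `var_explained` vector.
#' @export
gen_pca <- function(G, drop = character(0), scale = TRUE, n_pcs = 10) {
  G <- G[!(rownames(G) %in% drop), , drop = FALSE]
  stopifnot(nrow(G) >= 3)
  p <- allele_freqs(G)
  keep <- p > 0 & p < 1
  X <- sweep(G[, keep, drop = FALSE], 2, 2 * p[keep])
  if (scale) X <- sweep(X, 2, sqrt(p[keep] * (1 - p[keep])), "/")
  sv <- svd(X, nu = min(n_pcs, nrow(X) - 1), nv = 0)
  d2 <- sv$d^2
  k <- ncol(sv$u)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(id = rownames(G)),
                              tibble::as_tibble(scores)),
    var_explained = d2[seq_len(k)] / sum(d2)
  ), class = "gen_pca")
}

#' @export
print.gen_pca <- function(x, ...) {
  cat(sprintf("<gen_pca> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}
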