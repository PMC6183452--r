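#' Gower double-centering of a squared-distance matrix
#'
#' Converts a squared genotypic distance matrix into the covariance form
#' used by the multilocus autocorrelation estimator:
#' `c_ij = -0.5 (d2_ij - m_i - m_j + m)` with `m_i` row means and `m` the
#' grand mean. Rows and columns of the result sum to zero.
#'
#' @param D2 Symmetric squared-distance matrix.
#' @return Centered covariance matrix.
#' @export
center_distance_matrix <- function(D2) {
  D2 <- as.matrix(D2)
  m_i <- rowMeans(D2)
  m <- mean(D2)
  -0.5 * (D2 - outer(m_i, m_i, "+") + m)
}

interp_crossing <- function(xs, f) {
  # first down-crossing of 0 by f over midpoints xs (NA entries skipped)
  ok <- which(!is.na(f))
  if (length(ok) < 2 || f[ok[1]] <= 0) return(NA_real_)
  for (k in seq_len(length(ok) - 1)) {
    a <- ok[k]; b <- ok[k + 1]
    if (f[a] > 0 && f[b] <= 0) {
      return(xs[a] + (xs[b] - xs[a]) * f[a] / (f[a] - f[b]))
    }
  }
  NA_real_
}

#' Multilocus spatial genetic correlogram
#'
#' Computes the autocorrelation coefficient `r(h)` per geographic distance
#' class as the ratio of summed pair cross-covariances to summed mean
#' self-covariances, from the Gower-centered squared genotypic distance
#' matrix. The null model of no spatial structure is built by permuting
#' the assignment of coordinates to individuals (`n_perm` times), giving a
#' 95% envelope and one-tailed p-values; pair-resampling bootstraps
#' (`n_boot`) give a confidence interval per class. Two patch-size
#' intercepts are reported, found by linear interpolation between class
#' midpoints: where `r` first crosses zero, and where `r` first drops into
#' the permutation envelope (below its upper bound `U`).
#'
#' @param d2 Squared genotypic distance matrix (see
#'   [genotypic_distance()]).
#' @param coords Two-column matrix or data frame of planar coordinates
#'   (m), one row per individual in `d2` order.
#' @param n_classes Number of even distance classes (default 15).
#' @param width Class width in metres (default 2,000); class `h` covers
#'   `((h-1) width, h width]`.
#' @param n_perm,n_boot Permutation and bootstrap replicates (defaults
#'   999).
#' @param seed Integer seed.
#' @return Object of class `correlogram`: `classes` tibble (`class,
#'   midpoint, n_pairs, r, L, U, p, boot_lo, boot_hi`), intercepts
#'   `x_intercept` and `u_intercept` (m), and the retained permutation and
#'   bootstrap replicate matrices.
#' @export
genetic_correlogram <- function(d2, coords, n_classes = 15, width = 2000,
                                n_perm = 999, n_boot = 999,
                                seed = 20160601) {
  stopifnot(n_classes >= 1, width > 0)
  coords <- as.matrix(coords[, 1:2])
  n <- nrow(coords)
  stopifnot(nrow(d2) == n)
  C <- center_distance_matrix(d2)
  S <- outer(diag(C), diag(C), "+") / 2
  geo <- as.matrix(stats::dist(coords))
  cl <- ceiling(geo / width)
  cl[cl > n_classes | cl == 0] <- NA     # pairs beyond range; zero-distance
  cl[geo == 0] <- 1L                     # co-located pairs: first class
  diag(cl) <- NA
  ut <- upper.tri(cl)
  idx_h <- lapply(seq_len(n_classes), function(h) which(ut & !is.na(cl) & cl == h))
  n_pairs <- lengths(idx_h)
  r_of <- function(Cm, Sm) {
    vapply(seq_len(n_classes), function(h) {
      if (!n_pairs[h]) return(NA_real_)
      sum(Cm[idx_h[[h]]]) / sum(Sm[idx_h[[h]]])
    }, numeric(1))
  }
  r_obs <- r_of(C, S)
  with_seed(seed, {
    perm_mat <- matrix(NA_real_, n_perm, n_classes)
    for (k in seq_len(n_perm)) {
      p <- sample(n)
      perm_mat[k, ] <- r_of(C[p, p], S[p, p])
    }
    boot_mat <- matrix(NA_real_, n_boot, n_classes)
    cvals <- lapply(idx_h, function(ix) C[ix])
    svals <- lapply(idx_h, function(ix) S[ix])
    for (h in seq_len(n_classes)) {
      m <- n_pairs[h]
      if (!m) next
      for (k in seq_len(n_boot)) {
        s <- sample.int(m, m, replace = TRUE)
        boot_mat[k, h] <- sum(cvals[[h]][s]) / sum(svals[[h]][s])
      }
    }
    env <- apply(perm_mat, 2, stats::quantile,
                 probs = c(0.025, 0.975), na.rm = TRUE)
    pval <- vapply(seq_len(n_classes), function(h) {
      if (!n_pairs[h]) return(NA_real_)
      (1 + sum(perm_mat[, h] >= r_obs[h], na.rm = TRUE)) / (n_perm + 1)
    }, numeric(1))
    boot_ci <- apply(boot_mat, 2, stats::quantile,
                     probs = c(0.025, 0.975), na.rm = TRUE)
    mids <- (seq_len(n_classes) - 0.5) * width
    classes <- tibble::tibble(
      class = seq_len(n_classes), midpoint = mids, n_pairs = n_pairs,
      r = r_obs, L = env[1, ], U = env[2, ], p = pval,
      boot_lo = boot_ci[1, ], boot_hi = boot_ci[2, ]
    )
    structure(list(
      classes = classes,
      x_intercept = interp_crossing(mids, r_obs),
      u_intercept = interp_crossing(mids, r_obs - env[2, ]),
      perm = perm_mat, boot = boot_mat,
      width = width, n = n
    ), class = "correlogram")
  })
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d individuals, %d classes of %g m\n",
              x$n, nrow(x$classes), x$width))
  cat(sprintf("  zero-intercept %.0f m; envelope (U) intercept %.0f m\n",
              x$x_intercept, x$u_intercept))
  invisible(x)
}

#' Heterogeneity test against the permutation null
#'
#' Standardizes each class coefficient against its permutation
#' distribution, `t2(h) = (r(h) - mean_perm)^2 / var_perm`, and sums over
#' classes into the global statistic `omega`. P-values are the fraction of
#' permutation replicates with a statistic at least as large as observed
#' (with the add-one correction), so `p >= 1/(n_perm + 1)`.
#'
#' @param cg A [genetic_correlogram()] result with retained permutations.
#' @return List with `classes` tibble (`class, t2, p`) and one-row
#'   `global` tibble (`omega, p`).
#' @export
heterogeneity_test <- function(cg) {
  perm <- cg$perm
  if (is.null(perm)) stop("correlogram lacks permutation replicates")
  mu <- colMeans(perm, na.rm = TRUE)
  v <- apply(perm, 2, stats::var, na.rm = TRUE)
  usable <- !is.na(cg$classes$r) & !is.na(v) & v > 0
  if (any(!usable & !is.na(cg$classes$r))) {
    warning("class(es) with zero permutation variance skipped")
  }
  t2_obs <- (cg$classes$r - mu)^2 / v
  t2_obs[!usable] <- NA
  t2_perm <- sweep(sweep(perm, 2, mu), 2, sqrt(v), "/")^2
  n_perm <- nrow(perm)
  p_class <- vapply(seq_along(t2_obs), function(h) {
    if (!usable[h]) return(NA_real_)
    (1 + sum(t2_perm[, h] >= t2_obs[h], na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1))
  omega_obs <- sum(t2_obs[usable])
  omega_perm <- rowSums(t2_perm[, usable, drop = FALSE], na.rm = TRUE)
  p_omega <- (1 + sum(omega_perm >= omega_obs)) / (n_perm + 1)
  list(
    classes = tibble::tibble(class = cg$classes$class, t2 = t2_obs,
                             p = p_class),
    global = tibble::tibble(omega = omega_obs, p = p_omega)
  )
}

boot_intercepts <- function(cg) {
  # U-intercept of each bootstrap curve against the fixed envelope
  mids <- cg$classes$midpoint
  U <- cg$classes$U
  apply(cg$boot, 1, function(rb) interp_crossing(mids, rb - U))
}

#' Sex-stratified correlograms and dispersal-bias call
#'
#' Runs the correlogram separately among males, among females and among
#' all individuals (unknown-sex individuals are excluded from the sexed
#' strata), and compares genetic patch sizes: strata whose bootstrap 95%
#' confidence intervals of the envelope (U) intercept overlap are called
#' consistent with no sex-biased dispersal.
#'
#' @param d2 Squared genotypic distance matrix for all individuals.
#' @param samples Sample tibble (`id, x, y, sex`) in `d2` row order.
#' @param min_n Strata smaller than this are flagged underpowered.
#' @param ... Passed to [genetic_correlogram()].
#' @return List with `comparison` (per-stratum tibble: `stratum, n,
#'   x_intercept, u_intercept, u_lo, u_hi, underpowered`), the
#'   per-stratum `correlograms`, and `sex_biased` (logical call).
#' @export
sex_stratified <- function(d2, samples, min_n = 10, ...) {
  stopifnot(nrow(samples) == nrow(d2))
  strata <- list(
    male = which(samples$sex == "M"),
    female = which(samples$sex == "F"),
    all = seq_len(nrow(samples))
  )
  cgs <- lapply(strata, function(ix) {
    genetic_correlogram(d2[ix, ix], cbind(samples$x, samples$y)[ix, ], ...)
  })
  rows <- purrr::imap(cgs, function(cg, nm) {
    bi <- boot_intercepts(cg)
    ci <- stats::quantile(bi, c(0.025, 0.975), na.rm = TRUE)
    tibble::tibble(
      stratum = nm, n = cg$n,
      x_intercept = cg$x_intercept, u_intercept = cg$u_intercept,
      u_lo = ci[1], u_hi = ci[2],
      underpowered = cg$n < min_n
    )
  })
  comparison <- dplyr::bind_rows(rows)
  m <- comparison[comparison$stratum == "male", ]
  f <- comparison[comparison$stratum == "female", ]
  overlap <- !is.na(m$u_lo) && !is.na(f$u_lo) &&
    m$u_lo <= f$u_hi && f$u_lo <= m$u_hi
  list(comparison = comparison, correlograms = cgs,
       sex_biased = !overlap)
}
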