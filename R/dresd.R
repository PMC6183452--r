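#' Isolation-by-distance regression over individual pairs
#'
#' Ordinary least squares of the pairwise squared genotypic distance on
#' pairwise geographic distance over all unordered pairs. Each pair
#' contributes one residual, located at the arithmetic midpoint of the two
#' individuals' coordinates: positive residuals mark pairs more
#' genetically distinct than their separation predicts (candidate
#' dispersal barriers once they accumulate in space), negative residuals
#' mark corridors.
#'
#' @param d2 Squared genotypic distance matrix.
#' @param coords Two-column coordinate matrix/data frame (m), `d2` order.
#' @param log_geo Regress on `log(geo)` instead of `geo` (zero distances
#'   offset by 1 m).
#' @return Object of class `ibd_model`: `slope`, `intercept`, `r_squared`
#'   and `pairs` tibble (`i, j, geo, d2, resid, mx, my`).
#' @export
ibd_fit <- function(d2, coords, log_geo = FALSE) {
  coords <- as.matrix(coords[, 1:2])
  n <- nrow(coords)
  stopifnot(n >= 3, nrow(d2) == n)
  geo <- as.matrix(stats::dist(coords))
  ut <- which(upper.tri(geo), arr.ind = TRUE)
  g <- geo[ut]
  if (log_geo) g <- log(g + 1)
  if (stats::sd(g) == 0) stop("no variation in geographic distance")
  y <- d2[ut]
  b <- stats::cov(g, y) / stats::var(g)
  a <- mean(y) - b * mean(g)
  res <- y - (a + b * g)
  structure(list(
    slope = b, intercept = a,
    r_squared = if (stats::var(y) > 0) 1 - stats::var(res) / stats::var(y) else NA_real_,
    log_geo = log_geo,
    pairs = tibble::tibble(
      i = ut[, 1], j = ut[, 2], geo = geo[ut], d2 = y, resid = res,
      mx = (coords[ut[, 1], 1] + coords[ut[, 2], 1]) / 2,
      my = (coords[ut[, 1], 2] + coords[ut[, 2], 2]) / 2
    )
  ), class = "ibd_model")
}

#' @export
print.ibd_model <- function(x, ...) {
  cat(sprintf("<ibd_model> %d pairs: d2 = %.4g + %.4g * geo (R2 %.3f)\n",
              nrow(x$pairs), x$intercept, x$slope, x$r_squared))
  invisible(x)
}

# precompute the cell x midpoint IDW weight structure as a sparse matrix;
# midpoints are binned to columns first so each cell only scans nearby bins
idw_weights <- function(mx, my, spec, window_radius, min_pairs) {
  cc <- cell_centers(spec)
  n_cell <- nrow(cc)
  s <- spec$cell_size
  bin <- pmin(pmax(floor((mx - spec$origin_x) / s) + 1, 1), spec$n_cols)
  by_bin <- split(seq_along(mx), bin)
  reach <- ceiling(window_radius / s)
  cand_for_col <- lapply(seq_len(spec$n_cols), function(cl) {
    cols <- as.character(max(1, cl - reach - 1):min(spec$n_cols, cl + reach + 1))
    unlist(by_bin[cols], use.names = FALSE)
  })
  trip_i <- vector("list", n_cell)
  trip_j <- vector("list", n_cell)
  trip_w <- vector("list", n_cell)
  for (ci in seq_len(n_cell)) {
    cand <- cand_for_col[[cc$col[ci]]]
    if (!length(cand)) next
    d <- sqrt((mx[cand] - cc$x[ci])^2 + (my[cand] - cc$y[ci])^2)
    keep <- d <= window_radius
    if (!any(keep)) next
    trip_i[[ci]] <- rep(ci, sum(keep))
    trip_j[[ci]] <- cand[keep]
    trip_w[[ci]] <- 1 / (d[keep] + s / 10)
  }
  W <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_w),
    dims = c(n_cell, length(mx))
  )
  counts <- Matrix::rowSums(W > 0)
  list(W = W, wsum = Matrix::rowSums(W), ok = counts >= min_pairs,
       counts = counts, cc = cc)
}

idw_apply <- function(wt, values, spec) {
  v <- as.vector(wt$W %*% values) / wt$wsum
  v[!wt$ok] <- NA
  m <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  m[cbind(wt$cc$row, wt$cc$col)] <- v
  m
}

#' Interpolate IBD residuals onto a grid
#'
#' Cell value = inverse-distance-weighted mean (weight
#' `1 / (d + cell_size/10)`) of the residuals whose pair midpoints fall
#' within `window_radius` of the cell centre; cells with fewer than
#' `min_pairs` midpoints in range are masked.
#'
#' @param model An [ibd_fit()] result.
#' @param spec A [grid_spec()].
#' @param window_radius Moving-window radius (m).
#' @param min_pairs Minimum midpoints per cell.
#' @return A [cov_raster()] of interpolated residuals.
#' @export
interpolate_surface <- function(model, spec, window_radius = 3000,
                                min_pairs = 5) {
  stopifnot(window_radius > 0)
  wt <- idw_weights(model$pairs$mx, model$pairs$my, spec, window_radius,
                    min_pairs)
  m <- idw_apply(wt, model$pairs$resid, spec)
  cov_raster(m, spec, name = "ibd_residual", mask = !is.na(m))
}

#' Map isolation-by-distance residuals with significance and power
#'
#' Full spatially explicit residual analysis: interpolates the observed
#' residual surface, attaches per-cell two-tailed randomization p-values
#' (residual values permuted across the fixed midpoint geometry,
#' `n_iter` times, `p = (1 + #{|null| >= |obs|}) / (n_iter + 1)`), and a
#' per-cell bootstrap power measure (individuals resampled with
#' replacement `n_boot` times, pairs/regression/surface rebuilt; power =
#' fraction of bootstrap surfaces agreeing with the observed cell's sign;
#' degenerate resamples with fewer than 3 unique individuals are redrawn,
#' and pairs formed by two copies of the same individual are dropped).
#'
#' @param d2 Squared genotypic distance matrix.
#' @param coords Two-column coordinate matrix (m).
#' @param spec A [grid_spec()].
#' @param window_radius,min_pairs Interpolation controls (see
#'   [interpolate_surface()]).
#' @param n_iter Randomization iterations (`>= 100`; study default 1,000).
#' @param n_boot Bootstrap replicates (`>= 50`; study default 250).
#' @param alpha Significance level for the significant-cell mask.
#' @param power_threshold Sign-agreement level for the sufficient-power
#'   mask (default 0.95).
#' @param seed Integer seed.
#' @param log_geo Passed to [ibd_fit()].
#' @return Object of class `resistance_surface`: rasters `surface`, `p`,
#'   `power`; logical matrices `significant` and `sufficient_power`;
#'   and the underlying `model`.
#' @export
dresd <- function(d2, coords, spec = grid_spec(), window_radius = 3000,
                  min_pairs = 5, n_iter = 1000, n_boot = 250,
                  alpha = 0.05, power_threshold = 0.95,
                  seed = 20160601, log_geo = FALSE) {
  if (n_iter < 100) stop("n_iter must be at least 100")
  if (n_boot < 50) stop("n_boot must be at least 50")
  model <- ibd_fit(d2, coords, log_geo = log_geo)
  wt <- idw_weights(model$pairs$mx, model$pairs$my, spec, window_radius,
                    min_pairs)
  obs <- idw_apply(wt, model$pairs$resid, spec)
  res <- model$pairs$resid
  n_pair <- length(res)
  n <- nrow(as.matrix(coords))
  with_seed(seed, {
    exceed <- matrix(0, spec$n_rows, spec$n_cols)
    for (k in seq_len(n_iter)) {
      null_m <- idw_apply(wt, res[sample.int(n_pair)], spec)
      exceed <- exceed + (abs(null_m) >= abs(obs))
    }
    p <- (1 + exceed) / (n_iter + 1)
    p[is.na(obs)] <- NA
    agree <- matrix(0, spec$n_rows, spec$n_cols)
    denom <- matrix(0, spec$n_rows, spec$n_cols)
    for (k in seq_len(n_boot)) {
      repeat {
        ix <- sample.int(n, n, replace = TRUE)
        if (length(unique(ix)) >= 3) break
      }
      sub_coords <- as.matrix(coords)[ix, 1:2, drop = FALSE]
      sub_d2 <- d2[ix, ix]
      geo <- as.matrix(stats::dist(sub_coords))
      ut <- which(upper.tri(geo), arr.ind = TRUE)
      same <- ix[ut[, 1]] == ix[ut[, 2]]
      ut <- ut[!same, , drop = FALSE]
      g <- geo[ut]
      if (log_geo) g <- log(g + 1)
      if (stats::sd(g) == 0) next
      y <- sub_d2[ut]
      b <- stats::cov(g, y) / stats::var(g)
      a <- mean(y) - b * mean(g)
      rb <- y - (a + b * g)
      mx <- (sub_coords[ut[, 1], 1] + sub_coords[ut[, 2], 1]) / 2
      my <- (sub_coords[ut[, 1], 2] + sub_coords[ut[, 2], 2]) / 2
      wtb <- idw_weights(mx, my, spec, window_radius, min_pairs)
      sb <- idw_apply(wtb, rb, spec)
      both <- !is.na(sb) & !is.na(obs)
      agree[both] <- agree[both] + (sign(sb[both]) == sign(obs[both]))
      denom[both] <- denom[both] + 1
    }
    power <- ifelse(denom > 0, agree / denom, NA)
    power[is.na(obs)] <- NA
  })
  mask <- !is.na(obs)
  structure(list(
    surface = cov_raster(obs, spec, name = "ibd_residual", mask = mask),
    p = cov_raster(p, spec, name = "p_value", mask = mask),
    power = cov_raster(power, spec, name = "power",
                       mask = mask & !is.na(power)),
    significant = mask & !is.na(p) & p <= alpha,
    sufficient_power = mask & !is.na(power) & power >= power_threshold,
    alpha = alpha, power_threshold = power_threshold,
    n_iter = n_iter, n_boot = n_boot,
    window_radius = window_radius, min_pairs = min_pairs,
    model = model
  ), class = "resistance_surface")
}

#' @export
print.resistance_surface <- function(x, ...) {
  cat(sprintf("<resistance_surface> %d unmasked cells; %d significant (alpha %.2f), %d with power >= %.2f\n",
              sum(x$surface$mask), sum(x$significant), x$alpha,
              sum(x$sufficient_power), x$power_threshold))
  invisible(x)
}

#' Correlate dispersal resistance with landscape covariates
#'
#' Pearson correlation (with a two-sided test) of the interpolated
#' residual surface against each covariate raster, over all unmasked
#' cells and over the significant-cell mask, mirroring the two-panel
#' presentation of resistance--covariate relationships. Landscape class
#' rasters are expanded into per-class indicator rasters. P-values carry
#' the usual caveat that spatial autocorrelation among cells inflates
#' significance; no spatial correction is applied.
#'
#' @param rs A [dresd()] result (or list with `surface` raster and
#'   `significant` matrix).
#' @param rasters Named list of covariate rasters (categorical rasters
#'   need a `levels` field).
#' @return Tibble: `covariate, mask, n, r, p, flagged` with one row per
#'   covariate x mask combination (`flagged` marks undefined correlations
#'   or masks below 3 cells).
#' @export
covariate_correlation <- function(rs, rasters) {
  surf <- rs$surface
  expand <- function(name, ras) {
    if (!is.null(ras$levels)) {
      lv <- ras$levels
      present <- sort(unique(as.vector(ras$values[ras$mask])))
      stats::setNames(
        lapply(present, function(code) (ras$values == code) * 1),
        paste0(name, "_", lv[present])
      )
    } else {
      stats::setNames(list(ras$values), name)
    }
  }
  covs <- purrr::flatten(purrr::imap(rasters, function(r, nm) expand(nm, r)))
  masks <- list(all = surf$mask, significant = rs$significant)
  rows <- purrr::imap(masks, function(mk, mk_name) {
    purrr::imap(covs, function(v, cv_name) {
      s <- surf$values[mk]
      x <- v[mk]
      n <- sum(mk)
      if (n < 3 || stats::sd(x) == 0 || stats::sd(s) == 0) {
        return(tibble::tibble(covariate = cv_name, mask = mk_name, n = n,
                              r = NA_real_, p = NA_real_, flagged = TRUE))
      }
      ct <- stats::cor.test(s, x)
      tibble::tibble(covariate = cv_name, mask = mk_name, n = n,
                     r = unname(ct$estimate), p = ct$p.value,
                     flagged = FALSE)
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
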