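#' Ground-truth configuration for the synthetic-data generator
#'
#' Bundles every parameter the generator needs so downstream stages can be
#' tested by parameter recovery. Defaults reproduce the study conditions of
#' an island-wide urban pigeon survey: a log-linear cluster-abundance model
#' `log lambda = beta0 + beta_F * F + beta_L[landscape]` (clusters per
#' hectare), hazard-rate detection with landscape-specific scale, mean
#' cluster size 3.73 birds, and an isolation-by-distance allele-frequency
#' field whose correlation length `rho` controls the genetic patch size.
#'
#' @param beta0 Abundance intercept (log clusters/ha).
#' @param beta_F Feeding-intensity coefficient.
#' @param beta_L Named landscape offsets (classes `HR`,`LR`,`ID`,`OV`,`DT`;
#'   bare ground is never surveyed or predicted).
#' @param sigma Named hazard-rate scale (m) per landscape.
#' @param hazard_b Hazard-rate shape, shared across landscapes.
#' @param cluster_mean Mean cluster size (birds per detection).
#' @param rho Correlation length (m) of the latent allele-frequency field.
#'   The default is calibrated so that the multilocus correlogram of 150
#'   individuals enters its permutation envelope near 3 km.
#' @param tau Marginal SD of the latent field (0 = no spatial structure).
#' @param n_loci Number of biallelic loci to simulate.
#' @param barrier Optional barrier polygon: a two-column matrix of vertex
#'   coordinates (m). Individuals are split by the side of the polygon's
#'   principal axis they fall on.
#' @param barrier_frac Fraction of loci whose fields are independent on the
#'   two sides of the barrier.
#' @param n_kin Number of parent--offspring pairs appended.
#' @param sex_ratio Proportion of males.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(beta0 = 0.437, beta_F = 0.023,
                         beta_L = c(HR = 2.544, LR = 1.421, ID = 1.586,
                                    OV = 1.255, DT = -2.5),
                         sigma = c(HR = 40, LR = 50, ID = 55, OV = 65, DT = 60),
                         hazard_b = 3, cluster_mean = 3.73,
                         rho = 1050, tau = 1, n_loci = 500,
                         barrier = NULL, barrier_frac = 0.5,
                         n_kin = 0, sex_ratio = 0.5) {
  stopifnot(all(sigma > 0), hazard_b > 0, cluster_mean >= 1, rho > 0,
            n_loci >= 1, tau >= 0, barrier_frac >= 0, barrier_frac <= 1)
  structure(list(beta0 = beta0, beta_F = beta_F, beta_L = beta_L,
                 sigma = sigma, hazard_b = hazard_b,
                 cluster_mean = cluster_mean, rho = rho, tau = tau,
                 n_loci = n_loci, barrier = barrier,
                 barrier_frac = barrier_frac, n_kin = n_kin,
                 sex_ratio = sex_ratio),
            class = "truth_config")
}

# Gaussian-kernel smooth of a grid matrix; radius in cells (0 = no smoothing)
smooth_grid <- function(m, radius) {
  if (radius <= 0) return(m)
  k <- ceiling(3 * radius)
  off <- -k:k
  w1 <- exp(-off^2 / (2 * radius^2))
  pad <- function(mat, n, dim) {
    if (dim == 1) mat[pmin(pmax(seq_len(nrow(mat) + 2 * n) - n, 1), nrow(mat)), , drop = FALSE]
    else mat[, pmin(pmax(seq_len(ncol(mat) + 2 * n) - n, 1), ncol(mat)), drop = FALSE]
  }
  mp <- pad(m, k, 1)
  out <- matrix(0, nrow(m), ncol(m))
  # separable convolution, replicate-padded edges
  tmp <- matrix(0, nrow(m), ncol(mp))
  for (d in seq_along(off)) {
    tmp <- tmp + w1[d] * mp[seq_len(nrow(m)) + (d - 1), , drop = FALSE]
  }
  tmp <- tmp / sum(w1)
  tp <- pad(tmp, k, 2)
  for (d in seq_along(off)) {
    out <- out + w1[d] * tp[, seq_len(ncol(m)) + (d - 1), drop = FALSE]
  }
  out / sum(w1)
}

#' Generate synthetic covariate rasters
#'
#' Produces the four covariates used by the abundance and dispersal models:
#' a categorical landscape raster `L` with contiguous patches in exact
#' user-set proportions (level-set partition of a smoothed Gaussian field),
#' and non-negative spatially smoothed fields for feeding intensity `F`,
#' human population density `P` and road density `R`.
#'
#' @param spec A [grid_spec()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @param l_props Named class proportions over [landscape_levels()];
#'   must sum to 1. Default gives bare ground 3.28% (41 of 1,250 cells on
#'   the default grid) and splits the rest evenly.
#' @param smooth_radius Smoothing radius in cells for all fields
#'   (0 = independent cells).
#' @param f_mean Mean feeding intensity (incident counts per cell).
#' @return Named list of [cov_raster()]s: `F`, `L`, `P`, `R`.
#' @export
gen_covariates <- function(spec = grid_spec(), seed = 20160601,
                           l_props = c(HR = 0.19344, LR = 0.19344,
                                       ID = 0.19344, OV = 0.19344,
                                       DT = 0.19344, BG = 0.0328),
                           smooth_radius = 2, f_mean = 20) {
  if (abs(sum(l_props) - 1) > 1e-8) stop("landscape proportions must sum to 1")
  lv <- landscape_levels()
  stopifnot(all(names(l_props) %in% lv))
  props <- stats::setNames(rep(0, length(lv)), lv)
  props[names(l_props)] <- l_props
  nr <- spec$n_rows; nc <- spec$n_cols; ncell <- nr * nc
  with_seed(seed, {
    # landscape: exact per-class cell counts (largest remainder), assigned
    # as level sets of a smooth field so classes form contiguous patches
    target <- floor(props * ncell)
    rem <- props * ncell - target
    short <- ncell - sum(target)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      target[add] <- target[add] + 1
    }
    zL <- smooth_grid(matrix(stats::rnorm(ncell), nr, nc), smooth_radius)
    ord <- order(zL)                       # cell ranks along the field
    class_order <- sample(seq_along(lv))   # randomize which class sits where
    codes <- integer(ncell)
    pos <- 1
    for (ci in class_order) {
      n_ci <- target[ci]
      if (n_ci > 0) {
        codes[ord[pos:(pos + n_ci - 1)]] <- ci
        pos <- pos + n_ci
      }
    }
    L <- cov_raster(matrix(codes, nr, nc), spec, name = "L", levels = lv)
    pos_field <- function(mean_val, cv, cap = Inf) {
      z <- smooth_grid(matrix(stats::rnorm(ncell), nr, nc), smooth_radius)
      z <- z / stats::sd(z)
      pmin(mean_val * exp(cv * z - cv^2 / 2), cap)  # lognormal, mean ~mean_val
    }
    # feeding incidents are bounded counts; winsorize the lognormal tail so
    # exp(beta_F * F) in the abundance model stays in a realistic range
    Fr <- cov_raster(pos_field(f_mean, 0.9, cap = 8 * f_mean), spec,
                     name = "F")
    P <- cov_raster(pos_field(5000, 0.8), spec, name = "P")
    R <- cov_raster(pos_field(3, 0.6), spec, name = "R")
    list(F = Fr, L = L, P = P, R = R)
  })
}

#' Simulate a point-transect distance-sampling survey
#'
#' Sites are placed uniformly within cells of surveyable landscape classes
#' (never bare ground; dense trees down-weighted by `dt_weight`). At site
#' `i` the number of bird clusters present within the truncation circle is
#' Poisson with mean `lambda_i * pi * B^2 / 1e4` (lambda in clusters/ha);
#' each cluster sits at a radial distance with density `2r/B^2`, is
#' detected with hazard-rate probability
#' `g(r) = 1 - exp(-(r/sigma_L)^-b)`, and has size `1 + Poisson(s - 1)`.
#'
#' @param truth A [truth_config()].
#' @param rasters Covariate rasters from [gen_covariates()].
#' @param n_sites Number of survey points (study default 400).
#' @param truncation Truncation radius B in metres.
#' @param seed Integer seed.
#' @param dt_weight Relative sampling weight of dense-tree cells.
#' @return Long-format survey tibble (`site_id, x, y, landscape, feeding,
#'   distance_m, cluster_size`); zero-detection sites keep one row with
#'   `NA` distance.
#' @export
simulate_surveys <- function(truth, rasters, n_sites = 400, truncation = 100,
                             seed = 20160601, dt_weight = 0.5) {
  stopifnot(n_sites >= 1)
  if (truncation <= 0) stop("truncation radius must be positive")
  L <- rasters$L; Fr <- rasters$F
  lv <- L$levels %||% landscape_levels()
  lab <- matrix(lv[L$values], nrow(L$values))
  ok_cells <- which(lab %in% surveyable_levels() & L$mask)
  w <- ifelse(lab[ok_cells] == "DT", dt_weight, 1)
  sp <- L$spec
  with_seed(seed, {
    cells <- sample(ok_cells, n_sites, replace = TRUE, prob = w)
    rc <- arrayInd(cells, dim(lab))
    s <- sp$cell_size
    x <- sp$origin_x + (rc[, 2] - 1) * s + stats::runif(n_sites) * s
    y <- sp$origin_y + (sp$n_rows - rc[, 1]) * s + stats::runif(n_sites) * s
    land <- lab[cells]
    feed <- Fr$values[rc]
    lam <- exp(truth$beta0 + truth$beta_F * feed + truth$beta_L[land])
    area_ha <- pi * truncation^2 / 1e4
    n_clusters <- stats::rpois(n_sites, lam * area_ha)
    rows <- purrr::map(seq_len(n_sites), function(i) {
      base <- tibble::tibble(site_id = sprintf("s%03d", i), x = x[i], y = y[i],
                             landscape = land[i], feeding = feed[i])
      if (n_clusters[i] == 0) {
        return(dplyr::mutate(base, distance_m = NA_real_,
                             cluster_size = NA_integer_))
      }
      r <- truncation * sqrt(stats::runif(n_clusters[i]))
      keep <- stats::runif(n_clusters[i]) <
        hazard_rate(r, truth$sigma[land[i]], truth$hazard_b)
      r <- r[keep]
      if (!length(r)) {
        return(dplyr::mutate(base, distance_m = NA_real_,
                             cluster_size = NA_integer_))
      }
      sz <- 1L + stats::rpois(length(r), truth$cluster_mean - 1)
      dplyr::mutate(base[rep(1, length(r)), ], distance_m = r,
                    cluster_size = sz)
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate georeferenced individuals for genetic simulation
#'
#' Places sampling sites at least `min_dist` apart by rejection sampling
#' inside the grid extent, then distributes individuals among sites.
#'
#' @param n Number of individuals.
#' @param spec A [grid_spec()].
#' @param n_sites Number of distinct sampling locations.
#' @param min_dist Minimum distance between sites (m).
#' @param seed Integer seed.
#' @param sex_ratio Proportion of males.
#' @return Sample tibble (`id, x, y, site, sex`).
#' @export
gen_samples <- function(n = 150, spec = grid_spec(), n_sites = 55,
                        min_dist = 500, seed = 20160601, sex_ratio = 0.5) {
  stopifnot(n >= 2, n_sites >= 1)
  w <- spec$n_cols * spec$cell_size
  h <- spec$n_rows * spec$cell_size
  with_seed(seed, {
    sx <- numeric(0); sy <- numeric(0)
    tries <- 0
    while (length(sx) < n_sites && tries < 50000) {
      px <- spec$origin_x + stats::runif(1) * w
      py <- spec$origin_y + stats::runif(1) * h
      if (!length(sx) || min(sqrt((sx - px)^2 + (sy - py)^2)) >= min_dist) {
        sx <- c(sx, px); sy <- c(sy, py)
      }
      tries <- tries + 1
    }
    if (length(sx) < n_sites) stop("could not place sites this far apart")
    site <- sort(sample(seq_len(n_sites), n, replace = TRUE))
    jitter <- function(k) stats::runif(k, -100, 100)
    tibble::tibble(
      id = sprintf("ind%03d", seq_len(n)),
      x = sx[site] + jitter(n), y = sy[site] + jitter(n),
      site = sprintf("site%02d", site),
      sex = sample(c("M", "F"), n, replace = TRUE,
                   prob = c(sex_ratio, 1 - sex_ratio))
    )
  })
}

# side of the barrier polygon's principal axis each point falls on (+1/-1)
barrier_side <- function(barrier, x, y) {
  ctr <- colMeans(barrier)
  v <- stats::prcomp(barrier, center = TRUE)$rotation[, 1]
  nrm <- c(-v[2], v[1])
  sign((x - ctr[1]) * nrm[1] + (y - ctr[2]) * nrm[2] + 1e-12)
}

#' Simulate spatially structured SNP genotypes
#'
#' For each locus a latent surface `z(x)` is drawn as a zero-mean Gaussian
#' field with Gaussian correlation `exp(-d^2 / (2 rho^2))` and marginal SD
#' `tau`, evaluated at the individuals' coordinates; the local allele
#' frequency is `plogis(z)` and genotypes are Binomial(2, p). This gives
#' isolation-by-distance structure whose genetic patch size grows with
#' `rho`. With a barrier, a fraction `barrier_frac` of loci draw
#' independent fields on the two sides, mimicking restricted gene flow.
#' Parent--offspring pairs are appended as Mendelian offspring of randomly
#' chosen parents placed at the first parent's location.
#'
#' @param samples Sample tibble from [gen_samples()] (or with the same
#'   columns).
#' @param truth A [truth_config()].
#' @param seed Integer seed.
#' @return List with `genotypes` (matrix, samples x loci), `samples`
#'   (augmented when kin are appended) and `kin_pairs` (tibble of injected
#'   parent--offspring ids).
#' @export
simulate_genotypes <- function(samples, truth, seed = 20160601) {
  stopifnot(nrow(samples) >= 2)
  n <- nrow(samples)
  L <- truth$n_loci
  with_seed(seed, {
    if (truth$tau == 0) {
      G <- matrix(stats::rbinom(n * L, 2, 0.5), n, L)
    } else {
      D <- as.matrix(stats::dist(cbind(samples$x, samples$y)))
      K <- exp(-D^2 / (2 * truth$rho^2))
      if (!is.null(truth$barrier)) {
        side <- barrier_side(truth$barrier, samples$x, samples$y)
        cross <- outer(side, side, "!=")
        Ksplit <- K
        Ksplit[cross] <- 0
        n_split <- round(truth$barrier_frac * L)
      } else {
        n_split <- 0
      }
      draw <- function(Kmat, nl) {
        ch <- chol(Kmat + diag(1e-8, n))
        z <- truth$tau * crossprod(ch, matrix(stats::rnorm(n * nl), n, nl))
        matrix(stats::rbinom(n * nl, 2, stats::plogis(z)), n, nl)
      }
      if (n_split > 0) {
        G <- cbind(draw(Ksplit, n_split), draw(K, L - n_split))
      } else {
        G <- draw(K, L)
      }
    }
    rownames(G) <- samples$id
    colnames(G) <- sprintf("loc%04d", seq_len(L))
    kin <- tibble::tibble(parent = character(0), offspring = character(0))
    if (truth$n_kin > 0) {
      # one sampled parent per offspring; the other parent is an unsampled
      # random mate drawn from the sample allele frequencies, so each kin
      # injection creates exactly one related pair
      par_idx <- sample(n, truth$n_kin)
      p_pop <- pmin(pmax(colMeans(G) / 2, 1e-3), 1 - 1e-3)
      for (k in seq_len(truth$n_kin)) {
        p1 <- par_idx[k]
        child <- stats::rbinom(L, 1, G[p1, ] / 2) +
          stats::rbinom(L, 1, p_pop)
        cid <- sprintf("kin%02d", k)
        G <- rbind(G, child)
        rownames(G)[nrow(G)] <- cid
        samples <- dplyr::bind_rows(
          samples,
          dplyr::mutate(samples[p1, ], id = cid,
                        sex = sample(c("M", "F"), 1))
        )
        kin <- dplyr::bind_rows(kin, tibble::tibble(parent = samples$id[p1],
                                                    offspring = cid))
      }
    }
    list(genotypes = G, samples = samples, kin_pairs = kin)
  })
}
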