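test_that("hazard-rate detection has its characteristic shape", {
  for (b in c(0.5, 1, 3, 10)) {
    expect_equal(hazard_rate(30, 30, b), 1 - exp(-1))
  }
  expect_equal(hazard_rate(60, 30, 3), 1 - exp(-2^(-3)), tolerance = 1e-12)
  expect_equal(hazard_rate(0, 30, 3), 1)
  r <- seq(1, 200, by = 1)
  g <- hazard_rate(r, 50, 2.5)
  expect_true(all(diff(g) <= 0))
  shoulder <- g < 1 - 1e-12
  expect_true(all(diff(g[shoulder]) < 0))
  expect_true(all(g > 0 & g <= 1))
  expect_error(hazard_rate(10, -1, 3), "positive")
  expect_error(hazard_rate(10, 30, 0), "positive")
})

test_that("annulus probabilities integrate the point-transect geometry", {
  breaks <- c(0, 25, 50, 75, 100)
  # perfect detection limit: pi_j is the annulus area fraction
  cp <- cell_probs(breaks, sigma = 1e9, b = 3)
  expect_equal(cp$pi, diff(breaks^2) / 100^2, tolerance = 1e-9)
  expect_equal(cp$p, 1, tolerance = 1e-9)
  # additivity: refining breaks leaves p unchanged
  p1 <- cell_probs(seq(0, 100, 10), 30, 3)$p
  p2 <- cell_probs(seq(0, 100, 2.5), 30, 3)$p
  expect_equal(p1, p2, tolerance = 1e-9)
  # fast fixed-order quadrature agrees with adaptive
  a <- cell_probs(breaks, 30, 3, method = "adaptive")
  g <- cell_probs(breaks, 30, 3, method = "gauss")
  expect_equal(a$pi, g$pi, tolerance = 1e-9)
})

test_that("annulus probabilities match Monte-Carlo integration", {
  breaks <- c(0, 25, 50, 75, 100)
  cp <- cell_probs(breaks, 30, 3)
  set.seed(424242)
  acc <- numeric(4)
  n_chunk <- 5e6; n_chunks <- 10
  for (k in seq_len(n_chunks)) {
    r <- 100 * sqrt(runif(n_chunk))
    g <- hazard_rate(r, 30, 3)
    bin <- findInterval(r, breaks, rightmost.closed = TRUE, left.open = TRUE)
    acc <- acc + vapply(1:4, function(j) sum(g[bin == j]), numeric(1))
  }
  mc <- acc / (n_chunk * n_chunks)
  expect_lt(max(abs(mc - cp$pi)), 1e-4)
})

test_that("single-landscape fit recovers the generating parameters", {
  tr <- flat_truth(beta0 = 0.3, sigma = 45, b = 3)
  sv <- simulate_surveys(tr, flat_rasters(), n_sites = 4000, seed = 19)
  fit <- hds_fit(sv, abundance = ~1, detection = ~1)
  expect_true(fit$converged)
  est <- tidy(fit)
  truth <- c(0.3, log(45), log(3))
  for (k in 1:3) {
    expect_lt(abs(est$estimate[k] - truth[k]), 3 * est$std.error[k])
  }
})

test_that("duplicating every site doubles the log-likelihood only", {
  tr <- flat_truth(beta0 = 0.5)
  sv <- simulate_surveys(tr, flat_rasters(), n_sites = 300, seed = 23)
  sv2 <- dplyr::mutate(sv, site_id = paste0(site_id, "dup"))
  fit1 <- hds_fit(sv, abundance = ~1, detection = ~1)
  fit2 <- hds_fit(dplyr::bind_rows(sv, sv2), abundance = ~1, detection = ~1)
  expect_equal(fit2$logLik, 2 * fit1$logLik, tolerance = 1e-6)
  expect_equal(fit2$coef, fit1$coef, tolerance = 1e-5)
})

test_that("the binned likelihood equals the multinomial-Poisson mixture", {
  # one site, fixed detection: Poisson-per-bin log-likelihood differs from
  # Poisson(total) x multinomial(bins) only by the data-only multinomial
  # coefficient
  breaks <- seq(0, 100, 25)
  piv <- cell_probs(breaks, 40, 3)$pi
  p <- sum(piv)
  y <- c(4, 2, 1, 0)
  lam_area <- 1.7 * pi
  mu <- lam_area * piv
  ll_bins <- sum(y * log(mu) - mu - lgamma(y + 1))
  n <- sum(y)
  ll_mix <- stats::dpois(n, lam_area * p, log = TRUE) +
    lgamma(n + 1) - sum(lgamma(y + 1)) + sum(y * log(piv / p))
  expect_equal(ll_bins, ll_mix, tolerance = 1e-12)
})

test_that("AIC ordering is invariant to covariate rescaling", {
  rs <- gen_covariates(seed = 33)
  tr <- truth_config()
  sv <- simulate_surveys(tr, rs, n_sites = 400, seed = 34)
  sv10 <- dplyr::mutate(sv, feeding = feeding / 10)
  f1 <- hds_fit(sv, abundance = ~ feeding + landscape, detection = ~1)
  f2 <- hds_fit(sv10, abundance = ~ feeding + landscape, detection = ~1)
  expect_equal(f1$AIC, f2$AIC, tolerance = 1e-4)
  expect_equal(f2$coef[["lambda_feeding"]] / f1$coef[["lambda_feeding"]],
               10, tolerance = 1e-3)
})

test_that("model selection orders by AIC and breaks ties by parsimony", {
  tr <- flat_truth(beta0 = 0.4)
  sv <- simulate_surveys(tr, flat_rasters(), n_sites = 300, seed = 40)
  f <- hds_fit(sv, abundance = ~1, detection = ~1)
  sel <- hds_select(list(only = f))
  expect_equal(unname(sel$table$delta_AIC), 0)
  expect_identical(sel$best, f)
  # a tie in AIC goes to the smaller model
  f_big <- f
  f_big$npar <- f$npar + 2
  f_big$AIC <- f$AIC
  sel2 <- hds_select(list(big = f_big, small = f))
  expect_equal(sel2$table$model[1], "small")
  # all-failed selection errors
  f_bad <- f; f_bad$converged <- FALSE
  expect_error(hds_select(list(a = f_bad)), "no converged")
})

test_that("density prediction applies the log-linear model per cell", {
  rs <- gen_covariates(seed = 44)
  tr <- truth_config()
  sv <- simulate_surveys(tr, rs, n_sites = 600, seed = 45)
  fit <- hds_fit(sv)
  # zeroed coefficients give exp(0) = 1 everywhere unmasked
  fit0 <- fit
  fit0$coef[] <- 0
  surf0 <- predict_density(fit0, rs, s_bar = 1)
  expect_true(all(abs(surf0$density$values[surf0$density$mask] - 1) < 1e-12))
  # bare ground is never predicted
  bg <- rs$L$values == match("BG", landscape_levels())
  expect_false(any(surf0$density$mask[bg]))
  # raising F in one cell raises that cell's density iff beta_F > 0
  surf <- predict_density(fit, rs, s_bar = 3.73)
  rs2 <- rs
  cell <- which(surf$density$mask)[1]
  rs2$F$values[cell] <- rs2$F$values[cell] + 10
  surf2 <- predict_density(fit, rs2, s_bar = 3.73)
  expect_equal(surf2$density$values[cell] > surf$density$values[cell],
               fit$coef[["lambda_feeding"]] > 0)
})

test_that("total abundance sums density times area with a normal band", {
  sp <- grid_spec(2, 2, cell_size = 1000)
  dens <- cov_raster(matrix(2, 2, 2), sp)
  se <- cov_raster(matrix(0.5, 2, 2), sp)
  surf <- structure(list(density = dens, se = se, s_bar = 1),
                    class = "density_surface")
  ta <- total_abundance(surf, cell_area = 100)
  expect_equal(ta$estimate, 2 * 400)
  expect_equal(ta$se, sqrt(4 * (0.5 * 100)^2))
  ta2 <- total_abundance(surf, cell_area = 200)
  expect_equal(ta2$estimate, 2 * ta$estimate)
  zero <- structure(list(density = cov_raster(matrix(0, 2, 2), sp),
                         se = cov_raster(matrix(0, 2, 2), sp), s_bar = 1),
                    class = "density_surface")
  expect_equal(total_abundance(zero, 100)$estimate, 0)
})

test_that("cluster-size summary averages and tests across landscapes", {
  sv <- tibble::tibble(
    site_id = c("a", "a", "b"), x = 0, y = 0,
    landscape = "HR", feeding = 0,
    distance_m = c(10, 20, 30), cluster_size = c(3, 4, 4)
  )
  expect_message(out <- cluster_size_summary(sv), "single landscape")
  expect_equal(out$s_bar, 11 / 3, tolerance = 1e-12)
  expect_true(is.na(out$kw_p))
})

test_that("cluster-size homogeneity test is calibrated and has power", {
  pvals_null <- vapply(1:100, function(s) {
    set.seed(7000 + s)
    sv <- tibble::tibble(
      site_id = "x", x = 0, y = 0,
      landscape = rep(c("HR", "LR"), each = 200), feeding = 0,
      distance_m = 10,
      cluster_size = 1 + rpois(400, 2.7)
    )
    cluster_size_summary(sv)$kw_p
  }, numeric(1))
  expect_gte(sum(pvals_null > 0.05), 90)
  pvals_alt <- vapply(1:20, function(s) {
    set.seed(8000 + s)
    sv <- tibble::tibble(
      site_id = "x", x = 0, y = 0,
      landscape = rep(c("HR", "LR"), each = 200), feeding = 0,
      distance_m = 10,
      cluster_size = 1 + rpois(400, rep(c(2, 4), each = 200))
    )
    cluster_size_summary(sv)$kw_p
  }, numeric(1))
  expect_gte(mean(pvals_alt < 0.05), 0.9)
})

test_that("out-of-truncation detections are dropped with a message", {
  sv <- tibble::tibble(
    site_id = c("a", "a"), x = 0, y = 0, landscape = "HR", feeding = 0,
    distance_m = c(50, 150), cluster_size = c(2, 3)
  )
  expect_message(fit <- hds_fit(sv, abundance = ~1, detection = ~1),
                 "beyond the truncation")
  expect_equal(fit$n_detections, 1)
})
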