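# fixtures are built in code at test time

write_test_vcf <- function(path, include_triallelic = FALSE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t")
  )
  row <- function(pos, alt, g1, g2, g3) {
    paste("chr1", pos, paste0("snp", pos), "A", alt, ".", "PASS", ".",
          "GT", g1, g2, g3, sep = "\t")
  }
  body <- c(
    row(101, "T", "0/0", "0/1", "1/1"),
    row(102, "G", "0/1", "0/1", "0/0"),
    row(103, "C", "1/1", "0/0", "0/1"),
    row(104, "T", "0/0", "0/0", "0/1"),
    row(105, "G", "0/1", "1/1", "1/1")
  )
  if (include_triallelic) {
    body <- append(body, row(106, "T,C", "0/1", "1/2", "0/0"), after = 2)
  }
  writeLines(c(hdr, body), path)
  path
}

# naive correlogram oracle: explicit double loop over individual pairs
correlogram_oracle <- function(d2, coords, n_classes, width) {
  n <- nrow(coords)
  C <- center_distance_matrix(d2)
  num <- den <- rep(0, n_classes)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      h <- if (d == 0) 1L else ceiling(d / width)
      if (h >= 1 && h <= n_classes) {
        num[h] <- num[h] + C[i, j]
        den[h] <- den[h] + (C[i, i] + C[j, j]) / 2
      }
    }
  }
  ifelse(den == 0, NA_real_, num / den)
}

# naive moving-window IDW oracle: per-cell loop
idw_oracle <- function(mx, my, vals, spec, window_radius, min_pairs) {
  cc <- cell_centers(spec)
  out <- rep(NA_real_, nrow(cc))
  for (ci in seq_len(nrow(cc))) {
    d <- sqrt((mx - cc$x[ci])^2 + (my - cc$y[ci])^2)
    keep <- d <= window_radius
    if (sum(keep) >= min_pairs) {
      w <- 1 / (d[keep] + spec$cell_size / 10)
      out[ci] <- sum(w * vals[keep]) / sum(w)
    }
  }
  m <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  m[cbind(cc$row, cc$col)] <- out
  m
}

# exhaustive simplex grid search for the relatedness MLE
relatedness_grid_oracle <- function(gi, gj, p, step = 0.02) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  tabs <- pigeonscape:::pair_prob_tables(p)
  idx <- cbind(3 * gi + gj + 1, seq_along(gi))
  P0 <- tabs$T0[idx]; P1 <- tabs$T1[idx]; P2 <- tabs$T2[idx]
  best <- c(NA, NA, NA); bll <- -Inf
  for (k0 in seq(0, 1, by = step)) {
    for (k1 in seq(0, 1 - k0, by = step)) {
      k2 <- 1 - k0 - k1
      ll <- sum(log(pmax(k0 * P0 + k1 * P1 + k2 * P2, 1e-300)))
      if (ll > bll) { bll <- ll; best <- c(k0, k1, k2) }
    }
  }
  best
}

# flat single-landscape world: every covariate constant, one class
flat_rasters <- function(spec = grid_spec(), class = "HR", feeding = 0) {
  lv <- landscape_levels()
  code <- match(class, lv)
  list(
    F = cov_raster(matrix(feeding, spec$n_rows, spec$n_cols), spec, name = "F"),
    L = cov_raster(matrix(code, spec$n_rows, spec$n_cols), spec, name = "L",
                   levels = lv),
    P = cov_raster(matrix(1, spec$n_rows, spec$n_cols), spec, name = "P"),
    R = cov_raster(matrix(1, spec$n_rows, spec$n_cols), spec, name = "R")
  )
}

# single-landscape truth with flat abundance
flat_truth <- function(beta0 = 0.3, sigma = 45, b = 3, cluster_mean = 3.73,
                       class = "HR") {
  sig <- c(HR = sigma, LR = sigma, ID = sigma, OV = sigma, DT = sigma)
  bl <- c(HR = 0, LR = 0, ID = 0, OV = 0, DT = 0)
  truth_config(beta0 = beta0, beta_F = 0, beta_L = bl, sigma = sig,
               hazard_b = b, cluster_mean = cluster_mean)
}
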