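#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance-sampling fit
#'
#' @param x An [hds_fit()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error` and the parameter
#'   block (`abundance`, `detection`, `shape`).
#' @exportS3Method generics::tidy
tidy.hds_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  block <- dplyr::case_when(
    startsWith(names(x$coef), "lambda_") ~ "abundance",
    startsWith(names(x$coef), "sigma_") ~ "detection",
    TRUE ~ "shape"
  )
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(se), block = block)
}

#' @rdname tidy.hds_fit
#' @exportS3Method generics::glance
glance.hds_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, AIC = x$AIC, npar = x$npar,
                 n_sites = x$n_sites, n_detections = x$n_detections,
                 converged = x$converged)
}

#' Tidy a correlogram
#' @param x A [genetic_correlogram()] result.
#' @param ... Unused.
#' @return The per-class tibble.
#' @exportS3Method generics::tidy
tidy.correlogram <- function(x, ...) x$classes

#' @rdname tidy.correlogram
#' @exportS3Method generics::glance
glance.correlogram <- function(x, ...) {
  tibble::tibble(n = x$n, width = x$width,
                 x_intercept = x$x_intercept, u_intercept = x$u_intercept)
}

#' Tidy an isolation-by-distance model
#' @param x An [ibd_fit()] result.
#' @param ... Unused.
#' @return The per-pair tibble of distances and residuals.
#' @exportS3Method generics::tidy
tidy.ibd_model <- function(x, ...) x$pairs

#' @rdname tidy.ibd_model
#' @exportS3Method generics::glance
glance.ibd_model <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope,
                 r_squared = x$r_squared, n_pairs = nrow(x$pairs))
}

#' Tidy diversity, relatedness and PCA results
#' @param x The result object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.diversity_summary <- function(x, ...) x$loci

#' @rdname tidy.diversity_summary
#' @exportS3Method generics::glance
glance.diversity_summary <- function(x, ...) x$summary

#' @rdname tidy.diversity_summary
#' @exportS3Method generics::tidy
tidy.relatedness_matrix <- function(x, ...) x$pairs

#' @rdname tidy.diversity_summary
#' @exportS3Method generics::tidy
tidy.gen_pca <- function(x, ...) x$scores

#' @rdname tidy.diversity_summary
#' @exportS3Method generics::glance
glance.gen_pca <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores),
                 pc1_var = x$var_explained[1], pc2_var = x$var_explained[2])
}

#' Tidy a resistance surface
#' @param x A [dresd()] result.
#' @param ... Unused.
#' @return Cell-level tibble with surface value, p, power and masks.
#' @exportS3Method generics::tidy
tidy.resistance_surface <- function(x, ...) {
  out <- as_tibble.cov_raster(x$surface)
  idx <- cbind(out$row, out$col)
  out$p <- x$p$values[idx]
  out$power <- x$power$values[idx]
  out$significant <- x$significant[idx]
  out$sufficient_power <- x$sufficient_power[idx]
  out
}
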