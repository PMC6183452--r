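#' Study-grid specification
#'
#' Defines the rectangular analysis lattice used throughout the package.
#' The default mirrors an island-wide raster of 1,250 roughly 1 km^2 cells
#' (25 rows north--south, 50 columns east--west). Row 1 is the northernmost
#' row; cell `(i, j)` covers the half-open square
#' `[origin_x + (j-1)s, origin_x + j s) x [origin_y + (n_rows-i)s, origin_y + (n_rows-i+1)s)`
#' with `s = cell_size`, so a point on an interior cell edge belongs to the
#' lower-index cell and points on the outer boundary are clamped inward.
#'
#' @param n_rows,n_cols Grid dimensions (rows x columns).
#' @param origin_x,origin_y Planar coordinates (m) of the south-west corner.
#' @param cell_size Cell edge length in metres.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows = 25, n_cols = 50, origin_x = 0, origin_y = 0,
                      cell_size = 1000) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_x = origin_x, origin_y = origin_y, cell_size = cell_size),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (origin %g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell centres of a grid
#'
#' @param spec A [grid_spec()].
#' @return A tibble with `row`, `col`, `x`, `y` (centre coordinates, m),
#'   ordered row-major with row 1 (north) first.
#' @export
cell_centers <- function(spec) {
  s <- spec$cell_size
  g <- expand.grid(col = seq_len(spec$n_cols), row = seq_len(spec$n_rows))
  tibble::tibble(
    row = g$row, col = g$col,
    x = spec$origin_x + (g$col - 0.5) * s,
    y = spec$origin_y + (spec$n_rows - g$row + 0.5) * s
  )
}

#' Locate points on the grid
#'
#' Maps planar coordinates to (row, col) cell indices. Points outside the
#' grid get `NA`; points exactly on the far (east/south) boundary are
#' clamped to the last cell.
#'
#' @param spec A [grid_spec()].
#' @param x,y Coordinates in metres.
#' @return A tibble with columns `row`, `col`.
#' @export
locate_cells <- function(spec, x, y) {
  s <- spec$cell_size
  col <- floor((x - spec$origin_x) / s) + 1
  row <- spec$n_rows - floor((y - spec$origin_y) / s)
  # clamp exact far-boundary points inward
  col[x == spec$origin_x + spec$n_cols * s] <- spec$n_cols
  row[y == spec$origin_y + spec$n_rows * s] <- 1L
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Covariate raster
#'
#' A single covariate on the study lattice: feeding intensity (`F`),
#' landscape class (`L`), human population density (`P`) or road density
#' (`R`). Landscape rasters store integer class codes with a `levels`
#' vector; the canonical urban classes are `HR` (high-rise), `LR`
#' (low-rise), `ID` (industrial), `OV` (open vegetation), `DT` (dense
#' trees) and `BG` (bare ground).
#'
#' @param values Numeric (or integer-code) matrix, `n_rows x n_cols`,
#'   row 1 = north.
#' @param spec A [grid_spec()] matching `dim(values)`.
#' @param name Covariate name.
#' @param mask Logical matrix of valid cells (default: non-`NA` values).
#' @param levels Optional character vector of category labels for coded
#'   rasters.
#' @return An object of class `cov_raster`.
#' @export
cov_raster <- function(values, spec = grid_spec(n_rows = nrow(values), n_cols = ncol(values)),
                       name = "covariate", mask = NULL, levels = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == spec$n_rows, ncol(values) == spec$n_cols)
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(identical(dim(mask), dim(values)))
  if (any(!is.finite(values[mask]))) stop("raster has non-finite values in unmasked cells")
  structure(list(values = values, spec = spec, name = name,
                 mask = mask, levels = levels),
            class = "cov_raster")
}

#' @export
print.cov_raster <- function(x, ...) {
  cat(sprintf("<cov_raster '%s'> %d x %d (%d masked cells)\n", x$name,
              x$spec$n_rows, x$spec$n_cols, sum(!x$mask)))
  invisible(x)
}

#' @rdname cov_raster
#' @param x A `cov_raster`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.cov_raster <- function(x, ...) {
  cc <- cell_centers(x$spec)
  idx <- cbind(cc$row, cc$col)
  out <- dplyr::mutate(cc, value = x$values[idx], mask = x$mask[idx])
  if (!is.null(x$levels)) out$label <- x$levels[out$value]
  out
}

#' Landscape class labels
#'
#' @return The six canonical urban landscape codes in package order.
#' @export
landscape_levels <- function() c("HR", "LR", "ID", "OV", "DT", "BG")

#' Surveyable landscape classes (everything except bare ground)
#' @return Character vector of class codes.
#' @export
surveyable_levels <- function() setdiff(landscape_levels(), "BG")

raster_lookup <- function(raster, x, y) {
  rc <- locate_cells(raster$spec, x, y)
  val <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  val[ok] <- raster$values[cbind(rc$row[ok], rc$col[ok])]
  val
}
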