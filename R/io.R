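#' Read a SNP genotype matrix
#'
#' Loads biallelic genotypes coded as 0/1/2 copies of the alternate allele.
#' Two formats are supported: VCF (GT field only, via vcfR) and a plain
#' matrix CSV with samples as rows (first column `id`) and loci as columns.
#' Multi-allelic VCF sites are skipped with a message reporting the count.
#' By default any missing call is an error, matching a strict
#' complete-cases policy; set `allow_missing = TRUE` to keep `NA`s.
#'
#' @param path File path.
#' @param format `"vcf"` or `"matrix_csv"`.
#' @param allow_missing Keep missing calls as `NA` instead of erroring.
#' @return Integer matrix (samples x loci) with sample ids as rownames and
#'   locus ids as colnames.
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix_csv"),
                           allow_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(vcf)
    multi <- grepl(",", alt, fixed = TRUE)
    if (any(multi)) {
      message(sum(multi), " multi-allelic site(s) skipped")
      vcf <- vcf[!multi, ]
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ids <- colnames(gt)
    loci <- rownames(gt)
    if (is.null(loci)) loci <- paste0("locus", seq_len(nrow(gt)))
    count_alt <- function(g) {
      out <- rep(NA_integer_, length(g))
      ok <- !is.na(g) & !grepl("\\.", g)
      alleles <- strsplit(gsub("\\|", "/", g[ok]), "/", fixed = FALSE)
      out[ok] <- vapply(alleles, function(a) sum(as.integer(a) > 0), integer(1))
      out
    }
    calls <- apply(gt, 2, count_alt)
    if (is.null(dim(calls))) calls <- matrix(calls, ncol = length(ids))
    G <- t(calls)                     # samples x loci
    dimnames(G) <- list(ids, loci)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!nrow(df)) stop("empty genotype CSV: ", path)
    ids <- as.character(df[[1]])
    G <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(G) <- "integer"
    rownames(G) <- ids
  }
  if (anyNA(G)) {
    if (!allow_missing) {
      miss <- which(is.na(G), arr.ind = TRUE)[1, ]
      stop(sprintf("missing genotype call at sample '%s', locus '%s'",
                   rownames(G)[miss[1]], colnames(G)[miss[2]]))
    }
  }
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1 or 2")
  if (anyDuplicated(rownames(G))) stop("duplicate sample ids")
  G
}

#' Write a genotype matrix as CSV
#' @param G Genotype matrix (samples x loci).
#' @param path Output path.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(id = rownames(G), G, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample table
#'
#' CSV with columns `id, x, y, site, sex` (sex in `M`/`F`/`U`).
#' @param path File path.
#' @return Tibble with those columns.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "site", "sex")
  if (!all(need %in% names(df))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("duplicate sample ids")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop("non-finite sample coordinates")
  }
  if (!all(df$sex %in% c("M", "F", "U"))) stop("sex must be M, F or U")
  tibble::as_tibble(df)
}

#' Read a point-transect survey table
#'
#' Long-format CSV: one row per detection with columns
#' `site_id, x, y, landscape, feeding, distance_m, cluster_size`;
#' sites with no detections appear as a single row with empty
#' `distance_m`/`cluster_size`.
#' @param path File path.
#' @return Tibble in the same long format.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "x", "y", "landscape", "feeding", "distance_m", "cluster_size")
  if (!all(need %in% names(df))) {
    stop("survey table must have columns: ", paste(need, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' @rdname read_survey
#' @param survey Survey tibble.
#' @param path Output path.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(survey, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write covariate rasters
#'
#' `esri_ascii` follows the ESRI ASCII grid header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`) with rows
#' written north to south; `csv_grid` is a bare CSV of values in the same
#' row order which round-trips bit-exactly.
#'
#' @param path File path.
#' @param format `"esri_ascii"` or `"csv_grid"`.
#' @param spec Grid spec for `csv_grid` (dimensions inferred when `NULL`).
#' @param name Covariate name to attach.
#' @return A [cov_raster()].
#' @export
read_raster <- function(path, format = c("esri_ascii", "csv_grid"),
                        spec = NULL, name = "covariate") {
  format <- match.arg(format)
  if (format == "esri_ascii") {
    lines <- readLines(path)
    hdr <- list()
    i <- 1
    while (grepl("^[A-Za-z]", lines[i])) {
      kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
      i <- i + 1
    }
    vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
                 quiet = TRUE)
    nr <- hdr$nrows; nc <- hdr$ncols
    if (length(vals) != nr * nc) {
      stop(sprintf("raster dimension mismatch: header %d x %d, %d values",
                   nr, nc, length(vals)))
    }
    m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
    sp <- grid_spec(nr, nc, origin_x = hdr$xllcorner %||% 0,
                    origin_y = hdr$yllcorner %||% 0,
                    cell_size = hdr$cellsize %||% 1000)
    cov_raster(m, sp, name = name)
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    if (is.null(spec)) spec <- grid_spec(nrow(m), ncol(m))
    if (nrow(m) != spec$n_rows || ncol(m) != spec$n_cols) {
      stop("raster dimension mismatch with grid spec")
    }
    cov_raster(m, spec, name = name)
  }
}

#' @rdname read_raster
#' @param raster A [cov_raster()].
#' @param nodata Value written for masked cells in `esri_ascii`.
#' @export
write_raster <- function(raster, path, format = c("esri_ascii", "csv_grid"),
                         nodata = -9999) {
  format <- match.arg(format)
  m <- raster$values
  m[!raster$mask] <- NA
  if (format == "esri_ascii") {
    sp <- raster$spec
    hdr <- c(sprintf("ncols %d", sp$n_cols), sprintf("nrows %d", sp$n_rows),
             sprintf("xllcorner %.10g", sp$origin_x),
             sprintf("yllcorner %.10g", sp$origin_y),
             sprintf("cellsize %.10g", sp$cell_size),
             sprintf("NODATA_value %g", nodata))
    m[is.na(m)] <- nodata
    body <- apply(m, 1, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                          collapse = " "))
    writeLines(c(hdr, body), path)
  } else {
    # full 17 significant digits so the round-trip is bit-exact
    txt <- matrix(sprintf("%.17g", m), nrow(m))
    txt[is.na(m)] <- "NA"
    writeLines(apply(txt, 1, paste, collapse = ","), path)
  }
  invisible(path)
}

#' Equirectangular projection about a reference point
#'
#' Projects longitude/latitude (degrees) to planar metres using an
#' equirectangular projection centred on a reference point, adequate for
#' study areas tens of kilometres across at low latitude. `unproject_xy`
#' inverts it.
#'
#' @param lon,lat Coordinates in degrees (`abs(lat) < 85`).
#' @param ref_lon,ref_lat Reference point in degrees.
#' @return Tibble with `x`, `y` in metres (or `lon`, `lat` for the inverse).
#' @export
project_lonlat <- function(lon, lat, ref_lon, ref_lat) {
  stopifnot(all(abs(lat) < 85))
  R <- 6371000
  rad <- pi / 180
  tibble::tibble(
    x = R * (lon - ref_lon) * rad * cos(ref_lat * rad),
    y = R * (lat - ref_lat) * rad
  )
}

#' @rdname project_lonlat
#' @param x,y Planar coordinates in metres.
#' @export
unproject_xy <- function(x, y, ref_lon, ref_lat) {
  R <- 6371000
  rad <- pi / 180
  tibble::tibble(
    lon = ref_lon + x / (R * rad * cos(ref_lat * rad)),
    lat = ref_lat + y / (R * rad)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  force(seed)   # before saving state: the seed may itself consume RNG draws
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
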