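#' Zonal Shannon land-use diversity
#'
#' For each analysis cell, the Shannon index (natural log) of land-cover
#' class proportions among the cell's classified pixels:
#' \eqn{H = -\sum_c p_c \ln p_c}. No-data/sea pixels are excluded from the
#' denominator; all analysis classes count. H is 0 for a single-class cell
#' and unbounded above as classes proliferate; cells with zero classified
#' pixels get \code{NA} and are flagged.
#'
#' @param raster A \code{land_raster}.
#' @param grid Optional grid data.frame (with \code{row}, \code{col}); when
#'   supplied the result is a vector aligned to its rows, otherwise a
#'   grid_ny x grid_nx matrix.
#' @return Per-cell Shannon index; attribute \code{no_data_cells} lists
#'   flagged cells when a grid is supplied.
#' @examples
#' cfg <- world_config(grid_nx = 2, grid_ny = 2, pixels_per_cell_side = 4)
#' r <- generate_landcover(cfg, force_classes = 1:4)
#' shannon_landuse(r)  # every cell: log(4)
#' @export
shannon_landuse <- function(raster, grid = NULL) {
  stopifnot(inherits(raster, "land_raster"))
  H <- cell_shannon_matrix(raster)
  if (is.null(grid)) return(H)
  out <- H[cbind(grid$row, grid$col)]
  names(out) <- grid$cell_id
  attr(out, "no_data_cells") <- grid$cell_id[is.na(out)]
  out
}

#' Aggregate environmental covariates over grid cells
#'
#' Zonal statistics of fine-resolution covariate rasters aligned to the grid:
#' productivity (NDVI) is aggregated by the mean, all other covariates
#' (elevation, temperature, precipitation, human footprint) by the median.
#' No-data (NA) pixels are excluded; cells with no valid pixel for a
#' covariate get \code{NA} and are flagged.
#'
#' @param rasters Named list of numeric matrices, each with dimensions that
#'   are an integer multiple of the grid dimensions. The element named
#'   \code{"npp"} (or \code{"ndvi"}) is mean-aggregated.
#' @param grid Grid data.frame with \code{row} and \code{col}.
#' @return Data.frame (one row per grid row) of per-cell statistics, with
#'   attribute \code{missing_cells} (named list of flagged cell_ids).
#' @export
aggregate_covariates <- function(rasters, grid) {
  ny <- max(grid$row); nx <- max(grid$col)
  out <- data.frame(cell_id = grid$cell_id)
  flags <- list()
  for (nm in names(rasters)) {
    m <- rasters[[nm]]
    if (nrow(m) %% ny != 0 || ncol(m) %% nx != 0)
      stop("raster '", nm, "' is not aligned to the grid")
    pr <- nrow(m) %/% ny; pc <- ncol(m) %/% nx
    f <- if (tolower(nm) %in% c("npp", "ndvi")) {
      function(v) mean(v, na.rm = TRUE)
    } else {
      function(v) median(v, na.rm = TRUE)
    }
    vals <- vapply(seq_len(nrow(grid)), function(i) {
      px <- m[((grid$row[i] - 1) * pr + 1):(grid$row[i] * pr),
              ((grid$col[i] - 1) * pc + 1):(grid$col[i] * pc)]
      if (all(is.na(px))) NA_real_ else f(px)
    }, numeric(1))
    out[[nm]] <- vals
    if (anyNA(vals)) flags[[nm]] <- grid$cell_id[is.na(vals)]
  }
  attr(out, "missing_cells") <- flags
  out
}

#' Screening correlations among land-use diversity and covariates
#'
#' Pairwise Pearson correlations (with two-sided p-values) between the
#' per-cell Shannon land-use index and every covariate column, the diagnostic
#' used to decide which covariates must enter the models as confounders.
#' Zero-variance columns yield \code{NA}.
#'
#' @param metrics A \code{\link{cell_metrics}} table (or any data.frame with
#'   \code{landuse_shannon} and numeric covariate columns).
#' @param vars Covariate columns to screen (default: npp plus any
#'   \code{median_*} column present).
#' @return Data.frame: \code{var1}, \code{var2}, \code{r}, \code{p},
#'   \code{n}.
#' @export
covariate_correlations <- function(metrics, vars = NULL) {
  if (is.null(vars))
    vars <- intersect(c("npp", grep("^median_", names(metrics), value = TRUE)),
                      names(metrics))
  cols <- c("landuse_shannon", vars)
  stopifnot(all(cols %in% names(metrics)))
  if (nrow(metrics) < 3) stop("at least 3 cells required")
  pairs <- utils::combn(cols, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    x <- metrics[[pairs[1, k]]]; y <- metrics[[pairs[2, k]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
                 r = NA_real_, p = NA_real_, n = sum(ok))
    } else {
      ct <- cor.test(x[ok], y[ok])
      data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
                 r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
  })
  do.call(rbind, res)
}
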