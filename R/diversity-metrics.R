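#' Per-cell taxonomic richness
#'
#' @param occ An \code{\link{occurrence_grid}}.
#' @return Named integer vector (names = cell_id) of distinct-species counts.
#' @export
taxonomic_richness <- function(occ) {
  stopifnot(inherits(occ, "occurrence_grid"))
  setNames(as.integer(rowSums(occ$presence > 0)), occ$grid$cell_id)
}

#' Convex-hull volume of a point cloud
#'
#' Volume of the convex hull of \code{n} points in \code{d} dimensions,
#' computed by an incremental (beneath-beyond) construction with simplicial
#' facets. Degenerate clouds (fewer than d+1 points, or affine dimension
#' below d) return \code{NA}.
#'
#' @param points Numeric n x d matrix.
#' @return Hull volume (scalar), or NA for degenerate input.
#' @examples
#' convhull_volume(rbind(rep(0, 3), diag(3)))  # unit 3-simplex: 1/6
#' @export
convhull_volume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("non-finite coordinates")
  .convhull_volume_cpp(points)
}

#' Per-cell functional richness (FRic)
#'
#' For each cell, the convex-hull volume of its species' coordinates in the
#' retained functional space. Cells whose assemblage is degenerate in that
#' space (affine dimension below the number of axes) get \code{NA} and are
#' flagged; cells below the minimum richness raise an error because they
#' should have been excluded upstream.
#'
#' @param occ A filtered \code{\link{occurrence_grid}}.
#' @param space A \code{\link{pcoa}} functional space covering (at least) the
#'   occurrence grid's species.
#' @param min_species Minimum species count per cell (default 6).
#' @return Named numeric vector of hull volumes with attribute
#'   \code{degenerate} (cell_ids flagged NA).
#' @export
functional_richness <- function(occ, space, min_species = 6L) {
  stopifnot(inherits(occ, "occurrence_grid"), inherits(space, "functional_space"))
  idx <- match(occ$species, rownames(space$coordinates))
  if (any(is.na(idx)))
    stop("species missing from the functional space: ",
         paste(occ$species[is.na(idx)][1:5], collapse = ", "))
  coords <- space$coordinates[idx, , drop = FALSE]
  rich <- rowSums(occ$presence > 0)
  if (any(rich < min_species))
    stop(sum(rich < min_species), " cell(s) below the minimum richness; ",
         "apply filter_cells() first")
  out <- rep(NA_real_, nrow(occ$presence))
  for (i in seq_len(nrow(occ$presence))) {
    out[i] <- convhull_volume(coords[occ$presence[i, ] > 0, , drop = FALSE])
  }
  names(out) <- occ$grid$cell_id
  attr(out, "degenerate") <- occ$grid$cell_id[is.na(out)]
  out
}

#' Standardize a metric to its maximum observed value
#'
#' Divides by the global maximum over all retained cells, so the standardized
#' metric lies in [0, 1] and attains 1 exactly at the maximal cell(s).
#' Missing entries propagate.
#'
#' @param values Numeric vector (NA allowed).
#' @param scope \code{"global"} (one denominator, default) or
#'   \code{"per_realm"}, in which case \code{realm} must be given.
#' @param realm Realm labels aligned with \code{values} (per-realm scope).
#' @return Vector of the same length in [0, 1].
#' @export
standardize_to_max <- function(values, scope = c("global", "per_realm"),
                               realm = NULL) {
  scope <- match.arg(scope)
  if (length(values) == 0L) stop("empty input")
  if (scope == "global") {
    m <- max(values, na.rm = TRUE)
    if (!is.finite(m) || m <= 0) stop("maximum must be positive")
    return(values / m)
  }
  stopifnot(!is.null(realm), length(realm) == length(values))
  ave_max <- stats::ave(values, realm,
                        FUN = function(v) max(v, na.rm = TRUE))
  if (any(ave_max <= 0, na.rm = TRUE)) stop("maximum must be positive")
  values / ave_max
}

#' Median community range size per cell
#'
#' A species' range size is the number of grid cells it occupies anywhere on
#' the unfiltered grid (times cell area, to express it in area units); the
#' per-cell statistic is the median over species present in that cell. Range
#' sizes are computed on the full (pre-exclusion) occupancy so that a
#' species' range does not shrink because marginal cells failed the analysis
#' filters.
#'
#' @param occ_global The unfiltered \code{\link{occurrence_grid}}.
#' @param cells Optional cell_ids to report (default: all cells of
#'   \code{occ_global}); typically the retained analysis cells.
#' @param use_area Multiply occupied-cell counts by cell area (default TRUE).
#' @return Named numeric vector of per-cell medians (NA for empty cells).
#' @export
median_range_size <- function(occ_global, cells = NULL, use_area = TRUE) {
  stopifnot(inherits(occ_global, "occurrence_grid"))
  range_cells <- colSums(occ_global$presence > 0)
  range_size <- if (use_area) range_cells * mean(occ_global$grid$area) else range_cells
  ids <- cells %||% occ_global$grid$cell_id
  idx <- match(ids, occ_global$grid$cell_id)
  out <- vapply(idx, function(i) {
    sp <- occ_global$presence[i, ] > 0
    if (!any(sp)) NA_real_ else median(range_size[sp])
  }, numeric(1))
  setNames(out, ids)
}

#' Assemble the per-cell metrics table
#'
#' Joins taxonomic richness, functional richness (when a functional space is
#' supplied), their max-standardized versions, median range size, land-use
#' Shannon diversity, productivity and the environmental covariates into the
#' analysis table consumed by the model suite.
#'
#' @param occ Filtered \code{\link{occurrence_grid}} (analysis cells).
#' @param landcover A \code{land_raster} aligned to the unfiltered grid.
#' @param npp Output of \code{\link{generate_npp}} or a cell-level matrix.
#' @param covariates Named list of cell-level matrices (see
#'   \code{\link{generate_covariates}}); optional.
#' @param space Optional \code{\link{pcoa}} space; enables functional
#'   richness.
#' @param occ_global Unfiltered occurrence grid for range sizes (defaults to
#'   \code{occ}).
#' @param standardize_scope Passed to \code{\link{standardize_to_max}}.
#' @return Data.frame with one row per retained cell: identifiers and
#'   coordinates, \code{taxonomic_richness}, \code{functional_richness},
#'   \code{taxonomic_std}, \code{functional_std}, \code{median_range_size},
#'   \code{landuse_shannon}, \code{npp} and covariate medians.
#' @export
cell_metrics <- function(occ, landcover, npp, covariates = NULL, space = NULL,
                         occ_global = occ, standardize_scope = "global") {
  g <- occ$grid
  tr <- taxonomic_richness(occ)
  H_all <- shannon_landuse(landcover)
  npp_cell <- if (is.list(npp)) npp$cell else npp
  out <- data.frame(
    cell_id = g$cell_id, center_lon = g$center_lon, center_lat = g$center_lat,
    realm = g$realm, land_fraction = g$land_fraction,
    taxonomic_richness = as.integer(tr),
    landuse_shannon = H_all[cbind(g$row, g$col)],
    npp = npp_cell[cbind(g$row, g$col)],
    stringsAsFactors = FALSE)
  out$taxonomic_std <- standardize_to_max(out$taxonomic_richness,
                                          scope = standardize_scope,
                                          realm = g$realm)
  if (!is.null(space)) {
    fr <- functional_richness(occ, space)
    out$functional_richness <- as.numeric(fr)
    std <- rep(NA_real_, nrow(out))
    ok <- !is.na(fr)
    if (any(ok)) std[ok] <- standardize_to_max(fr[ok], scope = standardize_scope,
                                               realm = g$realm[ok])
    out$functional_std <- std
  }
  out$median_range_size <- as.numeric(median_range_size(occ_global,
                                                        cells = g$cell_id))
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      out[[paste0("median_", nm)]] <- covariates[[nm]][cbind(g$row, g$col)]
    }
  }
  out
}
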