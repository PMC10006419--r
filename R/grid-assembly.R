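#' Cell-by-species occurrence container
#'
#' Binary presence of species in the cells of an equal-area analysis grid.
#' The presence matrix is stored dense with dimnames; occupied pairs can be
#' iterated with \code{which(x$presence == 1L, arr.ind = TRUE)}.
#'
#' @param presence Integer/logical cell x species matrix (coerced to 0/1).
#' @param grid Grid attribute table: one row per cell with at least
#'   \code{cell_id}, \code{center_lon}, \code{center_lat}, \code{area},
#'   \code{land_fraction} and (possibly NA) \code{realm}.
#' @param species Character vector of species identifiers matching the
#'   presence columns.
#' @return An object of class \code{occurrence_grid}.
#' @export
occurrence_grid <- function(presence, grid, species) {
  presence <- matrix(as.integer(presence != 0), nrow(presence), ncol(presence),
                     dimnames = list(grid$cell_id, species))
  stopifnot(nrow(presence) == nrow(grid), ncol(presence) == length(species),
            all(grid$land_fraction >= 0 & grid$land_fraction <= 1))
  structure(list(presence = presence, grid = grid, species = species),
            class = "occurrence_grid")
}

#' @export
print.occurrence_grid <- function(x, ...) {
  cat(sprintf("<occurrence_grid> %d cells x %d species, %d occupied pairs\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

#' Build an equal-area analysis grid over a planar extent
#'
#' Tiles the extent with square cells of the given size (all cells therefore
#' share the same area, the planar analogue of an equal-area projection grid)
#' and computes each cell's land fraction from an aligned binary land mask.
#'
#' @param extent Numeric \code{c(xmin, xmax, ymin, ymax)}.
#' @param cell_size Positive cell side length; the extent must be an integer
#'   number of cells.
#' @param landmask Optional list with \code{values} (0/1 matrix, row 1 =
#'   southernmost strip) aligned to the extent; when NULL all cells are full
#'   land.
#' @return Grid data.frame: \code{cell_id}, \code{row}, \code{col},
#'   \code{center_lon}, \code{center_lat}, \code{area},
#'   \code{land_fraction}, \code{realm} (NA until assigned).
#' @export
build_grid <- function(extent, cell_size, landmask = NULL) {
  stopifnot(length(extent) == 4, cell_size > 0)
  wx <- extent[2] - extent[1]; wy <- extent[4] - extent[3]
  if (wx <= 0 || wy <= 0) stop("empty extent")
  nx <- round(wx / cell_size); ny <- round(wy / cell_size)
  if (abs(nx * cell_size - wx) > 1e-9 || abs(ny * cell_size - wy) > 1e-9)
    stop("extent is not an integer number of cells")
  rows <- rep(seq_len(ny), each = nx)
  cols <- rep(seq_len(nx), times = ny)
  lf <- rep(1, nx * ny)
  if (!is.null(landmask)) {
    m <- landmask$values
    if (nrow(m) %% ny != 0 || ncol(m) %% nx != 0)
      stop("landmask is not aligned to the grid")
    pr <- nrow(m) %/% ny; pc <- ncol(m) %/% nx
    ci <- 0L
    for (r in seq_len(ny)) {
      for (cc in seq_len(nx)) {
        ci <- ci + 1L
        lf[ci] <- mean(m[((r - 1) * pr + 1):(r * pr),
                         ((cc - 1) * pc + 1):(cc * pc)] != 0)
      }
    }
  }
  data.frame(cell_id = seq_len(nx * ny), row = rows, col = cols,
             center_lon = extent[1] + (cols - 0.5) * cell_size,
             center_lat = extent[3] + (rows - 0.5) * cell_size,
             area = cell_size^2, land_fraction = lf,
             realm = NA_character_, stringsAsFactors = FALSE)
}

range_seasonal_keep <- c("resident", "breeding")
range_origin_keep <- c("native", "reintroduced")
range_seasonal_known <- c(range_seasonal_keep, "non-breeding", "passage")
range_origin_known <- c(range_origin_keep, "introduced", "vagrant", "uncertain")

#' Filter range records by seasonality and origin
#'
#' Retains records coded resident or breeding-season, of native or
#' reintroduced origin; introduced-origin records are dropped. Records with
#' codes outside the known vocabularies are dropped with a warning and listed
#' in the \code{"dropped"} attribute together with the reason.
#'
#' @param records Data.frame with columns \code{species_id}, \code{seasonal},
#'   \code{origin} (and usually a \code{geometry} list-column).
#' @return The retained records, with attribute \code{dropped}.
#' @export
filter_range_records <- function(records) {
  if (nrow(records) == 0L) {
    attr(records, "dropped") <- records
    return(records)
  }
  seasonal <- tolower(records$seasonal)
  origin <- tolower(records$origin)
  unknown <- !(seasonal %in% range_seasonal_known) | !(origin %in% range_origin_known)
  if (any(unknown))
    warning(sum(unknown), " record(s) with unknown seasonal/origin code dropped")
  keep <- !unknown & seasonal %in% range_seasonal_keep & origin %in% range_origin_keep
  dropped <- records[!keep, , drop = FALSE]
  dropped$reason <- ifelse(unknown[!keep], "unknown_code",
                           ifelse(!(origin[!keep] %in% range_origin_keep),
                                  "origin_excluded", "seasonal_excluded"))
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

# even-odd point-in-polygon test; poly is a closed or open ring matrix (x, y)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) inside <- !inside
    j <- i
  }
  inside
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# Any-overlap test between a polygon ring and an axis-aligned rectangle
# rect = c(xmin, xmax, ymin, ymax).
poly_intersects_rect <- function(poly, rect) {
  if (max(poly[, 1]) < rect[1] || min(poly[, 1]) > rect[2] ||
      max(poly[, 2]) < rect[3] || min(poly[, 2]) > rect[4]) return(FALSE)
  inx <- poly[, 1] >= rect[1] & poly[, 1] <= rect[2] &
    poly[, 2] >= rect[3] & poly[, 2] <= rect[4]
  if (any(inx)) return(TRUE)
  corners <- rbind(c(rect[1], rect[3]), c(rect[2], rect[3]),
                   c(rect[2], rect[4]), c(rect[1], rect[4]))
  for (k in 1:4) if (point_in_polygon(corners[k, 1], corners[k, 2], poly)) return(TRUE)
  n <- nrow(poly)
  edges <- rbind(cbind(corners, corners[c(2, 3, 4, 1), ]))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    for (k in 1:4)
      if (segments_intersect(a, b, edges[k, 1:2], edges[k, 3:4])) return(TRUE)
  }
  FALSE
}

#' Rasterize range polygons onto the analysis grid
#'
#' A species is marked present in a cell when any of its retained range
#' polygons intersects the cell (any-overlap rule, no minimum-coverage
#' threshold); multiple records per species are OR-combined. Polygons with
#' fewer than three vertices or non-finite coordinates are skipped with a
#' warning.
#'
#' @param records Filtered range records with a \code{geometry} list-column of
#'   two-column (x, y) ring matrices.
#' @param grid A grid from \code{\link{build_grid}} (square cells assumed).
#' @return An \code{\link{occurrence_grid}} over the given grid.
#' @export
rasterize_ranges <- function(records, grid) {
  species <- sort(unique(records$species_id))
  half <- sqrt(grid$area) / 2
  pres <- matrix(0L, nrow(grid), length(species),
                 dimnames = list(grid$cell_id, species))
  skipped <- 0L
  for (i in seq_len(nrow(records))) {
    poly <- records$geometry[[i]]
    if (is.null(poly) || !is.matrix(poly) || nrow(poly) < 3 || !all(is.finite(poly))) {
      skipped <- skipped + 1L
      next
    }
    s <- match(records$species_id[i], species)
    for (ci in seq_len(nrow(grid))) {
      if (pres[ci, s] == 1L) next
      rect <- c(grid$center_lon[ci] - half[ci], grid$center_lon[ci] + half[ci],
                grid$center_lat[ci] - half[ci], grid$center_lat[ci] + half[ci])
      if (poly_intersects_rect(poly, rect)) pres[ci, s] <- 1L
    }
  }
  if (skipped > 0L) warning(skipped, " invalid geometry record(s) skipped")
  occurrence_grid(pres, grid, species)
}

#' Apply the analysis-cell exclusion filters
#'
#' Drops cells with land fraction below the threshold, then cells whose
#' species count is below the minimum needed to characterize the functional
#' space. Thresholds are inclusive (\code{>=} keeps), i.e. the exclusions are
#' the strict conditions "< 10\% land" and "fewer than six species". The
#' order (land first, then richness) and each dropped cell's reason are
#' recorded in the \code{"exclusion_log"} attribute.
#'
#' @param occ An \code{\link{occurrence_grid}}.
#' @param min_land_fraction Minimum land fraction kept (default 0.10).
#' @param min_species Minimum species count kept (default 6).
#' @return The filtered \code{occurrence_grid}, with attribute
#'   \code{exclusion_log} (data.frame of cell_id, reason).
#' @export
filter_cells <- function(occ, min_land_fraction = 0.10, min_species = 6L) {
  stopifnot(inherits(occ, "occurrence_grid"))
  land_ok <- occ$grid$land_fraction >= min_land_fraction
  rich <- rowSums(occ$presence)
  rich_ok <- rich >= min_species
  keep <- land_ok & rich_ok
  log <- data.frame(
    cell_id = occ$grid$cell_id[!keep],
    reason = ifelse(!land_ok[!keep], "land_fraction_below_threshold",
                    "species_count_below_minimum"))
  if (!any(keep)) stop("all cells excluded by the land-fraction/richness filters")
  out <- occurrence_grid(occ$presence[keep, , drop = FALSE],
                         occ$grid[keep, , drop = FALSE], occ$species)
  attr(out, "exclusion_log") <- log
  out
}

#' Assign biogeographic realm labels to grid cells
#'
#' @param grid A grid data.frame.
#' @param realm_map Data.frame with columns \code{cell_id} and \code{realm}
#'   covering every cell of the grid.
#' @return The grid with its \code{realm} column filled; per-realm cell
#'   counts are attached as attribute \code{realm_counts}.
#' @export
assign_realms <- function(grid, realm_map) {
  idx <- match(grid$cell_id, realm_map$cell_id)
  missing <- grid$cell_id[is.na(idx) | is.na(realm_map$realm[idx])]
  if (length(missing))
    stop("realm map does not cover cells: ",
         paste(utils::head(missing, 20), collapse = ", "))
  grid$realm <- as.character(realm_map$realm[idx])
  attr(grid, "realm_counts") <- table(grid$realm)
  grid
}

#' Read range records from GeoJSON
#'
#' Expects one polygon feature per record with properties \code{species_id}
#' (or \code{species}), \code{seasonal} and \code{origin}; only the outer ring
#' of the first polygon of each feature is used.
#'
#' @param path GeoJSON file path.
#' @return A range-record data.frame with a \code{geometry} list-column.
#' @export
read_ranges_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  n <- length(feats)
  geom <- vector("list", n)
  sp <- seas <- orig <- character(n)
  for (i in seq_len(n)) {
    pr <- feats[[i]]$properties
    sp[i] <- pr$species_id %||% pr$species %||% NA_character_
    seas[i] <- pr$seasonal %||% NA_character_
    orig[i] <- pr$origin %||% NA_character_
    g <- feats[[i]]$geometry
    ring <- if (identical(g$type, "Polygon")) g$coordinates[[1]]
            else if (identical(g$type, "MultiPolygon")) g$coordinates[[1]][[1]]
            else NULL
    if (!is.null(ring))
      geom[[i]] <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  }
  out <- data.frame(species_id = sp, seasonal = seas, origin = orig,
                    stringsAsFactors = FALSE)
  out$geometry <- I(geom)
  out
}
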