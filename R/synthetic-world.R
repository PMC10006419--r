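#' Configuration of a synthetic world
#'
#' Defines the dimensions, land-cover richness, species pool, ground-truth
#' effect structure and seed of a simulated study region. The generated world
#' emulates the inputs of the real-data analysis: a categorical land-cover
#' raster at fine resolution inside each analysis cell, a productivity (NDVI)
#' surface with a tunable correlation to land-use diversity, a species pool
#' carrying four body traits, four beak traits, hand-wing index and two
#' categorical ecological traits, habitat affinities gating occupancy, and
#' contiguous biogeographic realms.
#'
#' @param grid_nx,grid_ny Number of analysis cells along each axis.
#' @param pixels_per_cell_side Fine-raster pixels per cell side (>= 1).
#' @param n_classes Number of land-cover classes (default 22).
#' @param n_species Species-pool size (>= 6).
#' @param n_realms Number of contiguous longitudinal realms.
#' @param effect_lu_diversity Ground-truth log-linear effect of per-cell
#'   Shannon land-use diversity on expected occupancy (and hence on expected
#'   richness, exactly so in a generalist-only world).
#' @param effect_npp Ground-truth log-linear effect of the productivity
#'   surface (NDVI scale, 0-1) on expected occupancy. The default (2) gives
#'   productivity an explanatory weight comparable to the land-use effect,
#'   since the NDVI scale is an order of magnitude narrower than the Shannon
#'   scale.
#' @param npp_lu_correlation Target Pearson correlation between the cell-level
#'   productivity surface and realized land-use Shannon diversity.
#' @param lu_shape Shape of the land-use-diversity response: \code{"linear"}
#'   (log-linear in H) or \code{"saturating"} (plateauing,
#'   \code{effect * 1.25 * (1 - exp(-2 H))}, which matches the linear slope at
#'   the origin but flattens above H ~ 1.5).
#' @param baseline_occupancy Occupancy probability of an affinity-matching
#'   species in a cell with H = 0 and average productivity.
#' @param allometric_correlation Correlation on the log scale between body
#'   mass and the other morphometric traits.
#' @param generalist_fraction Fraction of species with affinity for all
#'   land-cover classes; remaining species are specialists anchored on a
#'   dedicated class so every class has a specialist subpool.
#' @param patch_size Side (in pixels) of the square blocks used for
#'   spatially-blocked land-cover sampling within cells.
#' @param range_scale Standard deviation of the per-species range kernel,
#'   as a fraction of the domain size (toroidal distance).
#' @param clump_strength Mixing weight of the range kernel: occupancy is
#'   multiplied by \code{(1 - w) + w * kernel}, so 0 disables clumping.
#' @param seed Master seed; all stages draw from named substreams of it.
#' @return An object of class \code{world_config} (a validated list).
#' @examples
#' cfg <- world_config(grid_nx = 5, grid_ny = 5, n_species = 20, seed = 1)
#' @export
world_config <- function(grid_nx = 20, grid_ny = 20, pixels_per_cell_side = 8,
                         n_classes = 22, n_species = 500, n_realms = 6,
                         effect_lu_diversity = 0.5, effect_npp = 2,
                         npp_lu_correlation = 0.49,
                         lu_shape = c("linear", "saturating"),
                         baseline_occupancy = 0.05,
                         allometric_correlation = 0.7,
                         generalist_fraction = 0.2,
                         patch_size = 2, range_scale = 0.15,
                         clump_strength = 0.5, seed = 1) {
  lu_shape <- match.arg(lu_shape)
  cfg <- list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              pixels_per_cell_side = as.integer(pixels_per_cell_side),
              n_classes = as.integer(n_classes),
              n_species = as.integer(n_species),
              n_realms = as.integer(n_realms),
              effect_lu_diversity = effect_lu_diversity,
              effect_npp = effect_npp,
              npp_lu_correlation = npp_lu_correlation,
              lu_shape = lu_shape,
              baseline_occupancy = baseline_occupancy,
              allometric_correlation = allometric_correlation,
              generalist_fraction = generalist_fraction,
              patch_size = as.integer(patch_size),
              range_scale = range_scale, clump_strength = clump_strength,
              seed = as.integer(seed))
  if (cfg$pixels_per_cell_side < 1L) stop("pixels_per_cell_side must be >= 1")
  if (cfg$n_classes < 2L) stop("n_classes must be >= 2")
  if (cfg$n_species < 6L) stop("n_species must be >= 6")
  if (cfg$grid_nx < 1L || cfg$grid_ny < 1L) stop("grid dimensions must be >= 1")
  if (cfg$n_realms < 1L || cfg$n_realms > cfg$grid_nx)
    stop("n_realms must be between 1 and grid_nx")
  if (abs(cfg$npp_lu_correlation) > 1) stop("npp_lu_correlation must be in [-1, 1]")
  if (cfg$baseline_occupancy <= 0 || cfg$baseline_occupancy >= 1)
    stop("baseline_occupancy must be in (0, 1)")
  if (cfg$generalist_fraction < 0 || cfg$generalist_fraction > 1)
    stop("generalist_fraction must be in [0, 1]")
  class(cfg) <- "world_config"
  cfg
}

land_raster <- function(values, n_classes, pixels_per_cell_side,
                        grid_nx, grid_ny, nodata = 0L) {
  structure(list(values = values, n_classes = as.integer(n_classes),
                 nodata = as.integer(nodata),
                 pixels_per_cell_side = as.integer(pixels_per_cell_side),
                 grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny)),
            class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("<land_raster> %d x %d pixels (%d x %d cells, %d px/side), %d classes + nodata=%d\n",
              nrow(x$values), ncol(x$values), x$grid_ny, x$grid_nx,
              x$pixels_per_cell_side, x$n_classes, x$nodata))
  invisible(x)
}

# Pixel index ranges of a cell within the fine raster.
cell_pixel_rows <- function(row, p) ((row - 1L) * p + 1L):(row * p)
cell_pixel_cols <- function(col, p) ((col - 1L) * p + 1L):(col * p)

#' Generate a categorical land-cover raster
#'
#' Builds a fine-resolution categorical raster whose per-cell class mixtures
#' follow cell-specific Dirichlet weights with a log-uniform concentration
#' parameter, so realized per-cell Shannon diversity spans a wide gradient
#' (near-monodominant through near-uniform cells). Pixels are sampled in
#' square blocks of \code{patch_size} to give within-cell spatial structure.
#' A smooth sea mask converts the trailing pixels of low-land cells to the
#' no-data class so land fraction varies across cells.
#'
#' @param config A \code{\link{world_config}}.
#' @param force_classes Optional integer vector; when supplied, every cell is
#'   tiled deterministically with equal pixel counts of exactly these classes
#'   (no sea), which is convenient for constructing rasters with known
#'   entropy.
#' @return A \code{land_raster}: integer matrix (class 0 = sea/no-data) plus
#'   metadata.
#' @export
generate_landcover <- function(config, force_classes = NULL) {
  stopifnot(inherits(config, "world_config"))
  p <- config$pixels_per_cell_side
  ny <- config$grid_ny; nx <- config$grid_nx
  K <- config$n_classes
  vals <- matrix(0L, ny * p, nx * p)

  if (!is.null(force_classes)) {
    force_classes <- as.integer(force_classes)
    stopifnot(all(force_classes >= 1L), all(force_classes <= K))
    per_cell <- rep_len(force_classes, p * p)
    block <- matrix(sort(per_cell), p, p)
    for (r in seq_len(ny)) for (cc in seq_len(nx))
      vals[cell_pixel_rows(r, p), cell_pixel_cols(cc, p)] <- block
    return(land_raster(vals, K, p, nx, ny))
  }

  with_substream(config$seed, "landcover", {
    b <- min(config$patch_size, p)
    nb <- ceiling(p / b)  # blocks per cell side
    for (r in seq_len(ny)) {
      for (cc in seq_len(nx)) {
        conc <- 10^runif(1, -1.3, 1.6)  # log-uniform Dirichlet concentration
        w <- rgamma(K, shape = conc)
        if (all(w == 0)) w <- rep(1, K)
        w <- w / sum(w)
        blocks <- sample.int(K, nb * nb, replace = TRUE, prob = w)
        bm <- matrix(blocks, nb, nb)
        cellpix <- bm[rep(seq_len(nb), each = b)[seq_len(p)],
                      rep(seq_len(nb), each = b)[seq_len(p)], drop = FALSE]
        vals[cell_pixel_rows(r, p), cell_pixel_cols(cc, p)] <- cellpix
      }
    }
  })

  # Sea mask: smooth field -> per-cell land fraction, most cells fully land,
  # a tail of partial and (rarely) sub-10% cells; sea pixels fill the cell
  # block from the bottom so the land part stays contiguous.
  with_substream(config$seed, "sea", {
    gf <- gaussian_field(ny, nx, range = max(2, min(ny, nx) / 5))
    lf <- matrix(pmin(1, pmax(0, 1.15 + 0.55 * gf)), ny, nx)
    for (r in seq_len(ny)) {
      for (cc in seq_len(nx)) {
        n_sea <- round((1 - lf[r, cc]) * p * p)
        if (n_sea > 0) {
          idx_rows <- cell_pixel_rows(r, p)
          idx_cols <- cell_pixel_cols(cc, p)
          block <- vals[idx_rows, idx_cols, drop = FALSE]
          block[order(row(block), col(block), decreasing = TRUE)[seq_len(n_sea)]] <- 0L
          vals[idx_rows, idx_cols] <- block
        }
      }
    }
  })
  land_raster(vals, K, p, nx, ny)
}

#' Generate the productivity (NDVI) surface
#'
#' Cell-level productivity is a standardized mixture of realized land-use
#' Shannon diversity and an independent smooth Gaussian random field, with
#' the mixing weight equal to the target correlation, then mapped onto an
#' NDVI-like 0-1 scale by a linear (hence monotone, correlation-preserving)
#' transform. This makes land-use diversity's key confounder reproducible at
#' a configurable strength.
#'
#' @param landcover A \code{land_raster}.
#' @param config The \code{\link{world_config}} used to build it.
#' @return List with \code{cell} (grid_ny x grid_nx matrix, NDVI scale) and
#'   \code{raster} (fine-resolution replication with sea pixels set to NA).
#' @export
generate_npp <- function(landcover, config) {
  H <- cell_shannon_matrix(landcover)
  zH <- as.vector(H)
  ok <- is.finite(zH)
  zH[ok] <- (zH[ok] - mean(zH[ok])) / max(sd(zH[ok]), 1e-12)
  zH[!ok] <- 0
  with_substream(config$seed, "npp", {
    g <- gaussian_field(config$grid_ny, config$grid_nx,
                        range = max(2, min(config$grid_ny, config$grid_nx) / 6))
    # The field is generated independently of the land-cover process, so the
    # mixing weight equals the correlation in expectation; the realized
    # per-world correlation fluctuates with the field's effective sample size.
    w <- config$npp_lu_correlation
    z <- w * matrix(zH, config$grid_ny, config$grid_nx) + sqrt(max(0, 1 - w^2)) * g
    cellnpp <- matrix(pmin(0.99, pmax(0.01, 0.5 + 0.15 * z)),
                      config$grid_ny, config$grid_nx)
    p <- config$pixels_per_cell_side
    rast <- cellnpp[rep(seq_len(config$grid_ny), each = p),
                    rep(seq_len(config$grid_nx), each = p), drop = FALSE]
    rast[landcover$values == landcover$nodata] <- NA_real_
    list(cell = cellnpp, raster = rast)
  })
}

#' Generate independent environmental covariate surfaces
#'
#' Elevation, temperature, precipitation and human footprint as smooth random
#' fields on realistic scales, independent of the land-cover process (their
#' ground-truth effect on richness is zero, which is what the model-comparison
#' and jackknife null checks rely on).
#'
#' @inheritParams generate_npp
#' @return Named list of grid_ny x grid_nx matrices: \code{elevation} (m),
#'   \code{temperature} (deg C), \code{precipitation} (mm),
#'   \code{human_footprint} (0-50 index).
#' @export
generate_covariates <- function(landcover, config) {
  ny <- config$grid_ny; nx <- config$grid_nx
  with_substream(config$seed, "covariates", {
    rg <- max(2, min(ny, nx) / 6)
    lat <- matrix(rep(seq_len(ny), nx), ny, nx) / ny  # 0..1 north-south
    m <- function(x) matrix(x, ny, nx)
    list(
      elevation = m(pmax(0, 600 + 500 * gaussian_field(ny, nx, rg))),
      temperature = m(25 - 30 * abs(lat - 0.5) * 2 + 4 * gaussian_field(ny, nx, rg)),
      precipitation = m(pmax(0, 1200 + 700 * gaussian_field(ny, nx, rg))),
      human_footprint = m(pmin(50, pmax(0, 12 + 8 * gaussian_field(ny, nx, rg))))
    )
  })
}

trophic_levels <- c("Aquatic predator", "Invertivore", "Vertivore", "Scavenger",
                    "Omnivore", "Frugivore", "Granivore", "Nectarivore",
                    "Aquatic herbivore", "Terrestrial herbivore")
lifestyle_levels <- c("Aerial", "Terrestrial", "Insessorial", "Aquatic",
                      "Generalist")

#' Generate a synthetic species pool
#'
#' Morphometric traits are drawn log-normally with a configurable allometric
#' correlation to body mass; hand-wing index is drawn on its raw scale;
#' trophic niche (10 levels) and primary lifestyle (5 levels) are sampled with
#' non-degenerate frequencies. Habitat affinities give every land-cover class
#' a dedicated specialist subpool plus a generalist fraction with affinity for
#' all classes.
#'
#' @param config A \code{\link{world_config}}.
#' @return A data.frame with one row per species: \code{species_id}, the eight
#'   positive morphometrics (\code{body_mass} g, lengths in mm),
#'   \code{hand_wing_index}, factors \code{trophic_niche} and
#'   \code{primary_lifestyle}, logical \code{generalist} and list-column
#'   \code{habitat_affinity} (integer class sets).
#' @export
generate_species_pool <- function(config) {
  stopifnot(inherits(config, "world_config"))
  n <- config$n_species
  K <- config$n_classes
  rho <- config$allometric_correlation
  with_substream(config$seed, "pool", {
    z_size <- rnorm(n)
    allo <- function(mu, sigma) {
      10^(mu + sigma * (rho * z_size + sqrt(max(0, 1 - rho^2)) * rnorm(n)))
    }
    shape <- rnorm(n)  # beak-shape factor shared across beak traits
    beak <- function(mu, sigma, sh) {
      10^(mu + sigma * (rho * z_size + sh * shape +
                          sqrt(max(0, 1 - rho^2 - sh^2)) * rnorm(n)))
    }
    pool <- data.frame(
      species_id = sprintf("sp%04d", seq_len(n)),
      body_mass = 10^(1.5 + 0.6 * z_size),
      tarsus_length = allo(1.40, 0.30),
      wing_length = allo(2.05, 0.28),
      tail_length = allo(1.90, 0.30),
      beak_culmen = beak(1.30, 0.25, 0.45),
      beak_nares = beak(1.05, 0.25, 0.45),
      beak_width = beak(0.78, 0.22, -0.40),
      beak_depth = beak(0.82, 0.22, -0.40),
      hand_wing_index = pmax(0.5, rnorm(n, 25, 12)),
      trophic_niche = factor(
        sample(trophic_levels, n, replace = TRUE,
               prob = c(0.05, 0.30, 0.08, 0.02, 0.15, 0.12, 0.12, 0.05, 0.03, 0.08)),
        levels = trophic_levels),
      primary_lifestyle = factor(
        sample(lifestyle_levels, n, replace = TRUE,
               prob = c(0.10, 0.25, 0.40, 0.10, 0.15)),
        levels = lifestyle_levels),
      stringsAsFactors = FALSE
    )
    n_gen <- round(config$generalist_fraction * n)
    generalist <- rep(FALSE, n)
    if (n_gen > 0) generalist[sample.int(n, n_gen)] <- TRUE
    # Specialists: anchor class cycles through all classes so each class has
    # a dedicated subpool; a few extra classes widen some niches.
    anchors <- rep_len(sample.int(K), n)
    aff <- vector("list", n)
    for (i in seq_len(n)) {
      if (generalist[i]) {
        aff[[i]] <- seq_len(K)
      } else {
        extra <- sample.int(K, min(K - 1L, stats::rpois(1, 1)))
        aff[[i]] <- sort(unique(c(anchors[i], setdiff(extra, anchors[i]))))
      }
    }
    pool$generalist <- generalist
    pool$habitat_affinity <- I(aff)
    pool
  })
}

# Per-cell Shannon diversity of a land_raster as a grid_ny x grid_nx matrix
# (internal fast path used by the generator; the public zonal operation is
# shannon_landuse()).
cell_shannon_matrix <- function(landcover) {
  p <- landcover$pixels_per_cell_side
  H <- matrix(NA_real_, landcover$grid_ny, landcover$grid_nx)
  for (r in seq_len(landcover$grid_ny)) {
    for (cc in seq_len(landcover$grid_nx)) {
      px <- landcover$values[cell_pixel_rows(r, p), cell_pixel_cols(cc, p)]
      px <- px[px != landcover$nodata]
      if (length(px)) H[r, cc] <- shannon_entropy(tabulate(px, landcover$n_classes))
    }
  }
  H
}

lu_response_value <- function(H, config) {
  if (config$lu_shape == "saturating") {
    config$effect_lu_diversity * 1.25 * (1 - exp(-2 * H))
  } else {
    config$effect_lu_diversity * H
  }
}

#' Generate species occupancy over the synthetic grid
#'
#' A species can occupy a cell only if at least one of its affinity classes is
#' present there (habitat gating). Conditional on the gate, the occupancy
#' probability is log-linear in the cell's realized Shannon land-use diversity
#' and productivity,
#' \code{p = p0 * exp(f(H) + effect_npp * (npp - 0.5)) * clump}, capped at
#' 0.95, where \code{f} is linear or saturating per the config and
#' \code{clump} is a per-species toroidal Gaussian range kernel mixed with a
#' constant floor. Because the link is log-linear and the kernel is
#' stationary, \code{effect_lu_diversity} is exactly the slope of log expected
#' richness on H in a generalist-only world. The exact expected-richness
#' surface is returned alongside the realized draw for recovery tests.
#'
#' @param pool A species pool from \code{\link{generate_species_pool}}.
#' @param landcover A \code{land_raster} from \code{\link{generate_landcover}}.
#' @param config The shared \code{\link{world_config}}.
#' @param npp Optional output of \code{\link{generate_npp}}; regenerated from
#'   the config substream when missing.
#' @return An \code{occurrence_grid} (see \code{\link{occurrence_grid}}) whose
#'   \code{grid} carries realm labels and land fractions, with attribute
#'   \code{ground_truth}: data.frame of cell_id, landuse_shannon, npp and
#'   expected_richness.
#' @export
generate_occupancy <- function(pool, landcover, config, npp = NULL) {
  stopifnot(inherits(landcover, "land_raster"), inherits(config, "world_config"))
  if (any(lengths(pool$habitat_affinity) == 0L))
    stop("species with empty habitat affinity set: ",
         paste(pool$species_id[lengths(pool$habitat_affinity) == 0L], collapse = ", "))
  if (is.null(npp)) npp <- generate_npp(landcover, config)

  grid <- grid_from_landcover(landcover, config)
  ny <- config$grid_ny; nx <- config$grid_nx; p <- landcover$pixels_per_cell_side
  n_cells <- nrow(grid)
  n_sp <- nrow(pool)
  H <- as.vector(t(cell_shannon_matrix(landcover)))       # cell order: row-major
  npp_cell <- as.vector(t(npp$cell))

  # classes present per cell (gate)
  present <- matrix(FALSE, n_cells, config$n_classes)
  ci <- 0L
  for (r in seq_len(ny)) {
    for (cc in seq_len(nx)) {
      ci <- ci + 1L
      px <- landcover$values[cell_pixel_rows(r, p), cell_pixel_cols(cc, p)]
      px <- px[px != landcover$nodata]
      if (length(px)) present[ci, sort(unique(px))] <- TRUE
    }
  }

  base <- ifelse(is.finite(H), exp(lu_response_value(ifelse(is.finite(H), H, 0), config) +
                                     config$effect_npp * (npp_cell - 0.5)), 0)
  base[!is.finite(H)] <- 0  # cells with no land pixels host nobody

  with_substream(config$seed, "occupancy", {
    # species range centers, toroidal Gaussian kernel over cell centers
    cx <- grid$center_lon / nx; cy <- grid$center_lat / ny  # scaled to [0,1]
    ux <- runif(n_sp); uy <- runif(n_sp)
    sigma <- config$range_scale
    w <- config$clump_strength
    presence <- matrix(0L, n_cells, n_sp,
                       dimnames = list(grid$cell_id, pool$species_id))
    expected <- numeric(n_cells)
    for (s in seq_len(n_sp)) {
      dx <- abs(cx - ux[s]); dx <- pmin(dx, 1 - dx)
      dy <- abs(cy - uy[s]); dy <- pmin(dy, 1 - dy)
      kern <- (1 - w) + w * exp(-(dx^2 + dy^2) / (2 * sigma^2))
      gate <- rowSums(present[, pool$habitat_affinity[[s]], drop = FALSE]) > 0
      ps <- pmin(0.95, config$baseline_occupancy * base * kern) * gate
      expected <- expected + ps
      presence[, s] <- rbinom(n_cells, 1L, ps)
    }
    occ <- occurrence_grid(presence, grid, pool$species_id)
    attr(occ, "ground_truth") <- data.frame(
      cell_id = grid$cell_id, landuse_shannon = H, npp = npp_cell,
      expected_richness = expected)
    occ
  })
}

# Planar analysis grid implied by a synthetic land raster: unit cells, realm
# labels as contiguous longitudinal blocks.
grid_from_landcover <- function(landcover, config) {
  ny <- landcover$grid_ny; nx <- landcover$grid_nx
  p <- landcover$pixels_per_cell_side
  rows <- rep(seq_len(ny), each = nx)
  cols <- rep(seq_len(nx), times = ny)
  lf <- numeric(ny * nx)
  ci <- 0L
  for (r in seq_len(ny)) {
    for (cc in seq_len(nx)) {
      ci <- ci + 1L
      px <- landcover$values[cell_pixel_rows(r, p), cell_pixel_cols(cc, p)]
      lf[ci] <- mean(px != landcover$nodata)
    }
  }
  realm_of <- cut(cols, breaks = seq(0.5, nx + 0.5, length.out = config$n_realms + 1),
                  labels = paste0("realm", seq_len(config$n_realms)))
  data.frame(cell_id = seq_len(ny * nx), row = rows, col = cols,
             center_lon = cols - 0.5, center_lat = rows - 0.5,
             area = 1, land_fraction = lf,
             realm = as.character(realm_of), stringsAsFactors = FALSE)
}

#' Generate a complete synthetic world
#'
#' Orchestrates \code{\link{generate_landcover}}, \code{\link{generate_npp}},
#' \code{\link{generate_covariates}}, \code{\link{generate_species_pool}} and
#' \code{\link{generate_occupancy}} from one config. Identical configs give
#' bit-identical worlds.
#'
#' @param config A \code{\link{world_config}}.
#' @return A list of class \code{synthetic_world} with elements \code{config},
#'   \code{landcover}, \code{npp}, \code{covariates}, \code{pool},
#'   \code{occurrence} and \code{ground_truth}.
#' @examples
#' w <- generate_world(world_config(grid_nx = 6, grid_ny = 6, n_species = 40,
#'                                  pixels_per_cell_side = 4, seed = 2))
#' head(attr(w$occurrence, "ground_truth"))
#' @export
generate_world <- function(config = world_config()) {
  landcover <- generate_landcover(config)
  npp <- generate_npp(landcover, config)
  covariates <- generate_covariates(landcover, config)
  pool <- generate_species_pool(config)
  occurrence <- generate_occupancy(pool, landcover, config, npp)
  structure(list(config = config, landcover = landcover, npp = npp,
                 covariates = covariates, pool = pool, occurrence = occurrence,
                 ground_truth = attr(occurrence, "ground_truth")),
            class = "synthetic_world")
}

#' Write a synthetic world to disk
#'
#' Persists every stage as plain text: rasters as TSV matrices, species pool
#' and long-format occupancy as CSV, ground truth as CSV and the config as
#' YAML.
#'
#' @param world A \code{synthetic_world}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    landcover = file.path(dir, "landcover.tsv"),
    npp = file.path(dir, "npp_cell.tsv"),
    pool = file.path(dir, "species_pool.csv"),
    occupancy = file.path(dir, "occupancy.csv"),
    grid = file.path(dir, "grid.csv"),
    truth = file.path(dir, "ground_truth.csv"),
    config = file.path(dir, "config.yaml"))
  write.table(world$landcover$values, paths["landcover"], sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(world$npp$cell, paths["npp"], sep = "\t",
              row.names = FALSE, col.names = FALSE)
  pool_out <- world$pool
  pool_out$habitat_affinity <- vapply(pool_out$habitat_affinity,
                                      paste, character(1), collapse = ";")
  write.csv(pool_out, paths["pool"], row.names = FALSE)
  idx <- which(world$occurrence$presence == 1L, arr.ind = TRUE)
  write.csv(data.frame(cell_id = world$occurrence$grid$cell_id[idx[, 1]],
                       species_id = world$occurrence$species[idx[, 2]]),
            paths["occupancy"], row.names = FALSE)
  write.csv(world$occurrence$grid, paths["grid"], row.names = FALSE)
  write.csv(world$ground_truth, paths["truth"], row.names = FALSE)
  cfg <- unclass(world$config)
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}
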