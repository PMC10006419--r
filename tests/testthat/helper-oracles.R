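# Shared fixtures and independent oracles for the test suite.

tiny_config <- function(...) {
  args <- list(grid_nx = 6, grid_ny = 6, pixels_per_cell_side = 4,
               n_species = 60, n_realms = 2, seed = 42)
  args[names(list(...))] <- list(...)
  do.call(world_config, args)
}

# Exact combinatorial hull-volume oracle for small point sets in general
# position: a d-subset is a facet iff all remaining points fall strictly on
# one side of its hyperplane; the volume is the fan of facet simplices around
# the centroid. Independent of the incremental construction used in src/.
brute_hull_volume <- function(P) {
  n <- nrow(P); d <- ncol(P)
  stopifnot(n >= d + 1)
  ctr <- colMeans(P)
  vol <- 0
  for (idx in utils::combn(n, d, simplify = FALSE)) {
    V <- P[idx, , drop = FALSE]
    A <- sweep(V[-1, , drop = FALSE], 2, V[1, ])
    # facet normal = null space of the spanning vectors (QR)
    qrA <- qr(t(A))
    if (qrA$rank < d - 1) next
    nrm <- qr.Q(qrA, complete = TRUE)[, d, drop = TRUE]
    s <- drop((P[-idx, , drop = FALSE] %*% nrm) - drop(V[1, ] %*% nrm))
    if (all(s > 1e-10) || all(s < -1e-10)) {
      M <- sweep(V, 2, ctr)
      vol <- vol + abs(det(M)) / factorial(d)
    }
  }
  vol
}

# qhull (via the pre-installed Python/scipy stack) as a fully independent
# reference for hull volumes, plus a Monte-Carlo rejection estimator whose
# membership test uses scipy's Delaunay triangulation.
python_available <- local({
  ok <- NULL
  function() {
    if (is.null(ok)) {
      ok <<- nzchar(Sys.which("python")) &&
        suppressWarnings(system2("python", c("-c", "'import scipy.spatial'"),
                                 stdout = FALSE, stderr = FALSE)) == 0
    }
    ok
  }
})

qhull_volume <- function(P) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  write.table(P, f, row.names = FALSE, col.names = FALSE)
  out <- system2("python", c("-c", shQuote(sprintf(
    "import numpy as np, scipy.spatial as s; print(float(s.ConvexHull(np.loadtxt('%s')).volume))",
    f))), stdout = TRUE)
  as.numeric(out[length(out)])
}

mc_hull_volume <- function(P, n_samples = 1e6, seed = 1) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  write.table(P, f, row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np, scipy.spatial as s; ",
    "rng=np.random.default_rng(%d); P=np.loadtxt('%s'); ",
    "tri=s.Delaunay(P); lo=P.min(0); hi=P.max(0); ",
    "X=rng.uniform(lo,hi,size=(%d,P.shape[1])); ",
    "inside=(tri.find_simplex(X)>=0).mean(); ",
    "print(float(inside*np.prod(hi-lo)))"), seed, f, as.integer(n_samples))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  as.numeric(out[length(out)])
}

# Fine-lattice point-sampling oracle for polygon/cell overlap.
lattice_overlap <- function(poly, rect, n = 80) {
  xs <- seq(rect[1], rect[2], length.out = n)
  ys <- seq(rect[3], rect[4], length.out = n)
  for (x in xs) for (y in ys) {
    if (aviland:::point_in_polygon(x, y, poly)) return(TRUE)
  }
  FALSE
}

# Simple random convex polygon around a center.
random_convex_poly <- function(center, radius, n = 8) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.3 * radius, radius)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# Build a metrics-like table directly (cheap substitute for a full world when
# only the model layer is exercised).
fake_metrics <- function(n = 400, seed = 1, beta_lu = 0.5, beta_npp = 1,
                         noise = 0.1, realms = 2) {
  set.seed(seed)
  d <- data.frame(
    cell_id = seq_len(n),
    center_lon = runif(n, 0, 20), center_lat = runif(n, 0, 20),
    realm = paste0("realm", rep_len(seq_len(realms), n)),
    landuse_shannon = runif(n, 0, 2.5),
    npp = runif(n, 0.1, 0.9),
    median_elevation = runif(n, 0, 2000))
  eta <- beta_lu * d$landuse_shannon + beta_npp * d$npp +
    rnorm(n, 0, noise)
  d$taxonomic_std <- exp(eta - max(eta))
  d$taxonomic_richness <- pmax(6L, as.integer(round(50 * d$taxonomic_std + 6)))
  d$median_range_size <- exp(0.2 * d$npp + rnorm(n, 3, noise))
  d
}
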