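test_that("taxonomic richness counts distinct species", {
  g <- build_grid(c(0, 3, 0, 1), 1)
  pres <- rbind(c(1, 1, 1, 1, 1, 1, 0),
                c(0, 0, 0, 0, 0, 0, 0),
                c(1, 0, 1, 0, 1, 0, 1))
  occ <- occurrence_grid(pres, g, paste0("s", 1:7))
  expect_equal(unname(taxonomic_richness(occ)), c(6L, 0L, 4L))
  # brute-force oracle on random sparse matrices
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(rbinom(60, 1, 0.3), 3, 20)
    occ2 <- occurrence_grid(m, g, paste0("t", 1:20))
    expect_equal(unname(taxonomic_richness(occ2)),
                 vapply(1:3, function(i) sum(m[i, ] > 0), integer(1)))
  }
})

test_that("hull volumes match closed forms", {
  simplex <- rbind(rep(0, 5), diag(5))
  expect_equal(convhull_volume(simplex), 1 / 120, tolerance = 1e-12)
  cube <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  expect_equal(convhull_volume(cube), 1, tolerance = 1e-10)
  # interior points must not change the volume
  set.seed(10)
  withint <- rbind(cube, matrix(runif(50), 10, 5))
  expect_equal(convhull_volume(withint), 1, tolerance = 1e-10)
  # degenerate clouds are NA
  expect_true(is.na(convhull_volume(cbind(matrix(rnorm(40), 10, 4), 1))))
  expect_true(is.na(convhull_volume(matrix(rnorm(20), 4, 5))))
})

test_that("hull volumes match the exact combinatorial oracle on small clouds", {
  set.seed(11)
  for (rep in 1:6) {
    P <- matrix(rnorm(12 * 5), 12, 5)
    expect_equal(convhull_volume(P), brute_hull_volume(P), tolerance = 1e-9)
  }
  # and in lower dimensions
  for (rep in 1:4) {
    P <- matrix(rnorm(10 * 3), 10, 3)
    expect_equal(convhull_volume(P), brute_hull_volume(P), tolerance = 1e-9)
  }
})

test_that("hull volume is monotone under species addition and equivariant", {
  set.seed(12)
  P <- matrix(rnorm(20 * 5), 20, 5)
  v20 <- convhull_volume(P)
  for (rep in 1:10) {
    sub <- P[sample(20, 12), ]
    expect_lte(convhull_volume(sub), v20 + 1e-12)
    expect_lte(convhull_volume(sub),
               convhull_volume(rbind(sub, rnorm(5))) + 1e-12)
  }
  # translation and rotation invariance
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(convhull_volume(sweep(P %*% Q, 2, c(1, -2, 3, 0, 7), "+")),
               v20, tolerance = 1e-9)
  # diagonal scaling multiplies volume by |det|
  dscale <- c(2, 0.5, 3, 1, 0.25)
  expect_equal(convhull_volume(sweep(P, 2, dscale, "*")),
               v20 * prod(dscale), tolerance = 1e-9)
})

test_that("per-cell functional richness flags degenerate assemblages", {
  set.seed(13)
  n_sp <- 30
  coords <- matrix(rnorm(n_sp * 5), n_sp, 5,
                   dimnames = list(sprintf("sp%02d", 1:n_sp), NULL))
  space <- structure(list(coordinates = coords,
                          eigenvalues = rep(1, 5),
                          variance_explained = rep(0.2, 5),
                          negative_eigenvalues = numeric(0)),
                     class = "functional_space")
  g <- build_grid(c(0, 3, 0, 1), 1)
  pres <- matrix(0L, 3, n_sp)
  pres[1, 1:15] <- 1L
  pres[2, 1:6] <- 1L   # 6 points: simplex-like, generically non-degenerate
  pres[3, 1:10] <- 1L
  occ <- occurrence_grid(pres, g, rownames(coords))
  fr <- functional_richness(occ, space)
  expect_true(all(fr > 0))
  expect_gte(fr[1], fr[3])  # superset of species

  # a cell whose species are coplanar in the 5-D space
  coords[7:12, 5] <- coords[7:12, 1]  # 6 species on a hyperplane
  space$coordinates <- coords
  pres2 <- matrix(0L, 3, n_sp)
  pres2[1, 1:15] <- 1L
  pres2[2, 7:12] <- 1L
  pres2[3, 1:10] <- 1L
  occ2 <- occurrence_grid(pres2, g, rownames(coords))
  fr2 <- functional_richness(occ2, space)
  expect_true(is.na(fr2[2]))
  expect_equal(attr(fr2, "degenerate"), occ2$grid$cell_id[2])

  pres3 <- pres2; pres3[2, ] <- 0L; pres3[2, 1:5] <- 1L
  occ3 <- occurrence_grid(pres3, g, rownames(coords))
  expect_error(functional_richness(occ3, space), "minimum richness")
})

test_that("standardization to the maximum preserves ranks and handles NA", {
  expect_equal(standardize_to_max(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(standardize_to_max(c(3, 3, 3)), c(1, 1, 1))
  x <- c(2, NA, 8)
  expect_equal(standardize_to_max(x), c(0.25, NA, 1))
  set.seed(14)
  v <- rexp(50)
  expect_equal(rank(standardize_to_max(v)), rank(v))
  expect_error(standardize_to_max(numeric(0)), "empty")
  expect_error(standardize_to_max(c(-1, -2)), "positive")
  # per-realm scope: each realm hits 1 at its own maximum
  s <- standardize_to_max(c(1, 2, 10, 5), scope = "per_realm",
                          realm = c("a", "a", "b", "b"))
  expect_equal(s, c(0.5, 1, 1, 0.5))
})

test_that("median range size uses the unfiltered grid and matches brute force", {
  g <- build_grid(c(0, 3, 0, 1), 1)
  pres <- rbind(c(1, 1, 1), c(0, 1, 1), c(0, 0, 1))
  occ <- occurrence_grid(pres, g, c("narrow", "mid", "wide"))
  mrs <- median_range_size(occ, use_area = FALSE)
  expect_equal(unname(mrs), c(2, 2.5, 3))  # medians of {1,2,3},{2,3},{3}
  # species of ranges {2, 10, 100} -> 10 in a cell holding all three
  g1 <- build_grid(c(0, 100, 0, 1), 1)
  pres1 <- matrix(0L, 100, 3)
  pres1[1:2, 1] <- 1L; pres1[1:10, 2] <- 1L; pres1[1:100, 3] <- 1L
  occ1 <- occurrence_grid(pres1, g1, c("r2", "r10", "r100"))
  expect_equal(unname(median_range_size(occ1, cells = 1, use_area = FALSE)), 10)
  # empty cell is NA
  pres[1, ] <- c(1, 1, 1); pres[3, ] <- 0
  occ2 <- occurrence_grid(pres, g, c("a", "b", "c"))
  expect_true(is.na(median_range_size(occ2, use_area = FALSE)[3]))
  # random occupancy vs direct counting
  set.seed(15)
  m <- matrix(rbinom(300, 1, 0.4), 3, 100)
  occ3 <- occurrence_grid(m, g, paste0("s", 1:100))
  ranges <- colSums(m)
  expect_equal(unname(median_range_size(occ3, use_area = FALSE)),
               vapply(1:3, function(i) median(ranges[m[i, ] > 0]), numeric(1)))
})

test_that("cell_metrics assembles a coherent analysis table", {
  w <- generate_world(tiny_config(n_species = 120))
  occ <- filter_cells(w$occurrence)
  traits <- build_trait_table(w$pool)
  space <- pcoa(gower_distance(traits), k_axes = 5)
  m <- cell_metrics(occ, w$landcover, w$npp, covariates = w$covariates,
                    space = space, occ_global = w$occurrence)
  expect_equal(nrow(m), nrow(occ$grid))
  expect_true(all(m$taxonomic_richness >= 6))
  expect_equal(max(m$taxonomic_std), 1)
  expect_true(all(m$functional_std <= 1, na.rm = TRUE))
  expect_true(all(is.finite(m$landuse_shannon)))
  expect_true(all(c("median_elevation", "median_temperature",
                    "median_precipitation", "median_human_footprint")
                  %in% names(m)))
})
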