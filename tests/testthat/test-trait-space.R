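test_that("body PCA handles rank-1 and independent-trait regimes", {
  # perfectly collinear log-traits: one axis carries everything
  m <- 10^rnorm(50, 1.5, 0.4)
  p <- pca_body(m, m^0.8, m^1.1, m^0.9)
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-10)
  # sign convention: mass loads positively on axis 1
  expect_gt(p$loadings["body_mass", 1], 0)
  expect_gt(cor(p$scores[, "PCA1m"], log10(m)), 0.99)

  # independent columns: each axis ~ 1/4 of the variance
  set.seed(1)
  n <- 10000
  q <- pca_body(10^rnorm(n), 10^rnorm(n), 10^rnorm(n), 10^rnorm(n))
  expect_true(all(abs(q$variance_explained - 0.25) < 0.02))

  expect_error(pca_body(c(1, -1, 2), 1:3, 1:3, 1:3), "non-positive")
})

test_that("beak size-correction residuals are orthogonal to mass", {
  set.seed(2)
  n <- 300
  lm_mass <- rnorm(n, 1.5, 0.5)
  # proportional trait -> zero residuals
  prop <- cbind(2 * lm_mass + 1)
  expect_equal(max(abs(size_correct_beak(prop, lm_mass))), 0, tolerance = 1e-10)
  # mass-independent trait -> centered trait
  ind <- cbind(rnorm(n))
  r <- size_correct_beak(ind, rep(c(1, 2), length.out = n))
  fit <- lm(ind[, 1] ~ rep(c(1, 2), length.out = n))
  expect_equal(as.vector(r), unname(stats::residuals(fit)), tolerance = 1e-10)
  # allometric data: exact OLS orthogonality
  beak <- cbind(0.3 * lm_mass + rnorm(n, 0, 0.1),
                0.5 * lm_mass + rnorm(n, 0, 0.2))
  res <- size_correct_beak(beak, lm_mass)
  expect_lt(max(abs(cor(res, lm_mass))), 1e-10)
  expect_error(size_correct_beak(beak, rep(1, n)), "zero variance")
})

test_that("beak PCA matches closed-form block structure", {
  set.seed(3)
  # identical columns: first axis carries all variance
  x <- rnorm(100)
  p1 <- pca_beak(cbind(x, x, x, x))
  expect_equal(p1$variance_explained[1], 1, tolerance = 1e-12)
  # two independent blocks of two collinear columns: correlation matrix has
  # eigenvalues (2, 2, 0, 0), so the first axis holds exactly half
  a <- rnorm(200)
  b <- unname(stats::residuals(lm(rnorm(200) ~ a)))  # exactly orthogonal to a
  p2 <- pca_beak(cbind(a, a, b, b))
  expect_equal(p2$variance_explained[1], 0.5, tolerance = 1e-10)
  expect_error(pca_beak(cbind(a, rep(1, 200), b, a)), "constant")
})

test_that("Gower distance matches hand arithmetic and the daisy oracle", {
  # canonical 3-species toy: equal weights, extremes on two quantitative
  # variables plus one categorical mismatch -> d(1,3) = (1 + 1 + 1)/3
  tt <- data.frame(q1 = c(0, 5, 10), q2 = c(0, 1, 2),
                   c1 = factor(c("u", "u", "v")))
  D <- gower_distance(tt, weights = c(1, 1, 1))
  expect_equal(D[1, 3], 1)
  # and diluted over six equally-weighted variables on which species 1 and 3
  # agree elsewhere, the same mismatches give (1/6)(1) + (1/6)(1) + (1/6)(1)
  D6 <- gower_distance(data.frame(q1 = c(0, 5, 10), q2 = c(0, 1, 2),
                                  q3 = c(0, 0.5, 0), q4 = c(2, 2.5, 2),
                                  c1 = factor(c("u", "u", "v")),
                                  c2 = factor(c("w", "x", "w"))))
  expect_equal(D6[1, 3], 0.5)
  # identical species at distance 0; range bounds hold
  expect_equal(diag(D6), setNames(rep(0, 3), rownames(D6)))
  expect_true(all(D6 >= 0 & D6 <= 1))
  expect_equal(D6, t(D6))

  # maximal distance: opposite extremes everywhere + categorical mismatches
  two <- data.frame(q1 = c(0, 1), q2 = c(-3, 4), q3 = c(10, 20), q4 = c(0, 5),
                    c1 = factor(c("a", "b")), c2 = factor(c("x", "y")))
  expect_equal(gower_distance(two)[1, 2], 1)

  skip_if_not_installed("cluster")
  set.seed(4)
  n <- 40
  tab <- data.frame(a = rnorm(n), b = runif(n), c = rnorm(n, 5),
                    d = rexp(n),
                    e = factor(sample(letters[1:4], n, TRUE)),
                    f = factor(sample(LETTERS[1:3], n, TRUE)))
  mine <- gower_distance(tab)
  ref <- as.matrix(cluster::daisy(tab, metric = "gower"))
  expect_equal(unname(mine[lower.tri(mine)]), unname(ref[lower.tri(ref)]),
               tolerance = 1e-12)
})

test_that("Gower distance is invariant to affine rescaling of quantitative traits", {
  set.seed(5)
  for (rep in 1:5) {
    tab <- data.frame(a = rnorm(20), b = rexp(20),
                      e = factor(sample(c("x", "y"), 20, TRUE)))
    scaled <- tab
    scaled$a <- 3.7 * tab$a - 11
    scaled$b <- 0.01 * tab$b + 2
    expect_equal(gower_distance(tab), gower_distance(scaled), tolerance = 1e-12)
  }
  expect_error(gower_distance(data.frame(a = c(1, 1, 1), b = 1:3)), "zero range")
})

test_that("trait contributions decompose the mean Gower distance exactly", {
  set.seed(6)
  tab <- data.frame(a = rnorm(30), b = runif(30),
                    e = factor(sample(c("x", "y", "z"), 30, TRUE)))
  tc <- trait_contributions(tab)
  expect_equal(sum(tc$contribution), 1, tolerance = 1e-9)
  expect_true(all(tc$contribution >= 0))
  # invariance to species reordering
  perm <- sample(30)
  tc2 <- trait_contributions(tab[perm, ])
  expect_equal(tc$contribution, tc2$contribution, tolerance = 1e-12)
  # single variable with full weight
  one <- trait_contributions(tab, weights = c(1, 0, 0))
  expect_equal(one$contribution, c(1, 0, 0), tolerance = 1e-12)
  # duplicated variable with equal weights splits evenly
  dup <- data.frame(a = tab$a, b = tab$a)
  expect_equal(trait_contributions(dup)$contribution, c(0.5, 0.5),
               tolerance = 1e-12)
  expect_error(trait_contributions(tab[1, , drop = FALSE]), "at least 2")
})

test_that("PCoA reproduces Euclidean geometry and closed-form cases", {
  set.seed(7)
  # exactness for Euclidean input
  X <- matrix(rnorm(50), 10, 5)
  D <- as.matrix(dist(X))
  fs <- pcoa(D, k_axes = 5)
  D2 <- as.matrix(dist(fs$coordinates))
  expect_lt(max(abs(D - D2)), 1e-8)
  expect_lt(max(abs(colMeans(fs$coordinates))), 1e-8)  # centered
  expect_true(all(diff(fs$eigenvalues) <= 1e-8))       # decreasing

  # points on a line: a single positive eigenvalue
  line <- as.matrix(dist(cbind(c(0, 1, 2, 4))))
  expect_error(pcoa(line, k_axes = 2), "positive eigenvalues")
  f1 <- pcoa(line, k_axes = 1)
  expect_equal(f1$variance_explained[1], 1, tolerance = 1e-9)

  # equilateral triangle, side 1: double-centering gives B = J/2, hence two
  # equal positive eigenvalues (0.5) and a zero
  tri <- matrix(1, 3, 3) - diag(3)
  ft <- pcoa(tri, k_axes = 2)
  expect_equal(ft$eigenvalues[1], ft$eigenvalues[2], tolerance = 1e-10)
  expect_equal(ft$variance_explained, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(as.matrix(dist(ft$coordinates))[1, 2], 1, tolerance = 1e-10)
})

test_that("PCoA agrees with the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(8)
  tab <- data.frame(a = rnorm(25), b = runif(25), cc = rexp(25),
                    e = factor(sample(c("x", "y", "z"), 25, TRUE)),
                    f = factor(sample(c("p", "q"), 25, TRUE)))
  D <- gower_distance(tab)
  mine <- pcoa(D, k_axes = 5)
  ref <- ape::pcoa(as.dist(D))
  expect_equal(head(mine$eigenvalues, 5), ref$values$Eigenvalues[1:5],
               tolerance = 1e-8)
  for (a in 1:5)
    expect_equal(abs(mine$coordinates[, a]), abs(ref$vectors[, a]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the assembled trait table carries the six variables and PCA shares", {
  pool <- generate_species_pool(tiny_config(n_species = 300))
  tt <- build_trait_table(pool)
  expect_named(tt, c("PCA1m", "PCA2m", "PCA1b", "HWI", "trophic_niche",
                     "primary_lifestyle"))
  expect_false(anyNA(tt))
  expect_equal(rownames(tt), pool$species_id)
  # allometric pools concentrate body variance on the size axis
  expect_gt(sum(attr(tt, "body_pca")[1:2]), 0.7)
  # HWI enters raw
  expect_equal(tt$HWI, pool$hand_wing_index)
  # categorical removal leaves distances strongly rank-correlated
  Dfull <- gower_distance(tt)
  Dquant <- gower_distance(tt[, 1:4])
  ut <- upper.tri(Dfull)
  expect_gt(cor(Dfull[ut], Dquant[ut], method = "spearman"), 0.4)
})
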