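test_that("additive fits recover a noiseless linear signal exactly", {
  d <- fake_metrics(n = 300, seed = 20, beta_lu = 0.8, beta_npp = 0, noise = 0)
  fit <- fit_additive(d, "taxonomic_std", c("landuse_shannon"))
  expect_gt(fit$deviance_explained, 0.999)
  pe <- partial_effect(fit, "landuse_shannon")$curve
  slope <- coef(lm(fit ~ x, data = pe))["x"]
  expect_equal(unname(slope), 0.8, tolerance = 0.01)
  # truth inside the confidence band
  centred <- 0.8 * (pe$x - mean(d$landuse_shannon))
  expect_true(all(pe$ci_low - 1e-6 <= centred & centred <= pe$ci_high + 1e-6))
})

test_that("shrinkage smooths collapse on pure-noise responses", {
  dev <- vapply(1:15, function(s) {
    d <- fake_metrics(n = 500, seed = 100 + s, beta_lu = 0, beta_npp = 0,
                      noise = 0.3)
    fit_additive(d, "taxonomic_std",
                 c("landuse_shannon", "npp", "median_elevation"))$deviance_explained
  }, numeric(1))
  expect_lt(quantile(dev, 0.95), 0.05)
})

test_that("log transform demands positive responses and k >= 3", {
  d <- fake_metrics(n = 50, seed = 21)
  d$taxonomic_std[3] <- 0
  expect_error(fit_additive(d, "taxonomic_std", "landuse_shannon"),
               "non-positive response")
  expect_error(fit_additive(d, "taxonomic_std", "landuse_shannon", k = 2),
               "k must be >= 3")
})

test_that("the model suite is ordered, labelled and monotone in deviance", {
  w <- generate_world(world_config(grid_nx = 12, grid_ny = 12, n_species = 250,
                                   seed = 22))
  occ <- filter_cells(w$occurrence)
  m <- cell_metrics(occ, w$landcover, w$npp, covariates = w$covariates)
  tab <- fit_model_suite(m, "taxonomic")
  expect_equal(tab$model_code, paste0("Mod_T", 1:5))
  expect_equal(tab$variables[4], "Latitude + Longitude + NPP + Land-use diversity")
  expect_equal(min(tab$delta_aic), 0)
  # nested monotonicity along models 1 -> 4
  expect_true(all(diff(tab$deviance_explained[c(1, 2, 4)]) >= -1e-9))
  expect_true(all(diff(tab$deviance_explained[c(1, 3, 4)]) >= -1e-9))
})

test_that("realm-wise fits recover contrasting per-realm effects", {
  set.seed(23)
  n <- 600
  d <- fake_metrics(n = n, seed = 23, beta_lu = 0, beta_npp = 0, noise = 0.08)
  d$realm <- rep(c("pos", "null"), each = n / 2)
  eta <- ifelse(d$realm == "pos", 1 * d$landuse_shannon, 0) +
    rnorm(n, 0, 0.08)
  d$taxonomic_std <- exp(eta - max(eta))
  rw <- fit_realmwise(d, "taxonomic", min_cells = 30)
  pos <- rw$effects[rw$effects$realm == "pos", ]
  null <- rw$effects[rw$effects$realm == "null", ]
  expect_gt(cor(pos$x, pos$fit), 0.99)          # increasing effect
  expect_gt(max(pos$fit) - min(pos$fit), 1.5)
  expect_true(all(null$ci_low <= 0 & 0 <= null$ci_high))  # flat, CI covers 0
  # label permutation restoring the same grouping leaves fits unchanged
  d2 <- d[order(d$realm, decreasing = TRUE), ]
  rw2 <- fit_realmwise(d2, "taxonomic", min_cells = 30)
  expect_equal(rw$effects$fit, rw2$effects$fit, tolerance = 1e-6)
  # realms below the floor are skipped and logged
  d3 <- rbind(d, within(d[1:5, ], realm <- "tiny"))
  rw3 <- fit_realmwise(d3, "taxonomic", min_cells = 30)
  expect_equal(rw3$skipped_realms, "tiny")
})

test_that("npp control leaves the land-use effect intact when npp is orthogonal", {
  d <- fake_metrics(n = 500, seed = 24, beta_lu = 0.8, beta_npp = 0,
                    noise = 0.1, realms = 1)
  rw0 <- fit_realmwise(d, "taxonomic", control_npp = FALSE)
  rw1 <- fit_realmwise(d, "taxonomic", control_npp = TRUE)
  # curves agree within the union of their CIs on a common grid
  agree <- mean(rw0$effects$fit >= rw1$effects$ci_low - 0.05 &
                  rw0$effects$fit <= rw1$effects$ci_high + 0.05)
  expect_gt(agree, 0.95)
})

test_that("jackknife importance isolates signal from noise variables", {
  d <- fake_metrics(n = 500, seed = 25, beta_lu = 1, beta_npp = 0, noise = 0.1)
  jk <- jackknife_importance(d, "taxonomic_std",
                             c("landuse_shannon", "npp", "median_elevation"))
  expect_equal(jk$variable[1], "landuse_shannon")
  # removing pure-noise variables barely moves deviance explained
  expect_lt(max(jk$importance[jk$variable != "landuse_shannon"]), 0.01)
  # near-duplicate predictors mask each other
  d$lu_copy <- d$landuse_shannon + rnorm(500, 0, 0.01)
  jk2 <- jackknife_importance(d, "taxonomic_std",
                              c("landuse_shannon", "lu_copy"))
  expect_lt(max(jk2$importance), 0.02)
})

test_that("partial slopes are exact on noiseless data and shift-invariant", {
  set.seed(26)
  n <- 200
  d <- data.frame(cell_id = 1:n, center_lon = runif(n), center_lat = runif(n),
                  realm = "palearctic-like", landuse_shannon = runif(n, 0, 2),
                  npp = runif(n))
  # noiseless construction with the target slope built in
  d$taxonomic_std <- exp(1.908 * d$landuse_shannon + 0.4 * d$center_lon -
                           0.2 * d$center_lat + 1.1 * d$npp - 6)
  ps <- partial_slopes(d, responses = "taxonomic")
  expect_equal(ps$beta, 1.908, tolerance = 1e-9)
  expect_true(ps$significant)
  # multiplying the response by a constant shifts the intercept only
  d2 <- d
  d2$taxonomic_std <- d$taxonomic_std * 5
  expect_equal(partial_slopes(d2, responses = "taxonomic")$beta, ps$beta,
               tolerance = 1e-9)
  # n <= p errors
  expect_error(partial_slopes(d[1:4, ], responses = "taxonomic"), "too small")
})

test_that("residual diagnostics detect coordinate structure", {
  d <- fake_metrics(n = 300, seed = 27, beta_lu = 0.5, noise = 0.1, realms = 1)
  fit <- fit_additive(d, "taxonomic_std",
                      c("landuse_shannon", "npp", "center_lon", "center_lat"))
  diag <- residual_diagnostics(fit)
  expect_true(all(abs(diag$coordinates$r) < 0.05))
  expect_true(diag$pass)
  # residuals equal to latitude: r = 1
  fake_fit <- list(model = structure(list(), class = "fake"),
                   data = d)
  assign("residuals.fake", function(object, ...) d$center_lat,
         envir = globalenv())
  on.exit(rm("residuals.fake", envir = globalenv()))
  diag2 <- residual_diagnostics(fake_fit, data = d)
  expect_equal(diag2$coordinates$r[diag2$coordinates$coordinate == "center_lat"],
               1, tolerance = 1e-12)
  expect_false(diag2$pass)
})

test_that("effects are insensitive to the smoothing basis dimension", {
  d <- fake_metrics(n = 500, seed = 28, beta_lu = 0.8, beta_npp = 0,
                    noise = 0.05, realms = 2)
  sens <- sensitivity_k(d, "taxonomic", k_values = c(3, 4), min_cells = 30)
  expect_true(all(sens$agreement$sign_agree))
  expect_true(all(sens$agreement$significance_agree))
  expect_true(all(sens$per_realm$trend > 0))
  expect_error(sensitivity_k(d, "taxonomic", k_values = c(2, 3)), "k_values")
})
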