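var_labels <- c(center_lat = "Latitude", center_lon = "Longitude",
                npp = "NPP", landuse_shannon = "Land-use diversity",
                median_elevation = "ME")

check_log_response <- function(data, response, log_response) {
  y <- data[[response]]
  if (is.null(y)) stop("response column '", response, "' not found")
  if (log_response && any(y <= 0, na.rm = TRUE))
    stop("non-positive response under log transform in cells: ",
         paste(utils::head(data$cell_id[which(y <= 0)], 10), collapse = ", "))
  if (log_response) log(y) else y
}

#' Fit a Gaussian additive model with shrinkage smooths
#'
#' Penalized additive model on the (log) response with thin-plate shrinkage
#' smooths (\code{bs = "ts"}) of basis dimension \code{k} for every listed
#' term, smoothing parameters selected by REML. A realm random effect can be
#' added as a random intercept, or random intercept plus random slope on the
#' land-use Shannon term, which is the global mixed-model configuration.
#' Missing-data rows are dropped and counted.
#'
#' @param data A \code{\link{cell_metrics}} table.
#' @param response Response column name (e.g. \code{"taxonomic_std"}).
#' @param smooth_terms Predictor columns receiving smooths.
#' @param linear_terms Optional columns entering linearly.
#' @param k Basis dimension for every smooth (>= 3; default 3).
#' @param log_response Log-transform the response (default TRUE; the response
#'   must then be strictly positive).
#' @param random_realm \code{"none"}, \code{"intercept"} or
#'   \code{"intercept_slope"} (random slope on \code{landuse_shannon}).
#' @param by Optional factor column: every smooth of
#'   \code{smooth_terms[1]} is replicated within each level (\code{by=}
#'   smooths); remaining terms stay global.
#' @return An \code{aviland_fit}: list with the \code{mgcv} model,
#'   \code{aic}, \code{deviance_explained}, \code{edf}, \code{n},
#'   \code{n_dropped}, and the pieces needed for partial effects.
#' @export
fit_additive <- function(data, response, smooth_terms,
                         linear_terms = character(0), k = 3,
                         log_response = TRUE,
                         random_realm = c("none", "intercept", "intercept_slope"),
                         by = NULL) {
  random_realm <- match.arg(random_realm)
  if (k < 3) stop("basis dimension k must be >= 3")
  used <- unique(c(response, smooth_terms, linear_terms,
                   if (random_realm != "none" || !is.null(by)) "realm"))
  cc <- complete.cases(data[, used, drop = FALSE])
  n_dropped <- sum(!cc)
  d <- data[cc, , drop = FALSE]
  d$.y <- check_log_response(d, response, log_response)
  if (!is.null(by) || random_realm != "none") d$realm <- factor(d$realm)

  sm <- function(v, with_by = FALSE) {
    if (with_by) sprintf("s(%s, k = %d, bs = 'ts', by = realm)", v, k)
    else sprintf("s(%s, k = %d, bs = 'ts')", v, k)
  }
  terms <- character(0)
  for (i in seq_along(smooth_terms))
    terms <- c(terms, sm(smooth_terms[i], with_by = !is.null(by) && i == 1L))
  if (!is.null(by) && nlevels(d$realm) > 1) terms <- c(terms, "realm")
  terms <- c(terms, linear_terms)
  if (random_realm == "intercept") {
    terms <- c(terms, "s(realm, bs = 're')")
  } else if (random_realm == "intercept_slope") {
    terms <- c(terms, "s(realm, bs = 're')",
               "s(realm, landuse_shannon, bs = 're')")
  }
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  m <- mgcv::gam(fml, data = d, method = "REML")
  sm_summary <- summary(m)
  structure(list(model = m, data = d, response = response,
                 log_response = log_response,
                 smooth_terms = smooth_terms, linear_terms = linear_terms,
                 k = k, random_realm = random_realm, by = by,
                 aic = AIC(m), logLik = as.numeric(logLik(m)),
                 edf = sum(m$edf),
                 deviance_explained = sm_summary$dev.expl,
                 n = nrow(d), n_dropped = n_dropped),
            class = "aviland_fit")
}

#' @export
print.aviland_fit <- function(x, ...) {
  cat(sprintf("<aviland_fit> %s ~ %s (k=%d, REML)\n",
              if (x$log_response) paste0("log(", x$response, ")") else x$response,
              paste(x$smooth_terms, collapse = " + "), x$k))
  cat(sprintf("  n=%d (dropped %d), AIC=%.1f, deviance explained=%.1f%%\n",
              x$n, x$n_dropped, x$aic, 100 * x$deviance_explained))
  invisible(x)
}

#' Partial effect of one smooth term
#'
#' Fitted partial response of a single smooth over a grid of predictor
#' values, with normal-approximation 95% bands, and the matching partial
#' residuals (term contribution plus working residuals).
#'
#' @param fit An \code{\link{fit_additive}} result.
#' @param term Predictor name of the focal smooth.
#' @param realm For by-realm smooths, the realm level to extract.
#' @param n_grid Number of grid points (default 100).
#' @return List: \code{curve} data.frame(x, fit, ci_low, ci_high) and
#'   \code{partial_residuals} data.frame(x, residual).
#' @export
partial_effect <- function(fit, term, realm = NULL, n_grid = 100) {
  d <- fit$data
  m <- fit$model
  sub <- if (!is.null(realm)) d[d$realm == realm, , drop = FALSE] else d
  xr <- range(sub[[term]], na.rm = TRUE)
  newd <- d[rep(1L, n_grid), , drop = FALSE]
  for (v in names(newd)) {
    col <- d[[v]]
    newd[[v]] <- if (is.numeric(col)) rep(median(col, na.rm = TRUE), n_grid)
                 else rep(col[1], n_grid)
  }
  if (!is.null(realm)) newd$realm <- factor(realm, levels = levels(d$realm))
  newd[[term]] <- seq(xr[1], xr[2], length.out = n_grid)
  pr <- predict(m, newdata = newd, type = "terms", se.fit = TRUE)
  lab <- if (is.null(realm)) sprintf("s(%s)", term)
         else sprintf("s(%s):realm%s", term, realm)
  ci <- match(lab, colnames(pr$fit))
  if (is.na(ci)) stop("no smooth term '", lab, "' in the model")
  curve <- data.frame(x = newd[[term]], fit = pr$fit[, ci],
                      ci_low = pr$fit[, ci] - 1.96 * pr$se.fit[, ci],
                      ci_high = pr$fit[, ci] + 1.96 * pr$se.fit[, ci])
  tm <- predict(m, type = "terms")
  res <- data.frame(x = sub[[term]],
                    residual = (tm[, ci] + stats::residuals(m, type = "working"))[
                      if (is.null(realm)) TRUE else d$realm == realm])
  list(curve = curve, partial_residuals = res)
}

suite_specs <- list(
  c("center_lat", "center_lon"),
  c("center_lat", "center_lon", "npp"),
  c("center_lat", "center_lon", "landuse_shannon"),
  c("center_lat", "center_lon", "npp", "landuse_shannon"),
  c("center_lat", "center_lon", "npp", "landuse_shannon", "median_elevation"))

#' Fit the competing-model suite
#'
#' Five nested additive models per response, from coordinates only to
#' coordinates + NPP + land-use diversity + median elevation, each with
#' shrinkage thin-plate smooths of basis dimension \code{k}. The comparison
#' table reports AIC, the AIC difference to the selected (lowest-AIC) model,
#' and deviance explained, in fixed row order.
#'
#' @param metrics A \code{\link{cell_metrics}} table.
#' @param response \code{"taxonomic"} or \code{"functional"} (uses the
#'   max-standardized, log-transformed metric).
#' @param k Smooth basis dimension (default 3).
#' @return Data.frame (one row per model) with attribute \code{fits}, the
#'   list of \code{aviland_fit} objects.
#' @export
fit_model_suite <- function(metrics, response = c("taxonomic", "functional"),
                            k = 3) {
  response <- match.arg(response)
  resp_col <- paste0(response, "_std")
  code <- paste0("Mod_", toupper(substr(response, 1, 1)), seq_along(suite_specs))
  fits <- vector("list", length(suite_specs))
  rows <- vector("list", length(suite_specs))
  for (i in seq_along(suite_specs)) {
    fit <- tryCatch(
      fit_additive(metrics, resp_col, suite_specs[[i]], k = k),
      error = function(e) e)
    fits[[i]] <- fit
    rows[[i]] <- if (inherits(fit, "error")) {
      data.frame(model_code = code[i], response = resp_col,
                 variables = paste(var_labels[suite_specs[[i]]], collapse = " + "),
                 aic = NA_real_, deviance_explained = NA_real_,
                 error = conditionMessage(fit))
    } else {
      data.frame(model_code = code[i], response = resp_col,
                 variables = paste(var_labels[suite_specs[[i]]], collapse = " + "),
                 aic = fit$aic, deviance_explained = fit$deviance_explained,
                 error = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  tab <- tab[, c("model_code", "response", "variables", "aic", "delta_aic",
                 "deviance_explained", "error")]
  attr(tab, "fits") <- setNames(fits, code)
  tab
}

#' Per-realm additive fits of the land-use diversity effect
#'
#' One model with a by-realm shrinkage smooth of land-use Shannon diversity
#' plus global smooths of longitude and latitude, optionally a smooth of NPP
#' (to remove the productivity signal) and optionally a smooth of log
#' taxonomic richness (the functional-richness-controlling-taxonomic
#' configuration). Realms with fewer cells than the floor are dropped and
#' logged.
#'
#' @param metrics A \code{\link{cell_metrics}} table.
#' @param response \code{"taxonomic"} or \code{"functional"}.
#' @param control_npp Include a smooth of NPP (default FALSE).
#' @param control_taxonomic Include a smooth of log taxonomic richness
#'   (default FALSE; only meaningful for the functional response).
#' @param k Smooth basis dimension (default 3).
#' @param min_cells Minimum cells per realm (default 30).
#' @return List: \code{fit} (an \code{aviland_fit}), \code{effects} (tidy
#'   data.frame realm, x, fit, ci_low, ci_high), \code{skipped_realms}.
#' @export
fit_realmwise <- function(metrics, response = c("taxonomic", "functional"),
                          control_npp = FALSE, control_taxonomic = FALSE,
                          k = 3, min_cells = 30) {
  response <- match.arg(response)
  resp_col <- paste0(response, "_std")
  counts <- table(metrics$realm)
  skipped <- names(counts)[counts < min_cells]
  d <- metrics[!(metrics$realm %in% skipped), , drop = FALSE]
  if (nrow(d) == 0L) stop("no realm reaches the cell floor of ", min_cells)
  d$realm <- factor(d$realm)
  smooths <- c("landuse_shannon", "center_lon", "center_lat")
  if (control_npp) smooths <- c(smooths, "npp")
  if (control_taxonomic) {
    d$log_taxonomic <- log(d$taxonomic_richness)
    smooths <- c(smooths, "log_taxonomic")
  }
  fit <- fit_additive(d, resp_col, smooths, k = k, by = "realm")
  eff <- do.call(rbind, lapply(levels(fit$data$realm), function(rl) {
    pe <- partial_effect(fit, "landuse_shannon", realm = rl)$curve
    cbind(realm = rl, pe)
  }))
  list(fit = fit, effects = eff, skipped_realms = skipped)
}

#' Leave-one-out jackknife variable importance
#'
#' Fits the full additive model (coordinates plus all candidate variables as
#' shrinkage smooths), then refits dropping each candidate in turn. A
#' variable's importance is the drop in deviance explained (the AIC increase
#' is reported alongside); variables are returned ranked.
#'
#' @param metrics A \code{\link{cell_metrics}} table.
#' @param response Response column (e.g. \code{"taxonomic_std"}).
#' @param variables Candidate predictor columns.
#' @param k Smooth basis dimension (default 3).
#' @param keep Columns always retained (default the coordinates).
#' @return Data.frame ranked by importance: \code{variable},
#'   \code{importance} (deviance-explained drop), \code{delta_aic},
#'   \code{rank}; the full fit is attached as attribute \code{full_fit}.
#' @export
jackknife_importance <- function(metrics, response, variables, k = 3,
                                 keep = c("center_lat", "center_lon")) {
  if (length(variables) < 1) stop("no candidate variables")
  full <- fit_additive(metrics, response, c(keep, variables), k = k)
  rows <- lapply(variables, function(v) {
    rest <- setdiff(variables, v)
    if (length(c(keep, rest)) == 0L) return(NULL)
    red <- fit_additive(metrics, response, c(keep, rest), k = k)
    data.frame(variable = v,
               importance = full$deviance_explained - red$deviance_explained,
               delta_aic = red$aic - full$aic)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "full_fit") <- full
  out
}

#' Partial linear slopes of richness on land-use diversity
#'
#' Per realm and metric, an ordinary linear model of the log response on
#' land-use Shannon diversity with longitude, latitude and NPP as covariates;
#' the Shannon coefficient with its two-sided 95% confidence interval is the
#' standardized, comparable effect size. An effect is flagged significant
#' when the interval excludes zero.
#'
#' @param metrics A \code{\link{cell_metrics}} table.
#' @param responses Metrics to analyze; any of \code{"taxonomic"},
#'   \code{"functional"}, \code{"median_range_size"}.
#' @param include_npp Keep NPP as covariate (default TRUE).
#' @return Data.frame: \code{realm}, \code{metric}, \code{beta},
#'   \code{ci_low}, \code{ci_high}, \code{significant}, \code{n}.
#' @export
partial_slopes <- function(metrics,
                           responses = c("taxonomic", "functional",
                                         "median_range_size"),
                           include_npp = TRUE) {
  resp_cols <- vapply(responses, function(r) {
    switch(r, taxonomic = "taxonomic_std", functional = "functional_std",
           median_range_size = "median_range_size",
           stop("unknown response: ", r))
  }, character(1))
  covs <- c("landuse_shannon", "center_lon", "center_lat",
            if (include_npp) "npp")
  out <- list()
  for (rl in unique(metrics$realm)) {
    sub <- metrics[metrics$realm == rl, , drop = FALSE]
    for (j in seq_along(responses)) {
      rc <- resp_cols[j]
      if (!rc %in% names(metrics)) next
      cols <- c(rc, covs)
      cc <- complete.cases(sub[, cols])
      d <- sub[cc, , drop = FALSE]
      if (nrow(d) <= length(covs) + 1)
        stop("realm ", rl, ": n (", nrow(d), ") too small for ",
             length(covs), " covariates")
      d$.y <- check_log_response(d, rc, log_response = TRUE)
      fml <- stats::as.formula(paste(".y ~", paste(covs, collapse = " + ")))
      m <- lm(fml, data = d)
      ci <- confint(m, "landuse_shannon", level = 0.95)
      out[[length(out) + 1L]] <- data.frame(
        realm = rl, metric = responses[j],
        beta = unname(coef(m)["landuse_shannon"]),
        ci_low = ci[1], ci_high = ci[2],
        significant = ci[1] > 0 | ci[2] < 0, n = nrow(d))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Residual diagnostics for a fitted model
#'
#' Pearson correlations (with p-values) of the model residuals against the
#' cell coordinates as a spatial-autocorrelation screen, plus a normality
#' check (Shapiro-Wilk up to n = 5000, a moment-based skewness/kurtosis test
#' above).
#'
#' @param fit An \code{\link{fit_additive}} result (or any object whose
#'   \code{model} has \code{residuals()}).
#' @param data Data with \code{center_lon}/\code{center_lat} aligned to the
#'   residuals (default: the fit's data).
#' @param r_threshold Pass threshold on |r| (default 0.05).
#' @return List: \code{coordinates} data.frame(coordinate, r, p, pass),
#'   \code{normality} (statistic, p), \code{pass}.
#' @export
residual_diagnostics <- function(fit, data = NULL, r_threshold = 0.05) {
  res <- stats::residuals(fit$model)
  d <- data %||% fit$data
  ctab <- do.call(rbind, lapply(c("center_lon", "center_lat"), function(v) {
    x <- d[[v]]
    if (sd(res) == 0 || sd(x) == 0)
      return(data.frame(coordinate = v, r = NA_real_, p = NA_real_, pass = NA))
    ct <- cor.test(res, x)
    data.frame(coordinate = v, r = unname(ct$estimate), p = ct$p.value,
               pass = abs(ct$estimate) < r_threshold)
  }))
  n <- length(res)
  norm <- if (sd(res) == 0) {
    list(test = "none", statistic = NA_real_, p = NA_real_)
  } else if (n >= 3 && n <= 5000) {
    sw <- shapiro.test(res)
    list(test = "shapiro", statistic = unname(sw$statistic), p = sw$p.value)
  } else {
    z <- (res - mean(res)) / sd(res)
    skew <- mean(z^3); kurt <- mean(z^4) - 3
    jb <- n / 6 * (skew^2 + kurt^2 / 4)
    list(test = "jarque-bera", statistic = jb,
         p = stats::pchisq(jb, df = 2, lower.tail = FALSE))
  }
  list(coordinates = ctab, normality = norm,
       pass = all(ctab$pass, na.rm = TRUE))
}

#' Sensitivity of per-realm effects to the smoothing basis dimension
#'
#' Reruns the realm-wise fits for each basis dimension and summarizes, per
#' realm, the approximate linear trend of the fitted land-use partial effect
#' and the smooth-term p-value, then reports sign and significance agreement
#' across the k values.
#'
#' @param metrics A \code{\link{cell_metrics}} table.
#' @param response \code{"taxonomic"} or \code{"functional"}.
#' @param k_values Basis dimensions to compare (default c(3, 4)).
#' @param ... Passed to \code{\link{fit_realmwise}}.
#' @return List: \code{per_realm} data.frame(realm, k, trend, p_value,
#'   significant) and \code{agreement} data.frame(realm, sign_agree,
#'   significance_agree).
#' @export
sensitivity_k <- function(metrics, response = "taxonomic",
                          k_values = c(3, 4), ...) {
  stopifnot(all(k_values >= 3))
  per <- list()
  for (k in k_values) {
    rw <- fit_realmwise(metrics, response, k = k, ...)
    st <- summary(rw$fit$model)$s.table
    for (rl in unique(rw$effects$realm)) {
      cv <- rw$effects[rw$effects$realm == rl, ]
      trend <- unname(coef(lm(fit ~ x, data = cv))["x"])
      row <- grep(sprintf("s\\(landuse_shannon\\):realm%s$", rl), rownames(st))
      pv <- if (length(row)) st[row[1], "p-value"] else NA_real_
      per[[length(per) + 1L]] <- data.frame(
        realm = rl, k = k, trend = trend, p_value = pv,
        significant = !is.na(pv) && pv < 0.05)
    }
  }
  per <- do.call(rbind, per)
  agr <- do.call(rbind, lapply(split(per, per$realm), function(g) {
    data.frame(realm = g$realm[1],
               sign_agree = length(unique(sign(g$trend))) == 1L,
               significance_agree = length(unique(g$significant)) == 1L)
  }))
  rownames(agr) <- NULL
  list(per_realm = per, agreement = agr)
}
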