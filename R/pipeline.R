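#' Pipeline run configuration
#'
#' Bundles the mode, stage toggles, synthetic-world configuration, filter
#' thresholds and modelling options of one end-to-end run. Every default
#' matches the analysis defaults elsewhere in the package: smooth basis
#' dimension 3, land fraction >= 10%, >= 6 species per cell, 5 retained
#' ordination axes, global max-standardization.
#'
#' @param mode \code{"synthetic"} (default) or \code{"real"}.
#' @param world A \code{\link{world_config}} (synthetic mode).
#' @param paths Named list of input files for real mode: \code{traits},
#'   \code{occupancy}, \code{grid}, \code{landuse} CSVs.
#' @param stages Stages to run, in order, out of \code{"simulate"},
#'   \code{"traitspace"}, \code{"diversity"}, \code{"models"}.
#' @param min_land_fraction,min_species Cell filters.
#' @param min_realm_cells Minimum cells per realm for realm-wise fits.
#' @param k_axes Retained ordination axes (default 5).
#' @param k Smooth basis dimension (default 3).
#' @param k_sensitivity Extra basis dimensions to compare (default 4).
#' @param standardize_scope \code{"global"} or \code{"per_realm"}.
#' @param seed Master seed (overrides the world config's seed).
#' @return A \code{run_config} list.
#' @export
run_config <- function(mode = c("synthetic", "real"), world = world_config(),
                       paths = list(), stages = c("simulate", "traitspace",
                                                  "diversity", "models"),
                       min_land_fraction = 0.10, min_species = 6L,
                       min_realm_cells = 30L,
                       k_axes = 5L, k = 3L, k_sensitivity = 4L,
                       standardize_scope = "global", seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) world$seed <- as.integer(seed)
  cfg <- list(mode = mode, world = world, paths = paths, stages = stages,
              min_land_fraction = min_land_fraction,
              min_species = as.integer(min_species),
              min_realm_cells = as.integer(min_realm_cells),
              k_axes = as.integer(k_axes), k = as.integer(k),
              k_sensitivity = as.integer(k_sensitivity),
              standardize_scope = standardize_scope,
              seed = world$seed)
  if (mode == "real") {
    needed <- c("traits", "occupancy", "grid", "landuse")
    missing_paths <- needed[!vapply(needed, function(p) {
      !is.null(cfg$paths[[p]]) && file.exists(cfg$paths[[p]])
    }, logical(1))]
    if (length(missing_paths))
      stop("real mode: missing or nonexistent input path(s): ",
           paste(missing_paths, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes simulate -> trait space -> diversity/land-use metrics -> model
#' suite, writing every stage output plus a manifest (config, seed, file
#' hashes, per-stage row counts) into the run directory. Synthetic-mode runs
#' with the same config are bit-identical.
#'
#' @param config A \code{\link{run_config}}.
#' @param outdir Output directory.
#' @return Invisibly, the run directory; its \code{manifest.json} lists all
#'   outputs.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("aviland_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  counts <- list()

  if (config$mode != "synthetic")
    stop("real mode requires externally prepared CSV inputs; see vignette")

  say("[simulate] generating world (seed %d)", config$world$seed)
  world <- generate_world(config$world)
  write_world(world, file.path(outdir, "world"))
  counts$species <- nrow(world$pool)
  counts$cells_total <- nrow(world$occurrence$grid)

  say("[grid] filtering cells (land >= %.2f, species >= %d)",
      config$min_land_fraction, config$min_species)
  occ <- filter_cells(world$occurrence, config$min_land_fraction,
                      config$min_species)
  excl <- attr(occ, "exclusion_log")
  write.csv(excl, file.path(outdir, "excluded_cells.csv"), row.names = FALSE)
  counts$cells_retained <- nrow(occ$grid)
  say("[grid] retained %d of %d cells (%d excluded: %s)",
      counts$cells_retained, counts$cells_total, nrow(excl),
      paste(names(table(excl$reason)), table(excl$reason),
            sep = "=", collapse = ", "))

  space <- NULL
  if ("traitspace" %in% config$stages) {
    say("[traitspace] building %d-axis functional space", config$k_axes)
    traits <- build_trait_table(world$pool)
    D <- gower_distance(traits)
    contrib <- trait_contributions(traits, dist = D)
    space <- pcoa(D, k_axes = config$k_axes)
    write.csv(cbind(species_id = rownames(space$coordinates),
                    as.data.frame(space$coordinates)),
              file.path(outdir, "pcoa_scores.csv"), row.names = FALSE)
    write.csv(data.frame(axis = seq_along(space$eigenvalues),
                         eigenvalue = space$eigenvalues),
              file.path(outdir, "pcoa_eigenvalues.csv"), row.names = FALSE)
    write.csv(contrib, file.path(outdir, "trait_contributions.csv"),
              row.names = FALSE)
  }

  say("[diversity] computing cell metrics")
  metrics <- cell_metrics(occ, world$landcover, world$npp,
                          covariates = world$covariates, space = space,
                          occ_global = world$occurrence,
                          standardize_scope = config$standardize_scope)
  write.csv(metrics, file.path(outdir, "cell_metrics.csv"), row.names = FALSE)
  counts$cells_metrics <- nrow(metrics)
  corr <- covariate_correlations(metrics)
  write.csv(corr, file.path(outdir, "covariate_correlations.csv"),
            row.names = FALSE)

  if ("models" %in% config$stages) {
    responses <- c("taxonomic", if (!is.null(space)) "functional")
    suites <- list()
    for (r in responses) {
      say("[models] %s suite (k=%d)", r, config$k)
      suites[[r]] <- fit_model_suite(metrics, r, k = config$k)
    }
    suite_tab <- do.call(rbind, lapply(suites, function(s) {
      s$error <- NULL
      s
    }))
    write.csv(suite_tab, file.path(outdir, "model_comparison.csv"),
              row.names = FALSE)

    say("[models] realm-wise partial effects")
    effects <- do.call(rbind, lapply(responses, function(r) {
      rw <- fit_realmwise(metrics, r, k = config$k,
                          min_cells = config$min_realm_cells)
      cbind(response = r, rw$effects)
    }))
    write.csv(effects, file.path(outdir, "partial_effects.csv"),
              row.names = FALSE)

    say("[models] partial slopes")
    slopes <- partial_slopes(metrics,
                             responses = c("taxonomic",
                                           if (!is.null(space)) "functional",
                                           "median_range_size"))
    write.csv(slopes, file.path(outdir, "partial_slopes.csv"),
              row.names = FALSE)

    say("[models] jackknife importance")
    jk <- jackknife_importance(metrics, "taxonomic_std",
                               c("landuse_shannon", "npp", "median_elevation"),
                               k = config$k)
    write.csv(jk, file.path(outdir, "jackknife_importance.csv"),
              row.names = FALSE)

    say("[models] residual diagnostics")
    full <- attr(suites[["taxonomic"]], "fits")[[4]]
    diag <- residual_diagnostics(full)
    jsonlite::write_json(diag, file.path(outdir, "residual_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    if (length(config$k_sensitivity)) {
      say("[models] k sensitivity (%s)",
          paste(c(config$k, config$k_sensitivity), collapse = ", "))
      sens <- sensitivity_k(metrics, "taxonomic",
                            k_values = c(config$k, config$k_sensitivity),
                            min_cells = config$min_realm_cells)
      write.csv(sens$per_realm, file.path(outdir, "sensitivity_k.csv"),
                row.names = FALSE)
    }
  }

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  manifest <- list(
    seed = config$world$seed, mode = config$mode,
    package_version = as.character(utils::packageVersion("aviland")),
    counts = counts,
    config_hash = sum(utf8ToInt(paste(deparse(unclass(config$world)),
                                      collapse = ""))),
    files = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(outdir, f))),
           bytes = file.size(file.path(outdir, f)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Summarize a completed run
#'
#' Collects the model-comparison table, per-realm partial-effect curves and
#' slope table of a run directory into a single summary document
#' (\code{report.md}) plus simple base-graphics figures (PDF). Regeneration
#' is idempotent; missing stages are listed rather than failing.
#'
#' @param run_dir A directory written by \code{\link{run_pipeline}}.
#' @param plots Draw PDF figures (default TRUE).
#' @return Invisibly, a list of the tables found; missing stage outputs are
#'   reported in \code{missing}.
#' @export
make_report <- function(run_dir, plots = TRUE) {
  wanted <- c(model_comparison = "model_comparison.csv",
              partial_effects = "partial_effects.csv",
              partial_slopes = "partial_slopes.csv",
              jackknife = "jackknife_importance.csv",
              cell_metrics = "cell_metrics.csv")
  tabs <- list()
  missing_files <- character(0)
  for (nm in names(wanted)) {
    f <- file.path(run_dir, wanted[[nm]])
    if (file.exists(f)) tabs[[nm]] <- read.csv(f)
    else missing_files <- c(missing_files, wanted[[nm]])
  }
  lines <- c("# aviland run report", "")
  if (length(missing_files))
    lines <- c(lines, paste("Missing stage outputs:",
                            paste(missing_files, collapse = ", ")), "")
  if (!is.null(tabs$model_comparison)) {
    tc <- tabs$model_comparison
    lines <- c(lines, "## Competing models", "",
               paste("|", paste(names(tc), collapse = " | "), "|"),
               paste("|", paste(rep("---", ncol(tc)), collapse = " | "), "|"),
               vapply(seq_len(nrow(tc)), function(i) {
                 paste("|", paste(format(unlist(tc[i, ]), digits = 4),
                                  collapse = " | "), "|")
               }, character(1)), "")
  }
  if (!is.null(tabs$partial_slopes)) {
    ps <- tabs$partial_slopes
    lines <- c(lines, "## Partial slopes (per realm)", "",
               vapply(seq_len(nrow(ps)), function(i) {
                 sprintf("- %s / %s: beta = %.3f [%.3f, %.3f]%s",
                         ps$realm[i], ps$metric[i], ps$beta[i], ps$ci_low[i],
                         ps$ci_high[i],
                         if (isTRUE(ps$significant[i])) " *" else "")
               }, character(1)), "")
  }
  writeLines(lines, file.path(run_dir, "report.md"))
  if (plots && !is.null(tabs$partial_effects)) {
    grDevices::pdf(file.path(run_dir, "report_figures.pdf"), width = 8, height = 6)
    on.exit(grDevices::dev.off())
    pe <- tabs$partial_effects
    for (resp in unique(pe$response)) {
      sub <- pe[pe$response == resp, ]
      realms <- unique(sub$realm)
      graphics::par(mfrow = c(2, ceiling(length(realms) / 2)), mar = c(4, 4, 2, 1))
      for (rl in realms) {
        cv <- sub[sub$realm == rl, ]
        graphics::plot(cv$x, cv$fit, type = "l",
                       ylim = range(cv$ci_low, cv$ci_high),
                       xlab = "Land-use Shannon diversity",
                       ylab = sprintf("partial effect, log %s richness", resp),
                       main = rl)
        graphics::lines(cv$x, cv$ci_low, lty = 2)
        graphics::lines(cv$x, cv$ci_high, lty = 2)
      }
    }
  }
  invisible(c(tabs, list(missing = missing_files)))
}
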