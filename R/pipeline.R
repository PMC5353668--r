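# End-to-end orchestration: synthetic world (or supplied layers) -> richness
# -> forest predictors -> correlation evidence -> importance -> SAR debt ->
# risk -> hotspot overlap, as one deterministic function of the config.

PREDICTOR_NAMES <- c("Areas1500", "Areas2000", "IFM1500", "IFM2000",
                     "Prox1500", "Prox2000", "Conc1500", "Conc2000")

#' Full-analysis configuration
#'
#' @param synthetic A [synthetic_config()] describing the world to simulate.
#' @param alpha Connectivity decay rate (1/km).
#' @param prox_radius Proximity search radius (km) or `NULL` for global.
#' @param ifm_cutoff Connectivity distance cutoff (km) or `NULL`.
#' @param nclass Distance classes for the spatial correlation test.
#' @param B_perm Permutations for the randomization test.
#' @param bonferroni_m Bonferroni family size (default 8, the number of
#'   forest predictors tested per taxon and method).
#' @param B_boot Bootstrap iterations for the importance analysis.
#' @param z_values SAR exponents for the debt maps.
#' @param fit_z Also fit the SAR per taxon and map debt under the fitted z.
#' @param hotspot_quantile Hotspot threshold quantile (default 0.9).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(synthetic = synthetic_config(),
                            alpha = 0.001, prox_radius = NULL,
                            ifm_cutoff = NULL, nclass = 13,
                            B_perm = 999, bonferroni_m = 8,
                            B_boot = 10000,
                            z_values = c(0.25, 0.1, 0.15), fit_z = TRUE,
                            hotspot_quantile = 0.9) {
  stopifnot(inherits(synthetic, "synthetic_config"), alpha > 0,
            B_perm >= 1, bonferroni_m >= 1, B_boot >= 1,
            all(z_values > 0), hotspot_quantile > 0, hotspot_quantile < 1)
  structure(as.list(environment()), class = "analysis_config")
}

correlation_table_one <- function(y, X, lat, lon, pairs, config, taxon, seed) {
  rows <- list()
  for (k in seq_along(PREDICTOR_NAMES)) {
    pred <- PREDICTOR_NAMES[k]
    x <- X[, pred]
    Z <- as.matrix(X[, setdiff(PREDICTOR_NAMES, pred)])
    sp <- modified_ttest(y, x, lat, lon, nclass = config$nclass, pairs = pairs)
    # a predictor duplicated in the control set (e.g. identical past and
    # current layers when nothing changed) makes the residual tests
    # undefined; such rows are flagged, not fatal
    not_eval <- function(method)
      cor_result(method, r = NA_real_, df = NA_real_, t = NA_real_,
                 p = NA_real_, evaluable = FALSE)
    se <- tryCatch(semipartial_cor(y, x, Z),
                   error = function(e) not_eval("semipartial"))
    pa <- tryCatch(partial_cor(y, x, Z),
                   error = function(e) not_eval("partial"))
    rt <- randomization_test(x, y, B = config$B_perm,
                             seed = stage_seed(seed, paste0("perm_", taxon, pred)))
    for (res in list(sp, se, pa)) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon = taxon, predictor = pred, method = res$method,
        r = res$r, df = res$df, t = res$t, p = res$p,
        ess = res$ess, p_randomization = rt$p)
    }
  }
  tab <- do.call(rbind, rows)
  # Bonferroni within each (taxon, method) family of m predictors
  tab$p_bonferroni <- NA_real_
  for (m in unique(tab$method)) {
    idx <- tab$method == m
    tab$p_bonferroni[idx] <- bonferroni(tab$p[idx], config$bonferroni_m)
  }
  tab
}

#' Run the full extinction-debt analysis
#'
#' Executes, in order: synthetic-world generation, habitat filtering and
#' richness rasterization, 50-year epoch means, the eight forest predictors,
#' the three correlation tests per predictor with Bonferroni adjustment and
#' a permutation null, bootstrap relative importance, SAR fitting and debt
#' maps under each z, IUCN-probability risk maps, and top-decile hotspot
#' overlap. Deterministic given the config (all randomness derives from the
#' synthetic config's seed).
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report` list: `world`, `epochs`, `metrics` (per-cell
#'   predictor table), `richness`, `correlations` (tidy table), `importance`
#'   (per taxon), `sar` (per taxon), `debt` (per taxon, per z), `risk`,
#'   `hotspots`, `overlap` (per taxon), `provenance`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$synthetic$seed
  world <- generate_world(config$synthetic)
  grid <- world$grid

  species <- filter_forest_terrestrial(world$species)
  richness <- richness_by_taxon(species, grid)

  yrs <- as.integer(names(world$forest$layers))
  f1500s <- epoch_mean(world$forest$layers[yrs <= 1550])
  f2000s <- epoch_mean(world$forest$layers[yrs >= 1950])

  metrics <- forest_metric_set(grid, f1500s, f2000s, alpha = config$alpha,
                               h = config$prox_radius,
                               cutoff = config$ifm_cutoff)
  ids <- metrics$cell_id
  lat <- grid$centroid_lat[ids]; lon <- grid$centroid_lon[ids]
  pairs <- crh_pairs(lat, lon, config$nclass)
  X <- metrics[, PREDICTOR_NAMES]

  a1500 <- forest_area(grid, f1500s)
  a2000 <- forest_area(grid, f2000s)

  correlations <- list(); importance <- list(); sar <- list()
  debt <- list(); risk <- list(); hotspots <- list(); overlap <- list()
  for (tx in names(richness)) {
    y <- richness[[tx]][ids]
    correlations[[tx]] <- correlation_table_one(y, X, lat, lon, pairs,
                                                config, tx, seed)
    # importance needs a full-rank design: drop columns pivoted out by a
    # rank-revealing QR (duplicated epochs in a no-change world)
    Xs <- scale(as.matrix(X))
    qx <- qr(Xs)
    keep_cols <- sort(qx$pivot[seq_len(qx$rank)])
    importance[[tx]] <- bootstrap_importance(
      as.matrix(X)[, keep_cols, drop = FALSE], y, B = config$B_boot,
      seed = stage_seed(seed, paste0("boot_", tx)))
    importance[[tx]]$dropped <- setdiff(PREDICTOR_NAMES,
                                        PREDICTOR_NAMES[keep_cols])
    dz <- debt_by_z(richness[[tx]], a1500, a2000,
                    z_values = config$z_values, fit_z = config$fit_z)
    sar[[tx]] <- dz$sar
    debt[[tx]] <- dz$maps
    extant <- species[species$taxon == tx &
                        !species$iucn_category %in% c("EX", "EW"), ,
                      drop = FALSE]
    risk[[tx]] <- extinction_risk(extant, grid)
    hs_rich <- top_decile_hotspots(richness[[tx]], "richness",
                                   config$hotspot_quantile)
    hs_risk <- top_decile_hotspots(risk[[tx]], "risk", config$hotspot_quantile)
    debt_layer <- debt[[tx]][[1]]$debt
    hs_debt <- if (length(unique(stats::na.omit(debt_layer))) > 1)
      top_decile_hotspots(debt_layer, "debt", config$hotspot_quantile)
    else suppressWarnings(top_decile_hotspots(debt_layer, "debt",
                                              config$hotspot_quantile))
    hotspots[[tx]] <- list(richness = hs_rich, risk = hs_risk, debt = hs_debt)
    overlap[[tx]] <- overlap_report(hs_debt, hs_rich, hs_risk)
  }

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "synthetic")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  syn_json <- jsonlite::toJSON(config$synthetic[
    !vapply(config$synthetic, is.null, TRUE)],
    auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(fileext = ".json")
  writeLines(c(cfg_json, syn_json), tf)
  provenance <- list(seed = seed,
                     config_hash = unname(tools::md5sum(tf)),
                     r_version = as.character(getRversion()),
                     package_version = "0.1.0")
  unlink(tf)

  structure(list(world = world,
                 epochs = list(f1500 = f1500s, f2000 = f2000s),
                 metrics = metrics, richness = richness,
                 correlations = do.call(rbind, correlations),
                 importance = importance, sar = sar, debt = debt,
                 risk = risk, hotspots = hotspots, overlap = overlap,
                 provenance = provenance),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis report: %d taxa, %d land cells, seed %d\n",
              length(x$richness), nrow(x$metrics), x$provenance$seed))
  cat(sprintf("  correlations: %d rows; SAR fitted z: %s\n",
              nrow(x$correlations),
              paste(sprintf("%s=%.3f", names(x$sar),
                            vapply(x$sar, function(s) s$z, 0)),
                    collapse = ", ")))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits tidy CSV tables (correlations, importance, metrics), per-taxon
#' layer CSVs (richness, risk, debt per z), JSON summaries (SAR fits,
#' overlap, provenance) and a manifest with md5 checksums of every file.
#'
#' @param report An `analysis_report`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "analysis_report"))
  if (is.null(report$correlations) || nrow(report$correlations) == 0)
    stop("report is empty")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  grid <- report$world$grid
  paths <- character(0)
  put <- function(name) {
    p <- file.path(outdir, name); paths <<- c(paths, p); p
  }
  utils::write.csv(report$correlations, put("correlations.csv"),
                   row.names = FALSE)
  imp <- do.call(rbind, lapply(names(report$importance), function(tx) {
    d <- tidy_importance(report$importance[[tx]]); d$taxon <- tx; d
  }))
  utils::write.csv(imp, put("importance.csv"), row.names = FALSE)
  utils::write.csv(report$metrics, put("metrics.csv"), row.names = FALSE)
  for (tx in names(report$richness)) {
    write_layer_csv(grid, report$richness[[tx]],
                    put(sprintf("richness_%s.csv", tx)))
    write_layer_csv(grid, report$risk[[tx]], put(sprintf("risk_%s.csv", tx)))
    for (zn in names(report$debt[[tx]]))
      write_layer_csv(grid, report$debt[[tx]][[zn]]$debt,
                      put(sprintf("debt_%s_%s.csv", tx, zn)))
  }
  summaries <- list(
    sar = lapply(report$sar, unclass),
    overlap = lapply(report$overlap, unclass),
    provenance = report$provenance)
  jsonlite::write_json(summaries, put("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
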