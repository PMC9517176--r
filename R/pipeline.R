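# End-to-end orchestration: simulate -> zones -> indices -> LUR ->
# surface -> zonal stats -> GWR, with a checksum manifest, stage-labelled
# errors, structured logging and checksum-based resumption.

#' Pipeline configuration
#'
#' Bundles the city configuration with the LUR, GWR and raster settings.
#' Unknown keys are rejected so configuration files cannot silently
#' misspell an option.
#'
#' @param city A [city_config()] or a list of its arguments.
#' @param lur List: `alpha`, `rcut`, `enforce_sign`, `cv_seed`.
#' @param gwr List: `kernel`, `rcut`, `nperm`.
#' @param raster List: `res` (m).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(city = city_config(),
                            lur = list(),
                            gwr = list(),
                            raster = list()) {
  if (!inherits(city, "city_config")) city <- do.call(city_config, city)
  merge_known <- function(given, defaults, block) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad))
      stop("unknown ", block, " config key(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  structure(list(
    city = city,
    lur = merge_known(lur, list(alpha = 0.10, rcut = 0.6,
                                enforce_sign = FALSE, cv_seed = 1L), "lur"),
    gwr = merge_known(gwr, list(kernel = "gaussian", rcut = 0.6,
                                nperm = 999L), "gwr"),
    raster = merge_known(raster, list(res = 100), "raster")
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' YAML round-trip of a [pipeline_config()]; unknown keys in the file are
#' rejected on read.
#'
#' @param path YAML file path.
#' @param config A `pipeline_config` (for writing).
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("city", "lur", "gwr", "raster"))
  if (length(bad))
    stop("unknown config block(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  city_args <- raw$city %||% list()
  known <- names(formals(city_config))
  badc <- setdiff(names(city_args), known)
  if (length(badc))
    stop("unknown city config key(s) in ", path, ": ",
         paste(badc, collapse = ", "))
  if (!is.null(city_args$zone_counts))
    city_args$zone_counts <- unlist(city_args$zone_counts)
  if (!is.null(city_args$building_density))
    city_args$building_density <- unlist(city_args$building_density)
  if (!is.null(city_args$zone_areas))
    city_args$zone_areas <- lapply(city_args$zone_areas, unlist)
  pipeline_config(city = do.call(city_config, city_args),
                  lur = raw$lur %||% list(), gwr = raw$gwr %||% list(),
                  raster = raw$raster %||% list())
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(
    city = unclass(config$city),
    lur = config$lur, gwr = config$gwr, raster = config$raster)
  out$city$zone_counts <- as.list(out$city$zone_counts)
  out$city$building_density <- as.list(out$city$building_density)
  out$city$zone_areas <- lapply(out$city$zone_areas, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order and writes every artifact plus a
#' `manifest.json` mapping each file to its MD5 checksum. Fully
#' deterministic given the seed in the city configuration (stage seeds
#' fan out from it by fixed offsets). With `resume = TRUE` a stage is
#' skipped when its outputs exist and both they and its inputs match the
#' previous manifest, so deleting one intermediate regenerates only that
#' artifact and its downstream dependents.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param resume Skip stages whose artifacts are up to date.
#' @return data.frame manifest (`file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  old_manifest <- NULL
  if (resume && file.exists(pth("manifest.json"))) {
    om <- jsonlite::fromJSON(pth("manifest.json"))
    old_manifest <- stats::setNames(unlist(om$md5), unlist(om$file))
  }
  md5 <- function(fs) unname(tools::md5sum(file.path(out_dir, fs)))
  fresh <- function(fs) {
    if (is.null(old_manifest)) return(FALSE)
    all(fs %in% names(old_manifest)) &&
      all(file.exists(file.path(out_dir, fs))) &&
      all(md5(fs) == old_manifest[fs])
  }
  run_stage <- function(stage, inputs, outputs, fn) {
    if (resume && fresh(c(inputs, outputs))) {
      log_stage(stage, "up to date; skipped")
      return(invisible(NULL))
    }
    log_stage(stage, "running")
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cc <- config$city

  sim_out <- c("parcels.geojson", "candidates.geojson", "buildings.geojson",
               "roads.geojson", "sites.csv", "panel.csv", "truth.json",
               "site_predictors.csv")
  run_stage("simulate", character(0), sim_out, function() {
    log_stage("simulate", "seed=", cc$seed, " sites=", cc$n_sites,
              " months=", cc$n_months)
    city <- generate_city(cc)
    write_geojson(city$parcels$parcels, pth("parcels.geojson"))
    write_geojson(city$parcels$candidates, pth("candidates.geojson"))
    write_geojson(city$buildings, pth("buildings.geojson"))
    write_geojson(city$roads, pth("roads.geojson"))
    utils::write.csv(city$sites, pth("sites.csv"), row.names = FALSE)
    utils::write.csv(city$panel, pth("panel.csv"), row.names = FALSE)
    tr <- city$truth
    jsonlite::write_json(
      list(coefficients = as.list(tr$coefficients),
           gwr_fields = tr$gwr_fields, noise_sd = tr$noise_sd,
           extent = cc$extent, pad = city$parcels$pad),
      pth("truth.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(city$site_predictors, pth("site_predictors.csv"),
                     row.names = FALSE)
  })

  read_parcel_set <- function() {
    truth_meta <- jsonlite::fromJSON(pth("truth.json"))
    structure(list(parcels = read_geojson(pth("parcels.geojson")),
                   candidates = read_geojson(pth("candidates.geojson")),
                   extent = truth_meta$extent, pad = truth_meta$pad),
              class = "parcel_set")
  }

  run_stage("zones", c("parcels.geojson", "candidates.geojson"),
            c("zones.geojson", "zones_summary.csv"), function() {
    ps <- read_parcel_set()
    zones <- identify_zones(ps$parcels, ps$candidates)
    write_geojson(zones, pth("zones.geojson"))
    utils::write.csv(zone_summary(zones), pth("zones_summary.csv"),
                     row.names = FALSE)
  })

  run_stage("indices", c("zones.geojson", "buildings.geojson"),
            "indices.csv", function() {
    zones <- read_geojson(pth("zones.geojson"))
    blds <- read_geojson(pth("buildings.geojson"))
    blds$fp_area <- (blds$xmax - blds$xmin) * (blds$ymax - blds$ymin)
    idx <- landscape_indices(zones, blds)
    utils::write.csv(idx, pth("indices.csv"), row.names = FALSE)
  })

  run_stage("lur", c("panel.csv", "site_predictors.csv"),
            "model.json", function() {
    panel <- read_panel(pth("panel.csv"))
    preds <- utils::read.csv(pth("site_predictors.csv"),
                             stringsAsFactors = FALSE)
    design <- build_design(panel, preds)
    sc <- screen_variables(design, panel$PM25, rcut = config$lur$rcut)
    model <- fit_lur(design, panel$PM25, sc$retained,
                     alpha = config$lur$alpha,
                     enforce_sign = config$lur$enforce_sign)
    cv <- cross_validate(design, panel$PM25, model$retained,
                         seed = config$lur$cv_seed)
    jsonlite::write_json(
      list(intercept = unname(model$coefficients["(Intercept)"]),
           coefficients = as.list(model$coefficients[model$retained]),
           r_squared = model$r_squared,
           adj_r_squared = model$adj_r_squared,
           cv_mae_rate = cv$mae_rate, cv_rmse = cv$rmse,
           settings = config$lur),
      pth("model.json"), auto_unbox = TRUE, digits = NA)
  })

  run_stage("surface",
            c("model.json", "parcels.geojson", "roads.geojson"),
            "pm25.asc", function() {
    mj <- jsonlite::fromJSON(pth("model.json"))
    cf <- c(`(Intercept)` = mj$intercept, unlist(mj$coefficients))
    model <- structure(list(coefficients = cf,
                            retained = names(mj$coefficients)),
                       class = "lur_model")
    ps <- read_parcel_set()
    roads <- read_geojson(pth("roads.geojson"))
    surf <- predict_surface(model, ps, roads, res = config$raster$res)
    write_raster_asc(surf, pth("pm25.asc"))
  })

  run_stage("stats", c("pm25.asc", "zones.geojson", "indices.csv"),
            c("zone_pm25.csv", "anova.csv", "lsd.csv", "correlations.csv"),
            function() {
    surf <- read_raster_asc(pth("pm25.asc"))
    zones <- read_geojson(pth("zones.geojson"))
    idx <- utils::read.csv(pth("indices.csv"), stringsAsFactors = FALSE)
    zones <- zones[zones$zone_id %in% idx$zone_id, ]
    zones <- zones[match(idx$zone_id, zones$zone_id), ]
    zpm <- vapply(seq_len(nrow(zones)), function(i)
      zonal_mean_pm25(surf, zones[i, ]), numeric(1))
    utils::write.csv(data.frame(zone_id = zones$zone_id,
                                zone_type = zones$zone_type,
                                pm25 = zpm),
                     pth("zone_pm25.csv"), row.names = FALSE)
    idx_cols <- c("H_bar", "E_vol", "L", "LHR", "S_div", "E_uni")
    an <- do.call(rbind, lapply(idx_cols, function(cl) {
      at <- one_way_anova(split(idx[[cl]], idx$zone_type))
      data.frame(index = cl, ss_between = at$ss[1], df = at$df[1],
                 ms = at$ms[1], F = at$F[1], p = at$p[1])
    }))
    utils::write.csv(an, pth("anova.csv"), row.names = FALSE)
    lsd <- do.call(rbind, lapply(idx_cols, function(cl)
      cbind(index = cl, lsd_posthoc(split(idx[[cl]], idx$zone_type)))))
    utils::write.csv(lsd, pth("lsd.csv"), row.names = FALSE)
    utils::write.csv(index_pm25_correlations(idx, zpm),
                     pth("correlations.csv"), row.names = FALSE)
  })

  gwr_out <- c(paste0("gwr_", c("industrial", "educational", "residential",
                                "commercial"), ".csv"), "gwr_summary.json")
  run_stage("gwr", c("indices.csv", "zone_pm25.csv", "zones.geojson"),
            gwr_out, function() {
    idx <- utils::read.csv(pth("indices.csv"), stringsAsFactors = FALSE)
    zpm <- utils::read.csv(pth("zone_pm25.csv"), stringsAsFactors = FALSE)
    zones <- read_geojson(pth("zones.geojson"))
    summary_list <- list()
    for (ty in unique(idx$zone_type)) {
      sel <- idx$zone_type == ty
      if (sum(sel) < 6L) {
        log_stage("gwr", "type '", ty, "' has fewer than 6 zones; skipped")
        next
      }
      sub_idx <- idx[sel, c("H_bar", "E_vol", "L", "LHR", "S_div", "E_uni")]
      y <- zpm$pm25[match(idx$zone_id[sel], zpm$zone_id)]
      zz <- zones[match(idx$zone_id[sel], zones$zone_id), ]
      coords <- cbind(zz$x, zz$y)
      vars <- select_gwr_predictors(sub_idx, y, rcut = config$gwr$rcut)
      X <- as.matrix(sub_idx[, vars, drop = FALSE])
      bw <- select_bandwidth(coords, y, X, kernel = config$gwr$kernel)
      fit <- fit_gwr(coords, y, X, bw, kernel = config$gwr$kernel,
                     nperm = config$gwr$nperm,
                     moran_seed = cc$seed + 7L)
      out <- data.frame(zone_id = idx$zone_id[sel], x = zz$x, y = zz$y,
                        fit$coefficients, residual = fit$residuals,
                        std_residual = fit$std_residuals,
                        check.names = FALSE)
      utils::write.csv(out, pth(paste0("gwr_", ty, ".csv")),
                       row.names = FALSE)
      summary_list[[ty]] <- list(
        predictors = vars, bandwidth = bw, r_squared = fit$r_squared,
        adj_r_squared = fit$adj_r_squared, moran_i = fit$morans$I,
        moran_p = fit$morans$p,
        credible = fit$morans$p > 0.05)
    }
    jsonlite::write_json(summary_list, pth("gwr_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- data.frame(file = files, md5 = md5(files),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  log_stage("done", length(files), " artifact(s) in ", out_dir)
  invisible(manifest)
}
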