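# End-to-end orchestration: one config, one run directory, a manifest.
# Stages: load -> thin -> screen -> fit -> replicates -> predict ->
# classify -> areas/centroid -> resistance/sources -> corridors -> metrics.
# Every intermediate is written as a plain-text standard format and the
# manifest records seeds, timings and file hashes so a run is re-runnable
# and auditable from the directory alone.

#' Write a ready-to-run synthetic workspace
#'
#' Materializes a [synthetic_spec()] as ESRI ASCII grids, an occurrence
#' CSV and a pipeline config JSON, so the full pipeline can be exercised
#' from files alone.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return the config file path, invisibly.
#' @export
write_synthetic_workspace <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ws <- make_synthetic_workspace(spec)
  layer_paths <- list()
  for (nm in names(ws$stack$layers)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_grid(ws$stack$layers[[nm]], p)
    layer_paths[[nm]] <- p
  }
  occ_path <- file.path(dir, "occurrences.csv")
  save_points(ws$presences, occ_path)
  cfg <- list(
    seed = spec$seed,
    layers = layer_paths,
    categorical = list("LUCC"),
    occurrences = occ_path,
    thin_min_dist = spec$cellsize / 2,
    maxent = list(n_background = 10000, reg_multiplier = 1.0,
                  convergence_tol = 1e-5, max_iterations = 500,
                  test_fraction = 0.25, n_replicates = 10),
    class_cuts = c(0.2, 0.5, 0.7),
    resistance = "from_model",
    min_area_km2 = 5)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfg_path)
}

#' Validate a pipeline config
#'
#' @param config a config list or path to a config JSON.
#' @return the validated config list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$layers) || !length(config$layers))
    stop("config: no layers declared")
  for (nm in names(config$layers)) {
    p <- config$layers[[nm]]
    if (!file.exists(p))
      stop(sprintf("config: layer '%s' file does not exist: %s", nm, p))
  }
  if (is.null(config$occurrences) || !file.exists(config$occurrences))
    stop("config: occurrences file does not exist")
  if (is.character(config$resistance) && config$resistance != "from_model" &&
      !file.exists(config$resistance))
    stop(sprintf("config: resistance scheme file does not exist: %s",
                 config$resistance))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$thin_min_dist)) config$thin_min_dist <- 100
  if (is.null(config$class_cuts)) config$class_cuts <- c(0.2, 0.5, 0.7)
  if (is.null(config$min_area_km2)) config$min_area_km2 <- 10
  if (is.null(config$resistance)) config$resistance <- "from_model"
  config
}

#' Run the full habitat-suitability and corridor pipeline
#'
#' @param config config list or path to a config JSON (see
#'   [write_synthetic_workspace()] for the layout).
#' @param out_dir run directory for all outputs.
#' @param quiet suppress stage logging to standard error.
#' @return the manifest list, invisibly; all outputs and `manifest.json`
#'   are written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  files <- character(0)
  t_all <- proc.time()[["elapsed"]]
  log_stage <- function(name) {
    if (!quiet) message(sprintf("[%s] ...", name))
  }
  run_stage <- function(name, fun) {
    log_stage(name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages[[length(stages) + 1L]] <<- list(
      name = name, seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  emit <- function(path) { files <<- c(files, path); path }

  st <- run_stage("load", function() {
    cat_names <- unlist(config$categorical)
    layers <- lapply(names(config$layers), function(nm)
      read_grid(config$layers[[nm]],
                kind = if (nm %in% c(cat_names, "LUCC")) "categorical"
                       else "continuous"))
    names(layers) <- names(config$layers)
    env_stack(layers)
  })
  occ_raw <- run_stage("load_points", function()
    load_points(config$occurrences, force = TRUE))
  occ <- run_stage("thin", function() {
    o <- thin(occ_raw, min_dist = config$thin_min_dist, seed = config$seed)
    save_points(o, emit(file.path(out_dir, "occurrences_thinned.csv")))
    o
  })
  mc_args <- config$maxent
  mc_args <- mc_args[names(mc_args) %in% names(formals(maxent_config))]
  mcfg <- do.call(maxent_config, c(mc_args, list(seed = config$seed)))
  screen <- run_stage("screen", function() {
    rep <- pearson_screen(st)
    utils::write.csv(as.data.frame(rep$pearson),
                     emit(file.path(out_dir, "pearson_matrix.csv")))
    rep
  })
  st_sel <- stack_subset(st, screen$selected)
  model <- run_stage("fit", function() {
    m <- fit_maxent(occ, st_sel, mcfg)
    write_maxent(m, emit(file.path(out_dir, "maxent_model.json")))
    m
  })
  evalr <- run_stage("replicates", function() {
    ev <- evaluate_replicates(occ, st_sel, mcfg)
    utils::write.csv(ev$per_rep,
                     emit(file.path(out_dir, "replicate_auc.csv")),
                     row.names = FALSE)
    ev
  })
  suit <- run_stage("predict", function() {
    s <- predict(model, st_sel, type = "logistic")
    write_grid(s, emit(file.path(out_dir, "suitability.asc")))
    s
  })
  classified <- run_stage("classify", function() {
    cl <- classify_suitability(suit, suitability_classes(config$class_cuts))
    write_grid(cl, emit(file.path(out_dir, "suitability_classes.asc")))
    cl
  })
  areas <- run_stage("areas_centroid", function() {
    at <- area_table(classified)
    utils::write.csv(as.data.frame(at),
                     emit(file.path(out_dir, "area_table.csv")),
                     row.names = FALSE)
    dem <- if ("DEM" %in% names(st$layers)) st$layers[["DEM"]] else NULL
    ctr <- habitat_centroid(suit, classified, dem)
    jsonlite::write_json(
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(ctr$x, ctr$y)),
           properties = list(mean_elevation = ctr$mean_elevation)),
      emit(file.path(out_dir, "centroid.geojson")),
      auto_unbox = TRUE, digits = NA, na = "null")
    list(table = at, centroid = ctr)
  })
  resist <- run_stage("resistance_sources", function() {
    scheme <- if (identical(config$resistance, "from_model")) {
      scheme_from_response(model)
    } else read_resistance_scheme(config$resistance)
    write_resistance_scheme(scheme,
                            emit(file.path(out_dir, "resistance_scheme.csv")))
    surf <- resistance_surface(st_sel, scheme)
    write_grid(surf, emit(file.path(out_dir, "resistance_surface.asc")))
    srcs <- identify_sources(classified, config$min_area_km2)
    list(surface = surf, sources = srcs)
  })
  corridors <- run_stage("corridors", function() {
    if (length(resist$sources) >= 2) {
      cs <- least_cost_corridors(resist$surface, resist$sources)
      corridors_to_geojson(cs, emit(file.path(out_dir, "corridors.geojson")))
      cs
    } else NULL
  })
  mets <- run_stage("metrics", function() {
    r <- landscape_metrics(classified)
    utils::write.csv(as.data.frame(r),
                     emit(file.path(out_dir, "landscape_metrics.csv")),
                     row.names = FALSE)
    r
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("ecocorridor")),
    seed = config$seed,
    stages = stages,
    auc_mean = evalr$auc_mean,
    n_presences = nrow(occ),
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    total_seconds = round(proc.time()[["elapsed"]] - t_all, 3))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

#' Corridors as GeoJSON LineStrings
#'
#' @param cs a `corridor_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
corridors_to_geojson <- function(cs, path) {
  feats <- lapply(cs$corridors, function(cr) {
    list(type = "Feature",
         geometry = if (cr$connected)
           list(type = "LineString",
                coordinates = unname(lapply(seq_len(nrow(cr$path)), function(i)
                  c(cr$path$x[i], cr$path$y[i]))))
         else NULL,
         properties = list(from = cr$from, to = cr$to,
                           total_cost = if (is.finite(cr$total_cost))
                             cr$total_cost else NULL,
                           connected = cr$connected))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(path)
}
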