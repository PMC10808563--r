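#' Assemble a pipeline configuration
#'
#' A single structured configuration drives the whole pipeline; all
#' randomness flows from the named seeds.  Either a synthetic study is
#' generated (\code{simulate}) or station/trap/elevation files are read from
#' the given paths.
#'
#' @param workdir directory for all stage artifacts (created if absent).
#' @param simulate optional \code{\link{synthetic_config}}; when given,
#'   inputs are generated rather than read.
#' @param stations_csv,traps_csv,elevation_file input paths (ignored when
#'   simulating); the elevation file uses the \code{\link{read_surface}}
#'   grid format with values in meters.
#' @param grid_dims \code{c(n_rows, n_cols)} of the kriging analysis grid.
#' @param vgm_policy variogram policy passed to
#'   \code{\link{make_daily_surface}}.
#' @param thin thin events to one per trap-month before modeling (default
#'   TRUE).
#' @param seed master seed for the split, CV folds, and Moran sampling.
#' @param moran_min_events equal-sampling cutoff (default 60).
#' @param threshold_grid,threshold_tolerance passed to
#'   \code{\link{find_low_precip_threshold}}.
#' @param max_neighbors kriging neighbor cap.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(workdir,
                            simulate = NULL,
                            stations_csv = NULL, traps_csv = NULL,
                            elevation_file = NULL,
                            grid_dims = c(30, 30),
                            vgm_policy = list(),
                            thin = TRUE,
                            seed = 1,
                            moran_min_events = 60,
                            threshold_grid = seq(0.01, 0.50, by = 0.01),
                            threshold_tolerance = 0.05,
                            max_neighbors = 64) {
  if (is.null(simulate)) {
    for (p in c(stations_csv, traps_csv, elevation_file))
      if (is.null(p) || !file.exists(p))
        stop(sprintf("input path missing or nonexistent: %s",
                     if (is.null(p)) "(NULL)" else p))
  }
  structure(list(workdir = workdir, simulate = simulate,
                 stations_csv = stations_csv, traps_csv = traps_csv,
                 elevation_file = elevation_file,
                 grid_dims = grid_dims, vgm_policy = vgm_policy,
                 thin = thin, seed = seed,
                 moran_min_events = moran_min_events,
                 threshold_grid = threshold_grid,
                 threshold_tolerance = threshold_tolerance,
                 max_neighbors = max_neighbors),
            class = "pipeline_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: input assembly (or simulation), daily kriged
#' surfaces, 20-day lag realignment with thinning, per-lag screens, the
#' presence/abundance model comparison, global Moran's I on equally sampled
#' traps, trapping-effort summary, and the low-precipitation threshold.
#' Every stage writes its artifact under the configured working directory;
#' exclusion counts are logged; a machine-readable manifest records the
#' outputs, seeds and a config digest.  Any stage failure aborts with the
#' stage name (partial outputs remain on disk).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with the in-memory stage results plus \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$workdir
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ## inputs ---------------------------------------------------------------
  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      bundle <- gen_study(config$simulate)
      st_long <- stations_long(bundle$stations, bundle$fields)
      write.csv(st_long, file.path(wd, "stations.csv"), row.names = FALSE)
      ev <- bundle$events[, c("trap_id", "lon", "lat", "trap_type",
                              "collection_date", "female_count",
                              "male_count")]
      write.csv(ev, file.path(wd, "traps.csv"), row.names = FALSE)
      list(station_days = st_long, events = read_traps(file.path(wd, "traps.csv")),
           elevation = bundle$elevation,
           bbox = config$simulate$bbox)
    } else {
      st <- read_stations(config$stations_csv)
      ev <- read_traps(config$traps_csv)
      elev <- read_surface(config$elevation_file)
      list(station_days = st, events = ev, elevation = elev,
           bbox = c(elev$grid$lon_min, elev$grid$lat_min,
                    elev$grid$lon_max, elev$grid$lat_max))
    }
  })
  outputs <- c(outputs, "stations.csv", "traps.csv")
  events <- filter_co2(inputs$events)
  message(sprintf("pipeline: %d trapping events after BG exclusion",
                  nrow(events)))

  ## kriged daily surfaces ------------------------------------------------
  surfaces <- stage("krige", {
    grid <- grid_spec(inputs$bbox, config$grid_dims[1], config$grid_dims[2])
    need <- sort(unique(format(
      rep(events$collection_date, each = lag_days) -
        rep(seq_len(lag_days), times = nrow(events)))))
    sdir <- file.path(wd, "surfaces")
    dir.create(sdir, showWarnings = FALSE)
    surf <- lapply(need, function(d) {
      day <- inputs$station_days[format(inputs$station_days$date) == d, ,
                                 drop = FALSE]
      s <- make_daily_surface(day, inputs$elevation, grid, as.Date(d),
                              vgm_policy = config$vgm_policy,
                              max_neighbors = config$max_neighbors)
      write_surface(s, file.path(sdir, sprintf("precip_%s.csv", d)))
      s
    })
    surface_store(surfaces = surf)
  })
  outputs <- c(outputs, "surfaces/")

  ## lag alignment --------------------------------------------------------
  lagmat <- stage("align", {
    rows <- extract_lags(events, surfaces)
    n0 <- nrow(rows)
    if (config$thin) rows <- thin_events(rows)
    message(sprintf("pipeline: thinning kept %d of %d events",
                    nrow(rows), n0))
    lm <- build_lag_matrix(rows)
    write.csv(lm, file.path(wd, "lagmatrix.csv"), row.names = FALSE)
    lm
  })
  outputs <- c(outputs, "lagmatrix.csv")

  ## per-lag screens ------------------------------------------------------
  screens <- stage("screen", {
    sp <- per_lag_presence_screen(lagmat)
    sa <- per_lag_abundance_screen(lagmat)
    write.csv(sp, file.path(wd, "screen_presence.csv"), row.names = FALSE)
    write.csv(sa, file.path(wd, "screen_abundance.csv"), row.names = FALSE)
    list(presence = sp, abundance = sa)
  })
  outputs <- c(outputs, "screen_presence.csv", "screen_abundance.csv")

  ## model comparison -----------------------------------------------------
  models <- stage("compare", {
    mp <- fit_model_suite(lagmat, "presence", seed = config$seed)
    ma <- fit_model_suite(lagmat, "abundance", seed = config$seed)
    res <- list(
      presence = c(list(table = mp$table), mp[c("n_train", "n_test")]),
      abundance = c(list(table = ma$table), ma[c("n_train", "n_test")]))
    write_json_file(res, file.path(wd, "models.json"))
    list(presence = mp, abundance = ma)
  })
  outputs <- c(outputs, "models.json")

  ## spatial autocorrelation ---------------------------------------------
  moran <- stage("moran", {
    agg <- equal_sample(events, config$moran_min_events, seed = config$seed)
    xy <- project_local(agg$lon, agg$lat)
    mi <- morans_i(agg$female_total, xy)
    res <- unclass(mi)
    res$median_spacing_m <- median_trap_spacing(xy)
    write_json_file(res, file.path(wd, "moran.json"))
    mi
  })
  outputs <- c(outputs, "moran.json")

  ## summaries + threshold ------------------------------------------------
  effort <- stage("summarize", {
    es <- summarize_effort(inputs$events)   # includes BG rows by design
    write.csv(es, file.path(wd, "effort.csv"), row.names = FALSE)
    es
  })
  outputs <- c(outputs, "effort.csv")

  threshold <- stage("threshold", {
    th <- find_low_precip_threshold(lagmat, config$threshold_grid,
                                    config$threshold_tolerance)
    res <- unclass(th)
    res$anthropogenic_pct <- anthropogenic_fraction(lagmat, th$threshold)
    write_json_file(res, file.path(wd, "threshold.json"))
    th
  })
  outputs <- c(outputs, "threshold.json")

  ## manifest -------------------------------------------------------------
  manifest <- stage("manifest", {
    cfg_path <- file.path(wd, "config.json")
    # digest the scientific configuration, not filesystem locations
    cfg_json <- config[setdiff(names(config),
                               c("simulate", "workdir", "stations_csv",
                                 "traps_csv", "elevation_file"))]
    cfg_json$vgm_policy <- lapply(cfg_json$vgm_policy, function(x)
      if (inherits(x, "variogram_model")) unclass(x) else x)
    cfg_json$simulate_seed <- if (is.null(config$simulate)) NULL
      else config$simulate$seed
    write_json_file(cfg_json, cfg_path)
    man <- list(stages = c("inputs", "krige", "align", "screen", "compare",
                           "moran", "summarize", "threshold"),
                outputs = outputs,
                seed = config$seed,
                config_md5 = unname(tools::md5sum(cfg_path)))
    write_json_file(man, file.path(wd, "manifest.json"))
    man
  })
  list(lagmat = lagmat, screens = screens, models = models, moran = moran,
       effort = effort, threshold = threshold, manifest = manifest)
}
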