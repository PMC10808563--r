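#' Configuration of the synthetic surveillance study
#'
#' Defines the generator for a synthetic arid-urban surveillance study: a
#' clustered weather-station network, a smooth elevation surface,
#' zero-inflated spatially correlated daily precipitation, a ~1-trap-per-
#' square-mile grid of weekly-serviced CO2 traps, and female counts driven by
#' known daily-lag precipitation coefficients.  Defaults emulate the
#' conditions of a metropolitan Sonoran Desert study: 355 stations, a ~29 x
#' 31 mile urban core, two-ish rain events per fortnight in season
#' (wet-day probability 0.15, wet-day mean 0.12 in, ~7 in/yr), a baseline
#' presence log-odds of -1.86, mean positive-trap count ~5 females, and a
#' planted effect structure in which rain 2 and 8 days before collection
#' suppresses presence while rain 10 and 15 days before enhances it.
#'
#' @param seed integer master seed; every generator output is a pure
#'   function of the configuration.
#' @param n_stations weather stations (default 355).
#' @param bbox study bounding box, degrees.
#' @param n_days days of simulated precipitation (default 390, covering a
#'   full annual cycle plus the 20-day burn-in).
#' @param start_date first simulated date.
#' @param wet_day_prob probability a day is wet anywhere (dry days are all
#'   zeros; default 0.15).
#' @param wet_mean regional mean precipitation on wet days, inches.
#' @param true_variogram \code{\link{vgm_model}} of the wet-day field.
#' @param elevation_effect inches of extra precipitation per km of elevation.
#' @param trap_spacing trap grid spacing, miles (default 1).
#' @param lag_effects list with \code{presence} and \code{abundance}, each
#'   \code{c(intercept, beta1..beta20)} on the logit / log-mean scale (per
#'   inch).
#' @param cum_effects list with \code{presence} and \code{abundance}, each
#'   \code{c(cum10, cum20)} coefficients (default all zero).
#' @param dispersion negative-binomial size for counts (larger = closer to
#'   Poisson).
#' @param elev_grid_dims \code{c(n_rows, n_cols)} of the elevation grid.
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1,
                             n_stations = 355,
                             bbox = c(-112.35, 33.25, -111.85, 33.70),
                             n_days = 390,
                             start_date = as.Date("2014-06-01"),
                             wet_day_prob = 0.15,
                             wet_mean = 0.12,
                             true_variogram = vgm_model("exponential",
                                                        nugget = 1e-4,
                                                        psill = 9e-3,
                                                        range = 15000),
                             elevation_effect = 0.05,
                             trap_spacing = 1,
                             lag_effects = NULL,
                             cum_effects = NULL,
                             dispersion = 1,
                             elev_grid_dims = c(45, 50)) {
  stopifnot(n_stations >= 3, wet_day_prob >= 0, wet_day_prob <= 1,
            trap_spacing > 0, n_days >= 1, dispersion > 0)
  beta_default <- function(scale) {
    b <- numeric(lag_days)
    b[c(2, 8, 10, 15)] <- c(-6, -3, 5, 3) * scale
    b
  }
  if (is.null(lag_effects))
    lag_effects <- list(presence = c(-1.86, beta_default(1)),
                        abundance = c(log(4.3), beta_default(0.5)))
  if (is.null(cum_effects))
    cum_effects <- list(presence = c(cum10 = 0, cum20 = 0),
                        abundance = c(cum10 = 0, cum20 = 0))
  stopifnot(length(lag_effects$presence) == lag_days + 1,
            length(lag_effects$abundance) == lag_days + 1)
  structure(list(seed = seed, n_stations = n_stations, bbox = bbox,
                 n_days = n_days, start_date = start_date,
                 wet_day_prob = wet_day_prob, wet_mean = wet_mean,
                 true_variogram = true_variogram,
                 elevation_effect = elevation_effect,
                 trap_spacing = trap_spacing,
                 lag_effects = lag_effects, cum_effects = cum_effects,
                 dispersion = dispersion,
                 elev_grid_dims = elev_grid_dims),
            class = "synthetic_config")
}

# correlation function matching a variogram model's structured part
vgm_corr <- function(h, model) {
  a <- model$range
  switch(model$family,
    spherical = ifelse(h < a, 1 - (1.5 * h / a - 0.5 * (h / a)^3), 0),
    exponential = exp(-h / a),
    gaussian = exp(-(h / a)^2),
    matern = {
      nu <- model$smoothness
      ha <- h / a
      ifelse(ha == 0, 1, (2^(1 - nu) / gamma(nu)) * ha^nu * besselK(ha, nu))
    })
}

#' Generate the station network and elevation surface
#'
#' Stations are drawn with mild clustering (a Gaussian mixture around random
#' cluster centers) inside the bounding box, mimicking the uneven geographic
#' coverage of real gauge networks.  Elevation is a smooth low-order trend
#' plus smooth sinusoidal relief, sampled bilinearly at the stations.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return list with \code{stations} (station_id, lon, lat, elevation_m),
#'   \code{elevation} (a gridded layer in meters), \code{grid}.
#' @export
gen_stations_and_elevation <- function(cfg) {
  bb <- cfg$bbox
  grid <- grid_spec(bb, cfg$elev_grid_dims[1], cfg$elev_grid_dims[2])
  with_seed(cfg$seed + 101L, {
    n_clusters <- max(3L, round(cfg$n_stations / 25))
    cx <- runif(n_clusters, bb[1], bb[3])
    cy <- runif(n_clusters, bb[2], bb[4])
    assign_cl <- sample.int(n_clusters, cfg$n_stations, replace = TRUE)
    sdx <- 0.08 * (bb[3] - bb[1])
    lon <- cx[assign_cl] + rnorm(cfg$n_stations, 0, sdx)
    lat <- cy[assign_cl] + rnorm(cfg$n_stations, 0, sdx)
    # reflect stray points back inside the box
    lon <- bb[1] + abs((lon - bb[1]) %% (2 * (bb[3] - bb[1])) -
                         (bb[3] - bb[1]))
    lat <- bb[2] + abs((lat - bb[2]) %% (2 * (bb[4] - bb[2])) -
                         (bb[4] - bb[2]))
    ctr <- grid_centers(grid)
    u <- (ctr$lon - bb[1]) / (bb[3] - bb[1])
    v <- (ctr$lat - bb[2]) / (bb[4] - bb[2])
    ph <- runif(4, 0, 2 * pi)
    elev <- 300 + 250 * u + 120 * v +
      80 * sin(2 * pi * u + ph[1]) * cos(pi * v + ph[2]) +
      50 * sin(3 * pi * v + ph[3]) * cos(2 * pi * u + ph[4])
    elevation <- precip_surface(grid, cfg$start_date,
                                matrix(elev, grid$n_rows, grid$n_cols,
                                       byrow = TRUE))
    stations <- data.frame(
      station_id = sprintf("S%03d", seq_len(cfg$n_stations)),
      lon = lon, lat = lat)
    stations$elevation_m <- as.vector(
      resample_point(elevation, stations$lon, stations$lat))
    list(stations = stations, elevation = elevation, grid = grid)
  })
}

# bilinear point sampling of a gridded layer, clamped at the edges
resample_point <- function(surface, lon, lat) {
  src <- surface$grid
  fc <- (lon - src$lon_min) / src$dx + 0.5
  fr <- (src$lat_max - lat) / src$dy + 0.5
  c0 <- pmin(pmax(floor(fc), 1L), max(src$n_cols - 1L, 1L))
  r0 <- pmin(pmax(floor(fr), 1L), max(src$n_rows - 1L, 1L))
  tc <- pmin(pmax(fc - c0, 0), 1)
  tr <- pmin(pmax(fr - r0, 0), 1)
  c1 <- pmin(c0 + 1L, src$n_cols); r1 <- pmin(r0 + 1L, src$n_rows)
  v <- surface$values
  (1 - tr) * ((1 - tc) * v[cbind(r0, c0)] + tc * v[cbind(r0, c1)]) +
    tr * ((1 - tc) * v[cbind(r1, c0)] + tc * v[cbind(r1, c1)])
}

#' Generate daily precipitation: station observations and true fields
#'
#' Each day is dry everywhere with probability \code{1 - wet_day_prob}.  Wet
#' days draw a Gaussian random field with the configured variogram's
#' structured part (one dense covariance factorization over all requested
#' points, reused across days), add the regional wet-day mean and the
#' elevation effect, and truncate below zero -- which doubles as natural
#' zero inflation within wet days.  Station observations add independent
#' nugget noise to the true field; with a zero nugget they equal it.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param stations station data.frame (lon, lat, elevation_m), or NULL to
#'   simulate only at \code{extra_points}.
#' @param extra_points optional data.frame (lon, lat, elevation_m) of
#'   additional locations (e.g. trap sites or grid centers) where the true
#'   field is retained for oracle checks.
#' @return list with \code{dates}, \code{wet} (logical per day),
#'   \code{station_obs} and \code{true_station} (stations x days matrices,
#'   or NULL), \code{true_extra} (extra points x days matrix, or NULL).
#' @export
gen_precip_days <- function(cfg, stations = NULL, extra_points = NULL) {
  if (is.null(stations) && is.null(extra_points))
    stop("nowhere to simulate: provide stations and/or extra_points")
  pts <- rbind(
    if (!is.null(stations))
      data.frame(lon = stations$lon, lat = stations$lat,
                 elevation_m = stations$elevation_m),
    if (!is.null(extra_points))
      data.frame(lon = extra_points$lon, lat = extra_points$lat,
                 elevation_m = extra_points$elevation_m))
  n_st <- if (is.null(stations)) 0L else nrow(stations)
  xy <- project_local(pts$lon, pts$lat,
                      c(mean(cfg$bbox[c(1, 3)]), mean(cfg$bbox[c(2, 4)])))
  vg <- cfg$true_variogram
  C <- vg$psill * vgm_corr(as.matrix(dist(xy)), vg)
  diag(C) <- diag(C) + 1e-10
  L <- tryCatch(chol(C), error = function(e)
    stop("covariance not positive-definite; increase jitter or thin points"))
  mu <- cfg$wet_mean + cfg$elevation_effect * pts$elevation_m / 1000
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1L
  with_seed(cfg$seed + 202L, {
    wet <- runif(cfg$n_days) < cfg$wet_day_prob
    truth <- matrix(0, nrow(pts), cfg$n_days)
    for (d in which(wet))
      truth[, d] <- pmax(mu + as.vector(crossprod(L, rnorm(nrow(pts)))), 0)
    station_obs <- NULL; true_station <- NULL
    if (n_st > 0) {
      true_station <- truth[seq_len(n_st), , drop = FALSE]
      noise <- matrix(rnorm(n_st * cfg$n_days, 0, sqrt(vg$nugget)),
                      n_st, cfg$n_days)
      noise[, !wet] <- 0
      station_obs <- pmax(true_station + noise, 0)
    }
    true_extra <- if (is.null(extra_points)) NULL else
      truth[n_st + seq_len(nrow(pts) - n_st), , drop = FALSE]
    list(dates = dates, wet = wet,
         station_obs = station_obs, true_station = true_station,
         true_extra = true_extra)
  })
}

#' Lay out the trap grid
#'
#' Traps sit on a regular grid at the configured spacing (default one per
#' square mile), inset half a spacing from the bounding-box edges, with their
#' elevation sampled from the elevation layer when given.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param elevation optional elevation layer for trap elevations.
#' @return data.frame trap_id, lon, lat, elevation_m.
#' @export
gen_traps <- function(cfg, elevation = NULL) {
  bb <- cfg$bbox
  mile_m <- 1609.344
  dlat <- cfg$trap_spacing * mile_m / 111320
  lat0 <- mean(bb[c(2, 4)])
  dlon <- dlat / cos(lat0 * pi / 180)
  lons <- seq(bb[1] + dlon / 2, bb[3] - dlon / 2, by = dlon)
  lats <- seq(bb[2] + dlat / 2, bb[4] - dlat / 2, by = dlat)
  traps <- expand.grid(lon = lons, lat = lats)
  traps <- data.frame(trap_id = sprintf("T%04d", seq_len(nrow(traps))),
                      lon = traps$lon, lat = traps$lat)
  traps$elevation_m <- if (is.null(elevation)) 0 else
    resample_point(elevation, traps$lon, traps$lat)
  traps
}

#' Generate trap events with known-truth lag effects
#'
#' Each trap is serviced weekly (with a per-trap jittered weekday) from day
#' 21 onward.  For every event the true 20-day lag vector is read from the
#' true fields and cleaned with the measurability rule; presence is drawn
#' from a logistic model on the lags (plus any cumulative terms) and female
#' counts follow a hurdle: zero when absent, otherwise 1 plus a negative
#' binomial with log-mean linear in the same lags.  Male counts are an
#' independent draw at ~46% of the female mean.  A truth table with the
#' per-event lag vectors accompanies the events.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param fields output of \code{\link{gen_precip_days}} whose
#'   \code{true_extra} rows correspond to \code{traps}.
#' @param traps trap table from \code{\link{gen_traps}}.
#' @return list with \code{events} (trap-event schema) and \code{truth}
#'   (lag-matrix schema with the true lag vectors) and \code{params}.
#' @export
gen_trap_events <- function(cfg, fields, traps) {
  stopifnot(cfg$n_days >= lag_days + 1,
            nrow(traps) == nrow(fields$true_extra))
  with_seed(cfg$seed + 303L, {
    offsets <- sample.int(7, nrow(traps), replace = TRUE) - 1L
    ev <- do.call(rbind, lapply(seq_len(nrow(traps)), function(i) {
      days <- seq(lag_days + 1L + offsets[i], cfg$n_days, by = 7L)
      if (!length(days)) return(NULL)
      data.frame(trap = i, day = days)
    }))
    n <- nrow(ev)
    lags <- matrix(NA_real_, n, lag_days,
                   dimnames = list(NULL, paste0("lag", seq_len(lag_days))))
    for (k in seq_len(lag_days))
      lags[, k] <- clean_precip(
        fields$true_extra[cbind(ev$trap, ev$day - k)])
    cum10 <- rowSums(lags[, 1:10, drop = FALSE])
    cum20 <- rowSums(lags)
    lin <- function(eff, cum) {
      eff[1] + as.vector(lags %*% eff[-1]) +
        cum[1] * cum10 + cum[2] * cum20
    }
    eta_p <- lin(cfg$lag_effects$presence, cfg$cum_effects$presence)
    mu_a <- exp(lin(cfg$lag_effects$abundance, cfg$cum_effects$abundance))
    present <- runif(n) < plogis(eta_p)
    female <- integer(n)
    female[present] <- 1L + rnbinom(sum(present), size = cfg$dispersion,
                                    mu = mu_a[present])
    male_present <- runif(n) < plogis(eta_p)
    male <- integer(n)
    male[male_present] <- rnbinom(sum(male_present), size = cfg$dispersion,
                                  mu = 0.46 * mu_a[male_present])
    dates <- fields$dates[ev$day]
    events <- data.frame(
      trap_id = traps$trap_id[ev$trap],
      lon = traps$lon[ev$trap], lat = traps$lat[ev$trap],
      trap_type = "CO2",
      collection_date = dates,
      female_count = female, male_count = male,
      presence = female >= 1)
    truth <- data.frame(trap_id = events$trap_id,
                        collection_date = dates,
                        presence = events$presence,
                        female_count = female)
    truth <- cbind(truth, as.data.frame(lags))
    truth$cum10 <- cum10
    truth$cum20 <- cum20
    list(events = events, truth = truth,
         params = list(lag_effects = cfg$lag_effects,
                       cum_effects = cfg$cum_effects))
  })
}

#' Generate a thinned lag matrix directly from the generator's truth
#'
#' Convenience wrapper for model and screening studies: simulates the true
#' precipitation fields at the trap locations only, generates events, thins
#' to one per trap-month, and returns the first \code{n_events} rows of the
#' truth lag matrix (stable trap/date order).
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param n_events optional cap on returned rows.
#' @return thinned lag matrix (\code{\link{build_lag_matrix}} schema).
#' @export
gen_lag_matrix <- function(cfg, n_events = NULL) {
  traps <- gen_traps(cfg)
  fields <- gen_precip_days(cfg, stations = NULL, extra_points = traps)
  sim <- gen_trap_events(cfg, fields, traps)
  lm <- build_lag_matrix(thin_events(sim$truth))
  if (!is.null(n_events)) {
    if (nrow(lm) < n_events)
      stop(sprintf("generator produced %d thinned events; %d requested",
                   nrow(lm), n_events))
    lm <- lm[seq_len(n_events), , drop = FALSE]
  }
  lm
}

#' Generate the full synthetic study bundle
#'
#' Stations + elevation, daily precipitation (station observations and true
#' fields at both stations and traps), the trap grid and its events with
#' known-truth lag vectors.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return list with \code{stations}, \code{elevation}, \code{grid},
#'   \code{traps}, \code{fields}, \code{events}, \code{truth},
#'   \code{params}.
#' @export
gen_study <- function(cfg) {
  net <- gen_stations_and_elevation(cfg)
  traps <- gen_traps(cfg, net$elevation)
  fields <- gen_precip_days(cfg, stations = net$stations,
                            extra_points = traps)
  sim <- gen_trap_events(cfg, fields, traps)
  c(net, list(traps = traps, fields = fields,
              events = sim$events, truth = sim$truth, params = sim$params))
}

#' Write one day's station observations as a station-day table
#'
#' Helper to materialize generator output in the \code{\link{read_stations}}
#' CSV schema.
#'
#' @param stations station table.
#' @param fields \code{\link{gen_precip_days}} output with
#'   \code{station_obs}.
#' @return data.frame in the station-day schema (all days, long format).
#' @export
stations_long <- function(stations, fields) {
  n_d <- length(fields$dates)
  data.frame(
    station_id = rep(stations$station_id, times = n_d),
    lon = rep(stations$lon, times = n_d),
    lat = rep(stations$lat, times = n_d),
    elevation_m = rep(stations$elevation_m, times = n_d),
    date = rep(fields$dates, each = nrow(stations)),
    precip_in = as.vector(fields$station_obs)
  )
}
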