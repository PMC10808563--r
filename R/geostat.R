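#' Project lon/lat to a local planar system
#'
#' Transverse-Mercator-style local projection centered on the data: meters
#' east/north of the center, with the east axis scaled by cos(latitude of the
#' center).  Adequate for county-scale extents, where planar distances differ
#' negligibly from geodesic ones.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param center optional \code{c(lon0, lat0)}; defaults to the data midpoint.
#' @return two-column matrix (x, y) in meters, with the center stored in
#'   attribute \code{"center"}.
#' @export
project_local <- function(lon, lat, center = NULL) {
  if (is.null(center))
    center <- c(mean(range(lon)), mean(range(lat)))
  R <- 6378137
  deg <- pi / 180
  xy <- cbind(x = (lon - center[1]) * deg * R * cos(center[2] * deg),
              y = (lat - center[2]) * deg * R)
  attr(xy, "center") <- center
  xy
}

#' Empirical semivariogram
#'
#' Bins all point pairs by separation distance up to \code{cutoff} and
#' averages half the squared value differences within each bin.  Bin centers
#' are the mean pair distances; empty bins are dropped.
#'
#' @param coords two-column matrix of planar coordinates (meters).
#' @param values numeric vector of observations at \code{coords}.
#' @param n_bins number of distance bins (default 15).
#' @param cutoff maximum pair distance; defaults to one third of the
#'   bounding-box diagonal of \code{coords}.
#' @return data.frame of class \code{empirical_variogram} with columns
#'   \code{dist}, \code{gamma}, \code{np}.
#' @export
empirical_semivariogram <- function(coords, values, n_bins = 15, cutoff = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2, nrow(coords) == length(values))
  d <- as.vector(dist(coords))
  if (all(d == 0))
    stop("all points share one location: no pairs with positive separation")
  if (is.null(cutoff)) {
    spans <- apply(coords, 2, function(z) diff(range(z)))
    cutoff <- sqrt(sum(spans^2)) / 3
  }
  stopifnot(cutoff > 0)
  dz <- as.vector(dist(values))            # |z_i - z_j| over the same pairs
  g <- 0.5 * dz^2
  keep <- d > 0 & d <= cutoff
  if (!any(keep)) stop("no point pairs within the cutoff distance")
  d <- d[keep]; g <- g[keep]
  bin <- cut(d, breaks = seq(0, cutoff, length.out = n_bins + 1),
             include.lowest = TRUE)
  out <- data.frame(
    dist = as.vector(tapply(d, bin, mean)),
    gamma = as.vector(tapply(g, bin, mean)),
    np = as.vector(tapply(d, bin, length))
  )
  out <- out[!is.na(out$np) & out$np >= 1, , drop = FALSE]
  out <- out[order(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Automatic initial variogram parameters
#'
#' The initialization used for automatic fitting: the initial sill is the mean
#' of the maximum and the median of the binned semivariances, the initial
#' range is 0.1 times the diagonal of the data bounding box, and the initial
#' nugget is the minimum semivariance.
#'
#' @param emp an \code{empirical_variogram}.
#' @param bbox \code{c(xmin, ymin, xmax, ymax)} in the same planar units as
#'   the variogram distances.
#' @return list with \code{sill0}, \code{range0}, \code{nugget0}.
#' @export
initial_params <- function(emp, bbox) {
  stopifnot(nrow(emp) >= 1, length(bbox) == 4)
  list(
    sill0 = (max(emp$gamma) + median(emp$gamma)) / 2,
    range0 = 0.1 * sqrt((bbox[3] - bbox[1])^2 + (bbox[4] - bbox[2])^2),
    nugget0 = min(emp$gamma)
  )
}

#' Parametric variogram model
#'
#' @param family one of \code{"spherical"}, \code{"exponential"},
#'   \code{"gaussian"}, \code{"matern"}.
#' @param nugget micro-scale variance, (inches)^2; >= 0.
#' @param psill partial sill (structured variance); >= 0.
#' @param range correlation distance parameter, meters; > 0.
#' @param smoothness Matern smoothness (only used for \code{family =
#'   "matern"}).
#' @param fit_sse optional weighted residual sum of squares from fitting.
#' @return object of class \code{variogram_model}.
#' @export
vgm_model <- function(family = c("spherical", "exponential", "gaussian", "matern"),
                      nugget, psill, range, smoothness = 0.5, fit_sse = NA_real_) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0, smoothness > 0)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range,
                 smoothness = if (family == "matern") smoothness else NA_real_,
                 fit_sse = fit_sse),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s (nugget=%.4g, psill=%.4g, range=%.4g m%s%s)\n",
              x$family, x$nugget, x$psill, x$range,
              if (is.finite(x$smoothness)) sprintf(", nu=%g", x$smoothness) else "",
              if (is.finite(x$fit_sse)) sprintf(", wSSE=%.3g", x$fit_sse) else ""))
  invisible(x)
}

#' Model semivariance at distance h
#'
#' Evaluates the fitted model curve \eqn{\gamma(h)}; at \code{h = 0} this is
#' the nugget (the limit of the curve from above).  Spherical, exponential and
#' Gaussian curves are non-decreasing in h.
#'
#' @param h distances (meters), >= 0.
#' @param model a \code{variogram_model}.
#' @return semivariances, (inches)^2.
#' @export
vgm_gamma <- function(h, model) {
  if (any(h < 0)) stop("negative distance")
  n <- model$nugget; p <- model$psill; a <- model$range
  s <- switch(model$family,
    spherical = ifelse(h < a, 1.5 * h / a - 0.5 * (h / a)^3, 1),
    exponential = 1 - exp(-h / a),
    gaussian = 1 - exp(-(h / a)^2),
    matern = {
      nu <- model$smoothness
      ha <- h / a
      corr <- ifelse(ha == 0, 1,
                     (2^(1 - nu) / gamma(nu)) * ha^nu * besselK(ha, nu))
      1 - corr
    })
  n + p * s
}

# Semivariance as used inside the kriging system: gamma(0) = 0 exactly at
# zero separation (the nugget is a discontinuity at the origin), so kriging
# honors observations exactly when the target coincides with a station.
krige_gamma <- function(h, model) {
  g <- vgm_gamma(h, model)
  g[h == 0] <- 0
  g
}

#' Fit a variogram model by automatic weighted least squares
#'
#' For each candidate family, nugget, partial sill and range are fitted to the
#' empirical semivariogram by weighted least squares (weights
#' \code{np / dist^2}, the common automatic-fitting default) starting from the
#' initialization of \code{\link{initial_params}}; the family with the lowest
#' weighted SSE wins.  Matern smoothness is searched over \{0.5, 1, 2\}.
#' Families that fail to converge are skipped with a warning.
#'
#' @param emp an \code{empirical_variogram} with at least 3 bins.
#' @param families candidate families (default all four).
#' @param init optional list with \code{sill0}, \code{range0}, \code{nugget0};
#'   when omitted it is derived from the bin distances.
#' @param bbox optional planar bounding box passed to
#'   \code{\link{initial_params}}; defaults to a box with diagonal equal to
#'   1.5 times the largest bin distance.
#' @return the winning \code{variogram_model}.
#' @export
fit_variogram <- function(emp,
                          families = c("spherical", "exponential",
                                       "gaussian", "matern"),
                          init = NULL, bbox = NULL) {
  stopifnot(nrow(emp) >= 3)
  if (is.null(init)) {
    if (is.null(bbox)) {
      dmax <- 1.5 * max(emp$dist)
      bbox <- c(0, 0, dmax / sqrt(2), dmax / sqrt(2))
    }
    init <- initial_params(emp, bbox)
  }
  w <- emp$np / pmax(emp$dist, .Machine$double.eps)^2
  gscale <- max(emp$gamma, 1e-12)   # puts nugget/psill near unit scale
  # parameters optimized as (nugget, psill) / gscale and log(range)
  objective <- function(par, family, nu) {
    m <- list(family = family, nugget = par[1] * gscale,
              psill = par[2] * gscale, range = exp(par[3]), smoothness = nu)
    sum(w * (vgm_gamma(emp$dist, m) - emp$gamma)^2)
  }
  psill0 <- max(init$sill0 - init$nugget0, 1e-6 * gscale)
  range_starts <- pmax(init$range0, 1e-6) * c(1, 0.3, 3)
  dmax <- max(emp$dist)
  candidates <- list()
  for (fam in families) {
    nus <- if (fam == "matern") c(0.5, 1, 2) else NA_real_
    for (nu in nus) {
      best <- NULL
      for (r0 in range_starts) {
        fit <- tryCatch(
          stats::nlminb(c(init$nugget0 / gscale, psill0 / gscale, log(r0)),
                        objective, family = fam, nu = nu,
                        lower = c(0, 0, log(dmax * 1e-4)),
                        upper = c(Inf, Inf, log(dmax * 100)),
                        control = list(iter.max = 500, eval.max = 1000,
                                       rel.tol = 1e-12)),
          error = function(e) NULL)
        # accept any finite minimum: nlminb's nonzero codes ("false/singular
        # convergence") routinely fire on flat, overparameterized surfaces
        if (is.null(fit) || !is.finite(fit$objective)) next
        if (is.null(best) || fit$objective < best$objective) best <- fit
      }
      if (is.null(best)) {
        warning(sprintf("variogram family '%s'%s did not converge; skipped",
                        fam, if (is.finite(nu)) sprintf(" (nu=%g)", nu) else ""))
        next
      }
      candidates[[length(candidates) + 1L]] <-
        vgm_model(fam, best$par[1] * gscale, best$par[2] * gscale,
                  exp(best$par[3]),
                  smoothness = if (is.finite(nu)) nu else 0.5,
                  fit_sse = best$objective)
    }
  }
  if (length(candidates) == 0)
    stop("no variogram family converged")
  candidates[[which.min(vapply(candidates, `[[`, numeric(1), "fit_sse"))]]
}

## ---- kriging ----------------------------------------------------------------

# Average duplicated station locations (per-day) so the kriging system stays
# non-singular without discarding observations.
dedupe_stations <- function(coords, values, drift) {
  key <- paste(signif(coords[, 1], 12), signif(coords[, 2], 12))
  if (!anyDuplicated(key))
    return(list(coords = coords, values = values, drift = drift))
  agg <- function(v) as.vector(tapply(v, key, mean))
  keys <- !duplicated(key)
  ord <- match(unique(key), key[keys])
  list(coords = cbind(agg(coords[, 1]), agg(coords[, 2]))[ord, , drop = FALSE],
       values = agg(values)[ord], drift = agg(drift)[ord])
}

solve_ked <- function(coords, values, drift, tcoords, tdrift, model, date = NULL) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  # a spatially constant drift is collinear with the intercept: fall back to
  # ordinary kriging (the drift then carries no information anyway)
  use_drift <- sd(drift) > 1e-8 * max(abs(drift), 1)
  d0 <- sqrt(outer(coords[, 1], tcoords[, 1], "-")^2 +
             outer(coords[, 2], tcoords[, 2], "-")^2)
  if (use_drift) {
    A <- rbind(cbind(krige_gamma(D, model), 1, drift),
               c(rep(1, n), 0, 0),
               c(drift, 0, 0))
    B <- rbind(krige_gamma(d0, model), 1, tdrift)
  } else {
    A <- rbind(cbind(krige_gamma(D, model), 1),
               c(rep(1, n), 0))
    B <- rbind(krige_gamma(d0, model), 1)
  }
  sol <- tryCatch(solve(A, B), error = function(e)
    stop(sprintf("singular kriging system%s: %s",
                 if (is.null(date)) "" else paste0(" on ", format(date)),
                 conditionMessage(e))))
  lambda <- sol[seq_len(n), , drop = FALSE]
  list(prediction = as.vector(crossprod(lambda, values)),
       variance = pmax(colSums(sol * B), 0),
       weights = lambda)
}

#' Kriging with an elevation drift
#'
#' Predicts precipitation at target locations from one day's station
#' observations by kriging with external drift: the mean model is an intercept
#' plus a linear elevation term, solved through the augmented kriging system.
#' Station weights sum to 1 for every target (unbiasedness), and with a zero
#' nugget the prediction at a station location equals its observation.
#' Predictions are passed through \code{\link{clean_precip}} unless
#' \code{clean = FALSE}.
#'
#' @param coords two-column matrix of station planar coordinates (meters);
#'   duplicated locations are averaged.
#' @param values station observations, inches.
#' @param drift elevation at the stations (meters).
#' @param tcoords two-column matrix of target coordinates.
#' @param tdrift elevation at the targets.
#' @param model a \code{variogram_model}.
#' @param max_neighbors cap on the number of nearest stations used per target
#'   (default 64); \code{Inf} uses all stations globally.
#' @param clean apply the measurable-precipitation cleaning rule to
#'   predictions (default TRUE).
#' @param date optional date used in error messages.
#' @return list with \code{prediction} (length = targets), \code{variance},
#'   and \code{weights} (stations x targets matrix of kriging weights;
#'   NA-padded when a neighbor cap is active).
#' @export
krige_points <- function(coords, values, drift, tcoords, tdrift, model,
                         max_neighbors = 64, clean = TRUE, date = NULL) {
  coords <- as.matrix(coords); tcoords <- as.matrix(tcoords)
  dd <- dedupe_stations(coords, values, drift)
  coords <- dd$coords; values <- dd$values; drift <- dd$drift
  n <- nrow(coords)
  if (n < 3) stop("kriging requires at least 3 distinct station locations")
  m <- nrow(tcoords)
  if (n <= max_neighbors) {
    res <- solve_ked(coords, values, drift, tcoords, tdrift, model, date)
  } else {
    pred <- numeric(m); vr <- numeric(m)
    wts <- matrix(NA_real_, n, m)
    for (j in seq_len(m)) {
      dj <- (coords[, 1] - tcoords[j, 1])^2 + (coords[, 2] - tcoords[j, 2])^2
      nb <- order(dj)[seq_len(max_neighbors)]
      r <- solve_ked(coords[nb, , drop = FALSE], values[nb], drift[nb],
                     tcoords[j, , drop = FALSE], tdrift[j], model, date)
      pred[j] <- r$prediction; vr[j] <- r$variance
      wts[nb, j] <- r$weights[, 1]
    }
    res <- list(prediction = pred, variance = vr, weights = wts)
  }
  if (clean) res$prediction <- clean_precip(res$prediction)
  res
}

#' Bilinear resampling of a gridded surface onto another grid
#'
#' Interpolates between the four surrounding cell centers of the source grid,
#' clamping at the edges.  Used to bring an elevation grid onto the analysis
#' grid.
#'
#' @param surface a \code{precip_surface}-like object (any gridded layer).
#' @param grid target \code{grid_spec}.
#' @return numeric matrix on the target grid.
#' @export
resample_bilinear <- function(surface, grid) {
  ctr <- grid_centers(grid)
  matrix(resample_point(surface, ctr$lon, ctr$lat),
         grid$n_rows, grid$n_cols, byrow = TRUE)
}

#' Build one day's precipitation surface from station data
#'
#' Fits that day's variogram (unless a pooled model is supplied via
#' \code{vgm_policy}) and kriges every cell center of the analysis grid with
#' elevation as the drift.  Days on which every station reports zero
#' short-circuit to an all-zero surface; days with a spatially constant
#' positive value return that constant.  Fewer than 3 reporting stations
#' yields an all-missing surface with a warning.
#'
#' @param stations_day data.frame with columns \code{lon}, \code{lat},
#'   \code{elevation_m}, \code{precip_in} (one date).
#' @param elevation elevation layer: a \code{precip_surface}-like object whose
#'   values are meters; resampled bilinearly onto \code{grid} if the grids
#'   differ.
#' @param grid analysis \code{grid_spec}.
#' @param date the surface date.
#' @param vgm_policy list: \code{model} (a \code{variogram_model} to reuse, or
#'   NULL to re-fit daily), \code{families}, \code{n_bins}, \code{cutoff}.
#' @param max_neighbors passed to \code{\link{krige_points}}.
#' @return a \code{precip_surface} with a variance layer.
#' @export
make_daily_surface <- function(stations_day, elevation, grid, date,
                               vgm_policy = list(), max_neighbors = 64) {
  vals <- clean_precip(stations_day$precip_in)
  empty <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  if (nrow(stations_day) < 3) {
    warning(sprintf("%s: only %d reporting station(s); surface is all-missing",
                    format(date), nrow(stations_day)))
    return(precip_surface(grid, date, empty))
  }
  if (all(vals == 0))
    return(precip_surface(grid, date,
                          matrix(0, grid$n_rows, grid$n_cols),
                          matrix(0, grid$n_rows, grid$n_cols)))
  if (var(vals) == 0)
    return(precip_surface(grid, date,
                          matrix(vals[1], grid$n_rows, grid$n_cols),
                          matrix(0, grid$n_rows, grid$n_cols)))
  ctr <- grid_centers(grid)
  center <- c(mean(c(grid$lon_min, grid$lon_max)),
              mean(c(grid$lat_min, grid$lat_max)))
  sxy <- project_local(stations_day$lon, stations_day$lat, center)
  txy <- project_local(ctr$lon, ctr$lat, center)
  elev_grid <- if (identical(unclass(elevation$grid), unclass(grid)))
    elevation$values else resample_bilinear(elevation, grid)
  telev <- as.vector(t(elev_grid))   # row-major, matching grid_centers order
  model <- vgm_policy$model
  if (is.null(model)) {
    emp <- empirical_semivariogram(
      sxy, vals,
      n_bins = if (is.null(vgm_policy$n_bins)) 15 else vgm_policy$n_bins,
      cutoff = vgm_policy$cutoff)
    bbox <- c(min(sxy[, 1]), min(sxy[, 2]), max(sxy[, 1]), max(sxy[, 2]))
    fams <- if (is.null(vgm_policy$families))
      c("spherical", "exponential", "gaussian", "matern") else vgm_policy$families
    model <- fit_variogram(emp, families = fams, bbox = bbox)
  }
  kr <- krige_points(sxy, vals, stations_day$elevation_m, txy, telev, model,
                     max_neighbors = max_neighbors, clean = TRUE, date = date)
  precip_surface(grid, date,
                 matrix(kr$prediction, grid$n_rows, grid$n_cols, byrow = TRUE),
                 matrix(kr$variance, grid$n_rows, grid$n_cols, byrow = TRUE))
}
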