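test_that("empirical semivariogram matches pair enumeration", {
  # collinear 3-point configuration, by hand: gamma(1000)=0.5, gamma(2000)=2
  xy <- cbind(c(0, 1000, 2000), c(0, 0, 0))
  emp <- empirical_semivariogram(xy, c(0, 1, 2), n_bins = 4, cutoff = 2000)
  expect_equal(emp$gamma[emp$dist == 1000], 0.5)
  expect_equal(emp$gamma[emp$dist == 2000], 2.0)
  expect_equal(emp$np[emp$dist == 1000], 2)

  # constant field: zero semivariance in every bin
  emp0 <- empirical_semivariogram(cbind(runif(20), runif(20)) * 1000,
                                  rep(3.2, 20), n_bins = 6)
  expect_true(all(emp0$gamma == 0))

  # random instance against the brute-force pair enumerator
  set.seed(7)
  xy <- cbind(runif(40, 0, 5000), runif(40, 0, 5000))
  z <- rnorm(40)
  cutoff <- 4000; n_bins <- 8
  emp <- empirical_semivariogram(xy, z, n_bins = n_bins, cutoff = cutoff)
  oracle <- semivariogram_bruteforce(xy, z, seq(0, cutoff, length.out = n_bins + 1))
  expect_equal(emp$dist, oracle$dist, tolerance = 1e-12)
  expect_equal(emp$gamma, oracle$gamma, tolerance = 1e-12)
  expect_equal(emp$np, oracle$np)

  expect_error(empirical_semivariogram(cbind(c(1, 1), c(2, 2)), c(0, 1)),
               "no pairs")
})

test_that("automatic initialization follows the max/median sill, 0.1-diagonal range, min nugget rule", {
  emp <- structure(data.frame(dist = c(1, 2, 3), gamma = c(0.2, 0.4, 1.0),
                              np = c(5, 5, 5)),
                   class = c("empirical_variogram", "data.frame"))
  ip <- initial_params(emp, c(0, 0, 3000, 4000))
  expect_equal(ip$sill0, 0.7)
  expect_equal(ip$nugget0, 0.2)
  expect_equal(ip$range0, 0.1 * 5000)
  emp$gamma <- rep(0.3, 3)
  ip <- initial_params(emp, c(0, 0, 3000, 4000))
  expect_equal(ip$sill0, 0.3)
  expect_equal(ip$nugget0, 0.3)
})

test_that("model curves honor their closed forms and monotonicity", {
  for (fam in c("spherical", "exponential", "gaussian", "matern")) {
    m <- vgm_model(fam, nugget = 0.1, psill = 0.9, range = 5000,
                   smoothness = 1.5)
    expect_equal(vgm_gamma(0, m), 0.1, info = fam)   # gamma(0) = nugget
  }
  sph <- vgm_model("spherical", 0.1, 0.9, 5000)
  expect_equal(vgm_gamma(5000, sph), 1.0)            # sill reached at range
  ex <- vgm_model("exponential", 0.1, 0.9, 5000)
  expect_equal(vgm_gamma(5000, ex), 0.1 + 0.9 * (1 - exp(-1)))
  h <- seq(0, 20000, by = 50)
  for (fam in c("spherical", "exponential", "gaussian")) {
    m <- vgm_model(fam, 0.05, 1, 4000)
    expect_true(all(diff(vgm_gamma(h, m)) >= -1e-12), info = fam)
  }
  # Matern with smoothness 0.5 collapses to the exponential curve
  expect_equal(vgm_gamma(h, vgm_model("matern", 0.1, 0.9, 5000, 0.5)),
               vgm_gamma(h, ex), tolerance = 1e-10)
  expect_error(vgm_gamma(-1, ex), "negative")
})

test_that("fitting recovers parameters from noiseless model curves within 1%", {
  truth <- vgm_model("spherical", nugget = 0.1, psill = 0.9, range = 5000)
  h <- seq(200, 12000, length.out = 20)
  emp <- structure(data.frame(dist = h, gamma = vgm_gamma(h, truth),
                              np = rep(30, 20)),
                   class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram(emp, bbox = c(0, 0, 9000, 9000))
  expect_equal(fit$family, "spherical")
  expect_equal(fit$nugget, 0.1, tolerance = 0.01)
  expect_equal(fit$psill, 0.9, tolerance = 0.01)
  expect_equal(fit$range, 5000, tolerance = 0.01)

  # pure-nugget data: flat semivariance collapses onto the nugget
  empn <- structure(data.frame(dist = h, gamma = rep(0.4, 20), np = rep(10, 20)),
                    class = c("empirical_variogram", "data.frame"))
  fitn <- fit_variogram(empn, bbox = c(0, 0, 9000, 9000))
  expect_lt(max(abs(vgm_gamma(h, fitn) - 0.4)), 0.01)  # flat curve at c
  expect_equal(fitn$nugget, 0.4, tolerance = 0.05)
})

test_that("the generating family wins the plurality over simulated exponential fields", {
  # Matern(0.5) duplicates the exponential curve exactly, so the
  # identifiability check runs over the three distinguishable families.
  # A single realization's binned variogram deviates from the model curve
  # (finite-domain fluctuation), so family identification is a plurality,
  # not a near-certainty.
  tally <- character(20)
  for (seed in 1:20) {
    set.seed(seed)
    n <- 500
    xy <- cbind(runif(n, 0, 30000), runif(n, 0, 30000))
    truth <- vgm_model("exponential", nugget = 0.02, psill = 1, range = 6000)
    C <- truth$psill * exp(-as.matrix(dist(xy)) / truth$range)
    z <- drop(crossprod(chol(C + (truth$nugget + 1e-10) * diag(n)), rnorm(n)))
    emp <- empirical_semivariogram(xy, z, n_bins = 14)
    fit <- suppressWarnings(
      fit_variogram(emp, families = c("spherical", "exponential", "gaussian"),
                    bbox = c(0, 0, 30000, 30000)))
    tally[seed] <- fit$family
  }
  wins <- table(tally)
  expect_equal(names(which.max(wins)), "exponential")
  expect_gte(wins[["exponential"]], 12)
})

test_that("kriging with drift is exact, unbiased, and honors flat fields", {
  set.seed(11)
  xy <- cbind(runif(8, 0, 10000), runif(8, 0, 10000))
  z <- runif(8, 0.5, 3)
  elev <- runif(8, 300, 700)
  m0 <- vgm_model("exponential", nugget = 0, psill = 0.5, range = 4000)
  kr <- krige_points(xy, z, elev, xy, elev, m0, clean = FALSE)
  expect_lt(max(abs(kr$prediction - z)), 1e-8)          # exact interpolation
  expect_lt(max(abs(colSums(kr$weights) - 1)), 1e-10)   # unbiasedness

  # constant observations, flat drift: prediction is that constant anywhere
  xyc <- cbind(c(0, 5000, 2500), c(0, 0, 4000))
  krc <- krige_points(xyc, rep(1.7, 3), rep(0, 3),
                      cbind(c(1000, 4000), c(1000, 2000)), c(0, 0),
                      m0, clean = FALSE)
  expect_equal(krc$prediction, c(1.7, 1.7), tolerance = 1e-10)
})

test_that("kriging agrees with an independent dense solve to 1e-8", {
  set.seed(5)
  for (rep in 1:3) {
    n <- 5 + rep
    xy <- cbind(runif(n, 0, 8000), runif(n, 0, 8000))
    z <- runif(n, 0, 2)
    elev <- runif(n, 200, 900)
    m <- vgm_model(c("spherical", "exponential", "gaussian")[rep],
                   nugget = 0.05, psill = 0.8, range = 3000)
    targets <- cbind(runif(4, 0, 8000), runif(4, 0, 8000))
    telev <- runif(4, 200, 900)
    kr <- krige_points(xy, z, elev, targets, telev, m, clean = FALSE)
    for (j in 1:4) {
      oracle <- krige_bruteforce(xy, z, elev, targets[j, ], telev[j], m)
      expect_lt(abs(kr$prediction[j] - oracle), 1e-8)
    }
  }
})

test_that("duplicate stations are averaged instead of breaking the system", {
  xy <- rbind(c(0, 0), c(0, 0), c(4000, 0), c(0, 4000))
  z <- c(1, 3, 2, 2)
  m <- vgm_model("exponential", 0, 1, 2000)
  kr <- krige_points(xy, z, rep(0, 4), cbind(0, 0), 0, m, clean = FALSE)
  expect_equal(kr$prediction, 2, tolerance = 1e-8)  # mean of the duplicates
})

test_that("daily surfaces short-circuit degenerate days and beat the mean predictor", {
  grid <- grid_spec(c(-112.2, 33.3, -112.0, 33.45), 12, 12)
  elev <- precip_surface(grid, as.Date("2015-01-01"),
                         matrix(400, 12, 12))
  dry <- data.frame(lon = runif(10, -112.2, -112.0),
                    lat = runif(10, 33.3, 33.45),
                    elevation_m = 400, precip_in = 0)
  s0 <- make_daily_surface(dry, elev, grid, as.Date("2015-07-01"))
  expect_true(all(s0$values == 0))
  expect_equal(dim(s0$values), c(12L, 12L))

  expect_warning(
    s_na <- make_daily_surface(dry[1:2, ], elev, grid, as.Date("2015-07-01")),
    "all-missing")
  expect_true(all(is.na(s_na$values)))

  # wet synthetic day from a known field: cell RMSE beats the station mean
  cfg <- small_cfg(seed = 4, n_stations = 80, n_days = 40)
  net <- gen_stations_and_elevation(cfg)
  ctr <- grid_centers(grid)
  ctr_elev <- resample_point(net$elevation, ctr$lon, ctr$lat)
  pts <- data.frame(lon = ctr$lon, lat = ctr$lat, elevation_m = ctr_elev)
  fields <- gen_precip_days(cfg, stations = net$stations, extra_points = pts)
  wet <- which(fields$wet)[1]
  day <- data.frame(lon = net$stations$lon, lat = net$stations$lat,
                    elevation_m = net$stations$elevation_m,
                    precip_in = fields$station_obs[, wet])
  s <- make_daily_surface(day, net$elevation, grid, fields$dates[wet])
  truth <- clean_precip(fields$true_extra[, wet])
  rmse_krige <- sqrt(mean((as.vector(t(s$values)) - truth)^2))
  rmse_mean <- sqrt(mean((mean(clean_precip(day$precip_in)) - truth)^2))
  expect_lt(rmse_krige, rmse_mean)
})

test_that("leave-one-out kriging beats the daily station mean on structured fields", {
  cfg <- small_cfg(seed = 9, n_stations = 60, n_days = 30)
  net <- gen_stations_and_elevation(cfg)
  fields <- gen_precip_days(cfg, stations = net$stations)
  wet <- which(fields$wet)[1]
  obs <- clean_precip(fields$station_obs[, wet])
  xy <- project_local(net$stations$lon, net$stations$lat)
  model <- cfg$true_variogram
  loo <- vapply(seq_len(nrow(xy)), function(i) {
    krige_points(xy[-i, ], obs[-i], net$stations$elevation_m[-i],
                 xy[i, , drop = FALSE], net$stations$elevation_m[i],
                 model, clean = FALSE)$prediction
  }, numeric(1))
  base <- vapply(seq_len(nrow(xy)), function(i) mean(obs[-i]), numeric(1))
  expect_lt(sqrt(mean((loo - obs)^2)), sqrt(mean((base - obs)^2)))
})
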