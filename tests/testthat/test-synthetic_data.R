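test_that("every generator output is a pure function of the configuration", {
  cfg <- small_cfg(seed = 51)
  a <- gen_stations_and_elevation(cfg)
  b <- gen_stations_and_elevation(cfg)
  expect_identical(a, b)
  expect_identical(gen_lag_matrix(small_cfg(seed = 51), n_events = 50),
                   gen_lag_matrix(small_cfg(seed = 51), n_events = 50))
  # and a different seed changes the draw
  expect_false(identical(a$stations,
                         gen_stations_and_elevation(small_cfg(seed = 52))$stations))
})

test_that("stations stay inside the box and minimal networks are valid", {
  cfg <- small_cfg(seed = 53)
  net <- gen_stations_and_elevation(cfg)
  bb <- cfg$bbox
  expect_true(all(net$stations$lon >= bb[1] & net$stations$lon <= bb[3]))
  expect_true(all(net$stations$lat >= bb[2] & net$stations$lat <= bb[4]))
  expect_equal(nrow(net$stations), 30)

  tiny <- gen_stations_and_elevation(small_cfg(seed = 54, n_stations = 3))
  expect_equal(nrow(tiny$stations), 3)
})

test_that("dry configurations and zero nuggets behave as limits", {
  cfg_dry <- small_cfg(seed = 55, wet_day_prob = 0)
  net <- gen_stations_and_elevation(cfg_dry)
  f <- gen_precip_days(cfg_dry, stations = net$stations)
  expect_true(all(f$station_obs == 0))
  expect_false(any(f$wet))

  cfg0 <- small_cfg(seed = 56,
                    true_variogram = vgm_model("exponential", nugget = 0,
                                               psill = 9e-3, range = 15000))
  net0 <- gen_stations_and_elevation(cfg0)
  f0 <- gen_precip_days(cfg0, stations = net0$stations)
  expect_identical(f0$station_obs, f0$true_station)
})

test_that("a wet-day draw reproduces the configured variogram at mid range", {
  cfg <- synthetic_config(seed = 57, bbox = c(-112.4, 33.2, -111.9, 33.7),
                          n_days = 30, wet_day_prob = 1,
                          elevation_effect = 0)
  with_seed_test(571, {
    pts <- data.frame(lon = runif(500, -112.4, -111.9),
                      lat = runif(500, 33.2, 33.7),
                      elevation_m = 0)
    f <- gen_precip_days(cfg, stations = NULL, extra_points = pts)
    # average the empirical variogram of the latent wet field over days to
    # curb Monte-Carlo noise, then compare at mid-range distances
    xy <- project_local(pts$lon, pts$lat)
    vg <- cfg$true_variogram
    days <- 1:8
    emps <- lapply(days, function(d)
      empirical_semivariogram(xy, f$true_extra[, d], n_bins = 12,
                              cutoff = 30000))
    gbar <- rowMeans(sapply(emps, `[[`, "gamma"))
    dbar <- rowMeans(sapply(emps, `[[`, "dist"))
    mid <- dbar > 8000 & dbar < 25000
    # truncation at zero shrinks variance relative to the latent Gaussian
    # field, so allow 20% plus the truncation bias
    truth <- vgm_gamma(dbar[mid], vg)
    expect_lt(max(abs(gbar[mid] - truth) / truth), 0.35)
  })
})

test_that("generated events satisfy the trap-event and lag-row invariants", {
  cfg <- small_cfg(seed = 58)
  study <- gen_study(cfg)
  ev <- study$events
  expect_true(all(ev$female_count >= 0 & ev$male_count >= 0))
  expect_identical(ev$presence, ev$female_count >= 1L)
  expect_true(all(ev$trap_type == "CO2"))
  expect_true(all(study$truth$cum20 >= study$truth$cum10))
  lagvals <- as.matrix(study$truth[paste0("lag", 1:20)])
  expect_true(all(lagvals >= 0))
  expect_false(any(lagvals > 0 & lagvals < 0.01))  # already cleaned

  # weekly cadence per trap
  one <- ev[ev$trap_id == ev$trap_id[1], ]
  expect_true(all(diff(sort(one$collection_date)) == 7))

  # the station-day long table round-trips through the CSV reader
  p <- withr::local_tempfile(fileext = ".csv")
  sl <- stations_long(study$stations, study$fields)
  write.csv(sl, p, row.names = FALSE)
  st <- read_stations(p)
  expect_equal(nrow(st), nrow(sl))
  expect_equal(st$precip_in, sl$precip_in, tolerance = 1e-12)
})

test_that("kriging the synthetic stations recovers truer lags with more stations", {
  # one fixed simulated field; only the reporting-network density varies,
  # with the sparse network a subset of the dense one
  cfg <- small_cfg(seed = 59, n_stations = 100, n_days = 30)
  net <- gen_stations_and_elevation(cfg)
  traps <- gen_traps(cfg, net$elevation)
  traps <- traps[seq(1, nrow(traps), by = 12), ]   # a handful of traps
  fields <- gen_precip_days(cfg, stations = net$stations,
                            extra_points = traps)
  grid <- grid_spec(cfg$bbox, 15, 15)
  truth_lags <- t(vapply(seq_len(nrow(traps)), function(i)
    clean_precip(fields$true_extra[i, cfg$n_days - (1:20)]), numeric(20)))
  lag_dates <- cfg$n_days - (1:20)
  maes <- vapply(c(25, 100), function(ns) {
    surf <- lapply(lag_dates, function(d) {
      day <- data.frame(lon = net$stations$lon[1:ns],
                        lat = net$stations$lat[1:ns],
                        elevation_m = net$stations$elevation_m[1:ns],
                        precip_in = fields$station_obs[1:ns, d])
      make_daily_surface(day, net$elevation, grid, fields$dates[d],
                         vgm_policy = list(model = cfg$true_variogram))
    })
    store <- surface_store(surfaces = surf)
    ev <- data.frame(trap_id = traps$trap_id, lon = traps$lon,
                     lat = traps$lat, trap_type = "CO2",
                     collection_date = fields$dates[cfg$n_days],
                     female_count = 0L, male_count = 0L)
    got <- extract_lags(ev, store)
    mean(abs(as.matrix(got[paste0("lag", 1:20)]) - truth_lags))
  }, numeric(1))
  expect_lt(maes[2], maes[1])
})
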