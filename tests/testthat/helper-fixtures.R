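# Shared fixtures, built in code at test time.

# Small study box (~18 x 17 km) keeping dense linear algebra cheap.
small_cfg <- function(seed = 1, n_stations = 30, n_days = 60, ...) {
  synthetic_config(seed = seed,
                   bbox = c(-112.2, 33.3, -112.0, 33.45),
                   n_stations = n_stations, n_days = n_days,
                   elev_grid_dims = c(20, 20), ...)
}

# A lag matrix of n rows from the generator's default effect structure.
make_lagmat <- function(seed = 1, n = 800, ...) {
  gen_lag_matrix(synthetic_config(seed = seed, ...), n_events = n)
}

# Uniform-valued surfaces covering `dates`, for lag-extraction arithmetic.
uniform_surfaces <- function(dates, value, grid = grid_spec(c(0, 0, 1, 1), 5, 5)) {
  surface_store(surfaces = lapply(dates, function(d)
    precip_surface(grid, d, matrix(value, grid$n_rows, grid$n_cols))))
}

# Synthetic cum20/count data with a planted plateau break at t0: below t0 the
# maximum count is pinned at `plateau_max`; just above t0 counts jump well
# beyond the plateau tolerance.
gen_threshold_data <- function(seed, n = 3000, t0 = 0.08, plateau_max = 175) {
  with_seed_test(seed, {
    n_below <- round(0.3 * n)
    cum_below <- runif(n_below, 1e-4, t0)
    cnt_below <- ifelse(runif(n_below) < 0.15, plateau_max,
                        sample(0:(plateau_max - 1), n_below, replace = TRUE))
    cum_above <- runif(n - n_below, t0 + 1e-6, 0.5)
    cnt_above <- plateau_max + 30 + stats::rpois(n - n_below, 40)
    data.frame(trap_id = sprintf("T%05d", seq_len(n)),
               collection_date = as.Date("2015-01-01") + seq_len(n) %% 300,
               female_count = c(cnt_below, cnt_above),
               presence = c(cnt_below, cnt_above) >= 1,
               cum20 = c(cum_below, cum_above))
  })
}

# seed-scoped RNG for helpers (tests must not leak RNG state)
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Independent brute-force oracles -------------------------------------------

# AUC as exhaustive pairwise concordance.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# Moran's I by direct evaluation of the double sum.
moran_bruteforce <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Empirical semivariogram by explicit pair enumeration into fixed bins.
semivariogram_bruteforce <- function(coords, values, breaks) {
  n <- nrow(coords)
  d <- c(); g <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, sqrt(sum((coords[i, ] - coords[j, ])^2)))
    g <- c(g, 0.5 * (values[i] - values[j])^2)
  }
  keep <- d > 0 & d <= max(breaks)
  d <- d[keep]; g <- g[keep]
  bin <- cut(d, breaks, include.lowest = TRUE)
  out <- data.frame(dist = as.vector(tapply(d, bin, mean)),
                    gamma = as.vector(tapply(g, bin, mean)),
                    np = as.vector(tapply(d, bin, length)))
  out[!is.na(out$np), , drop = FALSE]
}

# Kriging-with-drift by an independently coded dense solve, one target at a
# time, using the covariance-free semivariance formulation.
krige_bruteforce <- function(coords, values, drift, target, tdrift, model) {
  n <- nrow(coords)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    h <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    G[i, j] <- if (h == 0) 0 else vgm_gamma(h, model)
  }
  g0 <- vapply(seq_len(n), function(i) {
    h <- sqrt(sum((coords[i, ] - target)^2))
    if (h == 0) 0 else vgm_gamma(h, model)
  }, numeric(1))
  A <- cbind(rbind(G, 1, drift), c(rep(1, n), 0, 0), c(drift, 0, 0))
  b <- c(g0, 1, tdrift)
  sol <- solve(A, b)
  sum(sol[1:n] * values)
}
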