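#' Equal-sampling aggregation of trap histories
#'
#' Restricts to traps sampled at least \code{min_events} times, down-samples
#' busier traps to exactly \code{min_events} events (without replacement,
#' seeded), and sums female counts per surviving trap, so every location
#' contributes the same sampling effort to the spatial analysis.
#'
#' @param events trap-event data.frame.
#' @param min_events minimum (and exact, after down-sampling) number of
#'   events per trap (default 60).
#' @param seed integer seed for the random draws.
#' @return data.frame with one row per surviving trap: \code{trap_id},
#'   \code{lon}, \code{lat}, \code{n_events}, \code{female_total}.
#' @export
equal_sample <- function(events, min_events = 60, seed = 1) {
  stopifnot("trap_id" %in% names(events))
  counts <- table(events$trap_id)
  keep_ids <- sort(names(counts)[counts >= min_events])
  if (length(keep_ids) == 0)
    stop(sprintf("no trap has %d or more events", min_events))
  with_seed(seed, {
    rows <- lapply(keep_ids, function(id) {
      i <- which(events$trap_id == id)
      if (length(i) > min_events) i <- sort(sample(i, min_events))
      data.frame(trap_id = id,
                 lon = events$lon[i[1]], lat = events$lat[i[1]],
                 n_events = length(i),
                 female_total = sum(events$female_count[i]))
    })
    do.call(rbind, rows)
  })
}

# Inverse-distance or k-nearest-neighbor spatial weight matrix, zero diagonal.
spatial_weights <- function(coords, scheme = c("invdist", "knn"), k = 8,
                            row_standardize = FALSE) {
  scheme <- match.arg(scheme)
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  if (scheme == "invdist") {
    if (any(D[upper.tri(D)] == 0))
      stop("duplicate locations give infinite inverse-distance weights")
    W <- 1 / D
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(k + 1)]
      W[i, nb] <- 1
    }
  }
  diag(W) <- 0
  if (row_standardize) {
    rs <- rowSums(W); rs[rs == 0] <- 1
    W <- W / rs
  }
  W
}

#' Global Moran's I
#'
#' Measures spatial autocorrelation of values at point locations:
#' \deqn{I = (n / S_0) \sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar x) /
#'   \sum_i (x_i - \bar x)^2}
#' with expectation \eqn{-1/(n-1)} under no autocorrelation.  The standard
#' deviation and p-value come from the analytic normal approximation or from
#' seeded permutations of the values over the locations.
#'
#' @param values numeric vector, one value per location (non-constant).
#' @param coords two-column coordinate matrix (planar units).
#' @param weight_scheme \code{"invdist"} (inverse Euclidean distance, the
#'   default) or \code{"knn"}.
#' @param k neighbors for \code{"knn"}.
#' @param row_standardize row-standardize the weight matrix (default FALSE).
#' @param p_method \code{"analytic"} or \code{"permutation"}.
#' @param variance moment assumption for the analytic approximation:
#'   \code{"normality"} (default) or \code{"randomization"} (adjusts for the
#'   sample kurtosis, as under random permutation of the values).
#' @param n_perm permutations when \code{p_method = "permutation"} (>= 999).
#' @param seed seed for permutations.
#' @param W optional explicit weight matrix (overrides \code{weight_scheme});
#'   its diagonal is forced to zero.
#' @return list of class \code{moran_result}: \code{I_obs}, \code{I_exp},
#'   \code{sd}, \code{p}, \code{n}, \code{weight_scheme}.
#' @export
morans_i <- function(values, coords, weight_scheme = c("invdist", "knn"),
                     k = 8, row_standardize = FALSE,
                     p_method = c("analytic", "permutation"),
                     variance = c("normality", "randomization"),
                     n_perm = 999, seed = 1, W = NULL) {
  p_method <- match.arg(p_method)
  variance <- match.arg(variance)
  n <- length(values)
  stopifnot(n >= 3)
  if (var(values) == 0) stop("constant values: Moran's I undefined")
  if (is.null(W)) {
    weight_scheme <- match.arg(weight_scheme)
    W <- spatial_weights(coords, weight_scheme, k, row_standardize)
  } else {
    weight_scheme <- "user"
    W <- as.matrix(W)
    diag(W) <- 0
  }
  S0 <- sum(W)
  if (S0 <= 0) stop("weight matrix has no positive weights")
  z <- values - mean(values)
  denom <- sum(z^2)
  I_stat <- function(z) (n / S0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  I_obs <- I_stat(z)
  I_exp <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  var_I <- if (variance == "normality") {
    (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - I_exp^2
  } else {
    kur <- (sum(z^4) / n) / (denom / n)^2
    (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
       kur * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - I_exp^2
  }
  sd_I <- sqrt(max(var_I, 0))
  if (p_method == "analytic") {
    p <- 2 * stats::pnorm(abs(I_obs - I_exp) / sd_I, lower.tail = FALSE)
  } else {
    stopifnot(n_perm >= 999)
    perms <- with_seed(seed,
      vapply(seq_len(n_perm), function(i) I_stat(sample(z)), numeric(1)))
    p <- (1 + sum(abs(perms - I_exp) >= abs(I_obs - I_exp))) / (n_perm + 1)
  }
  structure(list(I_obs = I_obs, I_exp = I_exp, sd = sd_I, p = min(p, 1),
                 n = n, weight_scheme = weight_scheme),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I: I_obs=%.4f, I_exp=%.4f, sd=%.4f, p=%.3g (n=%d, %s weights)\n",
              x$I_obs, x$I_exp, x$sd, x$p, x$n, x$weight_scheme))
  invisible(x)
}

#' Median nearest-neighbor spacing of traps
#'
#' Median over locations of the distance to the nearest distinct other
#' location; duplicated coordinates are collapsed first, so the statistic is
#' invariant to repeated rows and to relabeling.
#'
#' @param coords two-column coordinate matrix (planar units).
#' @return median nearest-neighbor distance, same units as \code{coords}.
#' @export
median_trap_spacing <- function(coords) {
  coords <- unique(as.matrix(coords))
  stopifnot(nrow(coords) >= 2)
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  median(apply(D, 1, min))
}
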