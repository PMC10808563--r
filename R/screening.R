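#' Per-lag logistic screen of female presence
#'
#' Fits an independent intercept + slope logistic regression of presence on
#' each single day's precipitation, the univariate precursor to the joint
#' LASSO models.  Slopes come with Wald 95% confidence intervals.  A lag with
#' zero variance yields an NA row with a warning; complete separation is
#' flagged with an infinite-slope sentinel rather than an error.
#'
#' @param lagmat lag matrix from \code{\link{build_lag_matrix}} with both
#'   presence classes.
#' @return data.frame with columns \code{lag_day}, \code{effect} (logistic
#'   slope per inch), \code{ci_low}, \code{ci_high}, \code{n}, \code{note}.
#' @export
per_lag_presence_screen <- function(lagmat) {
  y <- lagmat$presence
  if (length(unique(y)) < 2)
    stop("presence outcome has a single class; screen undefined")
  res <- lapply(seq_len(lag_days), function(k) {
    x <- lagmat[[paste0("lag", k)]]
    n <- length(x)
    if (var(x) == 0) {
      warning(sprintf("lag %d has zero variance; slope undefined", k))
      return(data.frame(lag_day = k, effect = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n = n, note = "zero-variance"))
    }
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    sm <- summary(fit)$coefficients
    est <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
    separated <- !fit$converged || se > 1e3 * max(abs(est), 1)
    if (separated)
      return(data.frame(lag_day = k,
                        effect = sign(est) * Inf, ci_low = -Inf, ci_high = Inf,
                        n = n, note = "separation"))
    data.frame(lag_day = k, effect = est,
               ci_low = est - 1.959964 * se, ci_high = est + 1.959964 * se,
               n = n, note = "")
  })
  do.call(rbind, res)
}

#' Per-lag correlation screen of female abundance
#'
#' Pearson (default) or Spearman correlation between the female count and
#' each day's precipitation, with Fisher-z 95% confidence intervals.  The
#' \code{scope} argument restricts to events with at least one female, for
#' the variant that separates zeros from non-zero counts.
#'
#' @param lagmat lag matrix from \code{\link{build_lag_matrix}}.
#' @param scope \code{"all"} rows or \code{"positive"} (female count >= 1).
#' @param method correlation flavor, \code{"pearson"} or \code{"spearman"}.
#' @return data.frame with columns \code{lag_day}, \code{effect}
#'   (correlation), \code{ci_low}, \code{ci_high}, \code{n}, \code{note}.
#' @export
per_lag_abundance_screen <- function(lagmat, scope = c("all", "positive"),
                                     method = c("pearson", "spearman")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  if (scope == "positive")
    lagmat <- lagmat[lagmat$female_count >= 1, , drop = FALSE]
  if (nrow(lagmat) < 3)
    stop("fewer than 3 rows in scope; correlation undefined")
  y <- lagmat$female_count
  res <- lapply(seq_len(lag_days), function(k) {
    x <- lagmat[[paste0("lag", k)]]
    n <- length(x)
    if (var(x) == 0 || var(y) == 0) {
      warning(sprintf("lag %d: zero-variance column; correlation undefined", k))
      return(data.frame(lag_day = k, effect = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n = n, note = "zero-variance"))
    }
    r <- cor(y, x, method = method)
    z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
    se <- 1 / sqrt(n - 3)
    # tanh saturates in double precision near |r| = 1; keep r inside its CI
    data.frame(lag_day = k, effect = r,
               ci_low = min(tanh(z - 1.959964 * se), r),
               ci_high = max(tanh(z + 1.959964 * se), r),
               n = n, note = "")
  })
  do.call(rbind, res)
}
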