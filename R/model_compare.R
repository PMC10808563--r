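#' Predictor sets for the presence/abundance model comparison
#'
#' The compared specifications: an intercept-only null; all 20 daily lags;
#' daily lags plus 10- or 20-day cumulative precipitation; and the two
#' cumulative-only variants.
#'
#' @param spec one of \code{"null"}, \code{"daily"}, \code{"daily_cum10"},
#'   \code{"daily_cum20"}, \code{"cum10"}, \code{"cum20"}.
#' @return character vector of predictor column names (empty for the null).
#' @export
spec_predictors <- function(spec = c("null", "daily", "daily_cum10",
                                     "daily_cum20", "cum10", "cum20")) {
  spec <- match.arg(spec)
  daily <- paste0("lag", seq_len(lag_days))
  switch(spec,
         null = character(0),
         daily = daily,
         daily_cum10 = c(daily, "cum10"),
         daily_cum20 = c(daily, "cum20"),
         cum10 = "cum10",
         cum20 = "cum20")
}

#' Site-level train/test split
#'
#' Assigns whole trapping sites (not rows) to the training or testing set,
#' targeting a 75/25 observation split: sites are visited in seeded random
#' order and greedily added to the training set whenever that moves the
#' realized observation share closer to the target.  No site appears in both
#' sets and the same seed always yields the same split.
#'
#' @param lagmat data.frame carrying \code{trap_id}.
#' @param train_fraction target share of observations in training (default
#'   0.75).
#' @param seed integer seed.
#' @return list with \code{train}, \code{test} (row subsets),
#'   \code{train_sites}, \code{test_sites}.
#' @export
split_by_site <- function(lagmat, train_fraction = 0.75, seed = 1) {
  sites <- unique(lagmat$trap_id)
  if (length(sites) < 2) stop("need at least 2 sites to split")
  counts <- table(lagmat$trap_id)
  ord <- with_seed(seed, sample(sites))
  target <- train_fraction * nrow(lagmat)
  cum <- 0
  in_train <- logical(length(ord))
  for (i in seq_along(ord)) {
    ni <- counts[[ord[i]]]
    if (cum < target && abs(cum + ni - target) <= abs(cum - target)) {
      in_train[i] <- TRUE
      cum <- cum + ni
    }
  }
  if (all(in_train)) in_train[length(in_train)] <- FALSE
  if (!any(in_train)) in_train[1] <- TRUE
  train_sites <- ord[in_train]
  list(train = lagmat[lagmat$trap_id %in% train_sites, , drop = FALSE],
       test = lagmat[!lagmat$trap_id %in% train_sites, , drop = FALSE],
       train_sites = train_sites,
       test_sites = ord[!in_train])
}

#' Area under the ROC curve
#'
#' Rank implementation of the concordance probability
#' P(score+ > score-) + 0.5 P(tie); constant scores give exactly 0.5.
#'
#' @param scores numeric model scores.
#' @param labels logical (or 0/1) outcomes; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: only one outcome class present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Root mean squared error on the response scale
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return \code{sqrt(mean((predicted - observed)^2))}.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ")
  stopifnot(length(predicted) >= 1)
  sqrt(mean((predicted - observed)^2))
}

# Fit one specification on training rows and predict the test rows.
# Presence models are fit on raw inches; abundance models normalize
# predictors inside glmnet.  The L1 penalty is chosen by 5-fold CV on the
# training set; presence models fall back to an unpenalized fit when the CV
# path does not improve on the (near-)unpenalized end of the path.
fit_one_spec <- function(train, test, outcome, spec, seed, nfolds = 5) {
  preds <- spec_predictors(spec)
  fam <- if (outcome == "presence") binomial() else poisson()
  y_tr <- if (outcome == "presence") train$presence else train$female_count
  y_te <- if (outcome == "presence") test$presence else test$female_count
  normalize <- outcome == "abundance"
  lambda <- NA_real_
  if (length(preds) == 0) {
    fit <- glm(y_tr ~ 1, family = fam)
    pred <- rep(unname(fam$linkinv(coef(fit)[1])), nrow(test))
    coefs <- c("(Intercept)" = unname(coef(fit)))
    lambda <- 0
  } else {
    Xtr <- as.matrix(train[, preds, drop = FALSE])
    Xte <- as.matrix(test[, preds, drop = FALSE])
    const <- apply(Xtr, 2, var) == 0
    if (any(const))
      stop(sprintf("degenerate predictor matrix: constant column(s) %s",
                   paste(preds[const], collapse = ", ")))
    if (length(preds) == 1) {
      df_tr <- data.frame(y = y_tr, x = Xtr[, 1])
      fit <- glm(y ~ x, family = fam, data = df_tr)
      pred <- unname(predict(fit, newdata = data.frame(x = Xte[, 1]),
                             type = "response"))
      coefs <- setNames(coef(fit), c("(Intercept)", preds))
      lambda <- 0
    } else {
      foldid <- with_seed(seed,
        sample(rep(seq_len(nfolds), length.out = nrow(Xtr))))
      yy <- if (outcome == "presence") as.integer(y_tr) else y_tr
      cv <- glmnet::cv.glmnet(Xtr, yy, family = fam$family,
                              foldid = foldid, standardize = normalize)
      i_small <- which.min(cv$lambda)      # near-unpenalized end of the path
      # the penalty earns its keep only when it beats the (near-)unpenalized
      # end of the path by more than one CV standard error
      improves <- min(cv$cvm) < cv$cvm[i_small] - cv$cvsd[i_small]
      if (outcome == "presence" && !improves) {
        # the penalty does not help presence models: refit unpenalized
        df_tr <- as.data.frame(Xtr); df_tr$y <- yy
        fit <- suppressWarnings(glm(y ~ ., family = fam, data = df_tr))
        pred <- unname(predict(fit, newdata = as.data.frame(Xte),
                               type = "response"))
        coefs <- coef(fit)
        lambda <- 0
      } else {
        lambda <- cv$lambda.min
        fit <- cv$glmnet.fit
        pred <- as.vector(predict(fit, Xte, s = lambda, type = "response"))
        cf <- coef(fit, s = lambda)
        coefs <- setNames(as.vector(cf), rownames(cf))
      }
    }
  }
  coefs[is.na(coefs)] <- 0   # aliased (exactly collinear) terms are eliminated
  metric <- if (outcome == "presence") auc_roc(pred, y_te)
            else rmse(pred, y_te)
  list(spec = spec, metric = metric, lambda = lambda, coefficients = coefs,
       eliminated = names(coefs)[coefs == 0 & names(coefs) != "(Intercept)"])
}

#' Fit and score the presence/abundance model suite
#'
#' Splits sites 75/25, fits each specification with an L1 penalty chosen by
#' cross-validation on the training set (presence models fall back to
#' unpenalized fits when the penalty does not improve validation loss;
#' abundance models always use the CV-selected penalty with normalized
#' predictors), and scores on the held-out sites: AUC-ROC for presence,
#' count-scale RMSE for abundance.
#'
#' @param lagmat thinned lag matrix.
#' @param outcome \code{"presence"} or \code{"abundance"}.
#' @param specs specifications to compare (default the four compared head to
#'   head: null, daily, daily_cum10, daily_cum20).
#' @param seed integer seed controlling the split and CV folds.
#' @param train_fraction passed to \code{\link{split_by_site}}.
#' @return list of class \code{model_comparison}: \code{outcome},
#'   \code{metric_name}, \code{table} (one row per spec), \code{fits}
#'   (per-spec coefficient details), \code{n_train}, \code{n_test}.
#' @export
fit_model_suite <- function(lagmat,
                            outcome = c("presence", "abundance"),
                            specs = c("null", "daily", "daily_cum10",
                                      "daily_cum20"),
                            seed = 1, train_fraction = 0.75) {
  outcome <- match.arg(outcome)
  if (outcome == "presence" && length(unique(lagmat$presence)) < 2)
    stop("presence outcome has a single class")
  sp <- split_by_site(lagmat, train_fraction, seed)
  if (outcome == "presence" && length(unique(sp$test$presence)) < 2)
    stop("test split has a single presence class; use another seed")
  fits <- lapply(specs, function(s)
    fit_one_spec(sp$train, sp$test, outcome, s, seed))
  names(fits) <- specs
  tab <- data.frame(
    spec = specs,
    metric = if (outcome == "presence") "AUC-ROC" else "RMSE",
    estimate = vapply(fits, `[[`, numeric(1), "metric"),
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    n_nonzero = vapply(fits, function(f)
      sum(f$coefficients != 0) - 1L, numeric(1)),
    row.names = NULL
  )
  structure(list(outcome = outcome,
                 metric_name = tab$metric[1],
                 table = tab, fits = fits,
                 n_train = nrow(sp$train), n_test = nrow(sp$test),
                 train_sites = sp$train_sites, test_sites = sp$test_sites),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("model_comparison (%s, %s): n_train=%d, n_test=%d\n",
              x$outcome, x$metric_name, x$n_train, x$n_test))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Bootstrap confidence intervals for model coefficients
#'
#' Nonparametric case-resampling bootstrap of one specification: rows are
#' resampled with replacement (or whole sites with \code{site_level = TRUE}),
#' the model is refit at the penalty chosen once on the full data, and 95%
#' percentile intervals are taken per term.  Deterministic given the seed.
#'
#' @param lagmat lag matrix (conventionally the full thinned data).
#' @param outcome \code{"presence"} or \code{"abundance"}.
#' @param spec specification name (default \code{"daily"}).
#' @param replicates bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param site_level resample whole sites instead of rows (default FALSE).
#' @return data.frame with \code{term}, \code{estimate}, \code{ci_low},
#'   \code{ci_high}, \code{replicates}.
#' @export
bootstrap_coefficients <- function(lagmat, outcome = c("presence", "abundance"),
                                   spec = "daily", replicates = 1000, seed = 1,
                                   site_level = FALSE) {
  outcome <- match.arg(outcome)
  preds <- spec_predictors(spec)
  if (length(preds) == 0) stop("bootstrap of the null model is not meaningful")
  full <- fit_one_spec(lagmat, lagmat, outcome, spec, seed)
  if (replicates == 1)
    warning("replicates = 1 gives a degenerate confidence interval")
  fam <- if (outcome == "presence") binomial() else poisson()
  normalize <- outcome == "abundance"
  n <- nrow(lagmat)
  sites <- unique(lagmat$trap_id)
  draws <- with_seed(seed, {
    if (site_level)
      replicate(replicates,
                sample(sites, length(sites), replace = TRUE),
                simplify = FALSE)
    else
      replicate(replicates, sample.int(n, n, replace = TRUE),
                simplify = FALSE)
  })
  terms <- c("(Intercept)", preds)
  est <- matrix(NA_real_, replicates, length(terms),
                dimnames = list(NULL, terms))
  failures <- 0
  for (r in seq_len(replicates)) {
    rows <- if (site_level)
      unlist(lapply(draws[[r]], function(s) which(lagmat$trap_id == s)))
    else draws[[r]]
    bm <- lagmat[rows, , drop = FALSE]
    cf <- tryCatch({
      y <- if (outcome == "presence") as.integer(bm$presence)
           else bm$female_count
      X <- as.matrix(bm[, preds, drop = FALSE])
      if (full$lambda > 0) {
        fit <- glmnet::glmnet(X, y, family = fam$family,
                              lambda = full$lambda, standardize = normalize)
        cc <- coef(fit)
        setNames(as.vector(cc), rownames(cc))
      } else {
        df <- as.data.frame(X); df$y <- y
        fit <- suppressWarnings(glm(y ~ ., family = fam, data = df))
        if (!fit$converged) stop("glm did not converge")
        coef(fit)
      }
    }, error = function(e) NULL)
    if (is.null(cf)) failures <- failures + 1
    else est[r, names(cf)] <- cf
  }
  if (failures > 0.10 * replicates)
    stop(sprintf("bootstrap unstable: %d of %d replicates failed to converge",
                 failures, replicates))
  ok <- stats::complete.cases(est)
  data.frame(
    term = terms,
    estimate = unname(full$coefficients[terms]),
    ci_low = apply(est[ok, , drop = FALSE], 2, quantile, probs = 0.025,
                   names = FALSE),
    ci_high = apply(est[ok, , drop = FALSE], 2, quantile, probs = 0.975,
                    names = FALSE),
    replicates = sum(ok),
    row.names = NULL
  )
}
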