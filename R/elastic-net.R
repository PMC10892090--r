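#' Configuration of the Elastic Net bootstrap ensemble
#'
#' @param n_models ensemble size (default 1000).
#' @param alpha L1/L2 mixing parameter in (0, 1\]; 1 = lasso. Fixed rather
#'   than tuned: with ~20 fractions per-member alpha tuning is unstable.
#' @param nfolds internal cross-validation folds used to pick the penalty
#'   weight lambda within each bootstrap resample (default 5).
#' @param lambda_rule \code{"1se"} (default): largest lambda with CV error
#'   within one standard error of the minimum — the usual parsimony rule,
#'   which keeps ensemble members sparse so that selection frequencies
#'   discriminate; or \code{"min"}: the CV-minimizing lambda.
#' @param nlambda,lambda_min_ratio,thresh glmnet path resolution and
#'   convergence tolerance used for every member fit.
#' @param seed RNG seed making the whole ensemble reproducible.
#' @return an \code{ensemble_config} object.
#' @export
ensemble_config <- function(n_models = 1000L, alpha = 0.5, nfolds = 5L,
                            lambda_rule = c("1se", "min"), nlambda = 40L,
                            lambda_min_ratio = 1e-2, thresh = 1e-5,
                            seed = 1L) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (nfolds < 3) stop("nfolds must be >= 3")
  structure(list(n_models = as.integer(n_models), alpha = alpha,
                 nfolds = as.integer(nfolds),
                 lambda_rule = match.arg(lambda_rule),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio, thresh = thresh,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Fit a bootstrap ensemble of Elastic Net regressions
#'
#' Each ensemble member draws a bootstrap resample of the fractions (with
#' replacement, same size), standardizes predictors within the resample
#' (glmnet's internal standardization; coefficients are returned on the
#' original scale), fits the Elastic Net at fixed \code{alpha} over a lambda
#' path, and keeps the coefficient vector at the lambda minimizing the
#' internal cross-validation error on that resample. Members whose resampled
#' response is constant contribute an all-zero coefficient vector.
#'
#' @param X a (log-transformed) \code{\link{feature_matrix}} or numeric
#'   matrix, fractions x features.
#' @param y numeric transformed response, aligned with the rows of \code{X}.
#' @param config an \code{\link{ensemble_config}}.
#' @return an object of class \code{en_ensemble}: coefficient matrix
#'   (features x members), feature metadata, and the config.
#' @export
fit_ensemble <- function(X, y, config = ensemble_config()) {
  meta <- NULL
  if (inherits(X, "feature_matrix")) {
    meta <- list(feature_ids = X$feature_ids, mz = X$mz,
                 ion_mode = X$ion_mode)
    X <- X$intensities
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (n < 6) stop("need at least 6 fractions for bootstrap resampling")

  pad <- p == 1L  # glmnet requires >= 2 columns; pad with an inert zero column
  Xfit <- if (pad) cbind(X, 0) else X

  coefs <- matrix(0, p, config$n_models)
  y_const <- stats::sd(y) == 0
  with_seed(config$seed, {
    for (m in seq_len(config$n_models)) {
      idx <- sample.int(n, n, replace = TRUE)
      foldid <- sample(rep(seq_len(config$nfolds), length.out = n))
      if (y_const || stats::sd(y[idx]) == 0) next
      cf <- try(en_member_fit(Xfit[idx, , drop = FALSE], y[idx], foldid,
                              config),
                silent = TRUE)
      if (!inherits(cf, "try-error"))
        coefs[, m] <- cf[seq_len(p)]
    }
  })

  structure(
    list(coefficients = coefs,
         feature_ids = if (!is.null(meta)) meta$feature_ids else
           (colnames(X) %||% paste0("V", seq_len(p))),
         mz = if (!is.null(meta)) meta$mz else rep(NA_real_, p),
         ion_mode = if (!is.null(meta)) meta$ion_mode else NA_character_,
         config = config, n_fractions = n),
    class = "en_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## one member: glmnet path + manual k-fold CV reusing the full-path lambdas
en_member_fit <- function(Xb, yb, foldid, config) {
  f0 <- glmnet::glmnet(Xb, yb, alpha = config$alpha,
                       nlambda = config$nlambda,
                       lambda.min.ratio = config$lambda_min_ratio,
                       thresh = config$thresh)
  lam <- f0$lambda
  k <- config$nfolds
  err <- matrix(NA_real_, k, length(lam))
  for (fold in seq_len(k)) {
    tr <- foldid != fold
    if (sum(tr) < 2 || sum(!tr) < 1 || stats::sd(yb[tr]) == 0) next
    fk <- try(glmnet::glmnet(Xb[tr, , drop = FALSE], yb[tr],
                             alpha = config$alpha, lambda = lam,
                             thresh = config$thresh), silent = TRUE)
    if (inherits(fk, "try-error")) next
    pr <- glmnet::predict.glmnet(fk, Xb[!tr, , drop = FALSE])
    e2 <- (yb[!tr] - pr)^2
    mse <- if (is.matrix(e2)) colMeans(e2) else e2
    err[fold, seq_along(mse)] <- mse
  }
  cvm <- colMeans(err, na.rm = TRUE)
  if (all(is.nan(cvm))) return(rep(0, ncol(Xb)))
  best <- which.min(cvm)
  s <- if (config$lambda_rule == "1se" && !is.na(stats::sd(err[, best],
                                                           na.rm = TRUE))) {
    cvs <- stats::sd(err[, best], na.rm = TRUE) / sqrt(k)
    lam[min(which(cvm <= cvm[best] + cvs))]
  } else lam[best]
  as.numeric(glmnet::coef.glmnet(f0, s = s))[-1]
}

#' @export
print.en_ensemble <- function(x, ...) {
  freq <- rowMeans(x$coefficients != 0)
  cat(sprintf(
    "<en_ensemble> %d members, %d features (%d ever selected), alpha=%.2f\n",
    ncol(x$coefficients), nrow(x$coefficients), sum(freq > 0),
    x$config$alpha))
  invisible(x)
}

#' Rank features from an Elastic Net ensemble
#'
#' Features are ordered by selection frequency (fraction of members with a
#' non-zero coefficient) descending, then by mean absolute coefficient over
#' selecting members, then by ascending m/z. \code{n_selected} counts
#' features selected by at least one member; ranks beyond \code{n_selected}
#' belong to never-selected features and are reported without a rank label.
#'
#' @param ensemble an \code{\link{en_ensemble}}.
#' @return an \code{en_rank_result} data frame with columns
#'   \code{feature_id}, \code{selection_frequency},
#'   \code{mean_abs_coefficient}, \code{rank}, \code{n_selected},
#'   \code{rank_label} (e.g. \code{"1 (of 85)"}), ordered by rank.
#' @export
rank_features <- function(ensemble) {
  stopifnot(inherits(ensemble, "en_ensemble"))
  cf <- ensemble$coefficients
  if (ncol(cf) == 0) stop("empty ensemble")
  sel <- cf != 0
  freq <- rowMeans(sel)
  mac <- vapply(seq_len(nrow(cf)), function(j) {
    s <- sel[j, ]
    if (any(s)) mean(abs(cf[j, s])) else 0
  }, numeric(1))
  mz <- ensemble$mz
  if (all(is.na(mz))) mz <- seq_along(freq)
  rk <- integer(length(freq))
  rk[order(-freq, -mac, mz)] <- seq_along(freq)
  n_selected <- sum(freq > 0)
  out <- data.frame(feature_id = ensemble$feature_ids,
                    selection_frequency = freq,
                    mean_abs_coefficient = mac,
                    rank = rk,
                    n_selected = n_selected,
                    stringsAsFactors = FALSE)
  out$rank_label <- ifelse(out$selection_frequency > 0,
                           sprintf("%d (of %d)", out$rank, n_selected),
                           NA_character_)
  out$ion_mode <- ensemble$ion_mode
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("en_rank_result", "data.frame")
  out
}

#' Elastic Net ensemble analysis of one ionization mode
#'
#' Convenience wrapper: log-transforms intensities and viability, fits the
#' bootstrap ensemble and returns the ranked features.
#'
#' @param fm a raw \code{\link{feature_matrix}} (one ionization mode).
#' @param bio an aligned \code{\link{bioactivity}}.
#' @param config an \code{\link{ensemble_config}}.
#' @param pseudocount passed to \code{\link{log_transform}}.
#' @return an \code{en_rank_result}; the ensemble is attached as attribute
#'   \code{"ensemble"}.
#' @export
en_analysis <- function(fm, bio, config = ensemble_config(),
                        pseudocount = "half-min") {
  stopifnot(inherits(fm, "feature_matrix"))
  check_aligned(fm, bio)
  Xl <- if (fm$transformed) fm else log_transform(fm, pseudocount)
  yl <- log_transform_response(bio)
  ens <- fit_ensemble(Xl, yl, config)
  res <- rank_features(ens)
  attr(res, "ensemble") <- ens
  res
}
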