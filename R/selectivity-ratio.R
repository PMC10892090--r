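#' Fit a PLS1 regression model
#'
#' Standard univariate-response partial least squares (NIPALS-style
#' deflation). Columns are centered and, by default, scaled to unit variance;
#' penalized and latent-variable regressions are sensitive to variable
#' scaling, and autoscaling is the convention for selectivity-ratio work.
#'
#' @param X a (log-transformed) \code{\link{feature_matrix}} or plain numeric
#'   matrix, observations x variables.
#' @param y numeric response vector (already transformed).
#' @param ncomp number of latent components, or \code{"auto"} to choose by
#'   leave-one-out cross-validation over \code{1..min(10, n-2, p)}: the
#'   largest component count whose RMSECV lies within one standard error of
#'   the minimum. For variable ranking an underfitted target projection
#'   blurs selectivity, so among statistically indistinguishable models the
#'   one capturing the most predictive structure is preferred.
#' @param scale autoscale columns to unit variance (default \code{TRUE}).
#' @return an object of class \code{pls_model} with scores \code{T},
#'   loadings \code{P}, weights \code{W}, y-loadings \code{q}, regression
#'   vector \code{b} (preprocessed scale), the preprocessed matrix \code{X0},
#'   centering/scaling vectors and, when \code{ncomp = "auto"}, the RMSECV
#'   curve.
#' @export
fit_pls <- function(X, y, ncomp = "auto", scale = TRUE) {
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
  if (n < 3) stop("need at least 3 observations")

  rmsecv <- NULL
  if (identical(ncomp, "auto")) {
    kmax <- min(10L, n - 2L, p)
    cv <- pls_loo_rmsecv(X, y, kmax, scale = scale)
    rmsecv <- cv$rmsecv
    ## largest component count within 1 SE of the RMSECV minimum
    amin <- which.min(rmsecv)
    ncomp <- max(which(rmsecv <= rmsecv[amin] + cv$se[amin]))
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(n-1, p)")

  pre <- pls_preprocess(X, y, scale)
  core <- pls_core(pre$X0, pre$y0, ncomp)

  structure(
    c(core,
      list(x_center = pre$x_center, x_scale = pre$x_scale,
           y_center = pre$y_center, X0 = pre$X0, y0 = pre$y0,
           ncomp = ncomp, scale = scale, rmsecv = rmsecv,
           feature_ids = if (!is.null(meta)) meta$feature_ids else colnames(X),
           mz = if (!is.null(meta)) meta$mz else rep(NA_real_, p),
           ion_mode = if (!is.null(meta)) meta$ion_mode else NA_character_)),
    class = "pls_model")
}

pls_preprocess <- function(X, y, scale) {
  x_center <- colMeans(X)
  X0 <- sweep(X, 2, x_center)
  if (scale) {
    x_scale <- apply(X0, 2, stats::sd)
    x_scale[x_scale == 0] <- 1  # constant columns carry no information
    X0 <- sweep(X0, 2, x_scale, "/")
  } else {
    x_scale <- rep(1, ncol(X))
  }
  y_center <- mean(y)
  list(X0 = X0, y0 = y - y_center,
       x_center = x_center, x_scale = x_scale, y_center = y_center)
}

## PLS1 with deflation; E, f are the running residual matrices
pls_core <- function(X0, y0, ncomp) {
  n <- nrow(X0); p <- ncol(X0)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp); q <- numeric(ncomp)
  E <- X0; f <- y0
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(X0^2)))) {
      if (a == 1L) stop("no covariance between X and y; cannot fit PLS")
      ncomp <- a - 1L
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      TT <- TT[, seq_len(ncomp), drop = FALSE]
      q <- q[seq_len(ncomp)]
      break
    }
    w <- w / nw
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    pvec <- as.numeric(crossprod(E, t)) / tt
    qa <- sum(t * f) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - t * qa
    W[, a] <- w; P[, a] <- pvec; TT[, a] <- t; q[a] <- qa
  }
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  list(W = W, P = P, T = TT, q = q, b = b,
       fitted0 = as.numeric(X0 %*% b))
}

pls_loo_rmsecv <- function(X, y, kmax, scale) {
  n <- nrow(X)
  press <- matrix(NA_real_, n, kmax)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    pre <- pls_preprocess(Xi, yi, scale)
    kfit <- min(kmax, qr(pre$X0)$rank, nrow(Xi) - 1L)
    core <- try(pls_core(pre$X0, pre$y0, kfit), silent = TRUE)
    if (inherits(core, "try-error")) next
    x_new <- (X[i, ] - pre$x_center) / pre$x_scale
    ## prediction after a components: b_a from truncated decomposition
    for (a in seq_len(ncol(core$W))) {
      Wa <- core$W[, seq_len(a), drop = FALSE]
      Pa <- core$P[, seq_len(a), drop = FALSE]
      ba <- as.numeric(Wa %*% solve(crossprod(Pa, Wa), core$q[seq_len(a)]))
      pred <- sum(x_new * ba) + pre$y_center
      press[i, a] <- (y[i] - pred)^2
    }
  }
  ## components unreachable in some folds inherit the last reachable error
  for (i in seq_len(n)) {
    v <- press[i, ]
    if (anyNA(v) && any(!is.na(v)))
      press[i, ] <- v[cummax(ifelse(is.na(v), 0L, seq_along(v)))]
  }
  mse <- colMeans(press, na.rm = TRUE)
  rmsecv <- sqrt(mse)
  se_mse <- apply(press, 2, stats::sd, na.rm = TRUE) / sqrt(n)
  list(rmsecv = rmsecv, se = se_mse / (2 * pmax(rmsecv, 1e-12)))
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$intensities
  X0 <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
              object$x_scale, "/")
  as.numeric(X0 %*% object$b) + object$y_center
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d variables, %d observations\n",
              x$ncomp, nrow(x$W), nrow(x$X0)))
  invisible(x)
}

#' Target projection of a PLS model
#'
#' Rotates a multi-component PLS model onto the single direction of its
#' regression vector, concentrating all predictive variation in one
#' component: \eqn{t_{tp} = X b / \|b\|}, \eqn{p_{tp} = X^T t_{tp} /
#' (t_{tp}^T t_{tp})}.
#'
#' @param model a fitted \code{\link{fit_pls}} model.
#' @param X optional matrix to project (defaults to the model's preprocessed
#'   training matrix).
#' @return list with \code{t_tp} (scores) and \code{p_tp} (loadings).
#' @export
target_projection <- function(model, X = NULL) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(X)) X <- model$X0
  b <- model$b
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("regression vector has zero norm; no target projection")
  t_tp <- as.numeric(X %*% (b / nb))
  tt <- sum(t_tp^2)
  if (tt == 0) stop("target-projected scores are all zero")
  p_tp <- as.numeric(crossprod(X, t_tp)) / tt
  list(t_tp = t_tp, p_tp = p_tp)
}

#' Selectivity ratio of each feature
#'
#' For each variable (column of the preprocessed matrix), the variance
#' explained along the target-projected component is
#' \eqn{v_{expl,j} = \|t_{tp} p_{tp,j}\|^2} and the residual variance is
#' \eqn{v_{resid,j} = \|x_j - t_{tp} p_{tp,j}\|^2}; the selectivity ratio is
#' their quotient. A feature with SR = 1 has exactly half of its variance
#' explained along the target-projected component; SR grows without bound as
#' the explained fraction approaches one (a residual-free feature gets
#' \code{Inf} and is ranked first).
#'
#' @param X preprocessed matrix (observations x variables) the projection was
#'   computed on.
#' @param t_tp,p_tp target-projected scores and loadings from
#'   \code{\link{target_projection}}.
#' @param feature_ids,mz feature identifiers and m/z values used for
#'   reporting and tie-breaks (ties in SR are broken by ascending m/z).
#' @return an \code{sr_result} data frame with columns \code{feature_id},
#'   \code{sr}, \code{explained_fraction}, \code{rank} (1 = highest SR),
#'   ordered by rank.
#' @export
selectivity_ratio <- function(X, t_tp, p_tp, feature_ids = colnames(X),
                              mz = NULL) {
  X <- as.matrix(X)
  if (length(t_tp) != nrow(X)) stop("length(t_tp) != nrow(X)")
  if (length(p_tp) != ncol(X)) stop("length(p_tp) != ncol(X)")
  if (is.null(feature_ids)) feature_ids <- paste0("V", seq_len(ncol(X)))
  if (is.null(mz)) {
    mz <- suppressWarnings(
      as.numeric(sub("^.*_", "", feature_ids)))
    mz[is.na(mz)] <- seq_along(feature_ids)[is.na(mz)]
  }
  tt <- sum(t_tp^2)
  v_expl <- p_tp^2 * tt
  resid <- X - tcrossprod(t_tp, p_tp)
  v_resid <- colSums(resid^2)
  total <- v_expl + v_resid
  sr <- ifelse(v_resid <= .Machine$double.eps * pmax(total, 1),
               Inf, v_expl / v_resid)
  sr[total == 0] <- 0  # zero-variance feature: nothing to explain
  ef <- ifelse(total > 0, v_expl / total, 0)
  rk <- integer(length(sr))
  rk[order(-sr, mz)] <- seq_along(sr)
  out <- data.frame(feature_id = feature_ids, sr = sr,
                    explained_fraction = ef, rank = rk,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("sr_result", "data.frame")
  out
}

#' Selectivity-ratio analysis of one ionization mode
#'
#' Convenience wrapper: log-transforms intensities and viability, fits the
#' PLS model, computes the target projection and returns the per-feature
#' selectivity ratios.
#'
#' @param fm a raw \code{\link{feature_matrix}} (one ionization mode).
#' @param bio an aligned \code{\link{bioactivity}}.
#' @param ncomp passed to \code{\link{fit_pls}}.
#' @param scale autoscale columns (default \code{TRUE}).
#' @param pseudocount passed to \code{\link{log_transform}}.
#' @return an \code{sr_result} data frame (with \code{ion_mode} column); the
#'   fitted model is attached as attribute \code{"model"}.
#' @export
sr_analysis <- function(fm, bio, ncomp = "auto", scale = TRUE,
                        pseudocount = "half-min") {
  stopifnot(inherits(fm, "feature_matrix"))
  check_aligned(fm, bio)
  Xl <- if (fm$transformed) fm else log_transform(fm, pseudocount)
  yl <- log_transform_response(bio)
  model <- fit_pls(Xl, yl, ncomp = ncomp, scale = scale)
  tp <- target_projection(model)
  res <- selectivity_ratio(model$X0, tp$t_tp, tp$p_tp,
                           feature_ids = model$feature_ids, mz = model$mz)
  res$ion_mode <- fm$ion_mode
  attr(res, "model") <- model
  attr(res, "target_projection") <- tp
  res
}
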