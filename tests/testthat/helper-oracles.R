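## Independent reference implementations used as oracles. These deliberately
## avoid the package's own code paths.

## textbook iterative NIPALS PLS1 with deflation (power-iteration form)
nipals_pls1_oracle <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  xm <- colMeans(X); Xc <- sweep(X, 2, xm)
  xs <- rep(1, ncol(X))
  if (scale) {
    xs <- apply(Xc, 2, sd); xs[xs == 0] <- 1
    Xc <- sweep(Xc, 2, xs, "/")
  }
  ym <- mean(y); yc <- y - ym
  E <- Xc; f <- yc
  W <- NULL; P <- NULL; Q <- NULL
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    repeat {  # power iteration (converges in one step for univariate y)
      t <- drop(E %*% w)
      w_new <- drop(crossprod(E, f)) / sqrt(sum(crossprod(E, f)^2))
      if (sum((w_new - w)^2) < 1e-14) break
      w <- w_new
    }
    t <- drop(E %*% w); tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    q <- sum(t * f) / tt
    E <- E - tcrossprod(t, p)
    f <- f - t * q
    W <- cbind(W, w); P <- cbind(P, p); Q <- c(Q, q)
  }
  b <- drop(W %*% solve(crossprod(P, W), Q))
  list(predict = function(Xnew) {
    Xn <- sweep(sweep(as.matrix(Xnew), 2, xm), 2, xs, "/")
    drop(Xn %*% b) + ym
  }, b = b)
}

## brute-force per-column explained/residual variance decomposition
sr_bruteforce_oracle <- function(X, t_tp, p_tp) {
  sapply(seq_len(ncol(X)), function(j) {
    fitted <- t_tp * p_tp[j]
    e <- sum(fitted^2)
    r <- sum((X[, j] - fitted)^2)
    if (r == 0) Inf else e / r
  })
}

## plain union-find over an edge list; returns component label per node id
union_find_oracle <- function(node_ids, from, to) {
  parent <- seq_along(node_ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_along(from)) {
    a <- find(match(from[k], node_ids)); b <- find(match(to[k], node_ids))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(node_ids), find, integer(1))
  match(roots, unique(roots))
}

## quick spectrum constructor for fixtures
spec_fix <- function(id, pm, mz, intensity = rep(1, length(mz)),
                     mode = "NEG") {
  msms_spectrum(id, pm, cbind(mz = mz, intensity = intensity),
                ion_mode = mode)
}

## small synthetic dataset used across tests
small_synth <- function(seed = 1, n_features = 120, ...) {
  cfg <- synthetic_config(n_features = n_features, seed = seed, ...)
  gen <- generate_fraction_profiles(cfg)
  list(cfg = cfg, gen = gen)
}
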