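test_that("PLS1 reproduces a response that equals one predictor exactly", {
  set.seed(1)
  ## column-centred orthogonal predictors: one component gives an exact fit
  Xo <- qr.Q(qr(scale(matrix(rnorm(8 * 4), 8, 4), scale = FALSE)))
  yo <- Xo[, 2]
  m1 <- fit_pls(Xo, yo, ncomp = 1, scale = FALSE)
  expect_lt(sqrt(mean((predict(m1, Xo) - yo)^2)) / sd(yo), 1e-8)
  ## correlated predictors: the full decomposition recovers the exact fit
  X <- matrix(rnorm(8 * 4), 8, 4)
  y <- X[, 2]
  m4 <- fit_pls(X, y, ncomp = 4, scale = FALSE)
  expect_lt(sqrt(mean((predict(m4, X) - y)^2)) / sd(y), 1e-8)
})

test_that("zero covariance between X and y is an error", {
  ## columns of X are constant: no covariance with any response
  X <- matrix(1, 6, 3)
  y <- rnorm(6)
  expect_error(fit_pls(X, y, ncomp = 1), "no covariance")
})

test_that("predictions match an independent textbook NIPALS implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(10 * 5), 10, 5)
    y <- rnorm(10)
    for (nc in c(1, 2, 3)) {
      m <- fit_pls(X, y, ncomp = nc, scale = TRUE)
      oracle <- nipals_pls1_oracle(X, y, nc, scale = TRUE)
      expect_equal(predict(m, X), oracle$predict(X), tolerance = 1e-8)
    }
  }
})

test_that("target projection of a 1-component model is that component", {
  set.seed(2)
  X <- matrix(rnorm(9 * 5), 9, 5)
  y <- X %*% rnorm(5) + rnorm(9, sd = 0.1)
  m <- fit_pls(X, drop(y), ncomp = 1)
  tp <- target_projection(m)
  r <- cor(tp$t_tp, m$T[, 1])
  expect_equal(abs(r), 1, tolerance = 1e-10)
})

test_that("target-projection residuals are orthogonal to the scores", {
  set.seed(3)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- X %*% rnorm(6) + rnorm(12, sd = 0.3)
  m <- fit_pls(X, drop(y), ncomp = 3)
  tp <- target_projection(m)
  E <- m$X0 - tcrossprod(tp$t_tp, tp$p_tp)
  expect_lt(max(abs(crossprod(E, tp$t_tp))), 1e-10)
  ## p_tp equals the per-column least-squares regression on t_tp
  p_ls <- apply(m$X0, 2, function(col)
    sum(col * tp$t_tp) / sum(tp$t_tp^2))
  expect_equal(unname(tp$p_tp), unname(p_ls), tolerance = 1e-12)
})

test_that("a zero regression vector has no target projection", {
  m <- structure(list(b = rep(0, 3), X0 = matrix(0, 4, 3)),
                 class = "pls_model")
  expect_error(target_projection(m), "zero norm")
})

test_that("selectivity ratio matches its variance-decomposition definition", {
  set.seed(4)
  for (rep in 1:10) {
    X <- matrix(rnorm(15 * 8), 15, 8)
    y <- X %*% rnorm(8) + rnorm(15, sd = 0.5)
    m <- fit_pls(X, drop(y), ncomp = 2)
    tp <- target_projection(m)
    sr <- selectivity_ratio(m$X0, tp$t_tp, tp$p_tp)
    oracle <- sr_bruteforce_oracle(m$X0, tp$t_tp, tp$p_tp)
    ord <- match(paste0("V", 1:8), sr$feature_id)
    expect_equal(sr$sr[ord], oracle, tolerance = 1e-10)
    ## SR = f/(1-f) wherever finite
    fin <- is.finite(sr$sr)
    expect_equal(sr$sr[fin],
                 sr$explained_fraction[fin] / (1 - sr$explained_fraction[fin]),
                 tolerance = 1e-8)
    expect_setequal(sr$rank, 1:8)
  }
})

test_that("SR anchors: half-explained gives 1, orthogonal gives 0, perfect gives Inf", {
  set.seed(5)
  n <- 10
  t_tp <- rnorm(n); t_tp <- t_tp - mean(t_tp)
  e <- rnorm(n); e <- e - mean(e)
  e <- e - t_tp * sum(e * t_tp) / sum(t_tp^2)       # orthogonal residual
  e <- e * sqrt(sum(t_tp^2) / sum(e^2))             # equal norms
  X <- cbind(t_tp + e,      # explained == residual -> SR = 1
             e,             # orthogonal to t_tp    -> SR = 0
             2 * t_tp)      # residual-free         -> SR = Inf
  p_tp <- as.numeric(crossprod(X, t_tp)) / sum(t_tp^2)
  sr <- selectivity_ratio(X, t_tp, p_tp,
                          feature_ids = c("1.00_100.0000", "1.00_200.0000",
                                          "1.00_300.0000"))
  srv <- sr$sr[match(c("1.00_100.0000", "1.00_200.0000", "1.00_300.0000"),
                     sr$feature_id)]
  expect_equal(srv[1], 1, tolerance = 1e-10)
  expect_equal(sr$explained_fraction[sr$feature_id == "1.00_100.0000"],
               0.5, tolerance = 1e-10)
  expect_equal(srv[2], 0, tolerance = 1e-10)
  expect_identical(srv[3], Inf)
  expect_equal(sr$rank[sr$feature_id == "1.00_300.0000"], 1L)
})

test_that("SR is invariant to positive rescaling of the scores", {
  set.seed(6)
  X <- matrix(rnorm(12 * 5), 12, 5)
  t_tp <- rnorm(12)
  p1 <- as.numeric(crossprod(X, t_tp)) / sum(t_tp^2)
  s1 <- selectivity_ratio(X, t_tp, p1)
  t2 <- 7.3 * t_tp
  p2 <- as.numeric(crossprod(X, t2)) / sum(t2^2)
  s2 <- selectivity_ratio(X, t2, p2)
  expect_equal(s1$sr, s2$sr, tolerance = 1e-10)
})

test_that("dimension mismatches are rejected", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(selectivity_ratio(X, rnorm(5), rnorm(3)), "t_tp")
  expect_error(selectivity_ratio(X, rnorm(4), rnorm(2)), "p_tp")
})

test_that("the dominant noiseless spike attains the top selectivity ratio", {
  cfg <- synthetic_config(n_features = 60, n_bioactive = 1,
                          effect_sizes = 15, noise_sd = 0, seed = 10)
  gen <- generate_fraction_profiles(cfg)
  sr <- sr_analysis(gen$matrix, gen$viability)
  expect_equal(sr$rank[sr$feature_id == gen$spikes$feature_id], 1L)
})

test_that("sr_analysis is deterministic and reports ranks as a permutation", {
  s <- small_synth(seed = 12, n_features = 80)
  a <- sr_analysis(s$gen$matrix, s$gen$viability)
  b <- sr_analysis(s$gen$matrix, s$gen$viability)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_setequal(a$rank, seq_along(a$rank))
})
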