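test_that("feature tables parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,A1,A2",
               "1.41_353.0874,100,200",
               "1.79_515.1191,0,50",
               "0.90_180.0634,3,4"), path)
  fm <- read_feature_table(path, "NEG")
  expect_equal(dim(fm), c(2L, 3L))
  expect_identical(fm$fraction_ids, c("A1", "A2"))
  expect_equal(fm$mz[1], 353.0874)

  ## duplicate feature ID is rejected, naming the offender
  writeLines(c("feature,A1,A2",
               "1.41_353.0874,100,200",
               "1.41_353.0874,1,2"), path)
  expect_error(read_feature_table(path, "NEG"), "1.41_353.0874")

  ## negative intensity is rejected with its location
  writeLines(c("feature,A1,A2",
               "1.41_353.0874,100,-5"), path)
  expect_error(read_feature_table(path, "NEG"), "A2")

  ## synthetic output round-trips losslessly
  gen <- generate_fraction_profiles(synthetic_config(n_features = 40,
                                                     seed = 4))
  out <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(gen$matrix, out, comment = "seed=4")
  back <- read_feature_table(out, "NEG")
  expect_identical(back$feature_ids, gen$matrix$feature_ids)
  expect_equal(back$intensities, gen$matrix$intensities, tolerance = 1e-8)
})

test_that("malformed feature IDs are rejected", {
  expect_error(parse_feature_id("353.0874"), "malformed")
  expect_error(parse_feature_id("a_b"), "malformed")
  p <- parse_feature_id("1.41_353.0874")
  expect_equal(p$rt, 1.41)
  expect_equal(p$mz, 353.0874)
})

test_that("deconvolution is the identity without satellite pairs", {
  x <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 3)
  colnames(x) <- c("1.00_200.0000", "1.50_300.0000")
  rownames(x) <- c("A1", "A2", "A3")
  fm <- feature_matrix(x, "NEG")
  dec <- deconvolute(fm)
  expect_identical(dec$matrix$feature_ids, fm$feature_ids)
  expect_equal(dec$matrix$intensities, fm$intensities)
  expect_equal(nrow(dec$groups), 0L)
})

test_that("deconvolution merges known satellites and conserves intensity", {
  gen <- generate_fraction_profiles(synthetic_config(n_features = 150,
                                                     seed = 7))
  dec <- deconvolute(gen$matrix)
  expect_equal(length(unique(dec$groups$group)),
               length(unique(gen$satellites$parent_id)))
  ## every satellite merged into its parent (the lower-mass representative)
  expect_true(all(gen$satellites$parent_id %in% dec$matrix$feature_ids))
  expect_false(any(gen$satellites$satellite_id %in% dec$matrix$feature_ids))
  expect_equal(sum(dec$matrix$intensities), sum(gen$matrix$intensities))
  expect_lte(length(dec$matrix$feature_ids), length(gen$matrix$feature_ids))
})

test_that("log transform handles pseudo-counts, zeros and monotonicity", {
  x <- matrix(1, 2, 2)
  colnames(x) <- c("1.00_200.0000", "1.50_300.0000")
  fm <- feature_matrix(x, "NEG")
  lt <- log_transform(fm, pseudocount = 0)
  expect_true(all(lt$intensities == 0))
  expect_true(lt$transformed)

  x2 <- matrix(c(0, 4, 8, 16), 2, 2)
  colnames(x2) <- colnames(x)
  fm2 <- feature_matrix(x2, "NEG")
  lt2 <- log_transform(fm2)  # half-min pseudo-count = 2
  expect_equal(attr(lt2, "pseudocount"), 2)
  expect_equal(lt2$intensities[1, 1], log(2))
  expect_true(all(is.finite(lt2$intensities)))
  ## strict monotonicity on the raw ordering
  expect_true(all(diff(sort(as.vector(lt2$intensities))) >= 0))
  expect_true(lt2$intensities[1, 1] < lt2$intensities[2, 1])

  fm0 <- feature_matrix(matrix(0, 2, 2,
                               dimnames = list(NULL, colnames(x))), "NEG")
  expect_error(log_transform(fm0), "all-zero")

  bio <- bioactivity(c("A1", "A2"), c(0.2, 50))
  expect_equal(log_transform_response(bio), c(log(1), log(50)))
})

test_that("feature-viability Pearson correlation matches the direct formula", {
  v <- c(10, 30, 20, 50, 40)
  x <- cbind(v, -v + 60, c(1, 5, 2, 4, 3))
  colnames(x) <- c("1.00_200.0000", "1.50_300.0000", "2.00_400.0000")
  fm <- feature_matrix(x, "NEG", fraction_ids = paste0("A", 1:5))
  bio <- bioactivity(paste0("A", 1:5), v)
  expect_equal(pearson_feature_viability(fm, bio, "1.00_200.0000"), 1.0)
  expect_equal(pearson_feature_viability(fm, bio, "1.50_300.0000"), -1.0)
  ## brute-force covariance formula on the third feature
  z <- x[, 3]
  r_direct <- sum((z - mean(z)) * (v - mean(v))) /
    sqrt(sum((z - mean(z))^2) * sum((v - mean(v))^2))
  expect_equal(pearson_feature_viability(fm, bio, "2.00_400.0000"),
               r_direct, tolerance = 1e-12)
  ## noiseless single-spike synthetic data: r(spike, viability) on the
  ## unlogged scale equals the direct formula too
  cfg <- synthetic_config(n_features = 30, n_bioactive = 1,
                          effect_sizes = 12, noise_sd = 0,
                          viability_range = c(-Inf, Inf), seed = 8)
  gen <- generate_fraction_profiles(cfg)
  id <- gen$spikes$feature_id
  xs <- gen$matrix$intensities[, id]
  vv <- gen$viability$viability_pct
  r_direct2 <- sum((xs - mean(xs)) * (vv - mean(vv))) /
    sqrt(sum((xs - mean(xs))^2) * sum((vv - mean(vv))^2))
  expect_equal(pearson_feature_viability(gen$matrix, gen$viability, id),
               r_direct2, tolerance = 1e-12)

  zv <- cbind(x, "3.00_500.0000" = 1)
  fmz <- feature_matrix(zv, "NEG", fraction_ids = paste0("A", 1:5))
  expect_error(pearson_feature_viability(fmz, bio, "3.00_500.0000"),
               "zero variance")
})

test_that("total-intensity normalization equalizes fraction loads", {
  gen <- generate_fraction_profiles(synthetic_config(n_features = 40,
                                                     seed = 5))
  nm <- normalize_total_intensity(gen$matrix)
  tot <- rowSums(nm$intensities)
  expect_lt(diff(range(tot)) / mean(tot), 1e-9)
  expect_equal(sum(nm$intensities), sum(gen$matrix$intensities))
})
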