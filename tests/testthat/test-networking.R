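test_that("cosine score anchors: identical spectra score 1, disjoint score 0", {
  set.seed(1)
  s <- spec_fix("a", 400.1234, sort(runif(8, 100, 390)), runif(8, 1, 100))
  cs <- cosine_score(s, s)
  expect_equal(cs$score, 1.0)
  expect_equal(cs$n_matched, 8L)
  s2 <- spec_fix("b", 500.0, sort(runif(8, 600, 900)), runif(8, 1, 100))
  cs0 <- cosine_score(s, s2, network_params(use_modified_cosine = FALSE))
  expect_identical(cs0$score, 0)
  expect_identical(cs0$n_matched, 0L)
})

test_that("cosine score matches the hand-computed two-peak example", {
  s1 <- spec_fix("s1", 350.0, c(100.0, 200.0), c(1, 1))
  s2 <- spec_fix("s2", 350.0, c(100.0, 300.0), c(1, 1))
  cs <- cosine_score(s1, s2, network_params(fragment_tol = 0.05))
  ## one shared peak of normalized intensity 1/sqrt(2) each: score = 0.5
  expect_equal(cs$score, 0.5, tolerance = 1e-12)
  expect_equal(cs$n_matched, 1L)
})

test_that("cosine score is symmetric in its arguments", {
  set.seed(2)
  for (k in 1:5) {
    a <- spec_fix("a", runif(1, 300, 600), sort(runif(10, 100, 500)),
                  runif(10, 1, 100))
    b <- spec_fix("b", runif(1, 300, 600), sort(runif(10, 100, 500)),
                  runif(10, 1, 100))
    ab <- cosine_score(a, b)
    ba <- cosine_score(b, a)
    expect_equal(ab$score, ba$score, tolerance = 1e-12)
    expect_equal(ab$n_matched, ba$n_matched)
  }
})

test_that("modified cosine pairs peaks shifted by the precursor difference", {
  ## fragment sets offset by exactly the 10 Da precursor difference
  s1 <- spec_fix("s1", 400.0, c(100.0, 150.0, 200.0), c(3, 2, 1))
  s2 <- spec_fix("s2", 410.0, c(110.0, 160.0, 210.0), c(3, 2, 1))
  classic <- cosine_score(s1, s2, network_params(use_modified_cosine = FALSE))
  modified <- cosine_score(s1, s2, network_params())
  expect_identical(classic$score, 0)
  expect_equal(modified$score, 1.0, tolerance = 1e-12)
  expect_equal(modified$n_matched, 3L)
})

test_that("greedy matching never exceeds the exact assignment", {
  set.seed(3)
  for (k in 1:20) {
    a <- spec_fix("a", 400, sort(runif(7, 100, 120)), runif(7, 1, 10))
    b <- spec_fix("b", 400, sort(runif(7, 100, 120)), runif(7, 1, 10))
    g <- cosine_score(a, b, network_params(fragment_tol = 2))
    e <- cosine_score(a, b, network_params(fragment_tol = 2,
                                           matching = "exact"))
    expect_lte(g$score, e$score + 1e-12)
  }
  ## non-ambiguous fixture: both strategies agree exactly
  a <- spec_fix("a", 400, c(100, 110, 120), c(5, 3, 1))
  b <- spec_fix("b", 400, c(100.01, 110.01, 120.01), c(5, 3, 1))
  g <- cosine_score(a, b)
  e <- cosine_score(a, b, network_params(matching = "exact"))
  expect_equal(g$score, e$score, tolerance = 1e-12)
  expect_equal(g$n_matched, e$n_matched)
})

test_that("merge_identical collapses duplicates and keeps distinct spectra", {
  set.seed(4)
  base <- spec_fix("s1", 400.0, sort(runif(8, 100, 390)), runif(8, 10, 100))
  dup1 <- msms_spectrum("s2", 400.0, base$fragments, ion_mode = "NEG")
  dup2 <- msms_spectrum("s3", 400.001, base$fragments, ion_mode = "NEG")
  other <- spec_fix("s4", 500.0, sort(runif(8, 600, 900)), runif(8, 10, 100))
  merged <- merge_identical(list(base, dup1, dup2, other))
  expect_length(merged, 2)
  expect_equal(attr(merged[[1]], "n_merged"), 3L)
  ## all-distinct input is untouched
  distinct <- list(base, other)
  expect_length(merge_identical(distinct), 2)
})

test_that("network edges respect both the cutoff and matched-peak minimum", {
  s <- small_synth(seed = 5, n_features = 150)
  spectra <- generate_spectra(s$cfg, s$gen$matrix, s$gen$spikes)
  params <- network_params()
  net <- build_network(spectra, params)
  expect_true(all(net$edges$cosine >= params$cosine_cutoff))
  expect_true(all(net$edges$n_matched >= params$min_matched_peaks))
  ## components partition the node set
  expect_setequal(net$nodes$spectrum_id,
                  vapply(spectra, function(x) x$spectrum_id, character(1)))
  expect_false(anyNA(net$nodes$component))
  ## clusters all reach the minimum size
  expect_true(all(lengths(net$clusters) >= params$min_cluster_size))
})

test_that("components equal an independent union-find oracle", {
  s <- small_synth(seed = 6, n_features = 150)
  spectra <- generate_spectra(s$cfg, s$gen$matrix, s$gen$spikes)
  net <- build_network(spectra, network_params())
  oracle <- union_find_oracle(net$nodes$spectrum_id,
                              net$edges$from, net$edges$to)
  ## same partition up to label names
  tab <- table(net$nodes$component, oracle)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("a three-member family forms one component of size three", {
  cfg <- synthetic_config(n_features = 100, n_spectrum_families = 1,
                          n_bioactive = 1, n_singleton_spectra = 0, seed = 8)
  gen <- generate_fraction_profiles(cfg)
  spectra <- generate_spectra(cfg, gen$matrix, gen$spikes)
  fam1 <- spectra[1:3]
  net <- build_network(fam1, network_params())
  expect_equal(length(unique(net$nodes$component)), 1L)
  expect_equal(nrow(net$nodes), 3L)
  ## with an impossible cutoff no edges survive
  net0 <- build_network(fam1, network_params(cosine_cutoff = 1.0))
  net0_ok <- nrow(net0$edges) == 0 ||
    all(net0$edges$cosine >= 1 - 1e-12)
  expect_true(net0_ok)
  ## empty input gives an empty network
  empty <- build_network(list(), network_params())
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("bioactivity mapping produces normalized slices and sane bins", {
  x <- rbind(c(100, 0, 0, 0), c(0, 25, 25, 50), c(10, 10, 10, 10),
             c(0, 0, 0, 0), c(5, 5, 0, 0))
  x <- t(x)  # 4 fractions x 5 features
  colnames(x) <- sprintf("1.%02d_%s", 10:14,
                         c("200.1000", "300.2000", "400.3000", "500.4000",
                           "600.5000"))
  rownames(x) <- paste0("A", 1:4)
  fm <- feature_matrix(x, "NEG")
  bio <- bioactivity(paste0("A", 1:4), c(110, 75, 40, 103))
  specs <- list(spec_fix("n1", 200.1000, c(100, 110, 120, 130, 140, 150)),
                spec_fix("n2", 300.2000, c(100, 110, 120, 130, 140, 150)),
                spec_fix("n3", 400.3000, c(100, 110, 120, 130, 140, 150)),
                spec_fix("n4", 999.9000, c(100, 110, 120, 130, 140, 150)))
  net <- build_network(specs, network_params())
  net <- map_bioactivity(net, fm, bio)
  ## feature present in exactly one fraction: single slice of weight 1
  s1 <- net$slices[["n1"]]
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$weight, 1.0)
  expect_identical(s1$bin, "full")
  ## equal intensity in 4 fractions: four slices of 0.25
  s3 <- net$slices[["n3"]]
  expect_equal(sort(s3$weight), rep(0.25, 4))
  ## weights always sum to one
  for (sl in net$slices) expect_equal(sum(sl$weight), 1.0)
  ## unmatched node flagged, not an error
  expect_identical(net$nodes$main_bin[net$nodes$spectrum_id == "n4"],
                   "unmapped")
})

test_that("a spike concentrated in protective fractions maps to the top bin", {
  cfg <- synthetic_config(n_features = 120, n_spectrum_families = 3,
                          seed = 9)
  gen <- generate_fraction_profiles(cfg)
  spectra <- generate_spectra(cfg, gen$matrix, gen$spikes)
  net <- build_network(spectra, network_params())
  net <- map_bioactivity(net, gen$matrix, gen$viability)
  ## the strongest protective spike anchors family 1, spectrum fam01_m1
  sl <- net$slices[["fam01_m1"]]
  expect_false(is.null(sl))
  by_bin <- tapply(sl$weight, sl$bin, sum)
  top <- names(by_bin)[which.max(by_bin)]
  ## its abundance mass sits in fractions above 50% viability
  expect_gt(sum(sl$weight[sl$viability_pct >= 50]), 0.5)
  expect_true(top %in% c("partial", "full"))
})

test_that("GraphML export and import round-trip the network", {
  dir <- withr::local_tempdir()
  ## empty network
  empty <- build_network(list(), network_params())
  p0 <- file.path(dir, "empty.graphml")
  export_graphml(empty, p0)
  back0 <- read_graphml(p0)
  expect_equal(nrow(back0$nodes), 0L)
  ## three-node family
  cfg <- synthetic_config(n_features = 100, n_spectrum_families = 1,
                          n_bioactive = 1, n_singleton_spectra = 0, seed = 8)
  gen <- generate_fraction_profiles(cfg)
  spectra <- generate_spectra(cfg, gen$matrix, gen$spikes)[1:3]
  net <- build_network(spectra, network_params())
  net <- map_bioactivity(net, gen$matrix, gen$viability)
  p1 <- file.path(dir, "fam.graphml")
  export_graphml(net, p1)
  back <- read_graphml(p1)
  expect_equal(nrow(back$nodes), 3L)
  expect_equal(nrow(back$edges), nrow(net$edges))
  expect_setequal(back$nodes$spectrum_id, net$nodes$spectrum_id)
  ord <- match(net$nodes$spectrum_id, back$nodes$spectrum_id)
  expect_equal(back$nodes$precursor_mz[ord], net$nodes$precursor_mz,
               tolerance = 1e-9)
  expect_identical(back$nodes$main_bin[ord], net$nodes$main_bin)
  if (nrow(net$edges)) {
    expect_equal(sort(back$edges$cosine), sort(net$edges$cosine),
                 tolerance = 1e-9)
    expect_equal(sort(back$edges$n_matched), sort(net$edges$n_matched))
  }
  ## slice attribute serialized non-trivially for mapped nodes
  expect_true(any(nzchar(back$nodes$slices)))
})

test_that("MGF files round-trip spectra", {
  set.seed(10)
  spectra <- list(
    spec_fix("one", 400.12345, sort(runif(7, 100, 390)), runif(7, 1, 100)),
    msms_spectrum("two", 512.2, cbind(c(150.1, 200.2), c(5, 10)),
                  ion_mode = "POS", retention = 1.25))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, path)
  back <- read_mgf(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$precursor_mz, 400.12345, tolerance = 1e-5)
  expect_identical(back[[1]]$ion_mode, "NEG")
  expect_identical(back[[2]]$ion_mode, "POS")
  expect_equal(back[[2]]$retention, 1.25, tolerance = 1e-6)
  expect_equal(nrow(back[[1]]$fragments), 7)
  expect_equal(back[[2]]$fragments[, "intensity"], c(5, 10),
               ignore_attr = TRUE)
})
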