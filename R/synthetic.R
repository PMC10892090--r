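#' Configuration of the synthetic dataset generator
#'
#' The generator emulates a fractionated botanical extract profiled by
#' flow-injection HRMS: 21 fractions, >1500 molecular features with smooth
#' elution-like abundance gradients across the fraction series, a small set
#' of spiked bioactive features whose log-intensities linearly drive the
#' viability readout (clipped to the 5-117\% range seen in such assays),
#' adduct/isotopologue satellite features, MS/MS spectra in structurally
#' related families sharing fragments, and a compound library with decoys.
#'
#' @param n_fractions number of fractions (default 21).
#' @param n_features number of base molecular features (default 1500;
#'   satellites are appended on top).
#' @param n_bioactive number of spiked bioactive features (default 3; must
#'   be < \code{n_features}).
#' @param effect_sizes signed viability change (percentage points) per unit
#'   log-intensity for each spike; recycled to \code{n_bioactive}. Default
#'   \code{c(6, 5, 4)}: protective congeners of graded potency, sized so
#'   that viability rarely hits the clip bounds.
#' @param noise_sd Gaussian viability (assay) noise, percentage points
#'   (default 4).
#' @param profile_noise_sd log-scale SD of the fraction-specific
#'   compositional variability applied to every feature profile (default
#'   0.7).
#' @param congener_sd log-scale SD of the irregular abundance component
#'   shared by all spiked bioactives (default 1.0): chemically related
#'   congeners co-partition through every separation step, so their
#'   cross-fraction profiles co-vary tightly.
#' @param spike_jitter_sd log-scale SD of each spike's individual
#'   variability around the shared congener profile (default 0.4).
#' @param viability_range clip bounds for viability, percent (default
#'   \code{c(5, 117)}); use \code{c(-Inf, Inf)} to disable clipping.
#' @param adduct_satellites_per_feature satellites added per chosen parent
#'   (default 1).
#' @param satellite_parent_fraction share of features receiving satellites
#'   (default 0.05).
#' @param n_spectrum_families number of MS/MS spectrum families (default 8;
#'   must be >= \code{n_bioactive} so every spike owns a family).
#' @param fragments_per_spectrum fragment peaks per spectrum (default 12;
#'   at least 6 are required downstream for a network edge).
#' @param n_singleton_spectra unrelated singleton spectra (default 5).
#' @param lod limit of detection: intensities below it are set to 0
#'   (default 500; spiked features are kept above it so the bioactives are
#'   quantifiable in every fraction).
#' @param ion_mode ionization mode tag of the generated matrix.
#' @param seed RNG seed; identical configs produce identical datasets.
#' @return a \code{synthetic_config} object.
#' @export
synthetic_config <- function(n_fractions = 21L, n_features = 1500L,
                             n_bioactive = 3L,
                             effect_sizes = c(6, 5, 4),
                             noise_sd = 4, profile_noise_sd = 0.7,
                             congener_sd = 1.0, spike_jitter_sd = 0.4,
                             viability_range = c(5, 117),
                             adduct_satellites_per_feature = 1L,
                             satellite_parent_fraction = 0.05,
                             n_spectrum_families = 8L,
                             fragments_per_spectrum = 12L,
                             n_singleton_spectra = 5L,
                             lod = 500, ion_mode = c("NEG", "POS"),
                             seed = 1L) {
  ion_mode <- match.arg(ion_mode)
  if (n_fractions < 1 || n_features < 1 || n_bioactive < 0)
    stop("counts must be positive")
  if (n_bioactive >= n_features)
    stop("n_bioactive must be smaller than n_features")
  if (length(viability_range) != 2 ||
      viability_range[1] >= viability_range[2])
    stop("viability_range must be (low, high) with low < high")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_spectrum_families < n_bioactive)
    stop("need at least one spectrum family per bioactive spike")
  structure(list(
    n_fractions = as.integer(n_fractions),
    n_features = as.integer(n_features),
    n_bioactive = as.integer(n_bioactive),
    effect_sizes = if (n_bioactive > 0)
      rep_len(effect_sizes, n_bioactive) else numeric(0),
    noise_sd = noise_sd, profile_noise_sd = profile_noise_sd,
    congener_sd = congener_sd, spike_jitter_sd = spike_jitter_sd,
    viability_range = as.numeric(viability_range),
    adduct_satellites_per_feature = as.integer(adduct_satellites_per_feature),
    satellite_parent_fraction = satellite_parent_fraction,
    n_spectrum_families = as.integer(n_spectrum_families),
    fragments_per_spectrum = as.integer(fragments_per_spectrum),
    n_singleton_spectra = as.integer(n_singleton_spectra),
    lod = lod, ion_mode = ion_mode, seed = as.integer(seed)),
    class = "synthetic_config")
}

## draw n unique "RT_mz" ids; resample colliding rows until unique
draw_feature_ids <- function(n, rt_range = c(0.5, 2.5),
                             mz_range = c(150, 800)) {
  rt <- round(stats::runif(n, rt_range[1], rt_range[2]), 2)
  mz <- round(stats::runif(n, mz_range[1], mz_range[2]), 4)
  ids <- format_feature_id(rt, mz)
  while (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))
    mz[dup] <- round(stats::runif(length(dup), mz_range[1], mz_range[2]), 4)
    ids <- format_feature_id(rt, mz)
  }
  list(rt = rt, mz = mz, ids = ids)
}

#' Generate a fraction-profile matrix with a known bioactivity ground truth
#'
#' Each feature follows a unimodal, elution-like Gaussian bump over the
#' fraction index (random center, width and log-normal amplitude) on top of
#' a trace-level baseline (carry-over keeps most compounds detectable in
#' every fraction), multiplied by strong fraction-specific compositional
#' variability (\code{profile_noise_sd} on the log scale) — fraction series
#' from multi-step separations are patchy, not smooth. Spiked bioactive
#' features are abundant congeners that co-elute in one interior window of
#' the series and share an irregular abundance component
#' (\code{congener_sd}) with small individual deviations
#' (\code{spike_jitter_sd}). Viability is
#' \deqn{v_i = clip(b_0 + \sum_s c_s \log x_{is} + \epsilon_i)}
#' with \eqn{\epsilon_i \sim N(0, noise\_sd^2)} and clip bounds from
#' \code{viability_range}; the intercept \eqn{b_0} centers mean viability
#' at 60\%. Satellite features (13C isotopologue and Na-H adduct offsets)
#' are appended for a subset of parents with proportional, near-perfectly
#' correlated profiles. Intensities below \code{lod} are zeroed (except for
#' spiked features, which stay quantifiable).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{matrix} (a \code{\link{feature_matrix}}),
#'   \code{viability} (a \code{\link{bioactivity}}), \code{spikes} (data
#'   frame: \code{feature_id}, \code{true_coefficient}, \code{family_id})
#'   and \code{satellites} (data frame: \code{parent_id},
#'   \code{satellite_id}, \code{offset}).
#' @export
generate_fraction_profiles <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_fractions; p <- config$n_features
    idinfo <- draw_feature_ids(p)
    amp <- stats::rlnorm(p, log(1e5), 1)
    center <- stats::runif(p, 1, n)
    width <- stats::runif(p, 1.5, 3.5)
    fr <- seq_len(n)
    ## trace baseline (carry-over) + elution bump, times strong
    ## fraction-specific compositional variability
    X <- vapply(seq_len(p), function(j) {
      amp[j] * (0.02 + exp(-(fr - center[j])^2 / (2 * width[j]^2)))
    }, numeric(n))
    X <- X * exp(matrix(stats::rnorm(n * p, 0, config$profile_noise_sd),
                        n, p))

    spikes <- data.frame(feature_id = character(0),
                         true_coefficient = numeric(0),
                         family_id = integer(0), stringsAsFactors = FALSE)
    spike_idx <- integer(0)
    if (config$n_bioactive > 0) {
      spike_idx <- sample.int(p, config$n_bioactive)
      ## bioactive congeners: abundant, co-eluting in one interior window,
      ## sharing an irregular cross-fraction abundance component
      amp_s <- stats::rlnorm(config$n_bioactive, log(3e5), 0.3)
      w_center <- stats::runif(1, n / 3, 2 * n / 3)
      ctr_s <- w_center + stats::runif(config$n_bioactive, -0.75, 0.75)
      wid_s <- stats::runif(config$n_bioactive, 2, 3)
      u <- stats::rnorm(n, 0, config$congener_sd)
      for (k in seq_along(spike_idx)) {
        j <- spike_idx[k]
        bump <- exp(-(fr - ctr_s[k])^2 / (2 * wid_s[k]^2))
        X[, j] <- amp_s[k] * (0.02 + bump) *
          exp(u + stats::rnorm(n, 0, config$spike_jitter_sd))
      }
      spikes <- data.frame(feature_id = idinfo$ids[spike_idx],
                           true_coefficient = config$effect_sizes,
                           family_id = seq_len(config$n_bioactive),
                           stringsAsFactors = FALSE)
    }

    ## viability from spike log-intensities
    eps <- stats::rnorm(n, 0, config$noise_sd)
    contrib <- 0
    if (length(spike_idx)) {
      logs <- log(X[, spike_idx, drop = FALSE])
      contrib <- as.numeric(logs %*% config$effect_sizes)
      b0 <- 60 - mean(contrib)
    } else b0 <- 60
    v <- pmin(pmax(b0 + contrib + eps, config$viability_range[1]),
              config$viability_range[2])

    ## limit of detection (spiked features stay quantifiable)
    floor_mask <- X < config$lod
    if (length(spike_idx)) floor_mask[, spike_idx] <- FALSE
    X[floor_mask] <- 0

    ## satellite features: proportional, near-perfectly correlated profiles
    sats <- data.frame(parent_id = character(0), satellite_id = character(0),
                       offset = character(0), stringsAsFactors = FALSE)
    n_parents <- round(config$satellite_parent_fraction * p)
    if (n_parents > 0 && config$adduct_satellites_per_feature > 0) {
      parents <- sample(setdiff(seq_len(p), spike_idx), n_parents)
      offsets <- c("13C" = OFFSET_C13, "NaH" = OFFSET_NA_H)
      sat_cols <- list(); sat_rt <- numeric(0); sat_mz <- numeric(0)
      rows <- list()
      for (pa in parents) {
        for (s in seq_len(config$adduct_satellites_per_feature)) {
          oname <- names(offsets)[(s - 1L) %% length(offsets) + 1L]
          ratio <- stats::runif(1, 0.1, 0.5)
          prof <- ratio * X[, pa] * (1 + stats::rnorm(n, 0, 0.005))
          prof[prof < config$lod] <- 0
          if (all(prof == 0)) next
          sat_cols[[length(sat_cols) + 1L]] <- pmax(prof, 0)
          sat_rt <- c(sat_rt, idinfo$rt[pa])
          sat_mz <- c(sat_mz, round(idinfo$mz[pa] + offsets[[oname]], 4))
          rows[[length(rows) + 1L]] <- data.frame(
            parent_id = idinfo$ids[pa],
            satellite_id = format_feature_id(idinfo$rt[pa],
                                             idinfo$mz[pa] + offsets[[oname]]),
            offset = oname, stringsAsFactors = FALSE)
        }
      }
      if (length(sat_cols)) {
        sat_ids <- format_feature_id(sat_rt, sat_mz)
        keep <- !(sat_ids %in% idinfo$ids) & !duplicated(sat_ids)
        if (any(keep)) {
          X <- cbind(X, do.call(cbind, sat_cols[keep]))
          idinfo$ids <- c(idinfo$ids, sat_ids[keep])
          sats <- do.call(rbind, rows)[keep, ]
        }
      }
    }

    colnames(X) <- idinfo$ids
    rownames(X) <- paste0("A", fr)
    fm <- feature_matrix(X, ion_mode = config$ion_mode)
    bio <- bioactivity(fm$fraction_ids, v,
                       se_pct = config$noise_sd / sqrt(6), n_replicates = 6L)
    list(matrix = fm, viability = bio, spikes = spikes, satellites = sats)
  })
}

#' Generate MS/MS spectra in structurally related families
#'
#' Spectra come in families of 3-5 members that share a dominant set of
#' common fragment peaks (so that all within-family pairs reach cosine >=
#' 0.70 with >= 6 matched peaks) plus a few member-specific minor peaks;
#' fragment m/z windows of different families are disjoint, so inter-family
#' pairs share almost no matchable fragments. Family precursors are drawn
#' from the feature matrix so that network nodes can be mapped back to
#' molecular features; when \code{spikes} is supplied, family \code{f} of
#' the first \code{n_bioactive} families is anchored on spike \code{f}'s
#' feature. A handful of singleton spectra is appended.
#'
#' @param config a \code{\link{synthetic_config}} with
#'   \code{fragments_per_spectrum >= 6}.
#' @param fm the generated \code{\link{feature_matrix}} (precursor m/z
#'   values are taken from its features).
#' @param spikes optional spike table from
#'   \code{\link{generate_fraction_profiles}}.
#' @return list of \code{\link{msms_spectrum}} objects; each carries
#'   attribute \code{family} (integer, \code{NA} for singletons).
#' @export
generate_spectra <- function(config, fm, spikes = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(fm, "feature_matrix"))
  if (config$fragments_per_spectrum < 6)
    stop("fragments_per_spectrum must be >= 6 to satisfy the edge criterion")
  with_seed(config$seed + 1L, {
    fps <- config$fragments_per_spectrum
    n_common <- max(6L, ceiling(0.75 * fps))
    spectra <- list()
    used_feats <- integer(0)
    spike_pos <- if (!is.null(spikes) && nrow(spikes))
      match(spikes$feature_id, fm$feature_ids) else integer(0)

    for (f in seq_len(config$n_spectrum_families)) {
      size <- sample(3:5, 1)
      lo <- 120 + 70 * (f - 1)
      grid <- seq(lo, lo + 55, by = 0.3) +
        round(stats::runif(1, 0, 0.25), 4)
      common_mz <- sort(sample(grid, n_common))
      common_base <- stats::runif(n_common, 30, 100)
      rest_grid <- setdiff(grid, common_mz)

      members <- integer(size)
      if (f <= length(spike_pos) && !is.na(spike_pos[f]))
        members[1] <- spike_pos[f]
      avail <- setdiff(seq_along(fm$feature_ids),
                       c(used_feats, spike_pos, members))
      members[members == 0] <- sample(avail, sum(members == 0))
      used_feats <- c(used_feats, members)

      for (k in seq_len(size)) {
        n_u <- fps - n_common
        uniq_mz <- sort(sample(rest_grid, n_u))
        rest_grid <- setdiff(rest_grid, uniq_mz)
        frag <- rbind(
          cbind(mz = common_mz,
                intensity = common_base * stats::runif(n_common, 0.85, 1.15)),
          cbind(mz = uniq_mz, intensity = stats::runif(n_u, 2, 15)))
        j <- members[k]
        spectra[[length(spectra) + 1L]] <- structure(
          msms_spectrum(sprintf("fam%02d_m%d", f, k),
                        precursor_mz = fm$mz[j], fragments = frag,
                        ion_mode = fm$ion_mode, retention = fm$rt[j]),
          family = f)
      }
    }

    for (k in seq_len(config$n_singleton_spectra)) {
      grid <- seq(900, 980, by = 0.3)
      frag <- cbind(mz = sort(sample(grid, fps)),
                    intensity = stats::runif(fps, 5, 100))
      avail <- setdiff(seq_along(fm$feature_ids), used_feats)
      j <- sample(avail, 1)
      used_feats <- c(used_feats, j)
      spectra[[length(spectra) + 1L]] <- structure(
        msms_spectrum(sprintf("single%02d", k), precursor_mz = fm$mz[j],
                      fragments = frag, ion_mode = fm$ion_mode,
                      retention = fm$rt[j]),
        family = NA_integer_)
    }
    spectra
  })
}

#' Generate a compound library with reference entries and decoys
#'
#' Contains plant phenolics whose \code{[M-H]-} / \code{[M+H]+} ions fall
#' within 10 ppm of classic caffeoylquinic-acid and flavonoid feature m/z
#' values (mono-CQA at m/z 353.0874, di-CQA at 515.1191 in negative mode),
#' each with reference MS/MS fragments, plus decoy entries placed 50 ppm
#' away from the reference masses — outside any 10 ppm annotation window by
#' construction. Decoys falling within 10 ppm of a generated feature's
#' neutral mass are dropped when \code{fm} is supplied.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param fm optional \code{\link{feature_matrix}} used to screen decoys.
#' @return a \code{\link{compound_library}}.
#' @export
generate_library <- function(config = synthetic_config(), fm = NULL) {
  refs <- data.frame(
    name = c("mono-CQA", "di-CQA", "quercetin", "caffeic acid",
             "asiatic acid"),
    neutral_mass = c(354.095082, 516.126782, 302.042653, 180.042259,
                     488.350173),
    fragments = c("191.0556;179.0345;135.0441",
                  "353.0878;191.0556;179.0345;173.0450;135.0441",
                  "151.0026;121.0295;107.0139",
                  "135.0441;134.0368",
                  ""),
    stringsAsFactors = FALSE)
  decoys <- data.frame(
    name = paste0("decoy_", seq_len(nrow(refs) + 3)),
    neutral_mass = c(refs$neutral_mass * (1 + 50e-6),
                     c(258.075496, 420.1234, 611.9876)),
    fragments = "", stringsAsFactors = FALSE)
  if (!is.null(fm)) {
    neutral <- neutral_mass(fm$mz, fm$ion_mode)
    clash <- vapply(decoys$neutral_mass, function(m) {
      any(abs(1e6 * (neutral - m) / m) <= 10)
    }, logical(1))
    decoys <- decoys[!clash, ]
  }
  compound_library(rbind(refs, decoys))
}

#' Write a complete synthetic dataset to disk
#'
#' Writes the feature table, viability table, MGF spectra and compound
#' library generated from one \code{\link{synthetic_config}}, plus the
#' ground-truth spike table.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_fraction_profiles(config)
  spectra <- generate_spectra(config, gen$matrix, gen$spikes)
  lib <- generate_library(config, gen$matrix)
  cm <- sprintf("seed=%d", config$seed)
  paths <- c(
    features = file.path(dir, sprintf("features_%s.csv", config$ion_mode)),
    viability = file.path(dir, "viability.csv"),
    mgf = file.path(dir, "spectra.mgf"),
    library = file.path(dir, "library.csv"),
    spikes = file.path(dir, "spikes.csv"))
  write_feature_table(gen$matrix, paths[["features"]], comment = cm)
  write_viability_table(gen$viability, paths[["viability"]], comment = cm)
  write_mgf(spectra, paths[["mgf"]])
  write_compound_library(lib, paths[["library"]], comment = cm)
  utils::write.csv(gen$spikes, paths[["spikes"]], row.names = FALSE)
  invisible(paths)
}
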