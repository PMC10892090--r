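#' Adduct / isotopologue grouping rules
#'
#' A rule describes a satellite ion expected at a fixed mass offset from its
#' parent feature. Two features are grouped when their m/z values differ by
#' the rule offset (within \code{mz_tol} of \code{\link{deconvolute}}), their
#' retention times agree within \code{max_rt_diff}, and their cross-fraction
#' intensity profiles correlate at least \code{min_profile_correlation}.
#'
#' @param name rule label.
#' @param mass_offset offset in Da (non-zero); positive means the satellite
#'   is heavier than the parent.
#' @param max_rt_diff maximal retention-time difference, minutes.
#' @param min_profile_correlation Pearson threshold in \[-1, 1\].
#' @return an \code{adduct_rule} object.
#' @export
adduct_rule <- function(name, mass_offset, max_rt_diff = 0.05,
                        min_profile_correlation = 0.9) {
  if (mass_offset == 0) stop("mass_offset must be non-zero")
  if (min_profile_correlation < -1 || min_profile_correlation > 1)
    stop("min_profile_correlation must be in [-1, 1]")
  structure(list(name = name, mass_offset = mass_offset,
                 max_rt_diff = max_rt_diff,
                 min_profile_correlation = min_profile_correlation),
            class = "adduct_rule")
}

#' @rdname adduct_rule
#' @details \code{default_adduct_rules} returns the 13C isotopologue spacing
#'   (+1.003355 Da) and the sodium adduct offset (Na-H, +21.981944 Da).
#' @export
default_adduct_rules <- function() {
  list(adduct_rule("13C isotopologue", OFFSET_C13),
       adduct_rule("Na adduct (Na-H)", OFFSET_NA_H))
}

#' Collapse adduct and isotopologue satellites into molecular features
#'
#' Flow-injection spectra contain several ions per compound (isotopologues,
#' sodium adducts, ...). This step assembles such satellite features into one
#' molecular feature per compound: features linked by any
#' \code{\link{adduct_rule}} are grouped transitively, the group intensity is
#' the sum over members, and the representative ID is the member with the
#' lowest m/z (the presumed parent ion). Total matrix intensity is conserved.
#'
#' @param fm a \code{\link{feature_matrix}} (raw intensities).
#' @param rules list of \code{\link{adduct_rule}}s.
#' @param mz_tol tolerance (Da) around each rule offset.
#' @return a list with elements \code{matrix} (the collapsed
#'   \code{feature_matrix}) and \code{groups} (data frame of merges:
#'   \code{group}, \code{parent_id}, \code{member_id}, \code{rule}).
#' @export
deconvolute <- function(fm, rules = default_adduct_rules(), mz_tol = 0.01) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$transformed) stop("deconvolute expects raw (untransformed) intensities")
  p <- length(fm$feature_ids)
  ord <- order(fm$mz)
  mz <- fm$mz[ord]; rt <- fm$rt[ord]
  X <- fm$intensities[, ord, drop = FALSE]
  sds <- apply(X, 2, stats::sd)

  links <- list()
  for (rule in rules) {
    off <- rule$mass_offset
    for (i in seq_len(p)) {
      target <- mz[i] + off
      js <- which(mz >= target - mz_tol & mz <= target + mz_tol)
      js <- js[js != i & abs(rt[js] - rt[i]) <= rule$max_rt_diff]
      for (j in js) {
        if (sds[i] == 0 || sds[j] == 0) next
        r <- stats::cor(X[, i], X[, j])
        if (!is.na(r) && r >= rule$min_profile_correlation) {
          links[[length(links) + 1L]] <-
            data.frame(i = i, j = j, rule = rule$name,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }

  if (!length(links)) {
    return(list(matrix = fm,
                groups = data.frame(group = integer(), parent_id = character(),
                                    member_id = character(), rule = character(),
                                    stringsAsFactors = FALSE)))
  }

  links <- do.call(rbind, links)
  g <- igraph::graph_from_edgelist(cbind(links$i, links$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, p - igraph::vcount(g)))
  comp <- igraph::components(g)$membership

  keep_id <- character(0); keep_cols <- list(); groups <- list(); gid <- 0L
  for (cm in unique(comp)) {
    members <- which(comp == cm)
    if (length(members) == 1L) {
      keep_id <- c(keep_id, fm$feature_ids[ord[members]])
      keep_cols[[length(keep_cols) + 1L]] <- X[, members]
    } else {
      gid <- gid + 1L
      parent <- members[which.min(mz[members])]
      keep_id <- c(keep_id, fm$feature_ids[ord[parent]])
      keep_cols[[length(keep_cols) + 1L]] <-
        rowSums(X[, members, drop = FALSE])
      rl <- links[links$i %in% members & links$j %in% members, ]
      groups[[gid]] <- data.frame(
        group = gid,
        parent_id = fm$feature_ids[ord[parent]],
        member_id = fm$feature_ids[ord[members]],
        rule = vapply(members, function(m) {
          if (m == parent) return("parent")
          hit <- rl$rule[rl$i == m | rl$j == m]
          if (length(hit)) hit[1] else "linked"
        }, character(1)),
        stringsAsFactors = FALSE)
    }
  }

  merged <- do.call(cbind, keep_cols)
  colnames(merged) <- keep_id
  ## restore ascending-m/z order of representatives
  out <- feature_matrix(merged, ion_mode = fm$ion_mode,
                        fraction_ids = fm$fraction_ids)
  list(matrix = out,
       groups = if (gid)
         do.call(rbind, groups)
       else data.frame(group = integer(), parent_id = character(),
                       member_id = character(), rule = character(),
                       stringsAsFactors = FALSE))
}

#' Natural-log transform of intensities and response
#'
#' Both the predictors (feature intensities) and the response (viability) are
#' log-transformed before model fitting. Zeros in the intensity matrix are
#' handled by a pseudo-count \eqn{\delta}: by default half the smallest
#' non-zero intensity of the matrix (scale-adaptive), or a user constant.
#'
#' @param fm a \code{\link{feature_matrix}} with non-negative intensities.
#' @param pseudocount \code{"half-min"} (default) or a non-negative number.
#' @return a \code{feature_matrix} with \code{transformed = TRUE}.
#' @export
log_transform <- function(fm, pseudocount = "half-min") {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$intensities
  if (all(x == 0)) stop("all-zero intensity matrix cannot be log-transformed")
  if (identical(pseudocount, "half-min")) {
    delta <- min(x[x > 0]) / 2
  } else {
    delta <- as.numeric(pseudocount)
    if (is.na(delta) || delta < 0) stop("pseudocount must be >= 0 or 'half-min'")
  }
  out <- feature_matrix(log(x + delta), ion_mode = fm$ion_mode,
                        feature_ids = fm$feature_ids,
                        fraction_ids = fm$fraction_ids, transformed = TRUE)
  attr(out, "pseudocount") <- delta
  out
}

#' @rdname log_transform
#' @param bio a \code{\link{bioactivity}} object.
#' @param floor_pct viability values below this are raised to it before the
#'   log (default 1\%), so fractions with complete cell death stay finite.
#' @return \code{log_transform_response} returns a numeric vector of
#'   log-viability values.
#' @export
log_transform_response <- function(bio, floor_pct = 1) {
  stopifnot(inherits(bio, "bioactivity"))
  log(pmax(bio$viability_pct, floor_pct))
}

#' Optional total-intensity normalization
#'
#' Scales every fraction (row) to the same total intensity (the mean of the
#' raw row sums). Off by default in the pipeline: fractions of an extract
#' genuinely differ in load, and that variation is part of the signal the
#' ranking models exploit.
#'
#' @param fm a \code{\link{feature_matrix}}.
#' @return a normalized \code{feature_matrix}.
#' @export
normalize_total_intensity <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  tot <- rowSums(fm$intensities)
  if (any(tot == 0)) stop("cannot normalize: a fraction has zero total intensity")
  x <- fm$intensities * (mean(tot) / tot)
  feature_matrix(x, ion_mode = fm$ion_mode, feature_ids = fm$feature_ids,
                 fraction_ids = fm$fraction_ids, transformed = fm$transformed)
}

#' Pearson correlation of one feature with viability
#'
#' The simple univariate association between a feature's intensity and the
#' viability readout across fractions, reported alongside the multivariate
#' ranks in the consensus table.
#'
#' @param fm a \code{\link{feature_matrix}}.
#' @param bio a \code{\link{bioactivity}} aligned with \code{fm}.
#' @param feature_id the feature to correlate.
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_feature_viability <- function(fm, bio, feature_id) {
  stopifnot(inherits(fm, "feature_matrix"))
  check_aligned(fm, bio)
  if (length(fm$fraction_ids) < 3)
    stop("need at least 3 fractions for a correlation")
  k <- match(feature_id, fm$feature_ids)
  if (is.na(k)) stop("no such feature: ", feature_id)
  x <- fm$intensities[, k]
  if (stats::sd(x) == 0)
    stop("feature '", feature_id, "' has zero variance; correlation undefined")
  if (stats::sd(bio$viability_pct) == 0)
    stop("viability has zero variance; correlation undefined")
  stats::cor(x, bio$viability_pct)
}
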