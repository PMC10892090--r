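#' Molecular-network parameters
#'
#' Defaults mirror the standard GNPS-style settings: precursor tolerance
#' 0.01 Da, fragment tolerance 0.05 Da, cosine cutoff 0.70, at least 6
#' matched peaks per edge, reported clusters of 3 or more nodes, and the
#' modified cosine (precursor-shift peak pairing) switched on.
#'
#' @param precursor_tol precursor m/z tolerance, Da.
#' @param fragment_tol fragment m/z tolerance, Da.
#' @param cosine_cutoff minimum cosine score for an edge, in \[0, 1\].
#' @param min_matched_peaks minimum number of matched fragment peaks per edge.
#' @param min_cluster_size minimum component size counted as a cluster.
#' @param use_modified_cosine also pair peaks offset by the precursor mass
#'   difference (modified cosine) rather than direct matches only.
#' @param matching \code{"greedy"} (best-pair-first, each peak used once) or
#'   \code{"exact"} (optimal assignment; exhaustive, for small spectra).
#' @return a \code{network_params} object.
#' @export
network_params <- function(precursor_tol = 0.01, fragment_tol = 0.05,
                           cosine_cutoff = 0.70, min_matched_peaks = 6L,
                           min_cluster_size = 3L,
                           use_modified_cosine = TRUE,
                           matching = c("greedy", "exact")) {
  if (precursor_tol <= 0 || fragment_tol <= 0) stop("tolerances must be > 0")
  if (cosine_cutoff < 0 || cosine_cutoff > 1)
    stop("cosine_cutoff must be in [0, 1]")
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 cosine_cutoff = cosine_cutoff,
                 min_matched_peaks = as.integer(min_matched_peaks),
                 min_cluster_size = as.integer(min_cluster_size),
                 use_modified_cosine = isTRUE(use_modified_cosine),
                 matching = match.arg(matching)),
            class = "network_params")
}

#' Cosine similarity between two MS/MS spectra
#'
#' Fragment intensities are L2-normalized per spectrum; candidate peak pairs
#' are those within \code{fragment_tol} of each other directly and — for the
#' modified cosine — those whose m/z difference equals the precursor mass
#' difference within the same tolerance. Pairs are accepted greedily by
#' descending intensity product with each peak used at most once (or by the
#' optimal assignment with \code{matching = "exact"}); the score is the sum
#' of products of the paired normalized intensities. Identical spectra score
#' exactly 1; spectra with no pairable fragments score exactly 0. The score
#' is symmetric in its arguments.
#'
#' @param a,b \code{\link{msms_spectrum}} objects.
#' @param params a \code{\link{network_params}}.
#' @return list with \code{score} in \[0, 1\] and \code{n_matched}, the
#'   number of paired peaks.
#' @export
cosine_score <- function(a, b, params = network_params()) {
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  mza <- a$fragments[, "mz"]; ia <- a$fragments[, "intensity"]
  mzb <- b$fragments[, "mz"]; ib <- b$fragments[, "intensity"]
  na_ <- sqrt(sum(ia^2)); nb_ <- sqrt(sum(ib^2))
  if (na_ == 0 || nb_ == 0) return(list(score = 0, n_matched = 0L))
  ia <- ia / na_; ib <- ib / nb_

  tol <- params$fragment_tol
  d <- outer(mza, mzb, "-")
  cand <- abs(d) <= tol
  if (params$use_modified_cosine) {
    shift <- a$precursor_mz - b$precursor_mz
    cand <- cand | (abs(d - shift) <= tol)
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(score = 0, n_matched = 0L))
  prod <- ia[idx[, 1]] * ib[idx[, 2]]

  if (params$matching == "greedy") {
    ord <- order(-prod, idx[, 1], idx[, 2])
    usedA <- logical(length(mza)); usedB <- logical(length(mzb))
    score <- 0; n <- 0L
    for (k in ord) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (usedA[i] || usedB[j]) next
      usedA[i] <- TRUE; usedB[j] <- TRUE
      score <- score + prod[k]; n <- n + 1L
    }
  } else {
    res <- exact_assignment(idx, prod, length(mza), length(mzb))
    score <- res$score; n <- res$n
  }
  list(score = min(score, 1), n_matched = n)
}

## exhaustive maximum-weight one-to-one assignment over candidate pairs,
## with a suffix-sum bound for pruning; intended for small spectra
exact_assignment <- function(idx, prod, nA, nB) {
  ord <- order(-prod)
  idx <- idx[ord, , drop = FALSE]; prod <- prod[ord]
  m <- length(prod)
  suffix <- rev(cumsum(rev(prod)))
  best <- new.env(parent = emptyenv())
  best$score <- -Inf; best$n <- 0L
  recurse <- function(k, usedA, usedB, acc, n) {
    if (acc > best$score || (acc == best$score && n > best$n)) {
      best$score <- acc; best$n <- n
    }
    if (k > m || acc + suffix[k] <= best$score) return(invisible())
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      recurse(k + 1L, usedA, usedB, acc + prod[k], n + 1L)
      usedA[i] <- FALSE; usedB[j] <- FALSE
    }
    recurse(k + 1L, usedA, usedB, acc, n)
  }
  recurse(1L, logical(nA), logical(nB), 0, 0L)
  list(score = best$score, n = best$n)
}
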