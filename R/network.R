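#' Merge near-identical MS/MS spectra into consensus spectra
#'
#' Greedy single-pass clustering of replicate spectra: a spectrum joins an
#' existing consensus when its precursor is within \code{precursor_tol} and
#' its (classic) cosine against the consensus is at least
#' \code{merge_cosine}. Consensus fragments are the intensity-weighted mean
#' m/z with summed intensities of the member peaks grouped within
#' \code{fragment_tol}.
#'
#' @param spectra list of \code{\link{msms_spectrum}} objects.
#' @param merge_cosine cosine threshold for merging (default 0.95).
#' @param precursor_tol precursor tolerance, Da.
#' @param fragment_tol fragment tolerance, Da.
#' @return list of consensus \code{\link{msms_spectrum}} objects (length <=
#'   input length); each carries an attribute \code{n_merged}.
#' @export
merge_identical <- function(spectra, merge_cosine = 0.95,
                            precursor_tol = 0.01, fragment_tol = 0.05) {
  if (!length(spectra)) return(list())
  params <- network_params(precursor_tol = precursor_tol,
                           fragment_tol = fragment_tol,
                           use_modified_cosine = FALSE)
  out <- list()
  counts <- integer(0)
  for (s in spectra) {
    stopifnot(inherits(s, "msms_spectrum"))
    placed <- FALSE
    for (k in seq_along(out)) {
      if (out[[k]]$ion_mode != s$ion_mode) next
      if (abs(out[[k]]$precursor_mz - s$precursor_mz) > precursor_tol) next
      cs <- cosine_score(out[[k]], s, params)
      if (cs$score >= merge_cosine) {
        out[[k]] <- consensus_spectrum(out[[k]], s, fragment_tol,
                                       counts[k])
        counts[k] <- counts[k] + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      out[[length(out) + 1L]] <- s
      counts[length(out)] <- 1L
    }
  }
  for (k in seq_along(out)) attr(out[[k]], "n_merged") <- counts[k]
  out
}

## merge spectrum b into consensus a (a currently represents n_a members):
## pool peaks, group within tol, intensity-weighted mean m/z, summed intensity
consensus_spectrum <- function(a, b, fragment_tol, n_a) {
  frag <- rbind(a$fragments, b$fragments)
  frag <- frag[order(frag[, "mz"]), , drop = FALSE]
  grp <- cumsum(c(1, diff(frag[, "mz"]) > fragment_tol))
  mz <- tapply(seq_len(nrow(frag)), grp, function(ix) {
    stats::weighted.mean(frag[ix, "mz"], pmax(frag[ix, "intensity"], 1e-12))
  })
  it <- tapply(frag[, "intensity"], grp, sum)
  pm <- (a$precursor_mz * n_a + b$precursor_mz) / (n_a + 1)
  msms_spectrum(a$spectrum_id, pm, cbind(mz = as.numeric(mz),
                                         intensity = as.numeric(it)),
                ion_mode = a$ion_mode, retention = a$retention,
                charge = a$charge)
}

#' Build a molecular network from MS/MS spectra
#'
#' All spectrum pairs are scored with \code{\link{cosine_score}}; an edge is
#' kept when the score reaches \code{cosine_cutoff} \emph{and} the number of
#' matched peaks reaches \code{min_matched_peaks}. Connected components are
#' computed on the kept edges; components with at least
#' \code{min_cluster_size} nodes are reported as clusters (compound
#' families).
#'
#' @param spectra list of \code{\link{msms_spectrum}} (ideally after
#'   \code{\link{merge_identical}}).
#' @param params a \code{\link{network_params}}.
#' @return an object of class \code{spectral_network}: data frames
#'   \code{nodes} (spectrum_id, precursor_mz, ion_mode, retention, component,
#'   degree) and \code{edges} (from, to, cosine, n_matched), a list
#'   \code{clusters} of node-ID vectors, the \code{params}, and the input
#'   \code{spectra}.
#' @export
build_network <- function(spectra, params = network_params()) {
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate spectrum IDs")
  n <- length(spectra)
  edges <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        cs <- cosine_score(spectra[[i]], spectra[[j]], params)
        if (cs$score >= params$cosine_cutoff &&
            cs$n_matched >= params$min_matched_peaks) {
          edges[[length(edges) + 1L]] <-
            data.frame(from = ids[i], to = ids[j], cosine = cs$score,
                       n_matched = cs$n_matched, stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), cosine = numeric(),
               n_matched = integer(), stringsAsFactors = FALSE)

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$from, ids),
                                    match(edges$to, ids)))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)

  nodes <- data.frame(
    spectrum_id = ids,
    precursor_mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
    ion_mode = vapply(spectra, function(s) s$ion_mode, character(1)),
    retention = vapply(spectra, function(s) s$retention, numeric(1)),
    component = as.integer(comp$membership),
    degree = as.integer(deg),
    stringsAsFactors = FALSE)

  clusters <- lapply(which(comp$csize >= params$min_cluster_size),
                     function(cm) ids[comp$membership == cm])

  structure(list(nodes = nodes, edges = edges, clusters = clusters,
                 params = params, spectra = spectra),
            class = "spectral_network")
}

#' @export
print.spectral_network <- function(x, ...) {
  cat(sprintf(
    "<spectral_network> %d nodes, %d edges, %d components, %d clusters (>= %d nodes)\n",
    nrow(x$nodes), nrow(x$edges),
    length(unique(x$nodes$component)), length(x$clusters),
    x$params$min_cluster_size))
  invisible(x)
}

#' Map per-fraction bioactivity onto network nodes
#'
#' Each node's precursor is matched to a molecular feature of the intensity
#' matrix (same ionization mode, m/z within \code{precursor_tol}, retention
#' time within \code{rt_tol} when both are available; nearest m/z wins).
#' For a matched node, every fraction in which the feature is present
#' (intensity > 0) contributes a pie slice whose weight is the feature's
#' intensity in that fraction divided by the feature's total over included
#' fractions — slice weights sum to 1 — and each slice carries the
#' fraction's viability and its viability bin. Unmatched nodes are flagged
#' \code{"unmapped"}, not an error.
#'
#' @param network a \code{\link{build_network}} result.
#' @param fm a raw \code{\link{feature_matrix}}.
#' @param bio an aligned \code{\link{bioactivity}}.
#' @param bins named numeric vector of lower bin bounds in percent viability,
#'   default \code{c(low = 0, partial = 50, full = 100)}: full protection
#'   >= 100\%, partial 50-100\%, low < 50\%.
#' @param rt_tol retention-time tolerance in minutes for feature matching.
#' @return the network with \code{nodes$matched_feature},
#'   \code{nodes$main_bin} columns filled, and a named list element
#'   \code{slices}: per matched node a data frame (fraction, weight,
#'   viability_pct, bin).
#' @export
map_bioactivity <- function(network, fm, bio,
                            bins = c(low = 0, partial = 50, full = 100),
                            rt_tol = 0.2) {
  stopifnot(inherits(network, "spectral_network"),
            inherits(fm, "feature_matrix"))
  check_aligned(fm, bio)
  if (is.null(names(bins)) || is.unsorted(bins))
    stop("bins must be a named, ascending vector of lower bounds")
  bin_of <- function(v) names(bins)[findInterval(v, bins)]

  if (is.null(network$nodes$matched_feature))
    network$nodes$matched_feature <- NA_character_
  if (is.null(network$nodes$main_bin))
    network$nodes$main_bin <- "unmapped"
  if (is.null(network$slices)) network$slices <- list()

  for (k in seq_len(nrow(network$nodes))) {
    if (!is.na(network$nodes$matched_feature[k])) next
    if (network$nodes$ion_mode[k] != fm$ion_mode) next
    dmz <- abs(fm$mz - network$nodes$precursor_mz[k])
    cand <- which(dmz <= network$params$precursor_tol)
    rt_node <- network$nodes$retention[k]
    if (!is.na(rt_node))
      cand <- cand[is.na(fm$rt[cand]) | abs(fm$rt[cand] - rt_node) <= rt_tol]
    if (!length(cand)) next
    hit <- cand[which.min(dmz[cand])]
    x <- fm$intensities[, hit]
    present <- which(x > 0)
    if (!length(present)) next
    w <- x[present] / sum(x[present])
    sl <- data.frame(fraction = fm$fraction_ids[present],
                     weight = as.numeric(w),
                     viability_pct = bio$viability_pct[present],
                     bin = bin_of(bio$viability_pct[present]),
                     stringsAsFactors = FALSE)
    network$nodes$matched_feature[k] <- fm$feature_ids[hit]
    agg <- tapply(sl$weight, sl$bin, sum)
    network$nodes$main_bin[k] <- names(agg)[which.max(agg)]
    network$slices[[network$nodes$spectrum_id[k]]] <- sl
  }
  network
}

#' Export / import a molecular network as GraphML
#'
#' Node attributes: precursor m/z, ionization mode, component, matched
#' feature, main viability bin, and the pie slices serialized as
#' \code{"fraction:weight;..."}. Edge attributes: cosine score and matched
#' peak count. The file is re-importable by \code{read_graphml}.
#'
#' @param network a \code{\link{spectral_network}}.
#' @param path output file path.
#' @return \code{export_graphml} returns \code{path} invisibly.
#' @export
export_graphml <- function(network, path) {
  stopifnot(inherits(network, "spectral_network"))
  ids <- network$nodes$spectrum_id
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(network$edges))
    g <- igraph::add_edges(g, rbind(match(network$edges$from, ids),
                                    match(network$edges$to, ids)))
  igraph::V(g)$precursor_mz <- network$nodes$precursor_mz
  igraph::V(g)$ion_mode <- network$nodes$ion_mode
  igraph::V(g)$component <- network$nodes$component
  igraph::V(g)$matched_feature <-
    if (is.null(network$nodes$matched_feature)) NA_character_ else
      ifelse(is.na(network$nodes$matched_feature), "",
             network$nodes$matched_feature)
  igraph::V(g)$main_bin <-
    if (is.null(network$nodes$main_bin)) "unmapped" else
      network$nodes$main_bin
  igraph::V(g)$slices <- vapply(ids, function(id) {
    sl <- network$slices[[id]]
    if (is.null(sl)) return("")
    paste(sprintf("%s:%.6f", sl$fraction, sl$weight), collapse = ";")
  }, character(1))
  if (nrow(network$edges)) {
    igraph::E(g)$cosine <- network$edges$cosine
    igraph::E(g)$n_matched <- network$edges$n_matched
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @return \code{read_graphml} returns a list with \code{nodes} and
#'   \code{edges} data frames carrying the exported attributes.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as.data.frame(igraph::vertex_attr(g), stringsAsFactors = FALSE)
  if (nrow(nodes) && "name" %in% names(nodes)) {
    names(nodes)[names(nodes) == "name"] <- "spectrum_id"
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      stringsAsFactors = FALSE)
  for (at in setdiff(igraph::edge_attr_names(g), c("from", "to")))
    edges[[at]] <- igraph::edge_attr(g, at)
  list(nodes = nodes, edges = edges)
}

#' Summarize network clusters
#'
#' @param network a \code{\link{spectral_network}}.
#' @return data frame with one row per cluster (component of at least
#'   \code{min_cluster_size} nodes): component id, size, mean cosine of
#'   internal edges, and dominant viability bin when bioactivity has been
#'   mapped.
#' @export
cluster_summary <- function(network) {
  stopifnot(inherits(network, "spectral_network"))
  if (!length(network$clusters))
    return(data.frame(component = integer(), size = integer(),
                      mean_cosine = numeric(), main_bin = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(network$clusters, function(memb) {
    comp <- network$nodes$component[match(memb[1], network$nodes$spectrum_id)]
    e <- network$edges[network$edges$from %in% memb |
                         network$edges$to %in% memb, ]
    mb <- if (!is.null(network$nodes$main_bin)) {
      tabs <- table(network$nodes$main_bin[
        network$nodes$spectrum_id %in% memb])
      names(tabs)[which.max(tabs)]
    } else NA_character_
    data.frame(component = comp, size = length(memb),
               mean_cosine = if (nrow(e)) mean(e$cosine) else NA_real_,
               main_bin = mb, stringsAsFactors = FALSE)
  }))
}
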