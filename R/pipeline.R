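#' Pipeline run configuration
#'
#' Collects all file paths and module parameters for one end-to-end run.
#' Feature tables are given per ionization mode; either mode may be absent
#' (the run then covers the other mode only).
#'
#' @param features named character vector or list of feature-table paths,
#'   names in \code{c("NEG", "POS")}.
#' @param viability path to the viability table.
#' @param mgf optional MGF path for networking.
#' @param library optional compound-library CSV path for annotation.
#' @param out_dir output directory.
#' @param seed integer seed controlling every stochastic stage.
#' @param top_k consensus union takes the top \code{top_k} features of each
#'   estimator per mode (default 50).
#' @param deconvolute collapse adduct/isotopologue satellites first
#'   (default \code{TRUE}).
#' @param normalize apply total-intensity normalization (default
#'   \code{FALSE}; fraction loads genuinely differ).
#' @param ncomp PLS components for the selectivity ratio (\code{"auto"} =
#'   leave-one-out choice).
#' @param en an \code{\link{ensemble_config}} (its seed is derived from
#'   \code{seed} per mode).
#' @param net a \code{\link{network_params}}.
#' @param ppm annotation mass window, ppm.
#' @return a \code{run_config} object.
#' @export
run_config <- function(features, viability, mgf = NULL, library = NULL,
                       out_dir = "phytoactive_out", seed = 1L, top_k = 50L,
                       deconvolute = TRUE, normalize = FALSE,
                       ncomp = "auto", en = ensemble_config(),
                       net = network_params(), ppm = 10) {
  features <- unlist(features)
  if (is.null(names(features)) ||
      !all(names(features) %in% c("NEG", "POS")))
    stop("features must be a named vector with names in c('NEG', 'POS')")
  for (f in c(features, viability, mgf, library))
    if (!file.exists(f)) stop("no such file: ", f)
  structure(list(features = features, viability = viability, mgf = mgf,
                 library = library, out_dir = out_dir,
                 seed = as.integer(seed), top_k = as.integer(top_k),
                 deconvolute = isTRUE(deconvolute),
                 normalize = isTRUE(normalize),
                 ncomp = ncomp, en = en, net = net, ppm = ppm),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields above (module parameter blocks
#'   \code{en} and \code{net} as nested maps).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  en <- do.call(ensemble_config, as.list(y$en %||% list()))
  net <- do.call(network_params, as.list(y$net %||% list()))
  run_config(features = unlist(y$features), viability = y$viability,
             mgf = y$mgf, library = y$library,
             out_dir = y$out_dir %||% "phytoactive_out",
             seed = y$seed %||% 1L, top_k = y$top_k %||% 50L,
             deconvolute = y$deconvolute %||% TRUE,
             normalize = y$normalize %||% FALSE,
             ncomp = y$ncomp %||% "auto", en = en, net = net,
             ppm = y$ppm %||% 10)
}

#' Consensus table of the two estimators
#'
#' Takes the union of each estimator's top-\code{top_k} features per
#' ionization mode and reports, per feature: the selectivity ratio and its
#' rank, the Elastic Net rank with its \code{"(of N)"} denominator, the
#' univariate Pearson correlation with viability, and the annotation.
#' Rows are sorted by selectivity ratio descending. The number of features
#' present in both estimators' top-\code{top_k} lists is attached as
#' attribute \code{"overlap"}.
#'
#' @param sr_results list of \code{\link{sr_analysis}} results (one per
#'   mode).
#' @param en_results list of \code{\link{en_analysis}} results, same modes.
#' @param annotations optional data frame from
#'   \code{\link{annotate_features}}.
#' @param correlations optional named numeric vector of Pearson r per
#'   feature ID.
#' @param top_k union depth per estimator (default 50).
#' @return a \code{consensus_table} data frame.
#' @export
consensus <- function(sr_results, en_results, annotations = NULL,
                      correlations = NULL, top_k = 50L) {
  if (!length(sr_results) || !length(en_results)) {
    warning("empty estimator results; returning empty consensus table")
    out <- data.frame(feature_id = character(), ion_mode = character(),
                      sr = numeric(), sr_rank = integer(),
                      en_rank = integer(), en_n_selected = integer(),
                      pearson_r = numeric(), annotation = character(),
                      stringsAsFactors = FALSE)
    attr(out, "overlap") <- 0L
    class(out) <- c("consensus_table", "data.frame")
    return(out)
  }
  if (!is.list(sr_results) || is.data.frame(sr_results))
    sr_results <- list(sr_results)
  if (!is.list(en_results) || is.data.frame(en_results))
    en_results <- list(en_results)

  rows <- list(); overlap <- 0L
  for (k in seq_along(sr_results)) {
    sr <- sr_results[[k]]; en <- en_results[[k]]
    if (!identical(sr$ion_mode[1], en$ion_mode[1]))
      stop("sr_results and en_results must pair up by ionization mode")
    top_sr <- sr$feature_id[sr$rank <= top_k]
    top_en <- en$feature_id[en$rank <= top_k & en$selection_frequency > 0]
    overlap <- overlap + length(intersect(top_sr, top_en))
    ids <- union(top_sr, top_en)
    i_sr <- match(ids, sr$feature_id)
    i_en <- match(ids, en$feature_id)
    rows[[k]] <- data.frame(
      feature_id = ids,
      ion_mode = sr$ion_mode[1],
      sr = sr$sr[i_sr],
      sr_rank = sr$rank[i_sr],
      en_rank = en$rank[i_en],
      en_n_selected = en$n_selected[i_en],
      pearson_r = if (!is.null(correlations))
        as.numeric(correlations[ids]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$annotation <- if (!is.null(annotations))
    annotations$compound_name[match(out$feature_id,
                                    annotations$feature_id)]
  else NA_character_
  out <- out[order(-out$sr, out$feature_id), ]
  rownames(out) <- NULL
  attr(out, "overlap") <- overlap
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' Run the full biochemometric pipeline
#'
#' preprocess (read, optional deconvolution/normalization) -> selectivity
#' ratio + Elastic Net ensemble per ionization mode -> consensus table ->
#' annotation -> molecular networking with bioactivity mapping. All outputs
#' are written under \code{config$out_dir}; the run is deterministic given
#' \code{config$seed}, which is recorded in every output header and in the
#' key=value run log.
#'
#' @param config a \code{\link{run_config}}.
#' @return (invisibly) a list with the \code{consensus} table, per-mode
#'   \code{sr} and \code{en} results, the \code{network} (or \code{NULL})
#'   and the vector of written \code{paths}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed=%d", config$seed),
                 sprintf("top_k=%d", config$top_k),
                 sprintf("deconvolute=%s", config$deconvolute),
                 sprintf("normalize=%s", config$normalize),
                 sprintf("ncomp=%s", paste(config$ncomp, collapse = ",")),
                 sprintf("en.n_models=%d", config$en$n_models),
                 sprintf("en.alpha=%g", config$en$alpha),
                 sprintf("en.nfolds=%d", config$en$nfolds),
                 sprintf("net.cosine_cutoff=%g", config$net$cosine_cutoff),
                 sprintf("net.min_matched_peaks=%d",
                         config$net$min_matched_peaks),
                 sprintf("net.min_cluster_size=%d",
                         config$net$min_cluster_size),
                 sprintf("annotation.ppm=%g", config$ppm))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  bio <- stage("viability", read_viability_table(config$viability))
  modes <- names(config$features)
  matrices <- list(); sr_list <- list(); en_list <- list()
  correlations <- numeric(0)
  for (mode in c("NEG", "POS")) {
    if (!mode %in% modes) {
      log_lines <- c(log_lines, sprintf("mode.%s=skipped (no input)", mode))
      next
    }
    fm <- stage(paste0("read_", mode),
                read_feature_table(config$features[[mode]], mode))
    log_lines <- c(log_lines,
                   sprintf("mode.%s.n_features_raw=%d", mode,
                           length(fm$feature_ids)))
    if (config$deconvolute) {
      dec <- stage(paste0("deconvolute_", mode), deconvolute(fm))
      fm <- dec$matrix
      log_lines <- c(log_lines,
                     sprintf("mode.%s.n_groups_merged=%d", mode,
                             length(unique(dec$groups$group))),
                     sprintf("mode.%s.n_features=%d", mode,
                             length(fm$feature_ids)))
    }
    if (config$normalize)
      fm <- stage(paste0("normalize_", mode), normalize_total_intensity(fm))
    matrices[[mode]] <- fm

    sr <- stage(paste0("selectivity_ratio_", mode),
                sr_analysis(fm, bio, ncomp = config$ncomp))
    model <- attr(sr, "model")
    log_lines <- c(log_lines,
                   sprintf("mode.%s.pls_ncomp=%d", mode, model$ncomp))
    sr_list[[mode]] <- sr

    en_cfg <- config$en
    en_cfg$seed <- config$seed + match(mode, c("NEG", "POS"))
    en <- stage(paste0("elastic_net_", mode), en_analysis(fm, bio, en_cfg))
    log_lines <- c(log_lines,
                   sprintf("mode.%s.en_n_selected=%d", mode,
                           en$n_selected[1]))
    en_list[[mode]] <- en

    ## univariate correlations for the report
    keep <- apply(fm$intensities, 2, stats::sd) > 0
    correlations <- c(correlations, vapply(
      fm$feature_ids[keep],
      function(id) pearson_feature_viability(fm, bio, id), numeric(1)))
  }
  if (!length(matrices)) stop("no feature matrix could be read")

  lib <- if (!is.null(config$library))
    stage("library", read_compound_library(config$library)) else NULL

  tab <- stage("consensus", consensus(
    sr_list, en_list,
    annotations = NULL, correlations = correlations,
    top_k = config$top_k))
  if (!is.null(lib)) {
    ann <- stage("annotation",
                 annotate_features(tab$feature_id, tab$ion_mode, lib,
                                   ppm = config$ppm))
    tab$annotation <- ann$compound_name
  }
  log_lines <- c(log_lines,
                 sprintf("consensus.n_rows=%d", nrow(tab)),
                 sprintf("consensus.top_k_overlap=%d",
                         attr(tab, "overlap")))

  network <- NULL
  if (!is.null(config$mgf)) {
    spectra <- stage("read_mgf", read_mgf(config$mgf))
    merged <- stage("merge_identical",
                    merge_identical(spectra,
                                    precursor_tol = config$net$precursor_tol,
                                    fragment_tol = config$net$fragment_tol))
    network <- stage("build_network", build_network(merged, config$net))
    for (mode in names(matrices))
      network <- stage("map_bioactivity",
                       map_bioactivity(network, matrices[[mode]], bio))
    log_lines <- c(log_lines,
                   sprintf("network.n_nodes=%d", nrow(network$nodes)),
                   sprintf("network.n_edges=%d", nrow(network$edges)),
                   sprintf("network.n_clusters=%d",
                           length(network$clusters)))
  }

  ## outputs
  cm <- sprintf("seed=%d", config$seed)
  paths <- c(consensus = file.path(config$out_dir, "consensus.csv"),
             sr = file.path(config$out_dir, "sr_report.csv"),
             en = file.path(config$out_dir, "en_report.csv"),
             log = file.path(config$out_dir, "run_log.txt"))
  write_report_csv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", cm), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  write_report_csv(as.data.frame(tab), paths[["consensus"]])
  sr_all <- do.call(rbind, lapply(sr_list, as.data.frame))
  sr_all <- sr_all[order(-sr_all$sr, sr_all$feature_id), ]
  write_report_csv(sr_all, paths[["sr"]])
  write_report_csv(do.call(rbind, lapply(en_list, as.data.frame)),
                   paths[["en"]])
  if (!is.null(network)) {
    paths[["graphml"]] <- file.path(config$out_dir, "network.graphml")
    export_graphml(network, paths[["graphml"]])
    paths[["clusters"]] <- file.path(config$out_dir, "clusters.csv")
    write_report_csv(cluster_summary(network), paths[["clusters"]])
  }
  writeLines(log_lines, paths[["log"]])

  invisible(list(consensus = tab, sr = sr_list, en = en_list,
                 network = network, paths = paths, log = log_lines))
}
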