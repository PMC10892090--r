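#' Feature ID helpers
#'
#' Molecular features are identified by strings of the form
#' \code{"<RT>_<mz>"}: retention time in minutes (2 decimals) and m/z in Da
#' (4 decimals), e.g. \code{"1.79_515.1191"}.
#'
#' @param rt,mz numeric vectors of retention times (min) and m/z values (Da).
#' @return \code{format_feature_id} returns a character vector;
#'   \code{parse_feature_id} returns a data frame with columns \code{rt} and
#'   \code{mz}.
#' @examples
#' format_feature_id(1.79, 515.1191)
#' parse_feature_id("1.41_353.0874")
#' @export
format_feature_id <- function(rt, mz) {
  sprintf("%.2f_%.4f", rt, mz)
}

#' @rdname format_feature_id
#' @param feature_id character vector of \code{"RT_mz"} identifiers.
#' @export
parse_feature_id <- function(feature_id) {
  ok <- grepl("^[0-9]+(\\.[0-9]+)?_[0-9]+(\\.[0-9]+)?$", feature_id)
  if (!all(ok)) {
    stop("malformed feature ID(s): ",
         paste(utils::head(feature_id[!ok], 3), collapse = ", "),
         " (expected \"RT_mz\", e.g. \"1.41_353.0874\")")
  }
  parts <- strsplit(feature_id, "_", fixed = TRUE)
  data.frame(
    feature_id = feature_id,
    rt = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
    mz = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Fractions-by-features intensity matrix
#'
#' The central container of the package: a non-negative intensity matrix with
#' fractions as rows and molecular features as columns, tagged with the
#' ionization mode it was acquired in. Positive- and negative-mode data are
#' kept as separate objects throughout.
#'
#' @param intensities numeric matrix, fractions x features, non-negative
#'   (unless \code{transformed}).
#' @param ion_mode \code{"NEG"} or \code{"POS"}.
#' @param feature_ids character vector of \code{"RT_mz"} IDs (defaults to
#'   \code{colnames(intensities)}).
#' @param fraction_ids fraction labels (defaults to
#'   \code{rownames(intensities)}).
#' @param transformed logical; set by \code{\link{log_transform}}. Transformed
#'   matrices may contain negative values.
#' @return an object of class \code{feature_matrix}: a list with elements
#'   \code{intensities}, \code{feature_ids}, \code{fraction_ids},
#'   \code{ion_mode}, \code{rt}, \code{mz}, \code{transformed}.
#' @seealso \code{\link{read_feature_table}}, \code{\link{deconvolute}},
#'   \code{\link{log_transform}}
#' @export
feature_matrix <- function(intensities, ion_mode = c("NEG", "POS"),
                           feature_ids = colnames(intensities),
                           fraction_ids = rownames(intensities),
                           transformed = FALSE) {
  ion_mode <- match.arg(ion_mode)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(feature_ids))
    stop("feature_ids are required (none found in colnames)")
  if (is.null(fraction_ids))
    fraction_ids <- paste0("A", seq_len(nrow(intensities)))
  if (length(feature_ids) != ncol(intensities))
    stop("length(feature_ids) != number of matrix columns")
  if (length(fraction_ids) != nrow(intensities))
    stop("length(fraction_ids) != number of matrix rows")
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop("duplicate feature ID(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(intensities))
    stop("intensities contain NA")
  if (!transformed && any(intensities < 0)) {
    bad <- which(intensities < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative intensity at fraction '%s', feature '%s'",
                 fraction_ids[bad[1]], feature_ids[bad[2]]))
  }
  parsed <- parse_feature_id(feature_ids)
  dimnames(intensities) <- list(fraction_ids, feature_ids)
  structure(
    list(intensities = intensities,
         feature_ids = feature_ids,
         fraction_ids = as.character(fraction_ids),
         ion_mode = ion_mode,
         rt = parsed$rt, mz = parsed$mz,
         transformed = isTRUE(transformed)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d fractions x %d features [%s]%s\n",
              length(x$fraction_ids), length(x$feature_ids), x$ion_mode,
              if (x$transformed) " (log-transformed)" else ""))
  cat(" fractions:", paste(utils::head(x$fraction_ids, 5), collapse = ", "),
      if (length(x$fraction_ids) > 5) "..." else "", "\n")
  cat(" features :", paste(utils::head(x$feature_ids, 3), collapse = ", "),
      if (length(x$feature_ids) > 3) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensities)

#' Per-fraction bioassay readout
#'
#' Percent cell viability per fraction (with standard error and replicate
#' count), the response variable of both ranking models.
#'
#' @param fraction_ids fraction labels, aligned with a
#'   \code{\link{feature_matrix}} when paired.
#' @param viability_pct percent viability (non-negative).
#' @param se_pct standard error of the mean, percent.
#' @param n_replicates replicate count per fraction.
#' @return an object of class \code{bioactivity}.
#' @export
bioactivity <- function(fraction_ids, viability_pct, se_pct = 0,
                        n_replicates = 1L) {
  if (length(fraction_ids) != length(viability_pct))
    stop("fraction_ids and viability_pct differ in length")
  if (any(viability_pct < 0)) stop("viability_pct must be >= 0")
  se_pct <- rep_len(se_pct, length(fraction_ids))
  n_replicates <- rep_len(as.integer(n_replicates), length(fraction_ids))
  structure(
    list(fraction_ids = as.character(fraction_ids),
         viability_pct = as.numeric(viability_pct),
         se_pct = as.numeric(se_pct),
         n_replicates = n_replicates),
    class = "bioactivity"
  )
}

#' @export
print.bioactivity <- function(x, ...) {
  cat(sprintf("<bioactivity> %d fractions, viability %.1f-%.1f%%\n",
              length(x$fraction_ids), min(x$viability_pct),
              max(x$viability_pct)))
  invisible(x)
}

## check that a matrix and a bioactivity vector describe the same fractions,
## in the same order
check_aligned <- function(fm, bio) {
  if (!identical(fm$fraction_ids, bio$fraction_ids))
    stop("fraction IDs of feature matrix and bioactivity vector differ")
  invisible(TRUE)
}

#' Read and write feature tables
#'
#' Comma-separated layout: features as rows (first column \code{feature} =
#' \code{"RT_mz"} ID), fractions as columns (header = fraction labels).
#' Lines starting with \code{#} are treated as comments.
#'
#' @param path file path.
#' @param ion_mode ionization mode tag for the returned matrix.
#' @return \code{read_feature_table} returns a \code{\link{feature_matrix}};
#'   \code{write_feature_table} returns \code{path} invisibly.
#' @export
read_feature_table <- function(path, ion_mode = c("NEG", "POS")) {
  ion_mode <- match.arg(ion_mode)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("feature table needs a feature column plus fractions")
  ids <- as.character(tab[[1]])
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  feature_matrix(m, ion_mode = ion_mode, feature_ids = ids,
                 fraction_ids = colnames(tab)[-1])
}

#' @rdname read_feature_table
#' @param fm a \code{\link{feature_matrix}}.
#' @param comment optional comment lines (without \code{#}) written atop the
#'   file, e.g. the run seed.
#' @export
write_feature_table <- function(fm, path, comment = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  tab <- data.frame(feature = fm$feature_ids,
                    t(fm$intensities), check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c("feature", fm$fraction_ids)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write viability tables
#'
#' Comma-separated with columns \code{fraction}, \code{viability_pct},
#' \code{se_pct}, \code{n_replicates}.
#'
#' @param path file path.
#' @return \code{read_viability_table} returns a \code{\link{bioactivity}}.
#' @export
read_viability_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("fraction", "viability_pct")
  if (!all(need %in% names(tab)))
    stop("viability table needs columns: ", paste(need, collapse = ", "))
  bioactivity(tab$fraction, tab$viability_pct,
              se_pct = if ("se_pct" %in% names(tab)) tab$se_pct else 0,
              n_replicates = if ("n_replicates" %in% names(tab))
                tab$n_replicates else 1L)
}

#' @rdname read_viability_table
#' @param bio a \code{\link{bioactivity}} object.
#' @param comment optional comment lines written atop the file.
#' @export
write_viability_table <- function(bio, path, comment = NULL) {
  stopifnot(inherits(bio, "bioactivity"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  utils::write.csv(
    data.frame(fraction = bio$fraction_ids,
               viability_pct = bio$viability_pct,
               se_pct = bio$se_pct,
               n_replicates = bio$n_replicates),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
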