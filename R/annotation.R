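#' Neutral monoisotopic mass from an observed m/z
#'
#' Assumes singly protonated/deprotonated ions: \code{[M-H]-} in negative
#' mode (neutral = m/z + 1.007276) and \code{[M+H]+} in positive mode
#' (neutral = m/z - 1.007276).
#'
#' @param mz observed m/z, Da.
#' @param ion_mode \code{"NEG"} or \code{"POS"}.
#' @return neutral monoisotopic mass, Da.
#' @export
neutral_mass <- function(mz, ion_mode) {
  if (!all(ion_mode %in% c("NEG", "POS")))
    stop("ion_mode must be 'NEG' or 'POS'")
  if (any(ion_mode == "POS" & mz <= PROTON_MASS))
    stop("positive-mode m/z must exceed the proton mass")
  ifelse(ion_mode == "NEG", mz + PROTON_MASS, mz - PROTON_MASS)
}

#' Compound library
#'
#' @param entries data frame with columns \code{name} (unique),
#'   \code{neutral_mass} (Da, > 0) and optionally \code{fragments}
#'   (reference fragment m/z values as a \code{";"}-separated string).
#' @return a \code{compound_library} object.
#' @export
compound_library <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("name", "neutral_mass")
  if (!all(need %in% names(entries)))
    stop("library needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(entries$name))
    stop("duplicate compound names in library")
  if (any(entries$neutral_mass <= 0)) stop("neutral masses must be > 0")
  if (is.null(entries$fragments)) entries$fragments <- ""
  entries$fragments[is.na(entries$fragments)] <- ""
  rownames(entries) <- NULL
  structure(entries, class = c("compound_library", "data.frame"))
}

library_fragments <- function(library, name) {
  fr <- library$fragments[library$name == name]
  if (!length(fr) || !nzchar(fr)) return(numeric(0))
  as.numeric(strsplit(fr, ";", fixed = TRUE)[[1]])
}

#' @rdname compound_library
#' @param path CSV file with the columns above.
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  compound_library(utils::read.csv(path, comment.char = "#",
                                   stringsAsFactors = FALSE))
}

#' @rdname compound_library
#' @param library a \code{compound_library}.
#' @param comment optional comment lines written atop the file.
#' @export
write_compound_library <- function(library, path, comment = NULL) {
  stopifnot(inherits(library, "compound_library"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  utils::write.csv(as.data.frame(library), con, row.names = FALSE)
  invisible(path)
}

#' Annotate a molecular feature by exact mass
#'
#' The feature's m/z (parsed from its \code{"RT_mz"} identifier) is converted
#' to a neutral mass and queried against the library within a closed ppm
#' window: entries with \eqn{|10^6 (m_{obs} - m_{lib}) / m_{lib}|} at most
#' \code{ppm} are returned, sorted by absolute ppm error. An empty result
#' means no annotation (\code{"N/A"} in reports).
#'
#' @param feature_id \code{"RT_mz"} identifier.
#' @param ion_mode \code{"NEG"} or \code{"POS"}.
#' @param library a \code{\link{compound_library}}.
#' @param ppm mass tolerance in parts per million (default 10).
#' @return data frame with columns \code{feature_id}, \code{compound_name},
#'   \code{ppm_error} (signed); zero rows when nothing matches.
#' @export
annotate_feature <- function(feature_id, ion_mode, library, ppm = 10) {
  stopifnot(inherits(library, "compound_library"))
  mz <- parse_feature_id(feature_id)$mz
  m_obs <- neutral_mass(mz, ion_mode)
  err <- 1e6 * (m_obs - library$neutral_mass) / library$neutral_mass
  hit <- which(abs(err) <= ppm)
  hit <- hit[order(abs(err[hit]), library$name[hit])]
  data.frame(feature_id = rep(feature_id, length(hit)),
             compound_name = library$name[hit],
             ppm_error = err[hit],
             stringsAsFactors = FALSE)
}

#' @rdname annotate_feature
#' @param feature_ids,ion_modes parallel vectors of features to annotate.
#' @return \code{annotate_features} returns one row per feature: the best
#'   annotation or \code{"N/A"}.
#' @export
annotate_features <- function(feature_ids, ion_modes, library, ppm = 10) {
  ion_modes <- rep_len(ion_modes, length(feature_ids))
  rows <- lapply(seq_along(feature_ids), function(k) {
    hits <- annotate_feature(feature_ids[k], ion_modes[k], library, ppm)
    if (nrow(hits) == 0) {
      data.frame(feature_id = feature_ids[k], compound_name = "N/A",
                 ppm_error = NA_real_, stringsAsFactors = FALSE)
    } else hits[1, ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate an annotation with MS/MS fragments
#'
#' Counts how many of the library entry's reference fragments are matched by
#' an observed fragment within a relative ppm tolerance (default 50 ppm); the
#' annotation is flagged validated when the count reaches
#' \code{min_fragments}. An entry without reference fragments yields an
#' indeterminate flag (\code{NA}), not an error.
#'
#' @param spectrum an \code{\link{msms_spectrum}}.
#' @param reference_fragments numeric vector of reference fragment m/z, or a
#'   library entry name together with \code{library}.
#' @param library optional \code{\link{compound_library}} to look the entry
#'   up in.
#' @param ppm fragment tolerance in ppm (default 50).
#' @param min_fragments matches required for validation (default 3).
#' @return list with \code{validated} (logical or \code{NA}) and
#'   \code{n_matched}.
#' @export
validate_msms <- function(spectrum, reference_fragments, library = NULL,
                          ppm = 50, min_fragments = 3L) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  if (is.character(reference_fragments)) {
    if (is.null(library)) stop("library required to look up an entry by name")
    reference_fragments <- library_fragments(library, reference_fragments)
  }
  if (!length(reference_fragments))
    return(list(validated = NA, n_matched = 0L))
  obs <- spectrum$fragments[, "mz"]
  n <- sum(vapply(reference_fragments, function(rf) {
    any(abs(obs - rf) <= ppm * 1e-6 * rf)
  }, logical(1)))
  list(validated = n >= min_fragments, n_matched = as.integer(n))
}
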