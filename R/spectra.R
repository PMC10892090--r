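#' MS/MS spectrum
#'
#' A fragmentation spectrum: precursor m/z, ionization mode and a non-empty
#' fragment peak list (m/z, intensity), kept sorted by m/z.
#'
#' @param spectrum_id identifier.
#' @param precursor_mz precursor m/z in Da (> 0).
#' @param fragments two-column matrix or data frame (\code{mz},
#'   \code{intensity}); intensities must be non-negative.
#' @param ion_mode \code{"NEG"} or \code{"POS"}.
#' @param retention retention time in minutes (optional, \code{NA} if not
#'   available; flow-injection data has none).
#' @param charge absolute charge state (default 1).
#' @return an object of class \code{msms_spectrum}.
#' @export
msms_spectrum <- function(spectrum_id, precursor_mz, fragments,
                          ion_mode = c("NEG", "POS"), retention = NA_real_,
                          charge = 1L) {
  ion_mode <- match.arg(ion_mode)
  if (!is.numeric(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be > 0")
  fragments <- as.matrix(as.data.frame(fragments))
  if (nrow(fragments) == 0) stop("fragment list must be non-empty")
  if (ncol(fragments) != 2) stop("fragments need exactly 2 columns (mz, intensity)")
  colnames(fragments) <- c("mz", "intensity")
  if (any(fragments[, "intensity"] < 0)) stop("fragment intensities must be >= 0")
  fragments <- fragments[order(fragments[, "mz"]), , drop = FALSE]
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 ion_mode = ion_mode,
                 retention = as.numeric(retention),
                 charge = as.integer(charge),
                 fragments = fragments),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("<msms_spectrum> %s: precursor %.4f [%s], %d fragments\n",
              x$spectrum_id, x$precursor_mz, x$ion_mode, nrow(x$fragments)))
  invisible(x)
}

#' Read and write MGF files
#'
#' Mascot Generic Format: \code{BEGIN IONS}/\code{END IONS} blocks with
#' \code{TITLE}, \code{PEPMASS}, \code{CHARGE} (\code{1+}/\code{1-}; the sign
#' sets the ionization mode), optional \code{RTINSECONDS}, then one
#' \code{mz intensity} pair per line.
#'
#' @param path file path.
#' @return \code{read_mgf} returns a list of \code{\link{msms_spectrum}}.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  spectra <- list()
  i <- 1L; nline <- length(lines)
  while (i <= nline) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- NA_character_; pepmass <- NA_real_; charge <- 1L
      mode <- "POS"; rt <- NA_real_
      peaks <- list()
      i <- i + 1L
      while (i <= nline && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (ln == "" || startsWith(ln, "#")) {
          i <- i + 1L; next
        }
        if (grepl("=", ln, fixed = TRUE)) {
          key <- toupper(sub("=.*", "", ln))
          val <- sub("^[^=]*=", "", ln)
          if (key == "TITLE") title <- val
          else if (key == "PEPMASS")
            pepmass <- as.numeric(strsplit(val, "[ \t]+")[[1]][1])
          else if (key == "CHARGE") {
            mode <- if (grepl("-", val, fixed = TRUE)) "NEG" else "POS"
            charge <- as.integer(gsub("[^0-9]", "", val))
          } else if (key == "RTINSECONDS") rt <- as.numeric(val) / 60
          else if (key == "IONMODE")
            mode <- if (toupper(substr(val, 1, 3)) == "NEG") "NEG" else "POS"
        } else {
          xs <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
          peaks[[length(peaks) + 1L]] <- xs[1:2]
        }
        i <- i + 1L
      }
      if (!length(peaks)) stop("MGF block without fragment peaks: ", title)
      frag <- do.call(rbind, peaks)
      spectra[[length(spectra) + 1L]] <- msms_spectrum(
        spectrum_id = if (is.na(title)) paste0("spectrum", length(spectra) + 1L)
                      else title,
        precursor_mz = pepmass, fragments = frag, ion_mode = mode,
        retention = rt, charge = charge)
    }
    i <- i + 1L
  }
  spectra
}

#' @rdname read_mgf
#' @param spectra list of \code{\link{msms_spectrum}} objects.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "msms_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.5f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d%s", s$charge,
                       if (s$ion_mode == "NEG") "-" else "+"), con)
    if (!is.na(s$retention))
      writeLines(sprintf("RTINSECONDS=%.2f", s$retention * 60), con)
    writeLines(sprintf("%.5f %.6g", s$fragments[, "mz"],
                       s$fragments[, "intensity"]), con)
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}
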