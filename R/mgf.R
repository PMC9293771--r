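# Minimal MGF (Mascot generic format) reader/writer for the
# BEGIN IONS / TITLE / PEPMASS / CHARGE / peak-list subset that the
# synthetic spectrum generator emits and the localization stage consumes.

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS/END IONS blocks with TITLE, PEPMASS and CHARGE
#' headers followed by `mz intensity` peak lines.
#'
#' @param path Path to an MGF file.
#' @return List of spectra; each spectrum is a list with `title`,
#'   `pepmass`, `charge`, and `peaks` (data frame `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path)
  spectra <- list()
  cur <- NULL
  mz <- int <- NULL
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (!is.null(cur)) stop("nested BEGIN IONS at line ", ln)
      cur <- list(title = NA_character_, pepmass = NA_real_,
                  charge = NA_integer_)
      mz <- int <- numeric()
    } else if (line == "END IONS") {
      if (is.null(cur)) stop("END IONS without BEGIN IONS at line ", ln)
      cur$peaks <- data.frame(mz = mz, intensity = int)
      spectra[[length(spectra) + 1L]] <- cur
      cur <- NULL
    } else if (is.null(cur)) {
      stop("content outside BEGIN IONS/END IONS at line ", ln)
    } else if (grepl("^TITLE=", line)) {
      cur$title <- sub("^TITLE=", "", line)
    } else if (grepl("^PEPMASS=", line)) {
      cur$pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line),
                                         "\\s+")[[1]][1])
    } else if (grepl("^CHARGE=", line)) {
      cur$charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", line)))
    } else if (grepl("^[A-Z]+=", line)) {
      next  # other headers tolerated
    } else {
      f <- suppressWarnings(as.numeric(strsplit(line, "\\s+")[[1]]))
      if (length(f) < 2L || anyNA(f[1:2])) {
        stop("malformed peak line ", ln, ": '", line, "'")
      }
      mz <- c(mz, f[1])
      int <- c(int, f[2])
    }
  }
  if (!is.null(cur)) stop("unterminated BEGIN IONS block at end of file")
  spectra
}

#' Write spectra to an MGF file
#'
#' Deterministic fixed-precision writer (m/z to 6 decimals, intensity to
#' 4), so regeneration under a fixed seed is byte-identical.
#'
#' @param spectra List of spectra as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con, sep = "\n")
    if (!is.na(sp$title)) {
      writeLines(paste0("TITLE=", sp$title), con, sep = "\n")
    }
    if (!is.na(sp$pepmass)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con, sep = "\n")
    }
    if (!is.na(sp$charge)) {
      writeLines(sprintf("CHARGE=%d+", sp$charge), con, sep = "\n")
    }
    if (nrow(sp$peaks) > 0L) {
      writeLines(sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity),
                 con, sep = "\n")
    }
    writeLines("END IONS", con, sep = "\n")
  }
  invisible(path)
}
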