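#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes. Sequences containing any
#' other character (B, J, O, U, X, Z, ...) are rejected at parse time.
#'
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

canonical_ok <- function(sequence) {
  nzchar(sequence) &
    !grepl(paste0("[^", paste(AMINO_ACIDS, collapse = ""), "]"), sequence)
}

#' Read protein records from a FASTA file
#'
#' Parses a FASTA file into a data frame of protein records. Sequences
#' are upper-cased and validated against the canonical 20-letter
#' alphabet; entry order is preserved. The accession is the first
#' whitespace-delimited token of the header (with UniProt-style
#' `db|ACC|NAME` headers reduced to `ACC`), the remainder is kept as the
#' description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `accession`, `description`,
#'   `sequence`, one row per entry.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|TEST1|X demo", "ACDEF"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(accession = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  first_tok <- sub("\\s.*$", "", headers)
  acc <- vapply(first_tok, function(tok) {
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) parts[2] else tok
  }, character(1), USE.NAMES = FALSE)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  bad <- !canonical_ok(seqs)
  if (any(bad)) {
    stop("FASTA entry '", headers[which(bad)[1]],
         "' is empty or contains non-canonical residue characters")
  }
  data.frame(accession = acc, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' Deterministic plain-text writer (60-column wrapping) so that
#' regenerating a synthetic proteome under a fixed seed is byte-identical.
#'
#' @param records Data frame with columns `accession`, `sequence` and
#'   optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, open = "wb")  # "wb": fixed newlines across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records) &&
                nzchar(records$description[i])) {
      paste0(" ", records$description[i])
    } else ""
    writeLines(paste0(">", records$accession[i], desc), con, sep = "\n")
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con,
               sep = "\n")
  }
  invisible(path)
}

#' Read a domain-annotation table
#'
#' Reads a tab-separated table with header columns
#' `accession`, `domain_label`, `start`, `end` (1-based inclusive residue
#' coordinates, as in UniProt feature tables).
#'
#' @param path Path to the TSV file.
#' @return Data frame with the four columns, `start`/`end` integer.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) stop("domain table not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("accession", "domain_label", "start", "end")
  missing <- setdiff(needed, names(d))
  if (length(missing) > 0L) {
    stop("domain table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  bad <- which(is.na(d$start) | is.na(d$end) | d$start < 1L |
                 d$start > d$end)
  if (length(bad) > 0L) {
    stop("invalid domain coordinates at line ", bad[1] + 1L,
         " of ", path)
  }
  d[needed]
}

check_domain_in_sequence <- function(sequence, start, end) {
  n <- nchar(sequence)
  if (start < 1L || end > n || start > end) {
    stop("domain span [", start, ", ", end,
         "] lies outside the 1..", n, " sequence range")
  }
  invisible(TRUE)
}
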