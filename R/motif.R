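# Consensus rules for AspH-catalyzed D/N hydroxylation.
#
# Both rules describe a window whose first and tenth residues are the
# cysteines that close a disulfide-bridged 10-residue macrocycle (C3-C4
# in EGFD numbering); the acceptor D/N sits at ring position 3 and the
# TPR-binding aromatic F/Y at ring position 8. The legacy rule
# additionally demands a C4-X-C5 suffix, i.e. a further cysteine exactly
# two residues after the closing one (window length 12).

#' Consensus-motif rule definitions
#'
#' Returns the parameters of the legacy (12-residue,
#' C3-X-D/N-X-X-X-X-F/Y-X-C4-X-C5) or revised (10-residue macrocycle)
#' consensus rule for AspH substrate sites. Wildcard positions admit any
#' canonical residue, including C, D/N and F/Y.
#'
#' @param name `"legacy"` or `"revised"`.
#' @return A list with elements `name`, `pattern_length`, `site_offset`
#'   (ring position of the D/N acceptor, always 3), `aromatic_offset`
#'   (ring position of the required F/Y, always 8), and `regex` (a PCRE
#'   pattern for one window).
#' @export
motif_rule <- function(name = c("revised", "legacy")) {
  name <- match.arg(name)
  core <- "C.[DN]....[FY].C"        # ring positions 1-10
  list(
    name = name,
    pattern_length = if (name == "legacy") 12L else 10L,
    site_offset = 3L,
    aromatic_offset = 8L,
    regex = if (name == "legacy") paste0(core, ".C") else core
  )
}

#' Index the cysteines of an annotated domain
#'
#' Numbers the cysteine residues inside a domain span consecutively from
#' the N terminus (ordinal 1 = most N-terminal cysteine), the C1...Cn
#' convention used to describe EGFD disulfide patterns.
#'
#' @param sequence Protein sequence (canonical residues).
#' @param start,end 1-based inclusive domain span within the sequence.
#' @param accession Optional identifier carried into the result.
#' @param domain_label Optional label carried into the result.
#' @return An object of class `cysteine_index`: a data frame with
#'   columns `position` (absolute 1-based) and `ordinal`, with the span
#'   and labels stored as attributes.
#' @examples
#' idx <- index_cysteines("ACDEFCGHCIKCLMCNPCQ", 1, 19)
#' idx$position  # 2 6 9 12 15 18
#' @export
index_cysteines <- function(sequence, start, end, accession = NA_character_,
                            domain_label = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  check_domain_in_sequence(sequence, start, end)
  sub <- substr(sequence, start, end)
  rel <- gregexpr("C", sub, fixed = TRUE)[[1]]
  pos <- if (rel[1] == -1L) integer() else as.integer(rel) + start - 1L
  out <- data.frame(position = pos, ordinal = seq_along(pos))
  attr(out, "start") <- as.integer(start)
  attr(out, "end") <- as.integer(end)
  attr(out, "accession") <- accession
  attr(out, "domain_label") <- domain_label
  class(out) <- c("cysteine_index", "data.frame")
  out
}

#' Residue spacing between the fourth and fifth domain cysteines
#'
#' Counts the residues strictly between the C4 and C5 cysteines of a
#' domain cysteine index: `position(C5) - position(C4) - 1`. The legacy
#' C4-X-C5 consensus suffix corresponds to a spacing of exactly 1; the
#' worked C4-E-Y-C5 pattern has spacing 2.
#'
#' @param index A [index_cysteines()] result with at least 5 cysteines.
#' @return Integer spacing (0 when C4 and C5 are adjacent).
#' @export
c4_c5_spacing <- function(index) {
  stopifnot(inherits(index, "cysteine_index"))
  if (nrow(index) < 5L) {
    stop("domain has fewer than 5 cysteines; C4-C5 spacing is inapplicable")
  }
  as.integer(index$position[5] - index$position[4] - 1L)
}

scan_rule <- function(sequence, accession, rule) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!canonical_ok(sequence)) {
    stop("sequence for '", accession, "' contains non-canonical residues")
  }
  # lookahead so that overlapping windows are all reported
  m <- gregexpr(paste0("(?=", rule$regex, ")"), sequence, perl = TRUE)[[1]]
  starts <- if (m[1] == -1L) integer() else as.integer(m)
  if (length(starts) == 0L) {
    return(data.frame(accession = character(), rule = character(),
                      ring_start = integer(), ring_end = integer(),
                      site_position = integer(), site_residue = character(),
                      aromatic_residue = character(),
                      domain_label = character(), stringsAsFactors = FALSE))
  }
  site <- starts + rule$site_offset - 1L
  hits <- data.frame(
    accession = rep(accession, length(starts)),
    rule = rep(rule$name, length(starts)),
    ring_start = starts,
    ring_end = starts + 9L,
    site_position = site,
    site_residue = substring(sequence, site, site),
    aromatic_residue = substring(sequence, starts + rule$aromatic_offset - 1L,
                                 starts + rule$aromatic_offset - 1L),
    domain_label = rep(NA_character_, length(starts)),
    stringsAsFactors = FALSE
  )
  # dedupe by (accession, rule, ring_start); gregexpr cannot repeat a
  # start, so this is a guard rather than an expected path
  hits[!duplicated(hits[c("accession", "rule", "ring_start")]), ,
       drop = FALSE]
}

#' Scan a sequence under the revised 10-residue macrocycle rule
#'
#' Reports every 10-residue window with C at positions 1 and 10, D or N
#' at position 3 and F or Y at position 8 — the revised consensus for
#' AspH-catalyzed hydroxylation, which drops the legacy C4-X-C5
#' requirement. Overlapping windows are all reported; coordinates are
#' absolute and 1-based. The scan is purely sequence-level: it does not
#' check that a disulfide physically bridges the two cysteines.
#'
#' @param sequence Protein sequence.
#' @param accession Identifier carried into the hit table.
#' @return Data frame of motif hits with columns `accession`, `rule`,
#'   `ring_start`, `ring_end`, `site_position`, `site_residue`,
#'   `aromatic_residue`, `domain_label`.
#' @examples
#' scan_revised("CADGGGGYAC", "demo")
#' @export
scan_revised <- function(sequence, accession = "seq1") {
  scan_rule(sequence, accession, motif_rule("revised"))
}

#' Scan a sequence under the legacy 12-residue consensus
#'
#' As [scan_revised()], but additionally requiring a cysteine at window
#' position 12, i.e. the C4-X-C5 suffix of the legacy consensus
#' C3-X-D/N-X-X-X-X-F/Y-X-C4-X-C5. Every legacy hit is therefore also a
#' revised hit at the same site.
#'
#' @inheritParams scan_revised
#' @return Data frame of motif hits (see [scan_revised()]); `ring_end`
#'   is the closing macrocycle cysteine (window position 10), not the
#'   trailing C5.
#' @export
scan_legacy <- function(sequence, accession = "seq1") {
  scan_rule(sequence, accession, motif_rule("legacy"))
}

#' Classify candidate sites by consensus support
#'
#' Joins legacy and revised hit tables by (accession, site_position) and
#' flags each site `"both"` (matches the legacy consensus too) or
#' `"revised_only"` (a macrocycle lacking the C4-X-C5 suffix, the
#' fibulin-type case). A legacy hit without a matching revised hit
#' violates the subset relation between the rules and raises an error.
#'
#' @param legacy_hits,revised_hits Hit tables from [scan_legacy()] and
#'   [scan_revised()] over the same records.
#' @return The revised hit table with an added `flag` column.
#' @export
classify_sites <- function(legacy_hits, revised_hits) {
  key <- function(h) paste(h$accession, h$site_position, sep = "\r")
  lk <- key(legacy_hits)
  rk <- key(revised_hits)
  orphan <- setdiff(lk, rk)
  if (length(orphan) > 0L) {
    stop("internal consistency error: legacy hit(s) without a revised ",
         "counterpart at ", paste(gsub("\r", ":", orphan), collapse = ", "))
  }
  out <- revised_hits
  out$flag <- ifelse(rk %in% lk, "both", "revised_only")
  out
}

#' Scan a set of protein records and assemble the hit report
#'
#' Runs both consensus scanners over every record, classifies each site,
#' and, when domain annotations are supplied, labels hits with the
#' enclosing domain and that domain's C4-C5 spacing (NA when the domain
#' has fewer than five cysteines or the hit falls outside every
#' annotated domain).
#'
#' @param records Data frame from [read_fasta()].
#' @param domains Optional data frame from [read_domains()].
#' @return Data frame with the [scan_revised()] columns plus
#'   `c4_c5_spacing` and `flag`.
#' @export
scan_proteome <- function(records, domains = NULL) {
  leg <- do.call(rbind, c(list(scan_legacy("AAAA", "..none..")[0, ]),
                          lapply(seq_len(nrow(records)), function(i)
                            scan_legacy(records$sequence[i],
                                        records$accession[i]))))
  rev <- do.call(rbind, c(list(scan_revised("AAAA", "..none..")[0, ]),
                          lapply(seq_len(nrow(records)), function(i)
                            scan_revised(records$sequence[i],
                                         records$accession[i]))))
  hits <- classify_sites(leg, rev)
  hits$c4_c5_spacing <- rep(NA_integer_, nrow(hits))
  if (!is.null(domains) && nrow(hits) > 0L) {
    for (i in seq_len(nrow(hits))) {
      dom <- domains[domains$accession == hits$accession[i] &
                       domains$start <= hits$site_position[i] &
                       domains$end >= hits$site_position[i], , drop = FALSE]
      if (nrow(dom) > 0L) {
        dom <- dom[1, ]
        hits$domain_label[i] <- dom$domain_label
        seq_i <- records$sequence[match(hits$accession[i],
                                        records$accession)]
        idx <- index_cysteines(seq_i, dom$start, dom$end,
                               accession = hits$accession[i],
                               domain_label = dom$domain_label)
        if (nrow(idx) >= 5L) {
          hits$c4_c5_spacing[i] <- c4_c5_spacing(idx)
        }
      }
    }
  }
  rownames(hits) <- NULL
  hits
}

#' Write a motif hit report as TSV
#'
#' @param hits Data frame from [scan_proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_report <- function(hits, path) {
  cols <- c("accession", "rule", "ring_start", "ring_end", "site_position",
            "site_residue", "aromatic_residue", "domain_label",
            "c4_c5_spacing", "flag")
  for (cc in setdiff(cols, names(hits))) hits[[cc]] <- NA
  write.table(hits[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
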