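# b/y fragment prediction, peak matching, and localization of the
# hydroxylation mass shift from which fragments carry it.

#' Theoretical b/y fragment ions of a (modified) peptide
#'
#' Generates all b_i and y_i ions (i = 1..n-1) at charges 1..`max_charge`.
#' A fragment's mass includes the deltas of modifications whose positions
#' it spans: b_i spans residues 1..i, y_i spans residues (n-i+1)..n. At
#' charge 1, m/z(b_i) = prefix residue mass + proton and m/z(y_i) =
#' suffix residue mass + water + proton, so m/z(b_i) + m/z(y_{n-i}) =
#' neutral peptide mass + 2 protons.
#'
#' @inheritParams monoisotopic_mass
#' @param max_charge Highest fragment charge state (>= 1).
#' @return Data frame with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz`.
#' @export
theoretical_by_ions <- function(sequence, modifications = NULL,
                                max_charge = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 2L) stop("peptide must have length >= 2 to fragment")
  if (!canonical_ok(sequence)) {
    stop("non-canonical residue in '", sequence, "'")
  }
  if (max_charge < 1L) stop("max_charge must be >= 1")
  mods <- validate_modifications(sequence, modifications)
  res <- strsplit(sequence, "")[[1]]
  delta <- numeric(n)
  delta[mods$position] <- mods$mass_delta
  prefix <- cumsum(RESIDUE_MASSES[res] + delta)   # b_i neutral residue sum
  total <- prefix[n]
  idx <- seq_len(n - 1L)
  out <- do.call(rbind, lapply(seq_len(max_charge), function(z) {
    rbind(
      data.frame(series = "b", index = idx, charge = z,
                 mz = (prefix[idx] + z * PROTON_MASS) / z),
      data.frame(series = "y", index = idx, charge = z,
                 mz = (total - prefix[n - idx] + WATER_MASS +
                         z * PROTON_MASS) / z)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Match observed peaks to theoretical fragment ions
#'
#' Assigns each theoretical ion to the nearest observed peak within a
#' ppm tolerance. A peak may satisfy at most one ion: candidate pairs
#' are ranked by absolute ppm error (ties broken toward the lower series
#' index) and assigned greedily.
#'
#' @param peaks Data frame with columns `mz` and `intensity` (an empty
#'   peak list yields a match with every ion unmatched).
#' @param ions Data frame from [theoretical_by_ions()].
#' @param tol_ppm Match tolerance in parts per million (> 0), default 10.
#' @return An object of class `spectrum_match`: list with `matched`
#'   (ions plus `observed_mz`, `ppm_error`), `unmatched_theoretical`,
#'   and `tol_ppm`.
#' @export
match_peaks <- function(peaks, ions, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  if (is.null(peaks) || nrow(peaks) == 0L) {
    peaks <- data.frame(mz = numeric(), intensity = numeric())
  }
  cand <- NULL
  if (nrow(peaks) > 0L && nrow(ions) > 0L) {
    grid <- expand.grid(ion = seq_len(nrow(ions)),
                        peak = seq_len(nrow(peaks)))
    ppm <- (peaks$mz[grid$peak] - ions$mz[grid$ion]) /
      ions$mz[grid$ion] * 1e6
    keep <- abs(ppm) <= tol_ppm
    cand <- data.frame(ion = grid$ion[keep], peak = grid$peak[keep],
                       ppm = ppm[keep])
    cand <- cand[order(abs(cand$ppm), ions$index[cand$ion]), , drop = FALSE]
  }
  assigned_ion <- integer()
  assigned_peak <- integer()
  assigned_ppm <- numeric()
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      if (cand$ion[r] %in% assigned_ion ||
            cand$peak[r] %in% assigned_peak) next
      assigned_ion <- c(assigned_ion, cand$ion[r])
      assigned_peak <- c(assigned_peak, cand$peak[r])
      assigned_ppm <- c(assigned_ppm, cand$ppm[r])
    }
  }
  matched <- ions[assigned_ion, , drop = FALSE]
  matched$observed_mz <- peaks$mz[assigned_peak]
  matched$intensity <- peaks$intensity[assigned_peak]
  matched$ppm_error <- assigned_ppm
  unmatched <- ions[setdiff(seq_len(nrow(ions)), assigned_ion), ,
                    drop = FALSE]
  rownames(matched) <- rownames(unmatched) <- NULL
  structure(list(matched = matched, unmatched_theoretical = unmatched,
                 tol_ppm = tol_ppm),
            class = "spectrum_match")
}

#' @export
print.spectrum_match <- function(x, ...) {
  cat("<spectrum_match> ", nrow(x$matched), " matched / ",
      nrow(x$matched) + nrow(x$unmatched_theoretical),
      " theoretical ions (tol ", x$tol_ppm, " ppm)\n", sep = "")
  invisible(x)
}

shift_bounds <- function(series, index, shifted, n) {
  # b_i shifted    -> site <= i ; b_i unshifted -> site >= i + 1
  # y_i shifted    -> site >= n - i + 1 ; y_i unshifted -> site <= n - i
  lower <- 1L
  upper <- n
  for (k in seq_along(series)) {
    if (series[k] == "b") {
      if (shifted[k]) upper <- min(upper, index[k])
      else            lower <- max(lower, index[k] + 1L)
    } else {
      if (shifted[k]) lower <- max(lower, n - index[k] + 1L)
      else            upper <- min(upper, n - index[k])
    }
  }
  c(lower = lower, upper = upper)
}

#' Localize a mass shift from matched base/shifted fragment ions
#'
#' Given two matches of the *same* spectrum against the unmodified
#' theoretical b/y ions (`match_base`) and against the same ions with
#' the shift applied to every fragment (`match_shifted`), returns the
#' smallest residue interval consistent with which ions carry the shift.
#' For a length-n peptide where y_i is shifted for i >= 7 and unshifted
#' for i <= 6, the interval is the single position n - 6 — the pattern by
#' which the ~16 Da hydroxylation shift is read off annotated spectra.
#'
#' Candidate ions whose theoretical m/z under one hypothesis lies within
#' the match tolerance of another candidate implying the opposite status
#' are excluded as ambiguous before bounds are taken, so rare b/y mass
#' coincidences cannot flip an interval bound.
#'
#' @param match_base [match_peaks()] result against unmodified ions.
#' @param match_shifted [match_peaks()] result against shift-applied ions.
#' @param peptide_length Length n of the base peptide.
#' @return List with `interval_start`, `interval_end`, `position` (the
#'   site when the interval has width 1, otherwise NA) and
#'   `n_supporting_ions`.
#' @export
localize_shift <- function(match_base, match_shifted, peptide_length) {
  stopifnot(inherits(match_base, "spectrum_match"),
            inherits(match_shifted, "spectrum_match"))
  n <- as.integer(peptide_length)
  base <- match_base$matched
  shf <- match_shifted$matched
  as_evid <- function(d, status) {
    if (nrow(d) == 0L) {
      return(data.frame(series = character(), index = integer(),
                        charge = integer(), mz = numeric(),
                        shifted = logical()))
    }
    data.frame(series = d$series, index = d$index, charge = d$charge,
               mz = d$mz, shifted = status)
  }
  evid <- rbind(as_evid(base, FALSE), as_evid(shf, TRUE))
  # positional constraint a candidate implies for the site:
  # lower bound (site >= value) or upper bound (site <= value)
  constraint_of <- function(series, index, shifted) {
    lower <- ifelse(series == "b", !shifted, shifted)
    value <- ifelse(series == "b",
                    ifelse(shifted, index, index + 1L),
                    ifelse(shifted, n - index + 1L, n - index))
    paste0(ifelse(lower, "ge", "le"), value)
  }
  if (nrow(evid) > 0L) {
    # Residue-mass degeneracies (e.g. Gly+Gly vs Asn) can put two
    # candidates with conflicting positional implications at nearly the
    # same m/z, making an observed peak's assignment a coin flip. An
    # evidence ion is dropped as ambiguous when an *unmatched* candidate
    # implying a different constraint lies within half the tolerance;
    # when both candidates are matched the evidence is unambiguous.
    guard <- max(match_base$tol_ppm, match_shifted$tol_ppm) / 2
    unm <- rbind(as_evid(match_base$unmatched_theoretical, FALSE),
                 as_evid(match_shifted$unmatched_theoretical, TRUE))
    evid_con <- constraint_of(evid$series, evid$index, evid$shifted)
    unm_con <- constraint_of(unm$series, unm$index, unm$shifted)
    amb <- vapply(seq_len(nrow(evid)), function(i) {
      near <- abs(unm$mz - evid$mz[i]) / evid$mz[i] * 1e6 <= guard
      any(near & unm_con != evid_con[i])
    }, logical(1))
    evid <- evid[!amb, , drop = FALSE]
  }
  key <- paste(evid$series, evid$index, evid$charge)
  both <- key[duplicated(key)]
  if (length(both) > 0L) {
    stop("inconsistent shift pattern: ion(s) matched as both shifted ",
         "and unshifted: ", paste(unique(both), collapse = ", "))
  }
  b <- shift_bounds(evid$series, evid$index, evid$shifted, n)
  if (b["lower"] > b["upper"]) {
    stop("inconsistent shift pattern: bounds collapse (lower ",
         b["lower"], " > upper ", b["upper"], "); supporting ions: ",
         paste(paste0(evid$series, evid$index,
                      ifelse(evid$shifted, "*", "")), collapse = ", "))
  }
  list(interval_start = unname(b["lower"]),
       interval_end = unname(b["upper"]),
       position = if (b["lower"] == b["upper"]) unname(b["lower"])
                  else NA_integer_,
       n_supporting_ions = nrow(evid))
}

#' Localize a hydroxylation site directly from a peak list
#'
#' Convenience wrapper: builds the unmodified theoretical b/y ions and a
#' shift-applied copy, matches the observed peaks against the *combined*
#' candidate set in one competition (so each peak supports at most one
#' candidate, and a near-coincident shifted/unshifted pair resolves to
#' whichever lies closer in ppm), then calls [localize_shift()] on the
#' per-hypothesis assignments.
#'
#' @param sequence Base peptide sequence.
#' @param peaks Observed peak list (data frame `mz`, `intensity`).
#' @param mass_delta Shift to localize (default [HYDROXYLATION_DELTA]).
#' @param tol_ppm Match tolerance in ppm.
#' @param max_charge Highest fragment charge considered.
#' @return See [localize_shift()].
#' @export
localize_site <- function(sequence, peaks,
                          mass_delta = HYDROXYLATION_DELTA,
                          tol_ppm = 10, max_charge = 1L) {
  ions <- theoretical_by_ions(sequence, max_charge = max_charge)
  shifted <- ions
  shifted$mz <- ions$mz + mass_delta / ions$charge
  ions$shifted <- FALSE
  shifted$shifted <- TRUE
  joint <- match_peaks(peaks, rbind(ions, shifted), tol_ppm)
  split_match <- function(status) {
    m <- joint$matched[joint$matched$shifted == status, , drop = FALSE]
    u <- joint$unmatched_theoretical[
      joint$unmatched_theoretical$shifted == status, , drop = FALSE]
    structure(list(matched = m, unmatched_theoretical = u,
                   tol_ppm = tol_ppm),
              class = "spectrum_match")
  }
  localize_shift(split_match(FALSE), split_match(TRUE), nchar(sequence))
}
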