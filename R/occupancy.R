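#' Label-free site-occupancy estimate
#'
#' Estimates the percent occupancy of a hydroxylation site from the LFQ
#' intensities of the hydroxylated peptide and its non-hydroxylated
#' (base) counterpart: `percent = 100 * Ih / (Ih + Ib)`. Following
#' standard practice, occupancy is only defined when the base peptide was
#' detected (its intensity recorded — possibly zero hydroxylated signal);
#' a missing base intensity signals a not-estimable site.
#'
#' The estimator is scale invariant: multiplying both intensities by any
#' positive constant leaves the percentage unchanged.
#'
#' @param intensity_hydroxylated,intensity_base Non-negative LFQ
#'   intensities (arbitrary units). `intensity_base = NA` marks an
#'   undetected base peptide.
#' @param site Optional site identifier carried into the result.
#' @return List with `site`, `intensity_hydroxylated`, `intensity_base`,
#'   `percent`.
#' @examples
#' estimate_occupancy(3, 7)$percent  # 30
#' @export
estimate_occupancy <- function(intensity_hydroxylated, intensity_base,
                               site = NA_character_) {
  if (is.na(intensity_base)) {
    stop("base peptide not detected: occupancy not estimable for site ",
         site)
  }
  if (intensity_hydroxylated < 0 || intensity_base < 0) {
    stop("intensities must be non-negative")
  }
  if (intensity_hydroxylated == 0 && intensity_base == 0) {
    stop("both intensities are zero: occupancy undefined for site ", site)
  }
  list(site = site,
       intensity_hydroxylated = intensity_hydroxylated,
       intensity_base = intensity_base,
       percent = 100 * intensity_hydroxylated /
         (intensity_hydroxylated + intensity_base))
}

#' Occupancy estimates for a table of intensity pairs
#'
#' Vectorized wrapper over [estimate_occupancy()] for CSV-style input.
#' Rows whose base intensity is missing are flagged `not_estimable`
#' rather than raising an error; rows with both intensities zero are
#' flagged `undefined`.
#'
#' @param pairs Data frame with columns `site`,
#'   `intensity_hydroxylated`, `intensity_base`.
#' @return Data frame with columns `site`, `percent`, `status`
#'   (`"ok"`, `"not_estimable"`, or `"undefined"`).
#' @export
occupancy_table <- function(pairs) {
  stopifnot(all(c("site", "intensity_hydroxylated", "intensity_base")
                %in% names(pairs)))
  ih <- pairs$intensity_hydroxylated
  ib <- pairs$intensity_base
  status <- rep("ok", nrow(pairs))
  status[is.na(ib)] <- "not_estimable"
  both_zero <- !is.na(ib) & !is.na(ih) & ih == 0 & ib == 0
  status[both_zero] <- "undefined"
  pct <- ifelse(status == "ok", 100 * ih / (ih + ib), NA_real_)
  data.frame(site = pairs$site, percent = pct, status = status,
             stringsAsFactors = FALSE)
}
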