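# Seeded generators emitting ground-truthed inputs in the exact formats
# the analysis stages consume (FASTA/TSV, MGF, CSV), plus a JSON
# manifest per dataset. Regeneration under the same seed is
# byte-identical; every dataset ships a truth table sufficient to score
# the downstream stage without external reference data.

random_sequence <- function(length) {
  paste(sample(AMINO_ACIDS, length, replace = TRUE), collapse = "")
}

splice <- function(sequence, at, insert) {
  paste0(substr(sequence, 1L, at - 1L), insert,
         substr(sequence, at + nchar(insert), nchar(sequence)))
}

build_plant <- function(class) {
  x <- function(k) sample(AMINO_ACIDS, k, replace = TRUE)
  acceptor <- sample(c("D", "N"), 1)
  aromatic <- sample(c("F", "Y"), 1)
  ring <- c("C", x(1), acceptor, x(4), aromatic, x(1), "C")
  win <- switch(
    class,
    legacy = c(ring, x(1), "C"),
    revised_only = ring,
    near_miss = {
      if (sample(2, 1) == 1L) ring[3] <- sample(c("E", "Q"), 1)
      else ring[8] <- sample(c("W", "L"), 1)
      ring
    })
  paste(win, collapse = "")
}

write_manifest <- function(out_dir, generator, seed, params, files,
                           truth_file) {
  manifest <- list(generator = generator, seed = seed, params = params,
                   files = as.list(files), truth = truth_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Generate a synthetic proteome with planted consensus-motif instances
#'
#' Builds random background sequences (uniform residue composition, so
#' collision statistics are analytically checkable) and plants exact
#' legacy windows, revised-only windows (macrocycle whose closing
#' cysteine is *not* followed by the C4-X-C5 suffix), and near-misses
#' (acceptor E/Q instead of D/N, or aromatic W/L instead of F/Y) at
#' non-overlapping random positions. Accidental background motif
#' occurrences are allowed and left to the scanners/oracle to count.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins Number of background proteins.
#' @param length_range Length range (min, max) of each protein (>= 12).
#' @param n_legacy,n_revised_only,n_near_miss Number of planted windows
#'   of each class.
#' @param out_dir Optional directory; when given, writes
#'   `proteome.fasta`, `truth.tsv` and `manifest.json` there.
#' @return List with `records` (FASTA-ready data frame), `truth`
#'   (planted-site table with `class` in legacy/revised_only/near_miss),
#'   and `seed`.
#' @export
generate_proteome <- function(seed, n_proteins = 20,
                              length_range = c(200, 400),
                              n_legacy = 5, n_revised_only = 5,
                              n_near_miss = 5, out_dir = NULL) {
  stopifnot(n_legacy >= 0, n_revised_only >= 0, n_near_miss >= 0,
            min(length_range) >= 12)
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_proteins,
                 replace = TRUE)
  seqs <- vapply(lens, random_sequence, character(1))
  acc <- sprintf("SYN%04d", seq_len(n_proteins))
  occupied <- lapply(seq_len(n_proteins), function(i) {
    matrix(numeric(), ncol = 2)
  })
  classes <- rep(c("legacy", "revised_only", "near_miss"),
                 c(n_legacy, n_revised_only, n_near_miss))
  if (length(classes) > 0L) classes <- sample(classes)
  truth <- list()
  for (cl in classes) {
    win <- build_plant(cl)
    w <- nchar(win)
    placed <- FALSE
    for (try in seq_len(500L)) {
      p <- sample(n_proteins, 1)
      # reserve 2 residues past the window so the revised-only "no C5"
      # guard and plant independence hold
      if (lens[p] < w + 2L) next
      s <- sample(lens[p] - w - 1L, 1)
      occ <- occupied[[p]]
      if (nrow(occ) > 0L &&
            any(s <= occ[, 2] + 2 & s + w + 1 >= occ[, 1] - 2)) next
      seqs[p] <- splice(seqs[p], s, win)
      if (cl != "legacy") {
        # ensure no accidental C at the legacy C5 slot (ring_end + 2)
        c5 <- s + 11L
        if (c5 <= lens[p] && substr(seqs[p], c5, c5) == "C") {
          seqs[p] <- splice(seqs[p], c5, sample(setdiff(AMINO_ACIDS, "C"),
                                                1))
        }
      }
      occupied[[p]] <- rbind(occ, c(s, s + w - 1L))
      truth[[length(truth) + 1L]] <- data.frame(
        accession = acc[p], class = cl, ring_start = s, ring_end = s + 9L,
        site_position = s + 2L,
        site_residue = substr(seqs[p], s + 2L, s + 2L),
        aromatic_residue = substr(seqs[p], s + 7L, s + 7L),
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place all requested plants: proteome capacity ",
           "exceeded (", n_proteins, " proteins of length ",
           length_range[1], "-", length_range[2], ")")
    }
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(accession = character(), class = character(),
               ring_start = integer(), ring_end = integer(),
               site_position = integer(), site_residue = character(),
               aromatic_residue = character(), stringsAsFactors = FALSE)
  truth <- truth[order(truth$accession, truth$ring_start), , drop = FALSE]
  rownames(truth) <- NULL
  records <- data.frame(accession = acc,
                        description = sprintf("synthetic protein %d of %d",
                                              seq_len(n_proteins),
                                              n_proteins),
                        sequence = seqs, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(records, file.path(out_dir, "proteome.fasta"))
    write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
    write_manifest(out_dir, "generate_proteome", seed,
                   list(n_proteins = n_proteins,
                        length_range = length_range, n_legacy = n_legacy,
                        n_revised_only = n_revised_only,
                        n_near_miss = n_near_miss),
                   "proteome.fasta", "truth.tsv")
  }
  list(records = records, truth = truth, seed = seed)
}

#' Simulate MS/MS spectra of singly hydroxylated peptides
#'
#' For each spectrum: a random tryptic-length peptide, one hydroxylation
#' (+15.994915 Da) at a random position, all singly charged b/y peaks
#' with Gaussian ppm noise on m/z, each peak retained with probability
#' `1 - dropout_prob`. Peak intensities are uniform draws (the
#' localization stage uses only m/z).
#'
#' @param seed Integer RNG seed.
#' @param peptide_length_range Length range (min, max) of the peptides.
#' @param n_spectra Number of spectra.
#' @param dropout_prob Per-peak dropout probability in \[0, 1\].
#' @param mz_noise_ppm Standard deviation of the Gaussian m/z noise, ppm.
#' @param out_dir Optional directory; writes `spectra.mgf`, `truth.tsv`,
#'   `manifest.json`.
#' @return List with `spectra` (as [read_mgf()] returns) and `truth`
#'   (data frame `spectrum`, `title`, `sequence`, `mod_position`).
#' @export
simulate_msms_dataset <- function(seed, peptide_length_range = c(8, 16),
                                  n_spectra = 50, dropout_prob = 0.1,
                                  mz_noise_ppm = 2, out_dir = NULL) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, mz_noise_ppm >= 0,
            min(peptide_length_range) >= 2)
  set.seed(seed)
  spectra <- vector("list", n_spectra)
  truth <- vector("list", n_spectra)
  for (i in seq_len(n_spectra)) {
    n <- sample(peptide_length_range[1]:peptide_length_range[2], 1)
    pep <- random_sequence(n)
    pos <- sample(n, 1)
    mods <- data.frame(position = pos, mass_delta = HYDROXYLATION_DELTA)
    ions <- theoretical_by_ions(pep, mods, max_charge = 1L)
    keep <- runif(nrow(ions)) >= dropout_prob
    mz <- ions$mz[keep] * (1 + rnorm(sum(keep), 0, mz_noise_ppm) * 1e-6)
    ord <- order(mz)
    title <- sprintf("synthetic_spectrum_%04d", i)
    spectra[[i]] <- list(
      title = title,
      pepmass = (monoisotopic_mass(pep, mods) + 2 * PROTON_MASS) / 2,
      charge = 2L,
      peaks = data.frame(mz = mz[ord],
                         intensity = round(runif(sum(keep), 50, 100), 4)[ord]))
    truth[[i]] <- data.frame(spectrum = i, title = title, sequence = pep,
                             mod_position = pos, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
    write_manifest(out_dir, "simulate_msms_dataset", seed,
                   list(peptide_length_range = peptide_length_range,
                        n_spectra = n_spectra,
                        dropout_prob = dropout_prob,
                        mz_noise_ppm = mz_noise_ppm),
                   "spectra.mgf", "truth.tsv")
  }
  list(spectra = spectra, truth = truth, seed = seed)
}

#' Simulate paired hydroxylated/base peptide intensities
#'
#' Draws a lognormal total abundance per site, splits it by the true
#' occupancy, and multiplies each channel by independent lognormal
#' multiplicative noise with the given coefficient of variation (mean 1,
#' so `cv = 0` reproduces the true occupancy exactly).
#'
#' @param seed Integer RNG seed.
#' @param true_occupancy_pct True site occupancy in \[0, 100\].
#' @param cv Coefficient of variation of the channel noise (>= 0).
#' @param n_pairs Number of intensity pairs.
#' @param out_dir Optional directory; writes `intensities.csv`,
#'   `truth.tsv`, `manifest.json`.
#' @return List with `pairs` (data frame `site`,
#'   `intensity_hydroxylated`, `intensity_base`) and `truth`.
#' @export
simulate_lfq <- function(seed, true_occupancy_pct = 30, cv = 0.2,
                         n_pairs = 100, out_dir = NULL) {
  stopifnot(true_occupancy_pct >= 0, true_occupancy_pct <= 100, cv >= 0)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(k) {
    if (cv == 0) rep(1, k) else rlnorm(k, meanlog = -sdlog^2 / 2, sdlog)
  }
  total <- rlnorm(n_pairs, meanlog = log(1e6), sdlog = 0.5)
  f <- true_occupancy_pct / 100
  pairs <- data.frame(
    site = sprintf("SYN_site_%04d", seq_len(n_pairs)),
    intensity_hydroxylated = total * f * noise(n_pairs),
    intensity_base = total * (1 - f) * noise(n_pairs),
    stringsAsFactors = FALSE)
  truth <- data.frame(true_occupancy_pct = true_occupancy_pct, cv = cv,
                      n_pairs = n_pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pp <- pairs
    pp$intensity_hydroxylated <- sprintf("%.6f", pp$intensity_hydroxylated)
    pp$intensity_base <- sprintf("%.6f", pp$intensity_base)
    write.table(pp, file.path(out_dir, "intensities.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
    write_manifest(out_dir, "simulate_lfq", seed,
                   list(true_occupancy_pct = true_occupancy_pct, cv = cv,
                        n_pairs = n_pairs),
                   "intensities.csv", "truth.tsv")
  }
  list(pairs = pairs, truth = truth, seed = seed)
}

#' Simulate noisy enzymatic progress-curve datasets
#'
#' Runs the noiseless integrated Michaelis-Menten simulator at each
#' initial substrate concentration and adds Gaussian noise to the
#' conversion values, clipped to \[0, 100\].
#'
#' @param seed Integer RNG seed.
#' @param kcat True turnover number, s^-1.
#' @param km True Michaelis constant, uM.
#' @param prep An [enzyme_prep()].
#' @param s0 Vector of initial substrate concentrations, uM.
#' @param times Sampling times in seconds (shared across courses).
#' @param noise_sd_pct SD of the additive conversion noise, percentage
#'   points.
#' @param out_dir Optional directory; writes `timecourses.csv`,
#'   `truth.tsv`, `manifest.json`.
#' @return List with `courses` (data frame `substrate_uM`, `time_s`,
#'   `conversion_pct`) and `truth` (the generating parameters).
#' @export
simulate_time_course_dataset <- function(seed, kcat, km,
                                         prep = enzyme_prep(),
                                         s0 = c(1, 2, 5, 10, 20, 50),
                                         times = seq(0, 60, by = 7.5),
                                         noise_sd_pct = 0,
                                         out_dir = NULL) {
  stopifnot(kcat > 0, km > 0, all(s0 > 0), noise_sd_pct >= 0)
  set.seed(seed)
  courses <- do.call(rbind, lapply(s0, function(s) {
    tc <- simulate_progress(kcat, km, prep, s, times)
    conv <- tc$conversion_pct
    if (noise_sd_pct > 0) {
      conv <- pmin(100, pmax(0, conv + rnorm(length(conv), 0,
                                             noise_sd_pct)))
    }
    data.frame(substrate_uM = s, time_s = tc$time_s,
               conversion_pct = conv)
  }))
  truth <- data.frame(kcat = kcat, km = km,
                      enzyme_total_uM = prep$total_uM,
                      active_fraction = prep$active_fraction,
                      noise_sd_pct = noise_sd_pct)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cc <- courses
    cc$conversion_pct <- sprintf("%.6f", cc$conversion_pct)
    write.table(cc, file.path(out_dir, "timecourses.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
    write_manifest(out_dir, "simulate_time_course_dataset", seed,
                   list(kcat = kcat, km = km, s0 = s0, times = times,
                        noise_sd_pct = noise_sd_pct,
                        enzyme_total_uM = prep$total_uM,
                        active_fraction = prep$active_fraction),
                   "timecourses.csv", "truth.tsv")
  }
  list(courses = courses, truth = truth, seed = seed)
}
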