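test_that("monoisotopic masses match external reference values", {
  # glycine residue + water
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-7)
  # neutral mass of SAMPLER, frozen from an independent mass calculator
  expect_equal(monoisotopic_mass("SAMPLER"), 802.4007237, tolerance = 1e-8)
  expect_error(monoisotopic_mass(""), "empty|non-canonical")
  expect_error(monoisotopic_mass("ACBD"), "non-canonical")
})

test_that("one hydroxylation adds exactly +15.994915 Da", {
  set.seed(21)
  for (rep in 1:20) {
    pep <- random_aa_sequence(sample(6:20, 1))
    pos <- sample(nchar(pep), 1)
    mods <- data.frame(position = pos, mass_delta = HYDROXYLATION_DELTA)
    expect_equal(monoisotopic_mass(pep, mods) - monoisotopic_mass(pep),
                 15.994915, tolerance = 1e-6)
  }
})

test_that("b/y m/z values match frozen external reference for SAMPLER", {
  ions <- theoretical_by_ions("SAMPLER", max_charge = 2)
  pick <- function(se, i, z) ions$mz[ions$series == se & ions$index == i &
                                       ions$charge == z]
  expect_equal(pick("b", 3, 1), 290.116904, tolerance = 1e-6)
  expect_equal(pick("y", 4, 1), 514.298373, tolerance = 1e-6)
  expect_equal(pick("y", 1, 1), 175.118952, tolerance = 1e-6)
  expect_equal(pick("b", 2, 2), 80.041848, tolerance = 1e-6)
  # hydroxylation at position 4 shifts the y4 that spans it
  mods <- data.frame(position = 4, mass_delta = HYDROXYLATION_DELTA)
  imod <- theoretical_by_ions("SAMPLER", mods)
  expect_equal(imod$mz[imod$series == "y" & imod$index == 4],
               530.293288, tolerance = 1e-6)
  expect_equal(imod$mz[imod$series == "b" & imod$index == 3],
               290.116904, tolerance = 1e-6)
})

test_that("fragment sum rule b_i + y_(n-i) = M + 2 protons holds", {
  set.seed(22)
  for (rep in 1:25) {
    pep <- random_aa_sequence(sample(4:25, 1))
    n <- nchar(pep)
    mods <- if (rep %% 2 == 0)
      data.frame(position = sample(n, 1),
                 mass_delta = HYDROXYLATION_DELTA) else NULL
    ions <- theoretical_by_ions(pep, mods)
    m <- monoisotopic_mass(pep, mods)
    b <- ions[ions$series == "b", ]
    y <- ions[ions$series == "y", ]
    for (i in seq_len(n - 1L)) {
      expect_equal(b$mz[b$index == i] + y$mz[y$index == n - i],
                   m + 2 * PROTON_MASS, tolerance = 1e-6)
    }
  }
})

test_that("a modification shifts exactly the spanning fragments", {
  pep <- random_aa_sequence(12)
  mods <- data.frame(position = 6, mass_delta = HYDROXYLATION_DELTA)
  base <- theoretical_by_ions(pep)
  mod <- theoretical_by_ions(pep, mods)
  d <- mod$mz - base$mz
  shifted <- abs(d - HYDROXYLATION_DELTA) < 1e-9
  expect_equal(shifted[mod$series == "b"],
               (1:11) >= 6)   # b_i spans position 6 iff i >= 6
  expect_equal(shifted[mod$series == "y"],
               (1:11) >= 7)   # y_i spans position 6 iff i >= 12 - 6 + 1
  expect_true(all(abs(d[!shifted]) < 1e-9))
})

test_that("fragment m/z agree with a per-fragment summation oracle", {
  set.seed(23)
  for (rep in 1:15) {
    pep <- random_aa_sequence(sample(5:18, 1))
    n <- nchar(pep)
    pos <- sample(n, 1)
    ions <- theoretical_by_ions(
      pep, data.frame(position = pos, mass_delta = HYDROXYLATION_DELTA),
      max_charge = 2)
    for (r in sample(nrow(ions), min(10, nrow(ions)))) {
      expect_equal(ions$mz[r],
                   oracle_by_mz(pep, pos, HYDROXYLATION_DELTA,
                                ions$series[r], ions$index[r],
                                ions$charge[r]),
                   tolerance = 1e-6)
    }
  }
})

test_that("match_peaks matches exact peaks at 0 ppm and rejects displaced ones", {
  ions <- theoretical_by_ions("ACDEFGHIK")
  exact <- data.frame(mz = ions$mz, intensity = 1)
  m <- match_peaks(exact, ions, tol_ppm = 10)
  expect_equal(nrow(m$matched), nrow(ions))
  expect_true(all(abs(m$matched$ppm_error) < 1e-9))

  displaced <- data.frame(mz = ions$mz * (1 + 20e-6), intensity = 1)
  m2 <- match_peaks(displaced, ions, tol_ppm = 10)
  expect_equal(nrow(m2$matched), 0L)
  expect_equal(nrow(m2$unmatched_theoretical), nrow(ions))

  m3 <- match_peaks(data.frame(mz = numeric(), intensity = numeric()),
                    ions, tol_ppm = 10)
  expect_equal(nrow(m3$matched), 0L)
})

test_that("one peak satisfies at most one ion", {
  ions <- data.frame(series = c("b", "b"), index = c(1, 2),
                     charge = 1L, mz = c(100.000, 100.0005))
  peaks <- data.frame(mz = 100.0001, intensity = 1)
  m <- match_peaks(peaks, ions, tol_ppm = 20)
  expect_equal(nrow(m$matched), 1L)
  expect_equal(m$matched$index, 1)  # closest ppm wins
})

test_that("localize_shift reads the site off the shifted y-series", {
  # length 12, mod at position 6: y_7.. shifted, y_1..y_6 unshifted
  pep <- "ACDEFGHIKLMN"
  mods <- data.frame(position = 6, mass_delta = HYDROXYLATION_DELTA)
  ionsm <- theoretical_by_ions(pep, mods)
  y_only <- ionsm[ionsm$series == "y", ]
  loc <- localize_site(pep, data.frame(mz = y_only$mz, intensity = 1))
  expect_equal(loc$interval_start, 6)
  expect_equal(loc$interval_end, 6)
  expect_equal(loc$position, 6)
})

test_that("all b ions shifted with no y evidence localizes to position 1", {
  pep <- "ACDEFGHIKLMN"
  mods <- data.frame(position = 1, mass_delta = HYDROXYLATION_DELTA)
  ionsm <- theoretical_by_ions(pep, mods)
  b_only <- ionsm[ionsm$series == "b", ]
  loc <- localize_site(pep, data.frame(mz = b_only$mz, intensity = 1))
  expect_equal(loc$position, 1)
})

test_that("contradictory shift patterns raise an inconsistency error", {
  pep <- "ACDEFGHIKLMN"
  ions <- theoretical_by_ions(pep)
  # b_2 unshifted (site > 2) but y_11 unshifted too (site <= 1): collapse
  peaks <- data.frame(
    mz = c(ions$mz[ions$series == "b" & ions$index == 2],
           ions$mz[ions$series == "y" & ions$index == 11],
           ions$mz[ions$series == "b" & ions$index == 5] +
             HYDROXYLATION_DELTA),
    intensity = 1)
  expect_error(localize_site(pep, peaks), "[Ii]nconsistent")
})

test_that("matched set equals the generator's retained-ion truth under dropout", {
  set.seed(24)
  pep <- random_aa_sequence(14)
  pos <- 9
  mods <- data.frame(position = pos, mass_delta = HYDROXYLATION_DELTA)
  ions <- theoretical_by_ions(pep, mods)
  keep <- runif(nrow(ions)) >= 0.2
  peaks <- data.frame(mz = ions$mz[keep], intensity = 1)
  m <- match_peaks(peaks, ions, tol_ppm = 10)
  got <- paste(m$matched$series, m$matched$index)
  want <- paste(ions$series[keep], ions$index[keep])
  expect_setequal(got, want)
})
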