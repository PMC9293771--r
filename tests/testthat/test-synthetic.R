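test_that("planted proteome is recovered exactly by the scanners", {
  ds <- generate_proteome(seed = 7, n_proteins = 20,
                          length_range = c(200, 400),
                          n_legacy = 5, n_revised_only = 5,
                          n_near_miss = 5)
  expect_equal(nrow(ds$truth), 15L)
  hits <- scan_proteome(ds$records)

  # background collisions counted by the independent window oracle
  bg <- unlist(lapply(seq_len(nrow(ds$records)), function(i) {
    s <- oracle_scan_sites(ds$records$sequence[i], "revised")
    planted <- ds$truth$ring_start[
      ds$truth$accession == ds$records$accession[i] &
        ds$truth$class != "near_miss"]
    setdiff(s, planted)
  }))

  planted <- ds$truth[ds$truth$class != "near_miss", ]
  expect_equal(nrow(hits), nrow(planted) + length(bg))
  key <- function(a, p) paste(a, p)
  expect_true(all(key(planted$accession, planted$site_position) %in%
                    key(hits$accession, hits$site_position)))
  # no near-miss window is ever reported as a hit at its planted site
  nm <- ds$truth[ds$truth$class == "near_miss", ]
  expect_false(any(key(nm$accession, nm$site_position) %in%
                     key(hits$accession, hits$site_position)))
})

test_that("planted site flags equal the planted truth classes", {
  ds <- generate_proteome(seed = 8, n_proteins = 30,
                          length_range = c(150, 300),
                          n_legacy = 8, n_revised_only = 8, n_near_miss = 0)
  hits <- scan_proteome(ds$records)
  key <- function(a, p) paste(a, p)
  hk <- key(hits$accession, hits$site_position)
  for (i in seq_len(nrow(ds$truth))) {
    j <- match(key(ds$truth$accession[i], ds$truth$site_position[i]), hk)
    expect_false(is.na(j))
    expected_flag <- if (ds$truth$class[i] == "legacy") "both"
                     else "revised_only"
    expect_equal(hits$flag[j], expected_flag)
  }
})

test_that("with nothing planted the hit count equals the oracle's background count", {
  ds <- generate_proteome(seed = 9, n_proteins = 15,
                          length_range = c(200, 400),
                          n_legacy = 0, n_revised_only = 0, n_near_miss = 0)
  expect_equal(nrow(ds$truth), 0L)
  hits <- scan_proteome(ds$records)
  bg <- sum(vapply(ds$records$sequence, function(s)
    length(oracle_scan_sites(s, "revised")), numeric(1)))
  expect_equal(nrow(hits), as.integer(bg))
})

test_that("proteome generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_proteome(seed = 10, n_proteins = 5, length_range = c(50, 80),
                    n_legacy = 2, n_revised_only = 1, n_near_miss = 1,
                    out_dir = d1)
  generate_proteome(seed = 10, n_proteins = 5, length_range = c(50, 80),
                    n_legacy = 2, n_revised_only = 1, n_near_miss = 1,
                    out_dir = d2)
  for (f in c("proteome.fasta", "truth.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("capacity overflow raises an error", {
  expect_error(
    generate_proteome(seed = 1, n_proteins = 1, length_range = c(12, 12),
                      n_legacy = 5, n_revised_only = 0, n_near_miss = 0),
    "capacity")
})

test_that("noise-free complete spectra localize to the true site, width 1", {
  ds <- simulate_msms_dataset(seed = 12, n_spectra = 25,
                              dropout_prob = 0, mz_noise_ppm = 0)
  for (i in seq_along(ds$spectra)) {
    loc <- localize_site(ds$truth$sequence[i], ds$spectra[[i]]$peaks)
    expect_equal(loc$position, ds$truth$mod_position[i])
  }
})

test_that("localization interval always contains the truth under 30% dropout", {
  ds <- simulate_msms_dataset(seed = 13, n_spectra = 120,
                              dropout_prob = 0.3, mz_noise_ppm = 2)
  for (i in seq_along(ds$spectra)) {
    loc <- localize_site(ds$truth$sequence[i], ds$spectra[[i]]$peaks)
    expect_gte(ds$truth$mod_position[i], loc$interval_start)
    expect_lte(ds$truth$mod_position[i], loc$interval_end)
  }
})

test_that("MGF output round-trips and is deterministic under a seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds <- simulate_msms_dataset(seed = 14, n_spectra = 5, out_dir = d1)
  simulate_msms_dataset(seed = 14, n_spectra = 5, out_dir = d2)
  expect_identical(readBin(file.path(d1, "spectra.mgf"), "raw", 1e7),
                   readBin(file.path(d2, "spectra.mgf"), "raw", 1e7))
  back <- read_mgf(file.path(d1, "spectra.mgf"))
  expect_equal(length(back), 5L)
  expect_equal(back[[1]]$title, ds$spectra[[1]]$title)
  expect_equal(back[[1]]$peaks$mz, ds$spectra[[1]]$peaks$mz,
               tolerance = 1e-6)
})

test_that("LFQ pairs reproduce the true occupancy exactly at cv = 0", {
  ds <- simulate_lfq(seed = 15, true_occupancy_pct = 30, cv = 0,
                     n_pairs = 20)
  est <- occupancy_table(ds$pairs)
  expect_true(all(abs(est$percent - 30) < 1e-9))

  zero <- simulate_lfq(seed = 16, true_occupancy_pct = 0, cv = 0.3,
                       n_pairs = 20)
  expect_true(all(occupancy_table(zero$pairs)$percent == 0))
})

test_that("mean estimated occupancy is within 3 points at cv 0.2, n 200", {
  ds <- simulate_lfq(seed = 17, true_occupancy_pct = 30, cv = 0.2,
                     n_pairs = 200)
  est <- occupancy_table(ds$pairs)
  expect_lt(abs(mean(est$percent) - 30), 3)
})

test_that("noiseless time-course dataset round-trips the kinetic parameters", {
  prep <- enzyme_prep(0.1, 0.951)
  kcat <- 0.30; km <- 7.9
  s0 <- c(1, 2, 5, 10, 20, 50)
  # early window per course keeps conversion in the near-linear regime
  ds <- lapply(s0, function(s) {
    tmax <- 0.02 * (km + s) / (kcat * 0.0951)
    simulate_time_course_dataset(seed = 18, kcat, km, prep, s0 = s,
                                 times = seq(0, tmax, length.out = 6),
                                 noise_sd_pct = 0)$courses
  })
  rates <- vapply(ds, function(cc) {
    tc <- as_time_course(cc$time_s, conversion_pct = cc$conversion_pct,
                         substrate_initial = cc$substrate_uM[1])
    initial_rate(tc)
  }, numeric(1))
  fit <- fit_michaelis_menten(data.frame(substrate = s0, rate = rates))
  expect_lt(abs(fit$km - km) / km, 0.02)
  expect_lt(abs(fit$vmax - kcat * 0.0951) / (kcat * 0.0951), 0.02)
})

test_that("time-course CSV generation is deterministic under a seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    simulate_time_course_dataset(seed = 19, kcat = 0.3, km = 7.9,
                                 s0 = c(2, 10), times = seq(0, 60, 15),
                                 noise_sd_pct = 2, out_dir = d)
  }
  expect_identical(readBin(file.path(d1, "timecourses.csv"), "raw", 1e6),
                   readBin(file.path(d2, "timecourses.csv"), "raw", 1e6))
})
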