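test_that("peak detection finds single and well-separated Gaussians", {
  tr <- gaussian_trace(300, 1000, sd = 3, noise = 1, seed = 1)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$rt_apex - 300), 1)
  expect_gt(pk$area, 0)
  expect_true(pk$rt_lo < pk$rt_apex & pk$rt_apex < pk$rt_hi)

  two <- chromatogram(0:600,
                      1000 * exp(-((0:600) - 200)^2 / 18) +
                        800 * exp(-((0:600) - 260)^2 / 18) +
                        abs(sin(0:600)), 150, "MS1")
  pk2 <- detect_peaks(two)
  expect_equal(nrow(pk2), 2L)
  expect_lt(abs(pk2$rt_apex[1] - 200), 1)
  expect_lt(abs(pk2$rt_apex[2] - 260), 1)
})

test_that("pure noise and short traces yield no peaks", {
  set.seed(7)
  noise <- chromatogram(0:400, abs(rnorm(401)), 100, "MS1")
  expect_equal(nrow(detect_peaks(noise)), 0L)
  expect_equal(nrow(detect_peaks(chromatogram(1:3, c(0, 5, 0), 100, "MS1"))),
               0L)
})

test_that("reconstruction keeps correlated fragments and drops anti-correlated ones", {
  grid <- seq(0, 600, by = 1)
  prec <- gaussian_trace(200, 1000, grid = grid, mz = 400)
  frag_good <- chromatogram(grid, 0.5 * prec$intensity, 150, "MS2", 1L)
  # partially overlapping but RT-shifted fragment: anti-correlated on the
  # shared support, must be dropped by the correlation criterion
  frag_bad <- gaussian_trace(215, 800, grid = grid, mz = 180,
                             level = "MS2", window_id = 1L)
  run <- dia_run(list(prec), cbind(65, 1250), list(frag_good, frag_bad),
                 "negative")
  rec <- reconstruct_spectra(run, min_cor = 0.5)
  expect_length(rec, 1L)
  expect_equal(rec[[1]]$peaks[, "mz"], 150, ignore_attr = TRUE)
  expect_true(all(attr(rec[[1]], "correlations") >= 0.5))
  expect_equal(rec[[1]]$precursor_mz, 400)
})

test_that("simulated DIA runs reconstruct with high recall and low decoy retention", {
  sim <- simulate_dia_run(n_precursors = 20, fragments_per_precursor = 5,
                          decoys_per_precursor = 5, seed = 19)
  rec <- reconstruct_spectra(sim$run, min_cor = 0.5)
  stats <- reconstruction_stats(rec, sim$truth)
  expect_gte(stats$recall, 0.9)
  expect_lte(stats$decoy_retention, 0.1)
  # every retained fragment's correlation is re-checkably above threshold
  cors <- unlist(lapply(rec, attr, "correlations"))
  expect_true(all(cors >= 0.5))
})

test_that("raising the correlation threshold never retains more fragments", {
  sim <- simulate_dia_run(n_precursors = 8, seed = 3)
  pk <- detect_peaks_run(sim$run)
  n_frags <- vapply(c(0.2, 0.5, 0.8, 0.95), function(mc) {
    rec <- reconstruct_spectra(sim$run, pk$ms1, pk$ms2, min_cor = mc)
    sum(vapply(rec, function(s) nrow(s$peaks), integer(1)))
  }, numeric(1))
  expect_true(all(diff(n_frags) <= 0))
})

test_that("RT-window filtering is inclusive at the bounds and idempotent", {
  mk <- function(rt) {
    s <- make_spectrum(sprintf("s%g", rt), 200, 100)
    s$rt <- rt
    s
  }
  sp <- lapply(c(30, 60, 600, 1200, 1250), mk)
  kept <- filter_rt_window(sp, 60, 1200)
  expect_equal(vapply(kept, `[[`, numeric(1), "rt"), c(60, 600, 1200))
  expect_identical(filter_rt_window(kept, 60, 1200), kept)
})

test_that("spectrum merging unifies close peaks at max intensity and is idempotent", {
  s1 <- make_spectrum("a", 400.00, c(100.00, 250.0), c(100, 50))
  s2 <- make_spectrum("b", 400.01, c(100.04, 250.0), c(300, 20))
  merged <- merge_overlapping_spectra(list(s1, s2), mzd = 0.05, ppm = 50)
  expect_length(merged, 1L)
  pk <- merged[[1]]$peaks
  expect_equal(nrow(pk), 2L)
  expect_equal(pk[1, "intensity"], 300)  # max over members
  expect_equal(pk[1, "mz"], (100.00 * 100 + 100.04 * 300) / 400,
               ignore_attr = TRUE)
  again <- merge_overlapping_spectra(merged, mzd = 0.05, ppm = 50)
  expect_equal(again[[1]]$peaks, merged[[1]]$peaks)

  far <- merge_overlapping_spectra(
    list(make_spectrum("c", 500, c(100.00, 100.10), c(10, 20))),
    mzd = 0.05, ppm = 50)
  expect_equal(nrow(far[[1]]$peaks), 2L)
})

test_that("distant precursors are not merged", {
  s1 <- make_spectrum("a", 400, 100)
  s2 <- make_spectrum("b", 405, 100)
  expect_length(merge_overlapping_spectra(list(s1, s2)), 2L)
})

test_that("spectrum cleaning applies floor, relative threshold, and deisotoping", {
  cfg <- pipeline_config()
  s <- make_spectrum("x", 400, c(100, 150), c(5, 500))
  out <- clean_spectrum(s, cfg, run_base_intensity = 1000, deisotope = FALSE)
  expect_equal(out$peaks[, "mz"], 150, ignore_attr = TRUE)

  iso <- make_spectrum("y", 400, c(200.0000, 201.0034), c(1000, 300))
  out2 <- clean_spectrum(iso, cfg)
  expect_equal(nrow(out2$peaks), 1L)
  expect_equal(out2$peaks[, "mz"], 200, ignore_attr = TRUE)

  # all peaks below floor: rejection (NULL), not an error
  low <- make_spectrum("z", 400, c(100, 150), c(2, 3))
  expect_null(clean_spectrum(low, cfg))
  # base peak below the run-relative threshold: rejected
  weak <- make_spectrum("w", 400, 100, 50)
  expect_null(clean_spectrum(weak, cfg, run_base_intensity = 1e7))
  # too few surviving peaks: rejected
  many <- make_spectrum("m", 900, seq(100, 800, length.out = 30),
                        c(rep(1, 29), 100))
  expect_null(clean_spectrum(many, cfg))
  # empty spectrum is an error, distinct from rejection
  empty <- make_spectrum("e", 400, numeric(0), numeric(0))
  expect_error(clean_spectrum(empty, cfg), "empty")
})

test_that("isotopologue precursor spectra are removed across a run", {
  cfg <- pipeline_config()
  main <- make_spectrum("main", 300.0000, 150, 1000)
  iso <- make_spectrum("iso", 301.00335, 150, 200)
  other <- make_spectrum("other", 350, 150, 500)
  out <- deisotope_precursors(list(main, iso, other), cfg)
  expect_setequal(vapply(out, `[[`, character(1), "spectrum_id"),
                  c("main", "other"))
})
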