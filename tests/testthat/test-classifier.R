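test_that("neutral-loss decomposition emits fragments and precursor losses", {
  s <- make_spectrum("d", 300.0, c(120.0, 250.0), c(10, 20))
  d <- decompose_neutral_losses(s)
  expect_setequal(d$value[d$kind == "fragment"], c(120, 250))
  expect_setequal(d$value[d$kind == "neutral_loss"], c(180, 50))

  d2 <- decompose_neutral_losses(s, include_fragment_pairs = TRUE)
  expect_true(130 %in% d2$value[d2$kind == "neutral_loss"])
  expect_equal(nrow(d2), nrow(d) + 1L)

  # peak above the precursor: fragment feature only
  s3 <- make_spectrum("e", 300.0, 310.0, 5)
  d3 <- decompose_neutral_losses(s3)
  expect_equal(d3$kind, "fragment")
  expect_equal(d3$value, 310)
})

test_that("fragment matrices group features by m/z tolerance", {
  s1 <- make_spectrum("a", 500, 100.000, 50)
  s2 <- make_spectrum("b", 500, 100.005, 80)
  fm <- build_fragment_matrix(list(s1, s2), abs_tol = 0.01, ppm_tol = 20)
  expect_equal(sum(fm$features$kind == "fragment"), 1L)

  s3 <- make_spectrum("c", 500, 100.05, 80)
  fm2 <- build_fragment_matrix(list(s1, s3), abs_tol = 0.01, ppm_tol = 20)
  expect_equal(sum(fm2$features$kind == "fragment"), 2L)

  # entries are base-peak-normalised intensities
  s4 <- make_spectrum("d", 500, c(100, 200), c(50, 100))
  fm3 <- build_fragment_matrix(list(s4))
  expect_setequal(fm3$matrix["d", fm3$features$kind == "fragment"],
                  c(0.5, 1.0))
  expect_error(build_fragment_matrix(list()), "empty")
  expect_error(
    build_fragment_matrix(list(s1, make_spectrum("p", 500, 100,
                                                 mode = "positive"))),
    "ion mode")
})

test_that("planted class-signature losses map to single matrix columns", {
  lib <- simulate_spectral_library(n_classes = 3, spectra_per_class = 12,
                                   seed = 23)
  fm <- build_fragment_matrix(lib$spectra)
  for (sig in lib$signatures) {
    losses <- sig$value[sig$kind == "loss"]
    centers <- fm$features$mz[fm$features$kind == "neutral_loss"]
    hits <- vapply(losses, function(v) sum(abs(centers - v) <= 0.015),
                   numeric(1))
    expect_true(all(hits == 1))
  }
})

test_that("spectral clustering separates planted classes", {
  s1 <- make_spectrum("a", 500, c(100, 200))
  s2 <- make_spectrum("b", 500, c(100, 200))
  s3 <- make_spectrum("c", 800, c(350, 420))
  fm <- build_fragment_matrix(list(s1, s2, s3))
  hc <- cluster_spectra(fm)
  expect_equal(min(hc$height), 0)      # identical spectra merge at 0
  expect_equal(max(hc$height), 1)      # disjoint features merge at 1

  for (seed in c(2, 9)) {
    lib <- simulate_spectral_library(n_classes = 3, spectra_per_class = 15,
                                     seed = seed)
    fmx <- build_fragment_matrix(lib$spectra)
    tree <- cluster_spectra(fmx)
    part <- stats::cutree(tree, k = 3)
    expect_gte(oracle_ari(part, lib$truth[names(part)]), 0.95)
  }

  fm$matrix["a", ] <- 0
  expect_error(cluster_spectra(fm), "a")
})

test_that("consensus spectra keep shared features with their frequencies", {
  lib <- simulate_spectral_library(n_classes = 1, spectra_per_class = 12,
                                   noise_features = 0, seed = 31)
  fm <- build_fragment_matrix(lib$spectra)
  ids <- vapply(lib$spectra, `[[`, character(1), "spectrum_id")
  cons <- build_consensus_spectrum(ids, fm)
  expect_true(all(cons$freq >= 0.1))
  expect_true(all(cons$freq <= 1))
  # planted signature features occur in >= 75% of members by construction
  sig <- lib$signatures[[1]]
  for (i in seq_len(nrow(sig))) {
    kind <- ifelse(sig$kind[i] == "loss", "neutral_loss", "fragment")
    j <- which(cons$kind == kind & abs(cons$mz - sig$value[i]) <= 0.015)
    expect_length(j, 1L)
    expect_gte(cons$freq[j], 0.75)
  }
  # every consensus feature is backed by >= 2 members
  expect_true(all(colSums(fm$matrix[ids, cons$feature] > 0) >= 2))
})

test_that("family scores are the frequency-weighted matched fraction", {
  fam <- make_family(freqs = c(1.0, 0.5, 0.75, 0.75),
                     mzs = c(100, 150, 200, 250))
  hit <- make_spectrum("q", 600, c(100.002, 150.001))
  expect_equal(score_spectrum(hit, fam), 1.5 / 3.0)
  all_hit <- make_spectrum("q2", 600, c(100, 150, 200, 250))
  expect_equal(score_spectrum(all_hit, fam), 1.0)
  none <- make_spectrum("q3", 600, c(400, 450))
  expect_equal(score_spectrum(none, fam), 0.0)
  # monotone: adding a matched feature never decreases the score
  plus <- make_spectrum("q4", 600, c(100.002, 150.001, 200.004))
  expect_gte(score_spectrum(plus, fam), score_spectrum(hit, fam))
  # invariant to uniform intensity scaling
  scaled <- make_spectrum("q5", 600, c(100.002, 150.001),
                          c(1000, 2000))
  expect_equal(score_spectrum(scaled, fam), score_spectrum(hit, fam))
  expect_error(score_spectrum(hit, make_family(numeric(0), numeric(0))),
               "empty consensus")
})

test_that("classification ranks candidates, breaks ties by term, checks mode", {
  lib <- simulate_spectral_library(seed = 41)
  clf <- train_family_classifier(lib$spectra, onto = lib$ontology, seed = 1)
  expect_length(clf$families, 3L)
  res <- classify_spectrum(lib$spectra[[1]], clf)
  expect_equal(res$primary, lib$truth[[res$spectrum_id]], ignore_attr = TRUE)
  expect_true(all(diff(res$candidates$score) <= 0))
  expect_true(all(res$candidates$p_value <= 0.05))

  pos <- make_spectrum("p", 300, 100, mode = "positive")
  expect_error(classify_spectrum(pos, clf), "ion-mode mismatch")

  # deterministic tie-break: equal scores ordered by term id
  f1 <- make_family(c(1, 1), c(100, 150)); f1$term <- "ZZ9"
  f2 <- make_family(c(1, 1), c(100, 150)); f2$term <- "AA1"
  clf2 <- clf
  clf2$families <- list(f1, f2)
  clf2$background_scores <- list(ZZ9 = rep(0, 100), AA1 = rep(0, 100))
  r <- classify_spectrum(make_spectrum("t", 600, c(100, 150)), clf2)
  expect_equal(r$candidates$term, c("AA1", "ZZ9"))
})

test_that("training is reproducible and serialises losslessly", {
  lib <- simulate_spectral_library(n_classes = 2, spectra_per_class = 12,
                                   seed = 8)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_classifier(train_family_classifier(lib$spectra, seed = 99), f1)
  write_classifier(train_family_classifier(lib$spectra, seed = 99), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_classifier(f1)
  clf <- train_family_classifier(lib$spectra, seed = 99)
  expect_equal(back$families[[1]]$consensus, clf$families[[1]]$consensus,
               tolerance = 1e-9)
  expect_equal(back$background_scores, clf$background_scores,
               tolerance = 1e-9, ignore_attr = TRUE)
  s <- lib$spectra[[5]]
  expect_equal(classify_spectrum(s, back)$candidates,
               classify_spectrum(s, clf)$candidates, tolerance = 1e-9)
})

test_that("classification is invariant to peak order and intensity scale", {
  lib <- simulate_spectral_library(seed = 13)
  clf <- train_family_classifier(lib$spectra, seed = 2)
  s <- lib$spectra[[30]]
  shuffled <- spectrum(s$spectrum_id, s$precursor_mz, s$rt,
                       s$peaks[rev(seq_len(nrow(s$peaks))), ],
                       s$ion_mode)
  scaled <- spectrum(s$spectrum_id, s$precursor_mz, s$rt,
                     cbind(s$peaks[, 1], s$peaks[, 2] * 37.5), s$ion_mode)
  r0 <- classify_spectrum(s, clf)
  expect_equal(classify_spectrum(shuffled, clf)$candidates, r0$candidates)
  expect_equal(classify_spectrum(scaled, clf)$candidates, r0$candidates)
})

test_that("validation reports perfect separation for disjoint classes and is deterministic", {
  lib <- simulate_spectral_library(n_classes = 3, spectra_per_class = 20,
                                   seed = 17)
  rep1 <- validate_classifier(lib$spectra, n_repeats = 3, seed = 5,
                              onto = lib$ontology)
  rep2 <- validate_classifier(lib$spectra, n_repeats = 3, seed = 5,
                              onto = lib$ontology)
  expect_identical(rep1$per_family, rep2$per_family)
  expect_true(all(rep1$per_family$auc == 1))
  expect_true(all(rep1$per_family$sensitivity >= 0.9))
  expect_true(all(rep1$per_family$specificity >= 0.9))
})
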