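#' Simulate an annotated spectral library with planted class signatures
#'
#' Emulates a compound-class-annotated MS/MS library: every class owns a
#' signature set of fragment m/z values and neutral losses; each member
#' spectrum realises at least 75 percent of its class signature (losses as
#' peaks at `precursor - loss`) plus random noise peaks. Classes may share
#' a controlled fraction of signature features. Output is reproducible
#' from the seed.
#'
#' @param n_classes Number of compound classes (default 3).
#' @param spectra_per_class Spectra per class (default 20).
#' @param signature_size Signature features per class (default 8).
#' @param signature_overlap Fraction of each signature drawn from a pool
#'   shared by all classes, in `[0, 1)` (default 0).
#' @param noise_features Random noise peaks per spectrum (default 3).
#' @param mz_range Fragment m/z range in Da (default `c(80, 800)`).
#' @param compounds_per_class Distinct compounds per class (default 60
#'   percent of the spectra, at least one).
#' @param ion_mode Ion mode of the library (default `"negative"`).
#' @param seed Integer seed.
#' @return List with `spectra` (annotated [spectrum] list), `ontology`
#'   (an [ontology] with one class term per simulated class under a common
#'   root), and `truth` (named vector spectrum id -> class term).
#' @export
simulate_spectral_library <- function(n_classes = 3, spectra_per_class = 20,
                                      signature_size = 8,
                                      signature_overlap = 0,
                                      noise_features = 3,
                                      mz_range = c(80, 800),
                                      compounds_per_class =
                                        max(1L, ceiling(0.6 * spectra_per_class)),
                                      ion_mode = c("negative", "positive"),
                                      seed = 1L) {
  ion_mode <- match.arg(ion_mode)
  if (signature_overlap < 0 || signature_overlap >= 1)
    stop("signature_overlap must be in [0, 1)")
  n_shared <- floor(signature_overlap * signature_size)
  n_own <- signature_size - n_shared
  if (n_own < 1L && n_classes > 1L)
    stop("infeasible overlap: no class-specific features left")
  with_seed(seed, {
    # well-separated feature values (>= 1 Da apart, far beyond 0.01 Da
    # grouping) so planted signatures map to unambiguous bins
    n_pool <- n_shared + n_classes * n_own + 50L
    losses_pool <- round(seq(18, 18 + 2.13 * (n_pool - 1), by = 2.13) +
                           stats::runif(n_pool, -0.4, 0.4), 4)
    frags_pool <- round(seq(mz_range[1], mz_range[2],
                            length.out = n_pool) +
                          stats::runif(n_pool, -0.3, 0.3), 4)
    # one shared feature block (alternating kinds) plus per-class own blocks
    shared_sig <- if (n_shared > 0L) data.frame(
      kind = rep(c("loss", "frag"), length.out = n_shared),
      value = ifelse(rep(c(TRUE, FALSE), length.out = n_shared),
                     losses_pool[seq_len(n_shared)],
                     frags_pool[seq_len(n_shared)]),
      stringsAsFactors = FALSE) else NULL
    terms <- sprintf("CL%03d", seq_len(n_classes))
    signatures <- lapply(seq_len(n_classes), function(k) {
      own_idx <- n_shared + (k - 1L) * n_own + seq_len(n_own)
      own <- data.frame(
        kind = rep(c("loss", "frag"), length.out = n_own),
        value = ifelse(rep(c(TRUE, FALSE), length.out = n_own),
                       losses_pool[own_idx], frags_pool[own_idx]),
        stringsAsFactors = FALSE)
      rbind(shared_sig, own)
    })
    spectra <- list()
    truth <- character(0)
    min_feats <- ceiling(0.75 * signature_size)
    for (k in seq_len(n_classes)) {
      sig <- signatures[[k]]
      max_loss <- max(sig$value[sig$kind == "loss"], 0)
      for (j in seq_len(spectra_per_class)) {
        n_take <- sample(min_feats:signature_size, 1L)
        take <- sig[sample(signature_size, n_take), , drop = FALSE]
        precursor <- round(stats::runif(1, max(max_loss, mz_range[2]) + 60,
                                        max(max_loss, mz_range[2]) + 400), 4)
        mz <- ifelse(take$kind == "loss", precursor - take$value, take$value)
        int <- round(stats::rlnorm(n_take, log(500), 0.6), 1)
        if (noise_features > 0L) {
          nz <- round(stats::runif(noise_features, 50, precursor - 1), 4)
          mz <- c(mz, nz)
          int <- c(int, round(stats::rlnorm(noise_features, log(80), 0.5), 1))
        }
        ok <- !duplicated(round(mz, 3))
        sid <- sprintf("%s_S%03d", terms[k], j)
        spectra[[length(spectra) + 1L]] <- spectrum(
          spectrum_id = sid, precursor_mz = precursor,
          rt = round(stats::runif(1, 60, 1200), 1),
          peaks = cbind(mz = mz[ok], intensity = int[ok]),
          ion_mode = ion_mode,
          compound_id = sprintf("%s_C%02d", terms[k],
                                ((j - 1L) %% compounds_per_class) + 1L),
          ontology_terms = terms[k])
        truth[sid] <- terms[k]
      }
    }
    onto <- ontology(data.frame(
      term_id = c("ROOT", terms),
      name = c("Organic compounds", sprintf("Simulated class %d",
                                            seq_len(n_classes))),
      parent_id = c(NA, rep("ROOT", n_classes)),
      level = c("superclass", rep("class", n_classes)),
      stringsAsFactors = FALSE))
    list(spectra = spectra, ontology = onto, truth = truth,
         signatures = stats::setNames(signatures, terms))
  })
}

#' Simulate a DIA run with known precursor-fragment links
#'
#' Precursors get Gaussian MS1 elution profiles on a shared RT grid; their
#' true fragments co-elute in the correct isolation window as scaled copies
#' of the precursor profile, while decoy fragments are placed in the same
#' window at a shifted retention time. Additive Gaussian noise (clipped at
#' zero) is applied to every trace. The returned ground truth maps each
#' precursor to its true fragment m/z values.
#'
#' @param n_precursors Number of precursors (default 20).
#' @param fragments_per_precursor True co-eluting fragments each (default 5).
#' @param decoys_per_precursor Decoy fragments each (default 5).
#' @param decoy_rt_offset RT displacement of decoys in seconds (default 25;
#'   decoys keep the Gaussian shape, isolating the correlation criterion).
#' @param rt_range Elution window for precursor apexes (default
#'   `c(90, 500)`).
#' @param rt_step RT grid spacing in seconds (default 1).
#' @param peak_sd Gaussian peak width sigma in seconds (default 3).
#' @param noise_sd Additive noise standard deviation (default 1).
#' @param n_windows Number of isolation windows covering 65-1250 Da
#'   (default 24).
#' @param ion_mode Run ion mode (default `"negative"`).
#' @param seed Integer seed.
#' @return List with `run` (a [dia_run]) and `truth` (list per precursor:
#'   `mz`, `rt`, `fragments`, `decoys`).
#' @export
simulate_dia_run <- function(n_precursors = 20, fragments_per_precursor = 5,
                             decoys_per_precursor = 5, decoy_rt_offset = 25,
                             rt_range = c(90, 500), rt_step = 1,
                             peak_sd = 3, noise_sd = 1, n_windows = 24,
                             ion_mode = c("negative", "positive"),
                             seed = 1L) {
  ion_mode <- match.arg(ion_mode)
  with_seed(seed, {
    grid <- seq(rt_range[1] - 60, rt_range[2] + 60, by = rt_step)
    wbreaks <- seq(65, 1250, length.out = n_windows + 1L)
    windows <- cbind(low_mz = wbreaks[-length(wbreaks)],
                     high_mz = wbreaks[-1L])
    gauss <- function(apex, height)
      height * exp(-(grid - apex)^2 / (2 * peak_sd^2))
    noisy <- function(y) pmax(0, y + stats::rnorm(length(y), 0, noise_sd))
    prec_mz <- round(stats::runif(n_precursors, 150, 1100), 4)
    prec_rt <- round(stats::runif(n_precursors, rt_range[1], rt_range[2]), 1)
    prec_h <- stats::runif(n_precursors, 400, 1500)
    ms1 <- list(); ms2 <- list(); truth <- list()
    for (i in seq_len(n_precursors)) {
      ms1[[i]] <- chromatogram(grid, noisy(gauss(prec_rt[i], prec_h[i])),
                               prec_mz[i], "MS1")
      win <- which(prec_mz[i] >= windows[, 1] & prec_mz[i] <= windows[, 2])[1L]
      f_mz <- round(stats::runif(fragments_per_precursor, 65,
                                 prec_mz[i] - 10), 4)
      d_mz <- round(stats::runif(decoys_per_precursor, 65,
                                 prec_mz[i] - 10), 4)
      for (mz in f_mz) {
        sc <- stats::runif(1, 0.25, 0.9)
        ms2[[length(ms2) + 1L]] <- chromatogram(
          grid, noisy(gauss(prec_rt[i], sc * prec_h[i])), mz, "MS2", win)
      }
      for (mz in d_mz) {
        sc <- stats::runif(1, 0.25, 0.9)
        shift <- sample(c(-1, 1), 1L) * decoy_rt_offset
        ms2[[length(ms2) + 1L]] <- chromatogram(
          grid, noisy(gauss(prec_rt[i] + shift, sc * prec_h[i])), mz, "MS2",
          win)
      }
      truth[[i]] <- list(mz = prec_mz[i], rt = prec_rt[i],
                         fragments = f_mz, decoys = d_mz)
    }
    list(run = dia_run(ms1, windows, ms2, ion_mode), truth = truth)
  })
}

#' Score a reconstruction against simulated ground truth
#'
#' Matches reconstructed spectra to the simulated precursors by m/z and
#' counts how many true fragments were recovered and how many decoy
#' fragments slipped through.
#'
#' @param spectra Output of [reconstruct_spectra].
#' @param truth The `truth` element of [simulate_dia_run].
#' @param mz_tol Matching tolerance in Da (default 0.01).
#' @return List with `recall` (true fragments recovered / planted),
#'   `decoy_retention` (decoys retained / planted), `n_true`, `n_decoys`.
#' @export
reconstruction_stats <- function(spectra, truth, mz_tol = 0.01) {
  prec_mz <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  n_true <- n_dec <- got_true <- got_dec <- 0L
  for (tr in truth) {
    n_true <- n_true + length(tr$fragments)
    n_dec <- n_dec + length(tr$decoys)
    hit <- which(abs(prec_mz - tr$mz) <= mz_tol)
    if (length(hit) == 0L) next
    got <- unlist(lapply(spectra[hit], function(s) s$peaks[, "mz"]))
    got_true <- got_true + sum(vapply(tr$fragments, function(f)
      any(abs(got - f) <= mz_tol), logical(1)))
    got_dec <- got_dec + sum(vapply(tr$decoys, function(f)
      any(abs(got - f) <= mz_tol), logical(1)))
  }
  list(recall = got_true / n_true, decoy_retention = got_dec / n_dec,
       n_true = n_true, n_decoys = n_dec)
}

#' Simulate a two-condition multi-species abundance study
#'
#' Emulates a fresh vs dry (herbarium) study over several species: each
#' compound belongs to a class; its presence probability in a sample
#' follows a logistic model with a per-compound baseline, a per-species
#' random effect, and a class-level shift (in logit units) applied under
#' the dry condition. Abundances of present compounds are log-normal with
#' species random intercepts. The returned truth records the planted shift
#' direction per class.
#'
#' @param n_species Number of species (default 10).
#' @param samples_per_species_per_condition Replicates (default 4).
#' @param n_classes Number of compound classes (default 12).
#' @param compounds_per_class Compounds per class (default 15).
#' @param class_shift_effects Numeric vector (length `n_classes`) of
#'   logit-scale presence shifts fresh -> dry; default: first class +2,
#'   second -2, rest 0.
#' @param presence_base Baseline presence probability (default 0.5).
#' @param species_effect_sd SD of species effects on the logit scale
#'   (default 0.5).
#' @param abundance_sd Log-scale within-species abundance SD (default 0.5).
#' @param ion_mode Nominal ion mode for feature ids (default `"negative"`).
#' @param seed Integer seed.
#' @return List with `table` (raw-abundance [feature_table]), `classes`
#'   (named vector feature id -> class term), `ontology`, and `truth`
#'   (planted shifts per class).
#' @export
simulate_condition_study <- function(n_species = 10,
                                     samples_per_species_per_condition = 4,
                                     n_classes = 12, compounds_per_class = 15,
                                     class_shift_effects = NULL,
                                     presence_base = 0.5,
                                     species_effect_sd = 0.5,
                                     abundance_sd = 0.5,
                                     ion_mode = "negative",
                                     seed = 1L) {
  if (is.null(class_shift_effects)) {
    class_shift_effects <- numeric(n_classes)
    if (n_classes >= 1L) class_shift_effects[1L] <- 2
    if (n_classes >= 2L) class_shift_effects[2L] <- -2
  }
  stopifnot(length(class_shift_effects) == n_classes)
  with_seed(seed, {
    terms <- sprintf("CL%03d", seq_len(n_classes))
    n_comp <- n_classes * compounds_per_class
    comp_class <- rep(seq_len(n_classes), each = compounds_per_class)
    comp_base <- stats::qlogis(presence_base) + stats::rnorm(n_comp, 0, 0.4)
    comp_abund <- stats::rnorm(n_comp, 5, 0.8)  # log10-ish location
    species <- sprintf("SP%02d", seq_len(n_species))
    sp_eff <- matrix(stats::rnorm(n_comp * n_species, 0, species_effect_sd),
                     n_comp, n_species)
    sp_abund <- stats::rnorm(n_species, 0, 0.3)
    conditions <- c("fresh", "dry")
    n_samples <- n_species * 2L * samples_per_species_per_condition
    sample_id <- character(n_samples)
    herbarium <- character(n_samples)
    sp_of <- character(n_samples)
    m <- matrix(0, n_comp, n_samples)
    col <- 0L
    for (s in seq_len(n_species)) for (cond in conditions)
      for (r in seq_len(samples_per_species_per_condition)) {
        col <- col + 1L
        sample_id[col] <- sprintf("%s_%s_%d", cond, species[s], r)
        herbarium[col] <- cond
        sp_of[col] <- species[s]
        eta <- comp_base + sp_eff[, s] +
          if (cond == "dry") class_shift_effects[comp_class] else 0
        present <- stats::runif(n_comp) < stats::plogis(eta)
        ab <- 10^(comp_abund + sp_abund[s] +
                    stats::rnorm(n_comp, 0, abundance_sd))
        m[, col] <- ifelse(present, ab, 0)
      }
    colnames(m) <- sample_id
    features <- data.frame(
      mz = round(stats::runif(n_comp, 100, 1100), 4),
      rt = round(stats::runif(n_comp, 60, 1200), 1),
      ion_mode = ion_mode, stringsAsFactors = FALSE)
    ft <- feature_table(m, features = features,
                        factors = data.frame(sample_id = sample_id,
                                             herbarium = herbarium,
                                             species = sp_of,
                                             stringsAsFactors = FALSE))
    classes <- stats::setNames(terms[comp_class], rownames(ft$abundances))
    onto <- ontology(data.frame(
      term_id = c("ROOT", terms),
      name = c("Organic compounds", sprintf("Simulated class %d",
                                            seq_len(n_classes))),
      parent_id = c(NA, rep("ROOT", n_classes)),
      level = c("superclass", rep("class", n_classes)),
      stringsAsFactors = FALSE))
    list(table = ft, classes = classes, ontology = onto,
         truth = stats::setNames(class_shift_effects, terms))
  })
}
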