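#' Select metabolite families from a spectral clustering tree
#'
#' A metabolite family is a subtree of the fragment-based clustering whose
#' members share a chemical-ontology term and a common substructure signal.
#' A subtree is a candidate when a majority (> 50 percent) of its member
#' spectra carry one common ontology term; it is accepted when it
#' (1) contains at least `min_spectra` fragment spectra, (2) has at least
#' one feature present in at least `shared_fraction` of its spectra,
#' (3) covers at least `min_compounds` distinct compounds, and (4) its
#' parent subtree fails criterion 2 (so the most inclusive subtree with a
#' conserved feature wins). When several accepted subtrees map to the same
#' term, the largest is kept.
#'
#' @param tree `hclust` tree from [cluster_spectra].
#' @param fm The [build_fragment_matrix] result the tree was built on.
#' @param annotations Named list mapping spectrum id to a character vector
#'   of ontology term ids.
#' @param compounds Optional named character vector mapping spectrum id to
#'   compound id (defaults to the spectrum id itself).
#' @param onto Optional [ontology]; used to break majority-term ties toward
#'   the shallower term.
#' @param min_spectra Criterion 1 threshold (default 10).
#' @param min_compounds Criterion 3 threshold (default 5).
#' @param shared_fraction Criterion 2 threshold (default 0.75).
#' @return List of `metabolite_family` objects (empty, with a warning, when
#'   no cluster passes).
#' @export
select_metabolite_families <- function(tree, fm, annotations,
                                       compounds = NULL, onto = NULL,
                                       min_spectra = 10, min_compounds = 5,
                                       shared_fraction = 0.75) {
  ids <- tree$labels
  if (is.null(compounds)) compounds <- stats::setNames(ids, ids)
  pres <- fm$matrix[ids, , drop = FALSE] > 0
  members <- hclust_members(tree)
  parents <- hclust_parents(tree)
  passes_c2 <- vapply(members, function(mem) {
    max(colMeans(pres[mem, , drop = FALSE])) >= shared_fraction - 1e-12
  }, logical(1))
  accepted <- list()
  for (i in seq_along(members)) {
    mem <- members[[i]]
    if (length(mem) < min_spectra) next                       # criterion 1
    if (!passes_c2[i]) next                                   # criterion 2
    cmp <- unique(compounds[ids[mem]])
    if (length(cmp) < min_compounds) next                     # criterion 3
    if (!is.na(parents[i]) && passes_c2[parents[i]]) next     # criterion 4
    term <- majority_term(annotations[ids[mem]], onto)
    if (is.null(term)) next
    accepted[[length(accepted) + 1L]] <- list(
      node = i, term = term, member_ids = ids[mem],
      n = length(mem), height = tree$height[i])
  }
  if (length(accepted) == 0L) {
    warning("no cluster satisfies the family-selection criteria")
    return(list())
  }
  # one family per term: largest accepted cluster wins
  terms <- vapply(accepted, `[[`, character(1), "term")
  keep <- unlist(lapply(split(seq_along(accepted), terms), function(idx) {
    sizes <- vapply(accepted[idx], `[[`, numeric(1), "n")
    hts <- vapply(accepted[idx], `[[`, numeric(1), "height")
    idx[order(-sizes, hts)[1L]]
  }))
  lapply(accepted[sort(keep)], function(a) {
    consensus <- build_consensus_spectrum(a$member_ids, fm)
    structure(list(
      term = a$term,
      term_name = if (!is.null(onto)) onto$name[match(a$term, onto$term_id)]
                  else a$term,
      member_ids = a$member_ids,
      compound_ids = unique(unname(compounds[a$member_ids])),
      consensus = consensus),
      class = "metabolite_family")
  })
}

# plurality term carried by > 50% of member spectra; ties broken toward the
# shallower ontology term, then lexicographically
majority_term <- function(term_lists, onto) {
  tab <- table(unlist(lapply(term_lists, unique)))
  if (length(tab) == 0L) return(NULL)
  tab <- tab[tab > length(term_lists) / 2]
  if (length(tab) == 0L) return(NULL)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1L && !is.null(onto)) {
    d <- term_depths(as.data.frame(onto))[cand]
    cand <- cand[order(d, cand)]
  } else {
    cand <- sort(cand)
  }
  cand[1L]
}

#' @export
print.metabolite_family <- function(x, ...) {
  cat(sprintf("<metabolite_family> %s (%s): %d spectra, %d compounds, %d consensus features\n",
              x$term, x$term_name, length(x$member_ids),
              length(x$compound_ids), nrow(x$consensus)))
  invisible(x)
}

#' Build a consensus spectrum for a family
#'
#' For every feature bin present in at least two member spectra the
#' consensus records the occurrence frequency `freq` (fraction of members
#' containing the feature) and the median relative intensity among members
#' containing it. Features with `freq` below `min_freq` are dropped.
#'
#' @param member_ids Spectrum ids of the family members (rows of `fm`).
#' @param fm A [build_fragment_matrix] result.
#' @param min_freq Minimum occurrence frequency retained (default 0.1).
#' @return Data frame `feature`, `kind`, `mz`, `freq`, `median_intensity`.
#' @export
build_consensus_spectrum <- function(member_ids, fm, min_freq = 0.1) {
  m <- fm$matrix[member_ids, , drop = FALSE]
  count <- colSums(m > 0)
  keep <- which(count >= 2L & count / nrow(m) >= min_freq - 1e-12)
  med <- vapply(keep, function(j) stats::median(m[m[, j] > 0, j]), numeric(1))
  data.frame(feature = colnames(m)[keep],
             kind = fm$features$kind[keep],
             mz = fm$features$mz[keep],
             freq = unname(count[keep] / nrow(m)),
             median_intensity = med,
             row.names = NULL, stringsAsFactors = FALSE)
}

# score a decomposed feature set against a family consensus
score_features <- function(feats, family, abs_tol, ppm_tol) {
  cons <- family$consensus
  if (nrow(cons) == 0L) stop("family has an empty consensus spectrum")
  matched <- vapply(seq_len(nrow(cons)), function(i) {
    tol <- mz_tolerance(cons$mz[i], abs_tol, ppm_tol)
    any(feats$kind == cons$kind[i] & abs(feats$value - cons$mz[i]) <= tol)
  }, logical(1))
  sum(cons$freq[matched]) / sum(cons$freq)
}

#' Score a spectrum against one metabolite family
#'
#' The score is the frequency-weighted fraction of the family's consensus
#' features matched by the query's fragments and neutral losses:
#' `sum(w_f over matched) / sum(w_f)`, with m/z matching within
#' `max(abs_tol, ppm_tol * mz / 1e6)`. It is 0 when nothing matches, 1 when
#' every consensus feature is matched, monotone in the matched set, and
#' invariant to peak order and uniform intensity scaling.
#'
#' @param s A cleaned [spectrum].
#' @param family A `metabolite_family`.
#' @param abs_tol,ppm_tol Matching tolerances (defaults 0.01 Da, 20 ppm).
#' @return Score in `[0, 1]`.
#' @export
score_spectrum <- function(s, family, abs_tol = 0.01, ppm_tol = 20) {
  score_features(decompose_neutral_losses(s), family, abs_tol, ppm_tol)
}

#' Train a metabolite-family classifier
#'
#' End-to-end training: spectra are decomposed into fragments and neutral
#' losses, binned into a fragment matrix, clustered, and family subtrees
#' are selected ([select_metabolite_families]); each family gets a
#' consensus spectrum and a background score distribution (scores of all
#' non-member training spectra, supplemented with feature-permuted spectra
#' up to `bg_size` samples) from which classification p-values are drawn.
#'
#' @param spectra Annotated [spectrum] list (one ion mode); annotations are
#'   taken from each spectrum's `ontology_terms` and compound identity from
#'   `compound_id`.
#' @param onto Optional [ontology] for labels and tie-breaks.
#' @param abs_tol,ppm_tol Fragment-matrix grouping and scoring tolerances.
#' @param min_spectra,min_compounds,shared_fraction Family-selection
#'   criteria (see [select_metabolite_families]).
#' @param bg_size Minimum background sample size per family (default 100).
#' @param seed Integer seed making training reproducible.
#' @return An object of class `family_classifier` with `print`, `summary`
#'   and `predict` methods.
#' @export
train_family_classifier <- function(spectra, onto = NULL,
                                    abs_tol = 0.01, ppm_tol = 20,
                                    min_spectra = 10, min_compounds = 5,
                                    shared_fraction = 0.75,
                                    bg_size = 100, seed = 1L) {
  ids <- vapply(spectra, `[[`, character(1), "spectrum_id")
  annotations <- lapply(spectra, function(s) s$ontology_terms %||% character(0))
  names(annotations) <- ids
  if (all(lengths(annotations) == 0L))
    stop("training spectra carry no ontology annotations")
  compounds <- vapply(spectra, function(s) s$compound_id %||% s$spectrum_id,
                      character(1))
  names(compounds) <- ids
  fm <- build_fragment_matrix(spectra, abs_tol, ppm_tol)
  tree <- cluster_spectra(fm)
  families <- select_metabolite_families(
    tree, fm, annotations, compounds, onto,
    min_spectra = min_spectra, min_compounds = min_compounds,
    shared_fraction = shared_fraction)
  feats_by_id <- lapply(spectra, decompose_neutral_losses)
  names(feats_by_id) <- ids
  background <- lapply(seq_along(families), function(fi) {
    fam <- families[[fi]]
    non_members <- setdiff(ids, fam$member_ids)
    bg <- vapply(feats_by_id[non_members], score_features, numeric(1),
                 family = fam, abs_tol = abs_tol, ppm_tol = ppm_tol)
    bg <- unname(bg)
    if (length(bg) < bg_size) {
      extra <- with_seed(derive_seed(seed, fi), {
        vapply(seq_len(bg_size - length(bg)), function(k) {
          src <- feats_by_id[[sample(length(feats_by_id), 1L)]]
          perm <- fm$features[sample(nrow(fm$features), nrow(src),
                                     replace = TRUE), ]
          score_features(
            data.frame(kind = perm$kind, value = perm$mz,
                       stringsAsFactors = FALSE),
            fam, abs_tol, ppm_tol)
        }, numeric(1))
      })
      bg <- c(bg, extra)
    }
    bg
  })
  names(background) <- vapply(families, `[[`, character(1), "term")
  structure(list(
    families = families,
    background_scores = background,
    features = fm$features,
    abs_tol = abs_tol, ppm_tol = ppm_tol,
    ion_mode = spectra[[1L]]$ion_mode,
    library_size = length(spectra),
    seed = as.integer(seed),
    params = list(min_spectra = min_spectra, min_compounds = min_compounds,
                  shared_fraction = shared_fraction, bg_size = bg_size)),
    class = "family_classifier")
}

#' @export
print.family_classifier <- function(x, ...) {
  cat(sprintf("<family_classifier> %d metabolite families (%s mode), trained on %d spectra\n",
              length(x$families), x$ion_mode, x$library_size))
  invisible(x)
}

#' @export
summary.family_classifier <- function(object, ...) {
  df <- data.frame(
    term = vapply(object$families, `[[`, character(1), "term"),
    name = vapply(object$families, `[[`, character(1), "term_name"),
    n_spectra = vapply(object$families, function(f) length(f$member_ids),
                       integer(1)),
    n_compounds = vapply(object$families, function(f) length(f$compound_ids),
                         integer(1)),
    n_consensus = vapply(object$families, function(f) nrow(f$consensus),
                         integer(1)),
    n_background = lengths(object$background_scores),
    row.names = NULL, stringsAsFactors = FALSE)
  cat(sprintf("Metabolite-family classifier (%s mode), library of %d spectra\n",
              object$ion_mode, object$library_size))
  print(df, ...)
  invisible(df)
}

#' Classify one spectrum
#'
#' Scores the query against every family; the p-value of a score is its
#' conservative rank in the family's background distribution:
#' one plus the number of background scores at or above the observed score,
#' divided by one plus the background size. Families with
#' `p <= alpha` enter the candidate list, ranked by descending score with
#' ties broken by term id; the top candidate is the primary compound class
#' and the remainder are alternative parents. An empty candidate list means
#' the spectrum stays unclassified.
#'
#' @param s A [spectrum] (same ion mode as the classifier).
#' @param clf A [train_family_classifier] model.
#' @param alpha Candidate inclusion threshold (default 0.05).
#' @return An object of class `classification_result`.
#' @export
classify_spectrum <- function(s, clf, alpha = 0.05) {
  if (s$ion_mode != clf$ion_mode)
    stop(sprintf("ion-mode mismatch: spectrum is %s, classifier is %s",
                 s$ion_mode, clf$ion_mode))
  feats <- decompose_neutral_losses(s)
  terms <- vapply(clf$families, `[[`, character(1), "term")
  score <- vapply(clf$families, function(f)
    score_features(feats, f, clf$abs_tol, clf$ppm_tol), numeric(1))
  pval <- vapply(seq_along(terms), function(i) {
    bg <- clf$background_scores[[terms[i]]]
    (1 + sum(bg >= score[i] - 1e-12)) / (1 + length(bg))
  }, numeric(1))
  df <- data.frame(term = terms, score = score, p_value = pval,
                   stringsAsFactors = FALSE)
  cand <- df[df$p_value <= alpha, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$term), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(spectrum_id = s$spectrum_id,
                 candidates = cand,
                 all_scores = df,
                 primary = if (nrow(cand)) cand$term[1L] else NA_character_),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  if (is.na(x$primary)) {
    cat(sprintf("<classification> %s: unclassified\n", x$spectrum_id))
  } else {
    cat(sprintf("<classification> %s: %s (score %.3f, p %.3g)%s\n",
                x$spectrum_id, x$primary, x$candidates$score[1L],
                x$candidates$p_value[1L],
                if (nrow(x$candidates) > 1L)
                  sprintf(", +%d alternative parents", nrow(x$candidates) - 1L)
                else ""))
  }
  invisible(x)
}

#' Classify a batch of spectra
#'
#' @param object A `family_classifier`.
#' @param newdata List of [spectrum] objects (or a single spectrum).
#' @param alpha Candidate threshold (default 0.05).
#' @param ... Unused.
#' @return Data frame with one row per spectrum: `spectrum_id`,
#'   `primary_term`, `score`, `p_value`, `alternatives` (semicolon-joined).
#' @export
predict.family_classifier <- function(object, newdata, alpha = 0.05, ...) {
  if (inherits(newdata, "spectrum")) newdata <- list(newdata)
  rows <- lapply(newdata, function(s) {
    r <- classify_spectrum(s, object, alpha)
    data.frame(
      spectrum_id = r$spectrum_id,
      primary_term = r$primary,
      score = if (nrow(r$candidates)) r$candidates$score[1L] else NA_real_,
      p_value = if (nrow(r$candidates)) r$candidates$p_value[1L] else NA_real_,
      alternatives = if (nrow(r$candidates) > 1L)
        paste(r$candidates$term[-1L], collapse = ";") else "",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Validate a classifier by stratified repeated subset validation
#'
#' Repeats a stratified split (per annotated class) into training and test
#' portions, retrains on the training portion, and reports per-family
#' sensitivity and specificity of the `p <= alpha` call plus the AUC of the
#' score ranking (members vs non-members), averaged over repeats. Families
#' untrainable in a given split are skipped for that repeat.
#'
#' @param spectra Annotated [spectrum] list.
#' @param n_repeats Number of dataset compositions (default 10).
#' @param train_fraction Training fraction per class (default 0.7).
#' @param seed Integer seed.
#' @param alpha Call threshold (default 0.05).
#' @param onto,... Passed to [train_family_classifier].
#' @return An object of class `validation_report`: per-family mean
#'   sensitivity, specificity, AUC, and the number of contributing repeats.
#' @export
validate_classifier <- function(spectra, n_repeats = 10,
                                train_fraction = 0.7, seed = 1L,
                                alpha = 0.05, onto = NULL, ...) {
  ids <- vapply(spectra, `[[`, character(1), "spectrum_id")
  strata <- vapply(spectra, function(s)
    (s$ontology_terms %||% "unannotated")[1L], character(1))
  recs <- list()
  for (rep_i in seq_len(n_repeats)) {
    split_idx <- with_seed(derive_seed(seed, rep_i), {
      unlist(lapply(split(seq_along(spectra), strata), function(idx) {
        n_tr <- max(1L, round(train_fraction * length(idx)))
        sample(idx, n_tr)
      }))
    })
    train <- spectra[split_idx]
    test <- spectra[-split_idx]
    clf <- tryCatch(
      suppressWarnings(train_family_classifier(
        train, onto = onto, seed = derive_seed(seed, 1000L + rep_i), ...)),
      error = function(e) NULL)
    if (is.null(clf) || length(clf$families) == 0L || length(test) == 0L) next
    test_feats <- lapply(test, decompose_neutral_losses)
    test_terms <- lapply(test, function(s) s$ontology_terms %||% character(0))
    for (fam in clf$families) {
      sc <- vapply(test_feats, score_features, numeric(1), family = fam,
                   abs_tol = clf$abs_tol, ppm_tol = clf$ppm_tol)
      bg <- clf$background_scores[[fam$term]]
      pv <- vapply(sc, function(x) (1 + sum(bg >= x - 1e-12)) / (1 + length(bg)),
                   numeric(1))
      truth <- vapply(test_terms, function(tt) fam$term %in% tt, logical(1))
      called <- pv <= alpha
      recs[[length(recs) + 1L]] <- data.frame(
        repeat_id = rep_i, term = fam$term,
        sensitivity = if (any(truth)) mean(called[truth]) else NA_real_,
        specificity = if (any(!truth)) mean(!called[!truth]) else NA_real_,
        auc = rank_auc(sc, truth),
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) stop("no family was trainable in any split")
  all <- do.call(rbind, recs)
  per_family <- do.call(rbind, lapply(split(all, all$term), function(d) {
    data.frame(term = d$term[1L],
               sensitivity = mean(d$sensitivity, na.rm = TRUE),
               specificity = mean(d$specificity, na.rm = TRUE),
               auc = mean(d$auc, na.rm = TRUE),
               n_repeats = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(per_family) <- NULL
  structure(list(per_family = per_family, per_repeat = all,
                 n_repeats = n_repeats, train_fraction = train_fraction,
                 seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Stratified repeated subset validation: %d repeats, %.0f%% training\n",
              x$n_repeats, 100 * x$train_fraction))
  print(x$per_family, digits = 3)
  invisible(x)
}

#' Serialise a trained classifier to JSON
#' @param clf A `family_classifier`.
#' @param file Output path.
#' @export
write_classifier <- function(clf, file) {
  payload <- list(
    format = "specfam_classifier", version = 1L,
    ion_mode = clf$ion_mode, abs_tol = clf$abs_tol, ppm_tol = clf$ppm_tol,
    library_size = clf$library_size, seed = clf$seed, params = clf$params,
    families = lapply(clf$families, function(f)
      list(term = f$term, term_name = f$term_name,
           member_ids = f$member_ids, compound_ids = f$compound_ids,
           consensus = f$consensus)),
    feature_dictionary = clf$features,
    background_scores = clf$background_scores)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a classifier serialised by [write_classifier]
#' @param file Path to the JSON model.
#' @return A `family_classifier`.
#' @export
read_classifier <- function(file) {
  p <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  if (!identical(p$format, "specfam_classifier"))
    stop("not a specfam classifier file")
  fams <- lapply(seq_len(nrow(p$families)), function(i) {
    structure(list(term = p$families$term[i],
                   term_name = p$families$term_name[i],
                   member_ids = p$families$member_ids[[i]],
                   compound_ids = p$families$compound_ids[[i]],
                   consensus = as.data.frame(p$families$consensus[[i]])),
              class = "metabolite_family")
  })
  structure(list(families = fams,
                 background_scores = p$background_scores,
                 features = as.data.frame(p$feature_dictionary),
                 abs_tol = p$abs_tol, ppm_tol = p$ppm_tol,
                 ion_mode = p$ion_mode, library_size = p$library_size,
                 seed = p$seed, params = p$params),
            class = "family_classifier")
}
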