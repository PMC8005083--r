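#' Map reconstructed spectra onto MS1 features
#'
#' A spectrum is assigned to the feature whose m/z lies within
#' `mapping_mz_abs` and whose retention time differs by at most
#' `max_rt_difference` minutes; among multiple matches the closest m/z
#' wins.
#'
#' @param spectra List of [spectrum] objects.
#' @param ft A [feature_table] whose `features` metadata has `mz` and `rt`.
#' @param config A [pipeline_config].
#' @return Named character vector spectrum id -> feature id (`NA` when
#'   unmatched).
#' @export
map_spectra_to_features <- function(spectra, ft, config = pipeline_config()) {
  feat <- ft$features
  if (is.null(feat)) stop("feature table carries no feature metadata")
  rt_tol <- config$max_rt_difference * 60
  out <- vapply(spectra, function(s) {
    dmz <- abs(feat$mz - s$precursor_mz)
    drt <- abs(feat$rt - s$rt)
    ok <- which(dmz <= config$mapping_mz_abs & drt <= rt_tol)
    if (length(ok) == 0L) NA_character_
    else rownames(feat)[ok[which.min(dmz[ok])]]
  }, character(1))
  stats::setNames(out, vapply(spectra, `[[`, character(1), "spectrum_id"))
}

#' Run the full pipeline on in-memory or on-disk inputs
#'
#' Orchestrates the stages in study order: per ion mode, DIA spectra are
#' reconstructed (or taken as given), RT-filtered, merged and cleaned; a
#' family classifier is trained from the annotated library (or supplied
#' pre-trained) and applied; modes are joined by concatenating
#' mode-prefixed rows; presence and log-transformed tables feed the
#' diversity, composition and (when a phylogeny is supplied) chemotaxonomy
#' reports. All outputs plus a manifest with per-stage record counts are
#' written under `out_dir`.
#'
#' @param inputs Named list. Recognised elements: `runs` (named list of
#'   [dia_run]s, optional), `spectra` (list of [spectrum]s, alternative to
#'   `runs`), `library` ([spectrum] list or path to an MSP file),
#'   `classifier` (pre-trained [train_family_classifier] model, optional),
#'   `ontology` ([ontology] or path), `table` ([feature_table]), `classes`
#'   (named vector feature id -> class term, used instead of spectrum
#'   mapping when given), `phylogeny` (`phylo` or Newick path).
#' @param config A [pipeline_config].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of the computed result objects; side effect:
#'   TSV/JSON reports and `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = tempfile("specfam_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  log_stage <- function(stage, n) {
    counts[[stage]] <<- n
    message(sprintf("[specfam] %-24s %d records", stage, n))
  }
  onto <- inputs$ontology
  if (is.character(onto)) onto <- read_ontology(onto)
  lib <- inputs$library
  if (is.character(lib)) lib <- parse_msp(file = lib)

  # --- reconstruction ------------------------------------------------
  spectra <- inputs$spectra
  if (!is.null(inputs$runs)) {
    spectra <- list()
    for (run in inputs$runs) {
      rec <- reconstruct_spectra(run, min_cor = config$min_cor,
                                 peakwidth = config$peakwidth,
                                 snthresh = config$snthresh)
      spectra <- c(spectra, rec)
    }
  }
  if (!is.null(spectra)) {
    log_stage("reconstructed", length(spectra))
    spectra <- filter_rt_window(spectra, config$rt_window[1],
                                config$rt_window[2])
    log_stage("rt_filtered", length(spectra))
    spectra <- merge_overlapping_spectra(spectra, config$merge_mzd,
                                         config$merge_ppm)
    log_stage("merged", length(spectra))
    run_base <- max(c(0, vapply(spectra, base_peak_intensity, numeric(1))))
    spectra <- Filter(Negate(is.null),
                      lapply(spectra, clean_spectrum, config = config,
                             run_base_intensity = run_base))
    spectra <- deisotope_precursors(spectra, config)
    log_stage("cleaned", length(spectra))
    serialize_msp(spectra, file.path(out_dir, "spectra.msp"))
  }

  # --- classification ------------------------------------------------
  clf <- inputs$classifier
  if (is.null(clf) && !is.null(lib)) {
    clf <- train_family_classifier(lib, onto = onto,
                                   abs_tol = config$grouping_mz_abs,
                                   ppm_tol = config$grouping_ppm,
                                   seed = config$random_seed)
    write_classifier(clf, file.path(out_dir, "classifier.json"))
    log_stage("families_trained", length(clf$families))
  }
  classes <- inputs$classes
  classification <- NULL
  if (!is.null(clf) && !is.null(spectra) && length(spectra)) {
    classification <- predict(clf, spectra)
    utils::write.table(classification,
                       file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("classified", sum(!is.na(classification$primary_term)))
    if (is.null(classes) && !is.null(inputs$table)) {
      feat_of <- map_spectra_to_features(spectra, inputs$table, config)
      ok <- !is.na(feat_of) & !is.na(classification$primary_term)
      classes <- stats::setNames(classification$primary_term[ok],
                                 feat_of[ok])
    }
  }

  # --- tables, diversity, composition -------------------------------
  results <- list(spectra = spectra, classifier = clf,
                  classification = classification)
  ft <- inputs$table
  if (!is.null(ft)) {
    pm <- build_presence_matrix(ft, config$presence_threshold)
    prepared <- prepare_table(ft)
    div <- diversity_table(pm)
    utils::write.table(div, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("diversity_samples", nrow(div))
    results$presence <- pm
    results$prepared <- prepared
    results$diversity <- div
    if (!is.null(pm$factors$herbarium)) {
      results$unique_compounds <- unique_items(pm, pm$factors$herbarium)
      if (!is.null(classes)) {
        cc <- class_condition_counts(pm, classes)
        fisher <- fisher_composition_test(cc)
        shift <- composition_shift(cc)
        shifts <- merge(fisher[, c("class", "p_value", "significant")],
                        shift, by = "class")
        utils::write.table(shifts, file.path(out_dir, "composition.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        log_stage("classes_tested", nrow(shifts))
        results$composition <- shifts
        if (!is.null(onto)) {
          counts_tree <- aggregate_ontology_counts(
            unname(classes[rownames(pm$matrix)]), onto)
          jsonlite::write_json(sunburst_tree(counts_tree),
                               file.path(out_dir, "sunburst.json"),
                               auto_unbox = TRUE, digits = NA)
          results$ontology_counts <- counts_tree
        }
      }
    }
    # --- chemotaxonomy ----------------------------------------------
    if (!is.null(inputs$phylogeny) && !is.null(prepared$factors$species)) {
      phylo <- inputs$phylogeny
      if (is.character(phylo)) phylo <- parse_newick(file = phylo)
      prof <- species_profile(prepared)
      phylo <- prune_tree(phylo, intersect(phylo$tip.label, rownames(prof)))
      prof <- prof[phylo$tip.label, , drop = FALSE]
      chemo <- ward_dendrogram(bray_curtis(prof))
      cmp <- compare_trees(phylo, chemo, seed = config$random_seed)
      jsonlite::write_json(unclass(cmp),
                           file.path(out_dir, "tree_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      log_stage("species_compared", length(phylo$tip.label))
      results$chemotaxonomy <- list(dendrogram = chemo, phylogeny = phylo,
                                    comparison = cmp)
    }
  }

  manifest <- list(
    package = "specfam",
    version = as.character(utils::packageVersion("specfam")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$random_seed,
    config = unclass(config),
    record_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}
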