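#' Log-transform a feature table
#'
#' Positive abundances are replaced by their base-10 logarithm; zero (or
#' missing, already imputed to zero) cells stay zero. A table can only be
#' transformed once: a second call is rejected via the `transformed` flag.
#'
#' @param ft A [feature_table] with raw abundances.
#' @return The transformed [feature_table].
#' @export
prepare_table <- function(ft) {
  if (ft$transformed) stop("feature table is already log-transformed")
  m <- ft$abundances
  if (any(m < 0)) stop("abundances must be >= 0")
  pos <- m > 0
  m[pos] <- log10(m[pos])
  m[!pos] <- 0
  ft$abundances <- m
  ft$transformed <- TRUE
  ft
}

#' Binary presence matrix from abundances
#'
#' A compound is called present in a sample when its abundance exceeds
#' `threshold` times the largest abundance of that sample (strictly above;
#' default 0.1 percent). The per-sample referent makes the call invariant
#' to per-sample intensity rescaling.
#'
#' @param ft A [feature_table] with untransformed abundances.
#' @param threshold Relative presence threshold (default 0.001).
#' @return An object of class `presence_matrix`: binary matrix plus the
#'   inherited factors.
#' @export
build_presence_matrix <- function(ft, threshold = 0.001) {
  if (ft$transformed)
    stop("presence calls need untransformed abundances")
  m <- ft$abundances
  ref <- apply(m, 2L, max)
  zero <- ref == 0
  if (any(zero)) {
    warning("all-zero sample(s): ", paste(colnames(m)[zero], collapse = ", "))
    ref[zero] <- 1  # nothing exceeds the threshold anyway
  }
  pm <- sweep(m, 2L, threshold * ref, `>`) * 1L
  structure(list(matrix = pm, factors = ft$factors, features = ft$features,
                 threshold = threshold),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d compounds x %d samples, %.1f%% present\n",
              nrow(x$matrix), ncol(x$matrix), 100 * mean(x$matrix)))
  invisible(x)
}

#' Shannon/Pielou diversity profile of one composition
#'
#' Richness `S` is the number of positive entries; the Shannon index is
#' `H' = -sum(p_i * ln(p_i))` over the relative abundances `p_i = N_i / N`;
#' Pielou's evenness is `J = H' / ln(S)` (undefined, reported `NA`, when
#' `S <= 1`).
#'
#' @param x Non-negative vector of abundances or counts with at least one
#'   positive entry.
#' @return List with `S`, `H`, `J` and the relative abundances `p`.
#' @export
diversity_profile <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("abundances must be >= 0")
  if (all(x == 0)) stop("all-zero composition has no diversity profile")
  p <- x[x > 0] / sum(x)
  S <- length(p)
  H <- unname(vegan::diversity(x[x > 0], index = "shannon"))
  list(S = S, H = H, J = if (S > 1L) H / log(S) else NA_real_, p = p)
}

#' Per-sample diversity profiles of a matrix
#'
#' @param m Non-negative matrix, items x samples (e.g. a presence matrix,
#'   abundance matrix, or class-count matrix), or a [feature_table] /
#'   `presence_matrix`.
#' @return Data frame with one row per sample: `sample_id`, `S`, `H`, `J`.
#' @export
diversity_table <- function(m) {
  if (inherits(m, "feature_table")) m <- m$abundances
  if (inherits(m, "presence_matrix")) m <- m$matrix
  rows <- lapply(colnames(m), function(s) {
    d <- diversity_profile(m[, s])
    data.frame(sample_id = s, S = d$S, H = d$H, J = d$J,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Items unique to one factor level
#'
#' An item (compound or compound class) is unique to a level when it is
#' present in at least one sample of that level and absent from every
#' sample of all other levels.
#'
#' @param pm A `presence_matrix` (or binary matrix) with samples as columns.
#' @param groups Factor/character vector assigning each sample to a level;
#'   defaults to the herbarium factor of the presence matrix.
#' @return List with `counts` (named per-level unique-item counts) and
#'   `items` (per-item level assignment, `NA` when shared or absent).
#' @export
unique_items <- function(pm, groups = NULL) {
  m <- if (inherits(pm, "presence_matrix")) pm$matrix else as.matrix(pm)
  if (is.null(groups)) {
    if (inherits(pm, "presence_matrix") && !is.null(pm$factors))
      groups <- pm$factors$herbarium
    else stop("supply `groups`")
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) stop("one group per sample required")
  lv <- unique(groups)
  pres <- vapply(lv, function(l) rowSums(m[, groups == l, drop = FALSE]) > 0,
                 logical(nrow(m)))
  pres <- matrix(pres, nrow = nrow(m), dimnames = list(rownames(m), lv))
  n_levels <- rowSums(pres)
  assign <- rep(NA_character_, nrow(m))
  only <- n_levels == 1L
  assign[only] <- lv[apply(pres[only, , drop = FALSE], 1L, which.max)]
  counts <- vapply(lv, function(l) sum(assign == l, na.rm = TRUE), integer(1))
  list(counts = counts, items = stats::setNames(assign, rownames(m)))
}

#' Per-class Fisher exact composition tests
#'
#' For every compound class, a 2x2 contingency table (in-class vs all other
#' classes, by condition) is tested with the two-sided Fisher exact test.
#' Following the published workflow, p-values below `alpha` (default 0.005)
#' are flagged significant without multiplicity correction.
#'
#' @param class_counts Matrix or data frame of non-negative counts, classes
#'   as rows and exactly two condition columns (e.g. fresh, dry).
#' @param alpha Significance level (default 0.005, strict `<`).
#' @return Data frame `class`, the two count columns, `p_value`,
#'   `significant`.
#' @export
fisher_composition_test <- function(class_counts, alpha = 0.005) {
  m <- as.matrix(class_counts)
  if (ncol(m) != 2L) stop("exactly two condition columns required")
  if (any(m < 0)) stop("counts must be >= 0")
  tot <- colSums(m)
  if (any(tot == 0)) stop("empty condition: ", colnames(m)[tot == 0])
  p <- vapply(seq_len(nrow(m)), function(k) {
    tab <- rbind(m[k, ], tot - m[k, ])
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  out <- data.frame(class = rownames(m) %||% as.character(seq_len(nrow(m))),
                    m, p_value = p, significant = p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:3] <- colnames(m) %||% c("cond1", "cond2")
  out
}

#' Relative-frequency shift of compound classes between two conditions
#'
#' For class `k` with counts `dry_k` and `fresh_k`, the shift is
#' `f_k = dry_k / sum(dry) - fresh_k / sum(fresh)`: positive values mark
#' enrichment under the dry (herbarium) condition, negative values a
#' decline. The shifts sum to zero exactly.
#'
#' @param class_counts Matrix/data frame with classes as rows and two
#'   columns; the *first* column is the reference (fresh) condition and
#'   the *second* the contrast (dry).
#' @return Data frame `class`, `fresh`, `dry`, `f` sorted as input.
#' @export
composition_shift <- function(class_counts) {
  m <- as.matrix(class_counts)
  if (ncol(m) != 2L) stop("exactly two condition columns required")
  tot <- colSums(m)
  if (any(tot == 0)) stop("zero total count in a condition")
  f <- m[, 2L] / tot[2L] - m[, 1L] / tot[1L]
  data.frame(class = rownames(m) %||% as.character(seq_len(nrow(m))),
             fresh = m[, 1L], dry = m[, 2L], f = unname(f),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Class-by-condition count table from a presence matrix
#'
#' Aggregates presences into per-class, per-condition counts: either total
#' compound-sample occurrences (`mode = "occurrences"`) or distinct
#' compounds present in at least one sample of the condition
#' (`mode = "compounds"`).
#'
#' @param pm A `presence_matrix`.
#' @param classes Named character vector mapping compound (row) id to class
#'   term; unmapped compounds are dropped.
#' @param condition Per-sample condition labels; defaults to the herbarium
#'   factor.
#' @param mode Counting mode (default `"occurrences"`).
#' @return Matrix classes x conditions of counts.
#' @export
class_condition_counts <- function(pm, classes, condition = NULL,
                                   mode = c("occurrences", "compounds")) {
  mode <- match.arg(mode)
  m <- pm$matrix
  if (is.null(condition)) condition <- pm$factors$herbarium
  condition <- as.character(condition)
  cls <- classes[rownames(m)]
  keep <- !is.na(cls)
  m <- m[keep, , drop = FALSE]
  cls <- cls[keep]
  lv <- sort(unique(condition))
  if (setequal(lv, c("fresh", "dry"))) lv <- c("fresh", "dry")
  all_cls <- sort(unique(cls))
  out <- vapply(lv, function(cond) {
    sub <- m[, condition == cond, drop = FALSE]
    val <- if (mode == "occurrences") rowSums(sub) else (rowSums(sub) > 0) * 1L
    as.numeric(tapply(val, factor(cls, levels = all_cls), sum, default = 0))
  }, numeric(length(all_cls)))
  matrix(out, nrow = length(all_cls), dimnames = list(all_cls, lv))
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Fits a one-way ANOVA of the measure on the grouping factor, runs Tukey
#' honest-significant-difference pairwise comparisons at `alpha`, and
#' summarises them as a compact letter display: groups sharing a letter are
#' not significantly different.
#'
#' @param values Numeric response, one per sample.
#' @param groups Grouping factor (>= 2 levels, >= 2 samples per level).
#' @param alpha Comparison level (default 0.05).
#' @return Data frame `group`, `mean`, `letter`, sorted by group name. When
#'   within-group variance is zero everywhere the display is degenerate and
#'   a warning is raised.
#' @export
anova_tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("need >= 2 samples per group")
  d <- data.frame(y = as.numeric(values), g = groups)
  if (all(tapply(d$y, d$g, stats::var) == 0)) {
    warning("zero within-group variance everywhere; letter display degenerate")
    lv <- sort(levels(groups))
    return(data.frame(group = lv,
                      mean = as.numeric(tapply(d$y, d$g, mean)[lv]),
                      letter = letters[as.integer(factor(tapply(d$y, d$g, mean)[lv]))],
                      stringsAsFactors = FALSE))
  }
  fit <- stats::aov(y ~ g, data = d)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  cld <- multcomp::cld(glht, level = alpha)
  lv <- sort(levels(groups))
  data.frame(group = lv,
             mean = as.numeric(tapply(d$y, d$g, mean)[lv]),
             letter = unname(cld$mcletters$Letters[lv]),
             stringsAsFactors = FALSE)
}

#' Roll compound classifications up a chemical ontology
#'
#' Counts, for every ontology node, the compounds whose primary term equals
#' the node or descends from it (sunburst-style aggregation). Terms not
#' resolvable in the ontology are counted under a reserved `unclassified`
#' node with a warning. The root-level total (including `unclassified`)
#' equals the number of classified compounds.
#'
#' @param primary_terms Character vector of primary class terms, one per
#'   compound (`NA` allowed, counted as unclassified).
#' @param onto An [ontology].
#' @return Data frame `term_id`, `name`, `parent_id`, `level`, `direct`
#'   (compounds classified exactly at the node) and `count` (node plus all
#'   descendants), plus the `unclassified` row when needed.
#' @export
aggregate_ontology_counts <- function(primary_terms, onto) {
  terms <- as.character(primary_terms)
  unknown <- !is.na(terms) & !(terms %in% onto$term_id)
  if (any(unknown))
    warning("unresolvable terms counted as unclassified: ",
            paste(unique(terms[unknown]), collapse = ", "))
  unclassified <- sum(is.na(terms) | unknown)
  terms <- terms[!is.na(terms) & !unknown]
  direct <- table(factor(terms, levels = onto$term_id))
  # children-sum roll-up, deepest nodes first
  depth <- term_depths(as.data.frame(onto))
  count <- as.numeric(direct)
  names(count) <- onto$term_id
  for (id in onto$term_id[order(-depth[onto$term_id])]) {
    p <- onto$parent_id[onto$term_id == id]
    if (!is.na(p)) count[p] <- count[p] + count[id]
  }
  out <- data.frame(term_id = onto$term_id, name = onto$name,
                    parent_id = onto$parent_id, level = onto$level,
                    direct = as.integer(direct), count = as.integer(count),
                    stringsAsFactors = FALSE)
  if (unclassified > 0L)
    out <- rbind(out, data.frame(term_id = "unclassified",
                                 name = "Unclassified",
                                 parent_id = NA_character_,
                                 level = "superclass",
                                 direct = unclassified,
                                 count = unclassified,
                                 stringsAsFactors = FALSE))
  out
}

#' Nest an ontology count table for sunburst rendering
#'
#' @param counts Result of [aggregate_ontology_counts].
#' @return Nested list (one element per root) serialisable with
#'   [jsonlite::toJSON].
#' @export
sunburst_tree <- function(counts) {
  build <- function(id) {
    row <- counts[counts$term_id == id, ]
    kids <- counts$term_id[!is.na(counts$parent_id) & counts$parent_id == id]
    node <- list(term_id = row$term_id, name = row$name,
                 level = row$level, count = row$count)
    if (length(kids)) node$children <- lapply(kids, build)
    node
  }
  lapply(counts$term_id[is.na(counts$parent_id)], build)
}
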