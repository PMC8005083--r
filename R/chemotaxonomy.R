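#' Parse a Newick tree
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file Optional path to a Newick file.
#' @return An [ape::read.tree] `phylo` object with unique leaf labels.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- if (is.null(text)) ape::read.tree(file = file)
        else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Prune a phylogeny to a taxon subset
#'
#' Keeps only the named leaves, retaining the topology among them (interior
#' degree-2 nodes are collapsed).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain.
#' @return The pruned `phylo`.
#' @export
prune_tree <- function(tree, keep) {
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  ape::keep.tip(tree, keep)
}

#' Average per-species profiles over samples
#'
#' Fig-style chemotaxonomic trees cluster species, not samples; each
#' species' profile is the mean over its samples of the (typically
#' log-transformed) feature or class-count table.
#'
#' @param x A [feature_table], `presence_matrix`, or plain matrix with
#'   variables as rows and samples as columns.
#' @param species Per-sample species codes; defaults to the species factor
#'   carried by `x`.
#' @return Matrix species x variables.
#' @export
species_profile <- function(x, species = NULL) {
  if (inherits(x, "feature_table")) {
    species <- species %||% x$factors$species
    x <- x$abundances
  } else if (inherits(x, "presence_matrix")) {
    species <- species %||% x$factors$species
    x <- x$matrix
  }
  if (is.null(species)) stop("supply `species`")
  species <- as.character(species)
  if (length(species) != ncol(x)) stop("one species code per sample required")
  lv <- sort(unique(species))
  out <- t(vapply(lv, function(s)
    rowMeans(x[, species == s, drop = FALSE]), numeric(nrow(x))))
  rownames(out) <- lv
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum(|a_i - b_i|) / sum(a_i + b_i)`, bounded in `[0, 1]`.
#'
#' @param m Non-negative matrix, objects as rows; all-zero rows are an
#'   error.
#' @return Symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis needs non-negative entries")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero row(s): ",
         paste(rownames(m)[zero] %||% which(zero), collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Ward.D dendrogram from a dissimilarity matrix
#'
#' Agglomerates with the classic Ward.D convention (Lance-Williams update
#' applied to the dissimilarities as given, unsquared).
#'
#' @param d Symmetric matrix (zero diagonal) or `dist`.
#' @return An `hclust` tree.
#' @export
ward_dendrogram <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "ward.D")
}

#' Swap the two topmost subtrees of a dendrogram
#'
#' Cosmetic reordering (as used to place related groups side by side in
#' published tanglegrams); topology and heights are unchanged.
#'
#' @param hc An `hclust` tree.
#' @return The reordered `hclust`.
#' @export
swap_top <- function(hc) {
  root <- nrow(hc$merge)
  kids <- hc$merge[root, ]
  leaf_sets <- hclust_members(hc)
  left <- if (kids[1] < 0) -kids[1] else leaf_sets[[kids[1]]]
  right <- if (kids[2] < 0) -kids[2] else leaf_sets[[kids[2]]]
  pos <- match(hc$order, c(left, right))
  hc$order <- hc$order[order(ifelse(pos <= length(left), 2L, 1L),
                             seq_along(hc$order))]
  hc$merge[root, ] <- rev(kids)
  hc
}

#' Cophenetic distance matrix of a tree
#'
#' For a dendrogram the cophenetic distance of two leaves is the merge
#' height of their lowest common ancestor; for a phylogeny it is the
#' patristic path length.
#'
#' @param t An `hclust` dendrogram or `phylo` tree.
#' @return Symmetric matrix with zero diagonal, labelled by leaves.
#' @export
cophenetic_matrix <- function(t) {
  if (inherits(t, "phylo")) {
    m <- ape::cophenetic.phylo(t)
  } else {
    m <- as.matrix(stats::cophenetic(t))
  }
  m[order(rownames(m)), order(colnames(m))]
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle distance vectors, with
#' significance from joint row/column permutations:
#' `p = (1 + #permuted r >= observed) / (1 + permutations)`.
#'
#' @param d1,d2 Symmetric distance matrices over the same labels (matched
#'   by name when labelled).
#' @param permutations Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List with `r` and `p`.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("distance matrices have different labels")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  v1 <- d1[upper.tri(d1)]; v2 <- d2[upper.tri(d2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant distance vector: Mantel r undefined")
  res <- with_seed(seed,
    vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                  method = "pearson", permutations = permutations))
  list(r = unname(res$statistic), p = res$signif)
}

#' Normalised Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartitions, divided (when
#' `normalized`) by the maximum possible — the total number of internal
#' splits of both trees — so 0 means identical unrooted topologies and 1
#' no shared split.
#'
#' @param t1,t2 Trees (`phylo` or `hclust`) over the same >= 4 leaves.
#' @param normalized Return the normalised metric (default `TRUE`).
#' @return The (normalised) Robinson-Foulds distance.
#' @export
robinson_foulds <- function(t1, t2, normalized = TRUE) {
  t1 <- as_phylo_tree(t1); t2 <- as_phylo_tree(t2)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf sets differ; only in tree 1: ",
         paste(setdiff(t1$tip.label, t2$tip.label), collapse = ", "),
         "; only in tree 2: ",
         paste(setdiff(t2$tip.label, t1$tip.label), collapse = ", "))
  if (length(t1$tip.label) < 4L) stop("need >= 4 leaves")
  phangorn::RF.dist(t1, t2, normalize = normalized, check.labels = TRUE)
}

as_phylo_tree <- function(t) {
  if (inherits(t, "phylo")) return(t)
  if (inherits(t, "hclust")) return(ape::as.phylo(t))
  stop("expected a phylo or hclust tree")
}

#' Compare a chemotaxonomic dendrogram with a phylogeny
#'
#' Computes the comparison panel reported alongside tanglegrams: Mantel
#' statistic `r` (with permutation p-value) between the two cophenetic
#' distance matrices, the cophenetic correlation `c` (plain Pearson
#' correlation of the cophenetic upper triangles), the normalised
#' Robinson-Foulds distance `rf`, and the symmetric Procrustes `m2` from
#' aligning two-axis classical-scaling embeddings of the cophenetic
#' matrices.
#'
#' @param t1,t2 Trees (`phylo` or `hclust`) over the same leaves.
#' @param permutations Mantel permutations (default 999).
#' @param seed Integer seed.
#' @return An object of class `tree_comparison` with fields `mantel_r`,
#'   `mantel_p`, `cophenetic_c`, `rf`, `procrustes_m2`.
#' @export
compare_trees <- function(t1, t2, permutations = 999, seed = 1L) {
  c1 <- cophenetic_matrix(t1)
  c2 <- cophenetic_matrix(t2)
  if (!setequal(rownames(c1), rownames(c2)))
    stop("trees have different leaf sets")
  c2 <- c2[rownames(c1), rownames(c1)]
  mt <- mantel_test(c1, c2, permutations, seed)
  coph_c <- stats::cor(c1[upper.tri(c1)], c2[upper.tri(c2)])
  rf <- robinson_foulds(t1, t2, normalized = TRUE)
  e1 <- stats::cmdscale(stats::as.dist(c1), k = 2)
  e2 <- stats::cmdscale(stats::as.dist(c2), k = 2)
  m2 <- if (ncol(e1) == 2L && ncol(e2) == 2L)
    vegan::procrustes(e1, e2[rownames(e1), , drop = FALSE],
                      symmetric = TRUE)$ss
  else NA_real_
  structure(list(mantel_r = mt$r, mantel_p = mt$p,
                 cophenetic_c = unname(coph_c), rf = unname(rf),
                 procrustes_m2 = unname(m2)),
            class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf(
    "Tree comparison: Mantel r = %.3f (p = %.3g), cophenetic c = %.3f, rf = %.3g, Procrustes m2 = %.3g\n",
    x$mantel_r, x$mantel_p, x$cophenetic_c, x$rf, x$procrustes_m2))
  invisible(x)
}
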