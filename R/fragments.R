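#' Decompose a spectrum into fragment and neutral-loss features
#'
#' Every peak yields a fragment feature at its m/z and, when the peak lies
#' below the precursor, a precursor-to-fragment neutral loss
#' (`precursor_mz - mz`). Fragment-to-fragment losses are emitted only when
#' `include_fragment_pairs` is set (off by default). Peaks above the
#' precursor m/z contribute their fragment feature only.
#'
#' @param s A [spectrum] with `precursor_mz` set.
#' @param include_fragment_pairs Also emit pairwise fragment-to-fragment
#'   losses (default `FALSE`).
#' @return Data frame with columns `kind` (`"fragment"`/`"neutral_loss"`),
#'   `value` (Da) and `intensity` (the contributing fragment's intensity;
#'   pairwise losses carry the weaker fragment's intensity).
#' @export
decompose_neutral_losses <- function(s, include_fragment_pairs = FALSE) {
  mz <- s$peaks[, "mz"]
  int <- s$peaks[, "intensity"]
  loss <- s$precursor_mz - mz
  ok <- loss > 0
  out <- data.frame(
    kind = c(rep("fragment", length(mz)), rep("neutral_loss", sum(ok))),
    value = c(mz, loss[ok]),
    intensity = c(int, int[ok]),
    stringsAsFactors = FALSE)
  if (include_fragment_pairs && length(mz) > 1L) {
    pairs <- utils::combn(seq_along(mz), 2L)
    dmz <- abs(mz[pairs[1L, ]] - mz[pairs[2L, ]])
    pint <- pmin(int[pairs[1L, ]], int[pairs[2L, ]])
    keep <- dmz > 0
    out <- rbind(out, data.frame(kind = "neutral_loss", value = dmz[keep],
                                 intensity = pint[keep],
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Build a compounds x features fragment matrix
#'
#' Fragment and neutral-loss features of all spectra are grouped into m/z
#' bins by single linkage within `max(abs_tol, ppm_tol * value / 1e6)`
#' (fragments and losses binned separately). Entries are peak intensities
#' normalised to each spectrum's base peak, so every row's maximum is 1;
#' neutral-loss features inherit their fragment's intensity. Bin centers
#' are intensity-weighted means of the member values.
#'
#' @param spectra Non-empty list of [spectrum] objects, one ion mode.
#' @param abs_tol Absolute grouping tolerance in Da (default 0.01).
#' @param ppm_tol Relative grouping tolerance in ppm (default 20).
#' @param include_fragment_pairs Passed to [decompose_neutral_losses].
#' @return An object of class `fragment_matrix`: list with `matrix` (rows =
#'   spectrum ids, columns = feature bins), `features` (data frame `kind`,
#'   `mz`), and the tolerances.
#' @export
build_fragment_matrix <- function(spectra, abs_tol = 0.01, ppm_tol = 20,
                                  include_fragment_pairs = FALSE) {
  if (length(spectra) == 0L) stop("empty spectrum list")
  modes <- unique(vapply(spectra, `[[`, character(1), "ion_mode"))
  if (length(modes) > 1L)
    stop("all spectra must share one ion mode; got: ",
         paste(modes, collapse = ", "))
  ids <- vapply(spectra, `[[`, character(1), "spectrum_id")
  if (anyDuplicated(ids)) stop("duplicate spectrum ids")
  feats <- lapply(spectra, function(s) {
    d <- decompose_neutral_losses(s, include_fragment_pairs)
    bp <- base_peak_intensity(s)
    d$rel <- if (bp > 0) d$intensity / bp else 0
    d
  })
  all_kind <- unlist(lapply(feats, `[[`, "kind"))
  all_val <- unlist(lapply(feats, `[[`, "value"))
  all_rel <- unlist(lapply(feats, `[[`, "rel"))
  all_row <- rep(seq_along(spectra), vapply(feats, nrow, integer(1)))
  col <- integer(length(all_val))
  centers <- numeric(0)
  kinds <- character(0)
  for (k in c("fragment", "neutral_loss")) {
    sel <- which(all_kind == k)
    if (length(sel) == 0L) next
    g <- group_values_1d(all_val[sel], abs_tol, ppm_tol)
    ng <- max(g)
    ctr <- vapply(split(sel, g), function(ii) {
      w <- all_rel[ii]
      if (sum(w) == 0) mean(all_val[ii]) else sum(all_val[ii] * w) / sum(w)
    }, numeric(1))
    col[sel] <- g + length(centers)
    centers <- c(centers, ctr)
    kinds <- c(kinds, rep(k, ng))
  }
  m <- matrix(0, nrow = length(spectra), ncol = length(centers),
              dimnames = list(ids, sprintf(
                "%s_%.4f", ifelse(kinds == "fragment", "frag", "loss"),
                centers)))
  for (j in seq_along(all_val))
    m[all_row[j], col[j]] <- max(m[all_row[j], col[j]], all_rel[j])
  ord <- order(kinds, centers)
  structure(list(matrix = m[, ord, drop = FALSE],
                 features = data.frame(kind = kinds[ord], mz = centers[ord],
                                       stringsAsFactors = FALSE),
                 abs_tol = abs_tol, ppm_tol = ppm_tol,
                 ion_mode = modes),
            class = "fragment_matrix")
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat(sprintf(
    "<fragment_matrix> %d spectra x %d feature bins (%d fragment, %d loss), %.1f%% filled\n",
    nrow(x$matrix), ncol(x$matrix), sum(x$features$kind == "fragment"),
    sum(x$features$kind == "neutral_loss"),
    100 * mean(x$matrix > 0)))
  invisible(x)
}

#' Hierarchically cluster spectra on shared substructure features
#'
#' Average-linkage agglomeration on the Jaccard distance between binarised
#' feature-presence profiles: spectra sharing many fragments/losses merge
#' low, spectra with disjoint features merge at height 1.
#'
#' @param fm A [build_fragment_matrix] result with >= 2 rows.
#' @return An `hclust` tree over the spectrum ids.
#' @export
cluster_spectra <- function(fm) {
  m <- fm$matrix > 0
  if (nrow(m) < 2L) stop("need >= 2 spectra to cluster")
  zero <- rownames(m)[rowSums(m) == 0L]
  if (length(zero))
    stop("spectra with no features cannot be clustered: ",
         paste(zero, collapse = ", "))
  d <- stats::dist(m, method = "binary")  # Jaccard distance on presence
  stats::hclust(d, method = "average")
}

# members (leaf indices) of every internal node of an hclust tree
hclust_members <- function(hc) {
  n <- nrow(hc$merge) + 1L
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    members[[i]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else members[[k]]))
  }
  members
}

# parent merge index of each internal node (NA for the root)
hclust_parents <- function(hc) {
  n_merge <- nrow(hc$merge)
  parent <- rep(NA_integer_, n_merge)
  for (i in seq_len(n_merge)) {
    for (k in hc$merge[i, ]) if (k > 0) parent[k] <- i
  }
  parent
}
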