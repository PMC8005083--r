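# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Shannon/Pielou by direct summation
oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# 2x2 tables with the observed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k)
    stats::dhyper(k, r1, r2, c1), numeric(1))
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Ward.D agglomeration by the Lance-Williams update on the raw
# dissimilarities; deterministic merge of the smallest pair (ties to the
# smallest indices). Returns the merge heights and member sets.
oracle_ward <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  merges <- list()
  repeat {
    k <- length(active)
    if (k == 1L) break
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (d[i, j] < best[1] - 1e-12) best <- c(d[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    merges[[length(merges) + 1L]] <- sort(c(active[[i]], active[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    newd <- numeric(k)
    for (h in seq_len(k)) {
      if (h == i || h == j) next
      nh <- sizes[h]
      newd[h] <- ((ni + nh) * d[i, h] + (nj + nh) * d[j, h] -
                    nh * d[i, j]) / (ni + nj + nh)
    }
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], list(sort(c(active[[i]], active[[j]]))))
    sizes <- c(sizes[keep], ni + nj)
  }
  list(heights = heights, merges = merges)
}

# cophenetic distances of an hclust tree by explicit LCA walk
oracle_cophenetic <- function(hc) {
  n <- length(hc$labels)
  leaf_sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    leaf_sets[[i]] <- unlist(lapply(hc$merge[i, ], function(k)
      if (k < 0) -k else leaf_sets[[k]]))
  }
  m <- matrix(0, n, n, dimnames = list(hc$labels, hc$labels))
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    # lowest merge containing both leaves
    i <- which(vapply(leaf_sets, function(s) a %in% s && b %in% s,
                      logical(1)))[1L]
    m[a, b] <- m[b, a] <- hc$height[i]
  }
  m
}

# non-trivial bipartitions of an unrooted phylo tree as canonical strings
oracle_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  clade <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], clade))
  }
  internal <- tree$edge[tree$edge[, 2] > n, 2]
  splits <- character(0)
  for (node in internal) {
    side <- sort(clade(node))
    if (length(side) < 2L || length(side) > n - 2L) next
    other <- setdiff(tips, side)
    canon <- if (tips[1] %in% side) side else other
    splits <- c(splits, paste(canon, collapse = "|"))
  }
  unique(splits)
}

oracle_rf <- function(t1, t2, normalized = TRUE) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (normalized) rf / (length(b1) + length(b2)) else rf
}

# adjusted Rand index between two partitions
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# quartet topology of four leaves from a patristic distance matrix: returns
# the pair grouped against the other two, by the four-point condition
oracle_quartet <- function(d, leaves) {
  stopifnot(length(leaves) == 4L)
  l <- leaves
  sums <- c(d[l[1], l[2]] + d[l[3], l[4]],
            d[l[1], l[3]] + d[l[2], l[4]],
            d[l[1], l[4]] + d[l[2], l[3]])
  pairings <- list(c(1, 2), c(1, 3), c(1, 4))
  paste(sort(l[pairings[[which.min(sums)]]]), collapse = "|")
}

# Independent re-implementation of the family-selection rules, enumerating
# every subtree of the clustering directly from the merge table.
oracle_select <- function(tree, fm, annotations, compounds,
                          min_spectra = 10, min_compounds = 5,
                          shared_fraction = 0.75) {
  ids <- tree$labels
  pres <- fm$matrix[ids, , drop = FALSE] > 0
  n_merge <- nrow(tree$merge)
  members <- vector("list", n_merge)
  for (i in seq_len(n_merge)) {
    members[[i]] <- unlist(lapply(tree$merge[i, ], function(k)
      if (k < 0) -k else members[[k]]))
  }
  parent <- rep(NA_integer_, n_merge)
  for (i in seq_len(n_merge)) for (k in tree$merge[i, ])
    if (k > 0) parent[k] <- i
  c2 <- vapply(seq_len(n_merge), function(i)
    max(colMeans(pres[members[[i]], , drop = FALSE])) >= shared_fraction - 1e-12,
    logical(1))
  acc <- list()
  for (i in seq_len(n_merge)) {
    mem <- ids[members[[i]]]
    if (length(mem) < min_spectra) next
    if (!c2[i]) next
    if (length(unique(compounds[mem])) < min_compounds) next
    if (!is.na(parent[i]) && c2[parent[i]]) next
    tab <- sort(table(unlist(lapply(annotations[mem], unique))),
                decreasing = TRUE)
    tab <- tab[tab > length(mem) / 2]
    if (length(tab) == 0) next
    acc[[length(acc) + 1]] <- list(term = names(tab)[1], members = sort(mem))
  }
  terms <- vapply(acc, `[[`, character(1), "term")
  keep <- unlist(lapply(split(seq_along(acc), terms), function(idx) {
    idx[which.max(vapply(acc[idx], function(a) length(a$members),
                         numeric(1)))]
  }))
  acc[sort(keep)]
}
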