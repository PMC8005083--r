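test_that("species profiles are group means of sample profiles", {
  m <- cbind(s1 = c(1, 2), s2 = c(3, 4), s3 = c(10, 20))
  rownames(m) <- c("F1", "F2")
  prof <- species_profile(m, species = c("SPA", "SPA", "SPB"))
  expect_equal(prof["SPA", ], c(F1 = 2, F2 = 3))
  expect_equal(prof["SPB", ], c(F1 = 10, F2 = 20))

  # brute-force group mean oracle on a simulated study
  study <- simulate_condition_study(n_species = 4,
                                    samples_per_species_per_condition = 3,
                                    n_classes = 3, compounds_per_class = 5,
                                    seed = 2)
  prof2 <- species_profile(study$table)
  sp <- study$table$factors$species
  for (s in unique(sp)) {
    want <- rowMeans(study$table$abundances[, sp == s, drop = FALSE])
    expect_equal(prof2[s, ], want, tolerance = 1e-12)
  }
})

test_that("Bray-Curtis dissimilarity matches its closed form and bounds", {
  m <- rbind(a = c(1, 2), b = c(2, 1), c = c(1, 2), d = c(0, 5))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 2 / 6)
  expect_equal(d["a", "c"], 0)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
  disj <- bray_curtis(rbind(x = c(1, 0), y = c(0, 3)))
  expect_equal(disj["x", "y"], 1)
  set.seed(3)
  r <- matrix(rgamma(40, 1), 8)
  expect_true(all(bray_curtis(r) >= 0 & bray_curtis(r) <= 1))
  expect_error(bray_curtis(rbind(a = c(1, 1), zz = c(0, 0))), "zz")
})

test_that("Ward.D agglomeration matches a Lance-Williams oracle step for step", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- ward_dendrogram(d2)
  expect_equal(hc2$height, 3)

  d3 <- as.matrix(dist(c(0, 0.5, 10)))
  dimnames(d3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  hc3 <- ward_dendrogram(d3)
  expect_equal(sort(cutree(hc3, 2)[c("A", "B")]), c(A = 1L, B = 1L))

  set.seed(9)
  for (i in 1:5) {
    pts <- matrix(rnorm(16), 8)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(letters[1:8], letters[1:8])
    hc <- ward_dendrogram(d)
    oc <- oracle_ward(d)
    expect_equal(hc$height, oc$heights, tolerance = 1e-9)
    got_sets <- specfam:::hclust_members(hc)
    for (k in seq_along(oc$merges))
      expect_equal(sort(got_sets[[k]]), oc$merges[[k]])
  }
  expect_error(ward_dendrogram(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("cophenetic matrices equal a brute-force LCA walk", {
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  cm <- cophenetic_matrix(ward_dendrogram(d2))
  expect_equal(cm["a", "b"], 4)

  set.seed(12)
  for (i in 1:5) {
    d <- as.matrix(dist(matrix(rnorm(14), 7)))
    dimnames(d) <- list(letters[1:7], letters[1:7])
    hc <- ward_dendrogram(d)
    want <- oracle_cophenetic(hc)
    got <- cophenetic_matrix(hc)
    expect_equal(got, want[rownames(got), colnames(got)], tolerance = 1e-9)
  }

  # ultrametric fixed point: clustering a cophenetic matrix reproduces it
  d <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(d) <- list(letters[1:5], letters[1:5])
  cm1 <- cophenetic_matrix(stats::hclust(as.dist(d), "average"))
  cm2 <- cophenetic_matrix(stats::hclust(as.dist(cm1), "average"))
  expect_equal(cm2, cm1, tolerance = 1e-9)
})

test_that("Mantel statistics behave under identity, affine maps, and permutation", {
  set.seed(5)
  d1 <- as.matrix(dist(matrix(rnorm(20), 10)))
  dimnames(d1) <- list(LETTERS[1:10], LETTERS[1:10])
  expect_equal(mantel_test(d1, d1, seed = 1)$r, 1, tolerance = 1e-12)
  expect_equal(mantel_test(d1, 3 * d1 + 0.2, seed = 1)$r, 1,
               tolerance = 1e-12)
  expect_error(mantel_test(d1, 0 * d1, seed = 1), "constant")
  d2 <- as.matrix(dist(matrix(rnorm(20), 10)))
  dimnames(d2) <- dimnames(d1)
  m1 <- mantel_test(d1, d2, seed = 42)
  m2 <- mantel_test(d1, d2, seed = 42)
  expect_identical(m1, m2)                      # seeded determinism
  expect_true(m1$p > 0 && m1$p <= 1)
})

test_that("Robinson-Foulds distances equal the bipartition-set oracle", {
  t1 <- parse_newick("((A,B),(C,(D,E)));")
  expect_equal(robinson_foulds(t1, t1), 0)

  # caterpillars with fully incompatible internal splits
  c1 <- parse_newick("(((((A,B),C),D),E),F);")
  c2 <- parse_newick("(((((A,C),E),B),F),D);")
  expect_equal(oracle_rf(c1, c2), 1)            # confirmed maximal by oracle
  expect_equal(robinson_foulds(c1, c2), 1)

  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    ta <- ape::rtree(n, tip.label = LETTERS[1:n])
    tb <- ape::rtree(n, tip.label = LETTERS[1:n])
    expect_equal(robinson_foulds(ta, tb), oracle_rf(ta, tb),
                 tolerance = 1e-12)
    expect_equal(robinson_foulds(ta, tb, normalized = FALSE),
                 oracle_rf(ta, tb, normalized = FALSE))
  }
  t_bad <- parse_newick("((A,B),(C,(D,X)));")
  expect_error(robinson_foulds(t1, t_bad), "leaf sets differ")
})

test_that("tree comparison reports r = 1, c = 1, rf = 0, m2 = 0 for identical trees", {
  set.seed(14)
  phy <- ape::rtree(8)
  cmp <- compare_trees(phy, phy, seed = 2)
  expect_equal(cmp$mantel_r, 1, tolerance = 1e-9)
  expect_equal(cmp$cophenetic_c, 1, tolerance = 1e-9)
  expect_equal(cmp$rf, 0)
  expect_lt(cmp$procrustes_m2, 1e-9)

  other <- ape::rtree(8, tip.label = phy$tip.label)
  a <- compare_trees(phy, other, seed = 7)
  b <- compare_trees(other, phy, seed = 7)
  expect_equal(a$cophenetic_c, b$cophenetic_c, tolerance = 1e-12)
  expect_equal(a$rf, b$rf)
  expect_equal(a$mantel_r, b$mantel_r, tolerance = 1e-12)
  expect_identical(compare_trees(phy, other, seed = 7)$mantel_p, a$mantel_p)
})

test_that("swapping the topmost subtrees changes only leaf order", {
  d <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(d) <- list(letters[1:6], letters[1:6])
  hc <- ward_dendrogram(d)
  sw <- swap_top(hc)
  expect_equal(sort(sw$order), sort(hc$order))
  expect_equal(sw$height, hc$height)
  expect_equal(cophenetic_matrix(sw), cophenetic_matrix(hc))
})
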