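test_that("log transform maps positives to log10 and guards re-application", {
  ft <- feature_table(matrix(c(1000, 0, 10, 1), 2, 2,
                             dimnames = list(c("F1", "F2"), c("s1", "s2"))))
  out <- prepare_table(ft)
  expect_equal(out$abundances["F1", "s1"], 3)
  expect_equal(out$abundances["F2", "s1"], 0)
  expect_equal(out$abundances["F2", "s2"], 0)  # log10(1) = 0
  expect_error(prepare_table(out), "already")
})

test_that("presence calls use a strict per-sample relative threshold", {
  m <- matrix(c(1e6, 999, 1000, 1001), 4, 1,
              dimnames = list(sprintf("F%d", 1:4), "s1"))
  pm <- build_presence_matrix(feature_table(m), threshold = 0.001)
  expect_equal(unname(pm$matrix[, 1]), c(1, 0, 0, 1))  # 1000 is not > 1000

  # invariant to per-sample rescaling
  m2 <- cbind(s1 = c(5, 800, 1e5), s2 = 20 * c(5, 800, 1e5))
  rownames(m2) <- sprintf("F%d", 1:3)
  pm2 <- build_presence_matrix(feature_table(m2))
  expect_equal(unname(pm2$matrix[, 1]), unname(pm2$matrix[, 2]))

  m3 <- cbind(s1 = c(1, 2), s2 = c(0, 0))
  rownames(m3) <- c("F1", "F2")
  expect_warning(pm3 <- build_presence_matrix(feature_table(m3)), "s2")
  expect_equal(sum(pm3$matrix[, "s2"]), 0)
})

test_that("diversity profiles match direct-summation oracles", {
  u <- diversity_profile(rep(5, 4))
  expect_equal(u$H, log(4))
  expect_equal(u$J, 1.0)
  expect_equal(u$S, 4L)

  single <- diversity_profile(c(0, 7, 0))
  expect_equal(single$H, 0)
  expect_true(is.na(single$J))

  d <- diversity_profile(c(0.5, 0.25, 0.25))
  expect_equal(d$H, 1.5 * log(2))               # frozen closed form
  expect_equal(d$H, oracle_shannon(c(0.5, 0.25, 0.25)))

  set.seed(4)
  for (i in 1:20) {
    x <- rgamma(8, 1)
    p <- diversity_profile(x)
    expect_equal(p$H, oracle_shannon(x))
    expect_lte(p$H, log(p$S) + 1e-12)           # H' maximal at uniformity
    expect_true(p$J >= 0 && p$J <= 1)
  }
  expect_error(diversity_profile(c(0, 0)), "all-zero")
})

test_that("unique items are exclusive to a single factor level", {
  m <- rbind(F1 = c(1, 1, 0, 0), F2 = c(1, 0, 1, 0), F3 = c(0, 0, 1, 1),
             F4 = c(0, 0, 0, 0))
  colnames(m) <- sprintf("s%d", 1:4)
  u <- unique_items(m, groups = c("fresh", "fresh", "dry", "dry"))
  expect_equal(u$items[["F1"]], "fresh")
  expect_equal(u$items[["F3"]], "dry")
  expect_true(is.na(u$items[["F2"]]))  # shared
  expect_true(is.na(u$items[["F4"]]))  # absent
  expect_equal(unname(u$counts), c(1L, 1L))
  expect_lte(sum(u$counts), nrow(m))
})

test_that("Fisher composition tests equal the hypergeometric enumeration oracle", {
  same <- cbind(fresh = c(10, 20, 5), dry = c(10, 20, 5))
  res <- fisher_composition_test(same)
  expect_true(all(res$p_value == 1))

  tab <- cbind(fresh = c(10, 90), dry = c(0, 100))
  p_pkg <- fisher_composition_test(tab)$p_value[1]
  expect_equal(p_pkg, oracle_fisher_p(rbind(c(10, 0), c(90, 100))),
               tolerance = 1e-9)

  set.seed(11)
  for (i in 1:40) {
    counts <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(colSums(counts) == 0)) next
    got <- fisher_composition_test(counts)$p_value
    want <- c(oracle_fisher_p(rbind(counts[1, ], colSums(counts) - counts[1, ])),
              oracle_fisher_p(rbind(counts[2, ], colSums(counts) - counts[2, ])))
    expect_equal(got, want, tolerance = 1e-9)
  }

  swapped <- fisher_composition_test(tab[, c(2, 1)])
  expect_equal(swapped$p_value, fisher_composition_test(tab)$p_value,
               tolerance = 1e-12)
  expect_error(fisher_composition_test(cbind(c(0, 0), c(1, 2))), "empty")
})

test_that("composition shifts telescope to zero and recover planted direction", {
  eq <- composition_shift(cbind(fresh = c(30, 70), dry = c(3, 7)))
  expect_equal(eq$f, c(0, 0))

  one <- composition_shift(cbind(fresh = c(0, 100), dry = c(10, 90)))
  expect_equal(one$f[1], 0.10)

  set.seed(21)
  for (i in 1:200) {
    cc <- matrix(rpois(10, 20), 5)
    if (any(colSums(cc) == 0)) next
    expect_equal(sum(composition_shift(cc)$f), 0, tolerance = 1e-12)
    # antisymmetric under condition swap
    expect_equal(composition_shift(cc[, 2:1])$f, -composition_shift(cc)$f)
  }
  expect_error(composition_shift(cbind(c(0, 0), c(1, 2))), "zero total")
})

test_that("Tukey letter displays separate shifted groups and not identical ones", {
  set.seed(2)
  y_far <- c(rnorm(8, 0), rnorm(8, 10))   # 10 SDs apart
  g <- rep(c("a_grp", "b_grp"), each = 8)
  out <- anova_tukey_letters(y_far, g)
  expect_false(out$letter[1] == out$letter[2])

  y_same <- rnorm(16)
  out2 <- anova_tukey_letters(y_same, g)
  expect_equal(out2$letter[1], out2$letter[2])

  # invariant to group ordering
  perm <- sample(16)
  out3 <- anova_tukey_letters(y_far[perm], g[perm])
  expect_equal(out3$mean, out$mean, tolerance = 1e-12)
  expect_equal(out3$letter, out$letter)

  expect_warning(anova_tukey_letters(rep(c(1, 2), each = 3),
                                     rep(c("x", "y"), each = 3)),
                 "degenerate")
})

test_that("ontology roll-ups equal a brute-force ancestor walk and conserve totals", {
  onto <- ontology(data.frame(
    term_id = c("R", "A", "B", "A1", "A2", "B1"),
    name = c("root", "a", "b", "a1", "a2", "b1"),
    parent_id = c(NA, "R", "R", "A", "A", "B"),
    level = c("superclass", "class", "class", "subclass", "subclass",
              "subclass")))
  terms <- c("A1", "A1", "A1", "A2", "B1", "B", NA, "ZZZ")
  expect_warning(counts <- aggregate_ontology_counts(terms, onto), "ZZZ")

  # oracle: walk each compound's ancestor chain
  want <- setNames(numeric(nrow(onto)), onto$term_id)
  for (t in terms[!is.na(terms) & terms %in% onto$term_id]) {
    want[t] <- want[t] + 1
    for (anc in specfam:::term_ancestors(onto, t)) want[anc] <- want[anc] + 1
  }
  expect_equal(counts$count[match(onto$term_id, counts$term_id)],
               unname(want), ignore_attr = TRUE)
  # monotone roll-up and conservation including the unclassified node
  expect_gte(counts$count[counts$term_id == "A"],
             counts$count[counts$term_id == "A1"])
  root_total <- sum(counts$count[is.na(counts$parent_id)])
  expect_equal(root_total, length(terms))
  expect_equal(counts$count[counts$term_id == "unclassified"], 2)

  empty <- aggregate_ontology_counts(character(0), onto)
  expect_true(all(empty$count == 0))

  sb <- sunburst_tree(counts)
  expect_equal(sum(vapply(sb, `[[`, numeric(1), "count")), length(terms))
})
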