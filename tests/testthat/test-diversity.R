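test_that("alpha estimators match hand-computed values", {
  expect_equal(observed_otus(c(5, 0, 1, 2)), 3)
  expect_equal(observed_otus(rep(0, 4)), 0)

  expect_equal(chao1(c(1, 1, 2, 2, 5)), 5 + 2 * 1 / 6)
  expect_equal(chao1(c(1, 3)), 2)            # f2 = 0 is well defined
  expect_equal(chao1(c(3, 2, 2)), 3)          # f1 = 0 collapses to S_obs
  expect_equal(chao1(c(1, 1, 2, 2, 5), bias_corrected = FALSE), 5 + 4 / 4)

  expect_equal(shannon(rep(1, 4)), log(4))
  expect_equal(shannon(c(9)), 0)
  expect_equal(shannon(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_equal(shannon(rep(1, 4), base = 2), 2)

  expect_equal(inverse_simpson(rep(2, 7)), 7)
  expect_equal(inverse_simpson(c(42)), 1)
  expect_equal(inverse_simpson(c(3, 1)), 1.6)
  expect_error(shannon(c(0, 0)), "no reads")
})

test_that("alpha estimators respect their structural bounds", {
  withr::local_seed(71)
  for (i in 1:50) {
    x <- sample(0:6, 12, replace = TRUE)
    if (sum(x) == 0) next
    s <- observed_otus(x)
    f1 <- sum(x == 1)
    expect_gte(chao1(x), s)
    expect_equal(chao1(x) == s, f1 <= 1)  # equality iff f1 in {0, 1}
    if (s > 0) {
      expect_lte(shannon(x), log(s) + 1e-12)
      expect_lte(inverse_simpson(x), s + 1e-12)
    }
  }
})

test_that("alpha estimators agree with vegan on random samples", {
  withr::local_seed(101)
  m <- unclass(random_table(40, 6, max_count = 50, zero_prob = 0.3))
  a <- alpha_diversity(otu_table(m))
  expect_equal(a$shannon, unname(vegan::diversity(t(m), "shannon")))
  expect_equal(a$inverse_simpson, unname(vegan::diversity(t(m), "invsimpson")))
  est <- vegan::estimateR(t(m))
  expect_equal(a$chao1, unname(est["S.chao1", ]))
  expect_equal(a$observed_otus, unname(est["S.obs", ]))
})

test_that("Bray-Curtis matches its formula and boundary cases", {
  tab <- otu_table(matrix(c(6L, 2L, 2L, 2L), nrow = 2,
                          dimnames = list(c("A", "B"), c("S1", "S2"))))
  expect_equal(as.numeric(bray_curtis(tab)), 4 / 12)

  same <- otu_table(matrix(c(3L, 1L, 3L, 1L), nrow = 2))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disjoint <- otu_table(matrix(c(5L, 0L, 0L, 7L), nrow = 2))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)

  withr::local_seed(55)
  rt <- random_table(25, 5, zero_prob = 0.3)
  d <- as.matrix(bray_curtis(rt))
  m <- unclass(rt)
  for (j in 1:4) for (k in (j + 1):5) {
    expect_equal(d[j, k], bf_bray_curtis(m[, j], m[, k]))
    expect_equal(d[j, k], d[k, j])
  }
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))

  zz <- otu_table(matrix(c(0L, 0L, 0L, 0L), nrow = 2))
  expect_error(bray_curtis(zz), "all-zero")
})

test_that("PCoA reproduces Euclidean-realizable configurations", {
  # three collinear points: d(1,2) = d(2,3) = 1, d(1,3) = 2
  dm <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  fit <- pcoa(dm)
  emb <- as.matrix(stats::dist(fit$coordinates))
  expect_equal(unname(emb), unname(dm), tolerance = 1e-8)
  expect_equal(sum(fit$eigenvalues > 1e-8), 1)  # collinear: one positive axis

  withr::local_seed(77)
  pts <- matrix(stats::rnorm(5 * 3), 5, 3)
  d <- stats::dist(pts)
  fit2 <- pcoa(d)
  expect_true(all(fit2$eigenvalues > -1e-8))
  expect_equal(unname(as.matrix(stats::dist(fit2$coordinates))),
               unname(as.matrix(d)), tolerance = 1e-8)

  flat <- pcoa(matrix(0, 3, 3))
  expect_true(all(abs(flat$eigenvalues) < 1e-12))
})

test_that("PERMANOVA separates a degenerate two-block design", {
  n <- 20
  g <- rep(c("a", "b"), each = n / 2)
  dm <- 1 - outer(g, g, "==")
  res <- permanova(dm, g, n_permutations = 199, seed = 4)
  # within-group distances are all zero, so SS_within = 0 and R2 = 1
  expect_equal(res$r_squared, 1)
  # no permuted relabeling reproduces the split, so p is the smallest achievable
  expect_equal(res$p_value, 1 / 200)
  expect_error(permanova(dm, rep("a", n)), "2 groups")
  expect_error(permanova(dm, as.character(1:n)), "residual")
})

test_that("PERMANOVA matches vegan::adonis2 and is label-permutation invariant", {
  withr::local_seed(88)
  rt <- random_table(30, 9, zero_prob = 0.3)
  d <- bray_curtis(rt)
  g <- rep(c("x", "y", "z"), each = 3)
  res <- permanova(d, g, n_permutations = 99, seed = 1)
  ad <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res$r_squared, ad$R2[1])
  expect_equal(res$pseudo_f, ad$F[1])

  # applying one permutation consistently to matrix and labels leaves R2 unchanged
  p <- sample(9)
  dm <- as.matrix(d)
  res2 <- permanova(dm[p, p], g[p], n_permutations = 9, seed = 1)
  expect_equal(res2$r_squared, res$r_squared)

  # seeded determinism of the p-value
  res3 <- permanova(d, g, n_permutations = 99, seed = 1)
  expect_identical(res3$p_value, res$p_value)
})

test_that("taxon relative abundances partition each sample", {
  tax <- taxonomy_table(data.frame(
    otu_id = c("A", "B", "C"),
    phylum = c("Firmicutes", "Bacteroidetes", "Firmicutes")))
  tab <- otu_rows(list(A = c(75, 50, 10), B = c(25, 50, 0),
                       C = c(0, 0, 30)))
  ph <- phylum_relative_abundance(tab, tax)
  expect_equal(unname(colSums(ph$per_sample)), rep(100, 3))
  expect_equal(unname(ph$per_sample["Firmicutes", ]), c(75, 50, 100))

  solo <- phylum_relative_abundance(
    otu_rows(list(A = c(5, 5, 5))), tax)
  expect_equal(unname(solo$per_sample[1, ]), rep(100, 3))
  expect_equal(solo$summary$mean_pct, 100)
})

test_that("filtering never increases per-sample observed richness", {
  withr::local_seed(61)
  d <- triplicate_design(2)
  tab <- random_triplicate_table(2, 30, max_count = 15, zero_prob = 0.4)
  base <- alpha_diversity(tab)$observed_otus
  for (method in filter_methods()) {
    fr <- apply_filter(tab, method, design = d)
    expect_true(all(alpha_diversity(fr$table)$observed_otus <= base))
  }
})
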