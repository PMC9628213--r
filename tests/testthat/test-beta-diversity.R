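test_that("bray-curtis and jaccard match hand evaluations and edge cases", {
  ct <- count_table(matrix(c(2L, 2L, 1L, 3L), 2,
                           dimnames = list(c("f1", "f2"), c("x", "y"))))
  expect_equal(beta_distance(ct, "bray_curtis")["x", "y"], 1 - 2 * 3 / 8)
  # identical samples -> 0 for every metric
  same <- count_table(matrix(c(2L, 3L, 2L, 3L), 2,
                             dimnames = list(c("f1", "f2"), c("a", "b"))))
  tr <- star_tree(c("f1", "f2"))
  for (m in c("bray_curtis", "jaccard_binary")) {
    expect_equal(beta_distance(same, m)["a", "b"], 0)
  }
  expect_equal(beta_distance(same, "unweighted_unifrac", tree = tr)["a", "b"], 0)
  expect_equal(beta_distance(same, "weighted_unifrac", tree = tr)["a", "b"], 0)
  # disjoint presence sets -> jaccard 1
  disj <- count_table(matrix(c(5L, 0L, 0L, 7L), 2,
                             dimnames = list(c("f1", "f2"), c("a", "b"))))
  expect_equal(beta_distance(disj, "jaccard_binary")["a", "b"], 1)
})

test_that("distance matrices are symmetric, zero-diagonal, bounded in [0,1]", {
  ds <- simulate_dataset(small_config(seed = 13))
  for (m in c("bray_curtis", "jaccard_binary", "unweighted_unifrac",
              "weighted_unifrac")) {
    d <- beta_distance(ds$counts, m, tree = ds$tree)
    expect_equal(unname(diag(d)), rep(0, ncol(ds$counts)))
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
  }
})

test_that("unweighted unifrac on a star tree reduces to jaccard on presence", {
  # analytic identity with unit branches; random presence patterns
  set.seed(5)
  feats <- paste0("f", 1:12)
  tr <- star_tree(feats)
  for (i in 1:5) {
    m <- matrix(rbinom(12 * 4, 1, 0.5) * sample(1:5, 48, TRUE), nrow = 12,
                dimnames = list(feats, paste0("s", 1:4)))
    m[, colSums(m) == 0] <- 1L
    ct <- count_table(m)
    expect_equal(beta_distance(ct, "unweighted_unifrac", tree = tr),
                 beta_distance(ct, "jaccard_binary"))
  }
  # two samples on disjoint single tips: no shared branches -> distance 1
  ab <- count_table(matrix(c(3L, 0L, 0L, 2L), 2,
                           dimnames = list(c("A", "B"), c("s1", "s2"))))
  expect_equal(beta_distance(ab, "unweighted_unifrac",
                             tree = star_tree(c("A", "B")))["s1", "s2"], 1)
  expect_error(beta_distance(ab, "unweighted_unifrac"), "tree")
})

test_that("unifrac agrees with an independent implementation", {
  skip_if_not_installed("phyloseq")
  ds <- simulate_dataset(synthetic_config(
    n_per_group = 4L, n_features = 25L, depth_range = c(500L, 900L),
    n_differential = 0L, seed = 17))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(as.matrix(ds$counts), taxa_are_rows = TRUE),
    phyloseq::phy_tree(ds$tree))
  d_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  d_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  ids <- colnames(ds$counts)
  expect_equal(beta_distance(ds$counts, "unweighted_unifrac", tree = ds$tree)[ids, ids],
               d_u[ids, ids], tolerance = 1e-8)
  expect_equal(beta_distance(ds$counts, "weighted_unifrac", tree = ds$tree)[ids, ids],
               d_w[ids, ids], tolerance = 1e-8)
})

test_that("pcoa embeds euclidean distances exactly and handles edge cases", {
  set.seed(3)
  X <- matrix(rnorm(6 * 4), 6)
  rownames(X) <- paste0("s", 1:6)
  d <- as.matrix(dist(X))
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
  expect_lte(sum(ord$explained), 1 + 1e-12)
  # two samples at distance d -> coordinates +/- d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord2 <- pcoa(d2)
  expect_equal(unname(sort(ord2$coordinates[, 1])), c(-1.5, 1.5))
  # all-zero distances -> all eigenvalues 0
  z <- matrix(0, 3, 3)
  expect_true(all(abs(pcoa(z)$eigenvalues) < 1e-12))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})
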