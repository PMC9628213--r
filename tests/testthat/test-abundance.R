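test_that("mann-whitney exact p matches exhaustive enumeration oracle", {
  expect_equal(mann_whitney(1:3, 4:6)$p_value, 0.1)  # 2 of 20 arrangements
  set.seed(41)
  for (i in 1:8) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(1:8, n1, replace = TRUE)  # replacement forces ties
    y <- sample(1:8, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, mw_enum_oracle(x, y),
                 info = sprintf("case %d", i))
  }
  # identical groups under exact enumeration
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("tie-free exact mann-whitney agrees with wilcox.test", {
  set.seed(43)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(5)
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # large-sample normal approximation tracks wilcox.test closely
  x <- rnorm(30); y <- rnorm(25) + 0.5
  expect_equal(mann_whitney(x, y)$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("group_compare dispatches mann-whitney vs kruskal-wallis", {
  m <- rbind(f1 = c(1, 2, 3, 10, 11, 12), f2 = c(5, 5, 5, 5, 5, 6))
  colnames(m) <- paste0("s", 1:6)
  two <- group_compare(m, rep(c("a", "b"), each = 3), relative = FALSE)
  expect_equal(two$test[1], "mann_whitney")
  expect_equal(two$p_value[1], 0.1)
  three <- group_compare(m, c("a", "a", "b", "b", "c", "c"), relative = FALSE)
  expect_equal(three$test[1], "kruskal_wallis")
  # three identical groups -> KW statistic 0
  flat <- rbind(f1 = rep(c(1, 2, 3), 3))
  colnames(flat) <- paste0("s", 1:9)
  kw <- group_compare(flat, rep(c("a", "b", "c"), each = 3), relative = FALSE)
  expect_equal(kw$statistic[1], 0)
  expect_error(group_compare(m, rep("a", 6)), "2 non-empty groups")
})

test_that("taxonomic aggregation is additive and conserves totals", {
  ct <- toy_counts()  # ASV1+ASV2 share genus Streptococcus
  tax <- toy_taxonomy()
  g <- aggregate_taxa(ct, tax, "genus")
  strep <- grep("Streptococcus", rownames(g))
  expect_equal(unname(g[strep, "S1"]), 3 + 1)
  # conservation at every rank
  for (r in c("kingdom", "phylum", "family", "genus", "species"))
    expect_equal(colSums(aggregate_taxa(ct, tax, r)), colSums(ct))
  # one kingdom -> single row equal to column sums
  k <- aggregate_taxa(ct, tax, "kingdom")
  expect_equal(nrow(k), 1)
  expect_equal(unname(k[1, ]), unname(colSums(ct)))
  expect_error(aggregate_taxa(ct, tax, "strain"), "arg")
})

test_that("unclassified features aggregate under parent lineage + sentinel", {
  ct <- count_table(matrix(c(2L, 3L, 4L), 3,
                           dimnames = list(c("A", "B", "C"), "s1")))
  tax <- taxonomy_table(data.frame(
    feature_id = c("A", "B", "C"),
    kingdom = "k__Bacteria",
    phylum = c("p__X", "p__X", "p__Y"),
    class = NA, order = NA,
    family = c("f__Fam1", "f__Fam1", "f__Fam2"),
    genus = NA, species = NA))
  g <- aggregate_taxa(ct, tax, "genus")
  # A and B share family so their unclassified genera pool together;
  # C is unclassified under a different family and stays separate
  expect_equal(nrow(g), 2)
  expect_equal(sort(unname(g[, 1])), c(4, 5))
})

test_that("relative abundance normalises columns and is scale invariant", {
  p <- relative_abundance(matrix(c(1, 3), 2, dimnames = list(c("a", "b"), "s")))
  expect_equal(unname(p[, 1]), c(0.25, 0.75))
  m <- matrix(c(2, 5, 1, 20, 50, 10), 3,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  rel <- relative_abundance(m)
  expect_equal(unname(colSums(rel)), c(1, 1), tolerance = 1e-12)
  expect_equal(rel[, "s1"], rel[, "s2"])  # x10 scaling leaves proportions
  expect_error(relative_abundance(matrix(0, 1, 1,
                                         dimnames = list("f", "s"))), "zero")
})

test_that("venn partition conserves detected features and flags exclusives", {
  m <- matrix(c(5L, 0L, 1L, 0L,
                3L, 0L, 2L, 0L,
                0L, 4L, 1L, 0L), nrow = 4,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  ct <- count_table(m[rowSums(m) >= 0, colSums(m) > 0])
  grp <- c("A", "A", "B")
  v <- venn_partition(ct, grp)
  expect_equal(v$shared + sum(v$unique), v$total_detected)
  expect_true("f2" %in% v$features$unique$B)  # only in the B sample
  expect_error(venn_partition(ct, c("A", "A", "A")), "two groups")
})

test_that("spearman map reproduces hand-ranked rho and tier thresholds", {
  m <- rbind(taxon1 = c(1, 2, 3, 4, 5))
  colnames(m) <- paste0("s", 1:5)
  cov <- data.frame(v = c(2, 1, 4, 3, 5))
  sm <- spearman_map(m, cov)
  expect_equal(sm$rho, 0.8)  # 1 - 6*4/(5*24)
  # monotone increase -> rho 1
  inc <- spearman_map(m, data.frame(v = c(10, 20, 30, 40, 50)))
  expect_equal(inc$rho, 1)
  # tier consistency with p
  expect_equal(sm$tier, ifelse(sm$p_value <= 0.01, "strong",
                               ifelse(sm$p_value <= 0.05, "moderate", "none")))
  # constant vector flagged, not errored
  con <- spearman_map(m, data.frame(v = rep(1, 5)))
  expect_true(is.na(con$rho))
  expect_match(con$note, "constant")
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  set.seed(47)
  m <- rbind(t1 = rexp(12))
  colnames(m) <- paste0("s", 1:12)
  cov <- data.frame(v = rnorm(12))
  r1 <- spearman_map(m, cov)$rho
  r2 <- spearman_map(rbind(t1 = log(m[1, ] + 1)), cov)$rho
  r3 <- spearman_map(m, data.frame(v = exp(cov$v)))$rho
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})
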