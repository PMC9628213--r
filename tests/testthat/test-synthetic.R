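test_that("same seed gives bit-identical synthetic datasets", {
  cfg <- small_config(seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
})

test_that("per-sample depths honour the configured range and column sums", {
  cfg <- small_config(seed = 3)
  ds <- simulate_dataset(cfg)
  tot <- colSums(ds$counts)
  expect_true(all(tot >= cfg$depth_range[1] & tot <= cfg$depth_range[2]))
  expect_equal(ncol(ds$counts), 2 * cfg$n_per_group)
  expect_equal(nrow(ds$counts), cfg$n_features)
})

test_that("planted fold changes are recovered in group-mean abundance ratios", {
  # Monte-Carlo check of the generator's own expectation: with fold change 4
  # the case/control ratio of mean relative abundance should sit near 4
  cfg <- synthetic_config(n_per_group = 100L, n_features = 100L,
                          depth_range = c(5000L, 8000L), n_differential = 2L,
                          fold_changes = 4, seed = 5)
  ds <- simulate_dataset(cfg)
  rel <- relative_abundance(ds$counts)
  grp <- ds$metadata$group
  for (f in ds$truth$differential$feature_id) {
    ratio <- mean(rel[f, grp == "case"]) / mean(rel[f, grp == "control"])
    expect_gt(ratio, 3)
    expect_lt(ratio, 5)
  }
})

test_that("compositional renormalisation shifts non-planted features as expected", {
  # 3-feature toy, analytic: baseline (b1,b2,b3), fold f on feature 1 gives
  # case proportions b_i / (1 + (f-1) b1) for i != 1
  cfg <- synthetic_config(n_per_group = 300L, n_features = 3L,
                          depth_range = c(20000L, 20000L), n_differential = 1L,
                          fold_changes = 3, overdispersion = 1e5,
                          differential_quantile = 0, seed = 8)
  ds <- simulate_dataset(cfg)
  b <- ds$truth$baseline
  f1 <- ds$truth$differential$feature_id
  other <- setdiff(names(b), f1)
  expected <- b[other] / (1 + 2 * b[[f1]])
  rel <- relative_abundance(ds$counts)
  observed <- rowMeans(rel[other, ds$metadata$group == "case", drop = FALSE])
  expect_equal(unname(observed), unname(expected), tolerance = 0.02)
})

test_that("null simulation has an empty truth table and identical compositions", {
  ds <- simulate_null(small_config(seed = 9))
  expect_equal(nrow(ds$truth$differential), 0)
})

test_that("covariate links hit their target Spearman strength via the copula", {
  cfg <- synthetic_config(
    n_per_group = 150L, n_features = 50L, depth_range = c(5000L, 8000L),
    n_differential = 2L, fold_changes = 4,
    covariate_links = list(list(feature = 1, covariate = "dFLC", rho = 0.6)),
    seed = 21)
  ds <- simulate_dataset(cfg)
  f <- ds$truth$covariate_links$feature_id[1]
  rel <- relative_abundance(ds$counts)
  rho <- suppressWarnings(
    cor(rel[f, ], ds$metadata$dFLC, method = "spearman"))
  expect_gt(rho, 0.45)
  expect_lt(rho, 0.75)
})

test_that("impossible covariate link strength is rejected", {
  expect_error(
    synthetic_config(covariate_links = list(
      list(feature = 1, covariate = "x", rho = 1))),
    "rho")
})

test_that("written dataset directory round-trips through the readers", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(small_config(seed = 2))
  write_dataset(ds, dir)
  back <- read_count_table(file.path(dir, "counts.tsv"))
  expect_identical(as.matrix(back), as.matrix(ds$counts))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_setequal(tax$feature_id, rownames(ds$counts))
  tree <- read_tree(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, rownames(ds$counts))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$differential), nrow(ds$truth$differential))
})
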