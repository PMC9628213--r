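test_that("candidate filter applies both significance and abundance rules", {
  set.seed(71)
  n <- 20
  grp <- rep(c("case", "control"), each = n / 2)
  # f_sig: strong group shift, abundant; f_rare: strong shift, ~0.05% max;
  # f_null: abundant but no shift
  depth <- 10000L
  m <- rbind(
    f_sig  = c(rpois(n / 2, 800), rpois(n / 2, 200)),
    f_rare = c(rpois(n / 2, 4) + 1L, rep(0L, n / 2)),
    f_null = rpois(n, 500),
    filler = rpois(n, depth))
  colnames(m) <- paste0("s", 1:n)
  ct <- count_table(m)
  cand <- candidate_filter(ct, grp)
  expect_true("f_sig" %in% cand$feature_id)
  expect_false("f_rare" %in% cand$feature_id)  # significant but too rare
  expect_false("f_null" %in% cand$feature_id)  # abundant but p >= 0.05
  expect_true(all(cand$p_value < 0.05))
  expect_true(all(cand$max_abundance > 0.001))
  expect_error(candidate_filter(ct, grp, p_threshold = 1e-12),
               "empty candidate set")
})

test_that("auc matches brute-force concordant-pair counting", {
  # worked example: disease [.9,.8,.4] vs control [.7,.3] -> 5/6
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3),
               c("d", "d", "d", "c", "c"), disease = "d")
  expect_equal(r$auc, 5 / 6)
  # all disease > all control -> 1; all equal -> 0.5
  expect_equal(roc_auc(c(3, 4, 1, 2), c("d", "d", "c", "c"), "d")$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("d", "c"), 3), "d")$auc, 0.5)
  set.seed(73)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.1), 14, replace = TRUE)  # forces ties
    lab <- sample(rep(c("d", "c"), 7))
    x <- s[lab == "d"]; y <- s[lab == "c"]
    brute <- mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(s, lab, "d")$auc, brute)
  }
})

test_that("roc curve is monotone from (0,0) to (1,1) and ci brackets auc", {
  set.seed(79)
  s <- c(rnorm(15, 1), rnorm(12))
  lab <- rep(c("d", "c"), c(15, 12))
  r <- roc_auc(s, lab, "d")
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  expect_lte(r$ci_low, r$auc); expect_gte(r$ci_high, r$auc)
  expect_error(roc_auc(s, rep("d", 27)), "two label")
})

test_that("delong interval agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  s <- c(rnorm(20, 0.8), rnorm(18))
  lab <- rep(c(1, 0), c(20, 18))
  mine <- roc_auc(s, as.character(lab), disease = "1")
  ref <- pROC::roc(lab, s, levels = c("0", "1"), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(c(mine$ci_low, mine$ci_high), ci[c(1, 3)], tolerance = 1e-8)
})

test_that("pod index satisfies its vote-conservation and ratio identities", {
  ds <- simulate_dataset(small_config(seed = 89))
  rel <- relative_abundance(ds$counts)
  model <- fit_forest(rel[1:5, , drop = FALSE], ds$metadata$group,
                      disease = "case", n_trees = 101, seed = 4)
  # full-forest votes on new data: every sample scored by all trees
  pod <- pod_index(model, newdata = rel[1:5, , drop = FALSE])
  expect_true(all(pod$disease_votes + pod$control_votes == 101))
  fin <- is.finite(pod$pod_ratio) & pod$pod_fraction < 1
  expect_equal(pod$pod_ratio[fin],
               pod$pod_fraction[fin] / (1 - pod$pod_fraction[fin]))
  expect_true(all(pod$pod_fraction >= 0 & pod$pod_fraction <= 1))
  # oob votes: strictly fewer voters than trees, still conserved per sample
  oob <- pod_index(model)
  expect_true(all(oob$disease_votes + oob$control_votes <= 101))
  expect_true(all(oob$disease_votes + oob$control_votes > 0))
  # ranking is invariant to ratio vs fraction (monotone transform)
  ok <- is.finite(pod$pod_ratio)
  expect_equal(rank(pod$pod_fraction[ok]), rank(pod$pod_ratio[ok]))
})

test_that("forests are seed-deterministic and perfectly fit separable data", {
  m <- rbind(marker = c(rep(10, 8), rep(0, 8)),
             noise = rpois(16, 5) + 1)
  colnames(m) <- paste0("s", 1:16)
  lab <- rep(c("case", "control"), each = 8)
  f1 <- fit_forest(m, lab, disease = "case", n_trees = 51, seed = 7)
  f2 <- fit_forest(m, lab, disease = "case", n_trees = 51, seed = 7)
  expect_identical(pod_index(f1), pod_index(f2))
  pred <- predict(f1$forest, t(m))
  expect_equal(mean(pred != lab), 0)
  expect_error(fit_forest(m, rep("case", 16)), "both classes")
})

test_that("cv selection finds a single perfectly separating marker among noise", {
  set.seed(97)
  n <- 24
  m <- rbind(sep = c(rep(1, n / 2), rep(0, n / 2)) + rnorm(n, 0, 0.01),
             matrix(rnorm(8 * n), 8,
                    dimnames = list(paste0("noise", 1:8), NULL)))
  colnames(m) <- paste0("s", 1:n)
  lab <- rep(c("case", "control"), each = n / 2)
  sel <- cv_marker_selection(m, lab, k = 4, n_repeats = 2, n_trees = 101,
                             seed = 5)
  expect_equal(sel$optimal_count, 1)
  expect_equal(sel$markers, "sep")
  expect_true(all(sel$cv_curve$mean_error >= 0 & sel$cv_curve$mean_error <= 1))
  # curve grid includes every count up to min(10, p) and the full set
  expect_true(all(seq_len(9) %in% sel$cv_curve$n_markers))
  expect_true(9 %in% sel$cv_curve$n_markers)
})

test_that("train/test evaluation keeps test samples out of training", {
  ds <- simulate_dataset(small_config(seed = 101, n_per_group = 12L))
  grp <- ds$metadata$group
  names(grp) <- ds$metadata$sample_id
  split <- stratified_split(ds$metadata$sample_id, grp, fraction = 0.75,
                            seed = 2)
  ev <- train_test_evaluate(ds$counts, grp, split = split, disease = "case",
                            k = 3, n_repeats = 1, n_trees = 101, seed = 3)
  expect_length(intersect(ev$manifest$train_samples,
                          ev$manifest$test_samples), 0)
  expect_setequal(ev$train_pod$sample_id, split$train)
  expect_setequal(ev$test_pod$sample_id, split$test)
  # markers were selected from training candidates only
  expect_true(all(ev$manifest$markers %in% ev$candidates$feature_id))
  expect_error(
    train_test_evaluate(ds$counts, grp,
                        split = list(train = split$train,
                                     test = grep("CASE", split$test,
                                                 value = TRUE))),
    "both classes")
})

test_that("end-to-end marker evaluation is deterministic for a fixed seed", {
  ds <- simulate_dataset(small_config(seed = 103, n_per_group = 12L))
  run <- function() {
    ev <- train_test_evaluate(ds$counts, ds$metadata$group, disease = "case",
                              k = 3, n_repeats = 1, n_trees = 101, seed = 9)
    list(ev$manifest$markers, ev$train_roc$auc, ev$test_roc$auc,
         ev$test_pod$pod_fraction)
  }
  expect_identical(run(), run())
})
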