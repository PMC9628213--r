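#' Candidate-marker filter for diagnostic modelling
#'
#' Keeps features that are both significantly different between the two
#' groups (raw Mann-Whitney p < `p_threshold` on relative abundances) and
#' non-trivially abundant (maximum per-sample relative abundance strictly
#' greater than `abundance_threshold`, i.e. "more than 0.1% in any sample"
#' at the default).
#'
#' @param counts a [count_table()].
#' @param groups two-level group label per sample.
#' @param p_threshold Mann-Whitney screening level (default 0.05).
#' @param abundance_threshold relative-abundance floor (default 0.001).
#' @return data frame of class `candidate_set`: `feature_id`, `p_value`,
#'   `max_abundance`, sorted by p.
#' @export
candidate_filter <- function(counts, groups, p_threshold = 0.05,
                             abundance_threshold = 0.001) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2) stop("candidate_filter needs two groups")
  rel <- relative_abundance(counts)
  cmp <- group_compare(rel, groups, relative = FALSE)
  max_ab <- apply(rel, 1, max)
  keep <- cmp$p_value < p_threshold & max_ab > abundance_threshold
  if (!any(keep))
    stop("empty candidate set: ", sum(cmp$p_value < p_threshold),
         " feature(s) pass p < ", p_threshold, " and ",
         sum(max_ab > abundance_threshold), " pass abundance > ",
         abundance_threshold, ", but none pass both")
  out <- data.frame(feature_id = cmp$feature_id[keep],
                    p_value = cmp$p_value[keep],
                    max_abundance = max_ab[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$feature_id), ]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

# descending marker-count grid: all candidates, halving steps, and every
# integer up to 10
marker_count_grid <- function(p) {
  g <- p
  while (g[length(g)] > 1) g <- c(g, max(1, g[length(g)] %/% 2))
  sort(unique(c(g, seq_len(min(10, p)))))
}

#' Cross-validated random-forest marker selection
#'
#' Stratified k-fold cross-validation repeated `n_repeats` times. Within
#' each training fold the candidate features are ranked by mean decrease in
#' accuracy from a forest fitted on that fold only (no information from the
#' held-out fold); the held-out misclassification error is then evaluated at
#' a descending grid of marker counts (all candidates, halving steps, and
#' every count up to 10). The optimal count minimises the mean CV error,
#' with ties resolved towards the smaller (more parsimonious) count; the
#' final marker list is the top-ranked features on the full data at that
#' count.
#'
#' @param features feature x sample matrix restricted to the candidate set
#'   (relative abundances).
#' @param labels two-level class label per sample.
#' @param k folds (default 5).
#' @param n_repeats CV repetitions (default 5).
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed.
#' @return list of class `marker_selection`: `cv_curve` (data frame
#'   `n_markers`, `mean_error`, `sd_error`), `optimal_count`, `markers`
#'   (ordered IDs), `importance` (data frame with mean decrease in accuracy
#'   and Gini for the full-data ranking forest), `forest_spec`.
#' @export
cv_marker_selection <- function(features, labels, k = 5, n_repeats = 5,
                                n_trees = 500, seed = 1L) {
  X <- t(as.matrix(features) + 0)  # samples x features
  y <- factor(as.character(labels))
  if (nlevels(y) != 2) stop("marker selection needs two classes")
  if (ncol(X) < 2) stop("need at least two candidate features")
  set.seed(seed)
  grid <- marker_count_grid(ncol(X))
  errs <- matrix(NA_real_, length(grid), k * n_repeats)
  col <- 0L
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(y, k)
    for (f in seq_len(k)) {
      col <- col + 1L
      tr <- folds != f; te <- !tr
      if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 1)
        stop("degenerate fold: a fold lost a class; use fewer folds")
      rank_f <- rank_features(X[tr, , drop = FALSE], y[tr], n_trees)
      for (gi in seq_along(grid)) {
        top <- rank_f[seq_len(grid[gi])]
        rf <- randomForest::randomForest(
          X[tr, top, drop = FALSE], y[tr], ntree = n_trees,
          mtry = max(1, floor(sqrt(grid[gi]))))
        pred <- stats::predict(rf, X[te, top, drop = FALSE])
        errs[gi, col] <- mean(pred != y[te])
      }
    }
  }
  cv_curve <- data.frame(n_markers = grid,
                         mean_error = rowMeans(errs),
                         sd_error = apply(errs, 1, stats::sd))
  optimal <- grid[which.min(cv_curve$mean_error)]  # ties: smallest count
  full_rank <- rank_features(X, y, n_trees)
  markers <- full_rank[seq_len(optimal)]
  rf_full <- randomForest::randomForest(X[, full_rank, drop = FALSE], y,
                                        ntree = n_trees,
                                        mtry = max(1, floor(sqrt(length(full_rank)))),
                                        importance = TRUE)
  imp <- randomForest::importance(rf_full)
  importance <- data.frame(
    feature_id = rownames(imp),
    mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
    mean_decrease_gini = imp[, "MeanDecreaseGini"],
    stringsAsFactors = FALSE)
  rownames(importance) <- NULL
  res <- list(cv_curve = cv_curve, optimal_count = optimal, markers = markers,
              importance = importance,
              forest_spec = list(n_trees = n_trees, mtry_rule = "floor(sqrt(p))",
                                 k = k, n_repeats = n_repeats, seed = seed))
  class(res) <- "marker_selection"
  res
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (g in levels(y)) {
    idx <- sample(which(y == g))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# feature IDs ordered by decreasing mean-decrease-in-accuracy importance,
# ties broken by Gini then lexicographically (deterministic)
rank_features <- function(X, y, n_trees) {
  rf <- randomForest::randomForest(X, y, ntree = n_trees,
                                   mtry = max(1, floor(sqrt(ncol(X)))),
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  ord <- order(-imp[, "MeanDecreaseAccuracy"], -imp[, "MeanDecreaseGini"],
               rownames(imp))
  rownames(imp)[ord]
}

#' Fit the diagnostic random forest on the selected markers
#'
#' A bagged decision-tree ensemble (`randomForest`) with per-tree vote
#' access, mtry = floor(sqrt(#markers)) (minimum 1). Out-of-bag votes are
#' retained for training-set POD computation.
#'
#' @param features marker x sample matrix (training data).
#' @param labels two-level class label per sample; the level passed as
#'   `disease` is the positive ("disease") class.
#' @param disease label value of the disease class (default: first level).
#' @param n_trees trees (default 500).
#' @param seed integer seed.
#' @return list of class `marker_forest`: the fitted `forest`, `markers`,
#'   `disease`, `n_trees`, `oob_votes` (training-sample vote counts).
#' @export
fit_forest <- function(features, labels, disease = NULL, n_trees = 500,
                       seed = 1L) {
  X <- t(as.matrix(features) + 0)
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("labels must contain both classes")
  if (is.null(disease)) disease <- levels(y)[1]
  if (!disease %in% levels(y)) stop("disease label '", disease, "' not in labels")
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = n_trees,
                                   mtry = max(1, floor(sqrt(ncol(X)))),
                                   importance = TRUE, norm.votes = FALSE)
  res <- list(forest = rf, markers = colnames(X), disease = disease,
              n_trees = n_trees,
              oob_votes = rf$votes)  # counts: norm.votes = FALSE
  class(res) <- "marker_forest"
  res
}

#' Probability-of-disease (POD) index from forest votes
#'
#' The POD index of a sample is defined from the ensemble vote split: the
#' literal index is the ratio of trees voting "disease" to trees voting
#' "control" (`pod_ratio`, `Inf` when no tree votes control); ranking
#' statistics downstream (AUC, Mann-Whitney) use the vote fraction
#' `pod_fraction` = disease votes / total votes, a strictly monotone
#' transform of the ratio that avoids infinities.
#'
#' For training samples (`newdata = NULL`) the out-of-bag votes are used, so
#' each sample is scored only by trees that never saw it; full-forest votes
#' would be nearly resubstitution-pure and uninformative. Set
#' `resubstitution = TRUE` to override. Test samples are scored by the full
#' forest.
#'
#' @param model a `marker_forest` from [fit_forest()].
#' @param newdata optional marker x sample matrix of new samples.
#' @param resubstitution score training samples with all trees instead of
#'   out-of-bag votes.
#' @return data frame: `sample_id`, `disease_votes`, `control_votes`,
#'   `pod_fraction`, `pod_ratio`.
#' @export
pod_index <- function(model, newdata = NULL, resubstitution = FALSE) {
  stopifnot(inherits(model, "marker_forest"))
  if (is.null(newdata)) {
    votes <- if (resubstitution) {
      stats::predict(model$forest, type = "vote", norm.votes = FALSE)
    } else model$oob_votes
  } else {
    X <- t(as.matrix(newdata) + 0)
    if (!all(model$markers %in% colnames(X)))
      stop("newdata is missing marker feature(s): ",
           paste(setdiff(model$markers, colnames(X)), collapse = ", "))
    votes <- stats::predict(model$forest, X[, model$markers, drop = FALSE],
                            type = "vote", norm.votes = FALSE)
  }
  dv <- votes[, model$disease]
  cv <- rowSums(votes) - dv
  data.frame(sample_id = rownames(votes),
             disease_votes = as.integer(dv), control_votes = as.integer(cv),
             pod_fraction = dv / (dv + cv),
             pod_ratio = ifelse(cv == 0, Inf, dv / cv),
             stringsAsFactors = FALSE)
}

#' ROC curve, AUC with DeLong confidence interval, and group-difference p
#'
#' AUC via the Mann-Whitney identity with midrank tie handling:
#' AUC = (sum of disease-score ranks - n1 (n1 + 1) / 2) / (n1 n2). The 95%
#' confidence interval uses DeLong's placement-variance estimator (clamped
#' to `[0, 1]`); the group-difference p-value is the Mann-Whitney test on
#' the scores.
#'
#' @param scores numeric score per sample (e.g. POD fraction).
#' @param labels two-level label per sample.
#' @param disease label value treated as positive (default: first level).
#' @param conf_level confidence level (default 0.95).
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `p_value`, `curve` (data frame `fpr`, `tpr` from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels, disease = NULL, conf_level = 0.95) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("roc_auc needs exactly two label values")
  if (is.null(disease)) disease <- lev[1]
  x <- scores[labels == disease]   # positives
  y <- scores[labels != disease]   # negatives
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both classes must be non-empty")
  r <- rank(c(x, y))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)

  # DeLong placements
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  V01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  v <- stats::var(V10) / n1 + stats::var(V01) / n2
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(max(v, 0))
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))

  mw <- mann_whitney(x, y)

  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    fpr = vapply(th, function(t) mean(y >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(x >= t), numeric(1)))
  res <- list(auc = auc, ci_low = ci[1], ci_high = ci[2],
              p_value = mw$p_value, curve = curve,
              n_positive = n1, n_negative = n2, disease = disease)
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (95%% CI %.4f-%.4f), group-difference p = %.4g\n",
              x$auc, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Stratified train/test split of sample IDs
#'
#' @param sample_ids sample identifiers.
#' @param groups label per sample.
#' @param fraction training fraction per group (default 2/3).
#' @param seed integer seed.
#' @return list: `train`, `test` ID vectors (disjoint, stratified).
#' @export
stratified_split <- function(sample_ids, groups, fraction = 2 / 3, seed = 1L) {
  set.seed(seed)
  groups <- as.character(groups)
  train <- unlist(lapply(unique(groups), function(g) {
    ids <- sample_ids[groups == g]
    sample(ids, round(fraction * length(ids)))
  }))
  list(train = sort(train), test = sort(setdiff(sample_ids, train)))
}

#' End-to-end diagnostic-model evaluation on a train/test split
#'
#' Runs the full marker pipeline with strict separation: candidate
#' filtering, cross-validated marker selection and forest fitting use the
#' training samples only. Training-set POD comes from out-of-bag votes; the
#' held-out test set is scored by the full forest. Both sets are evaluated
#' by ROC/AUC on the POD fraction.
#'
#' @param counts a [count_table()].
#' @param groups two-level label per sample (aligned with `counts`).
#' @param split list with `train` and `test` sample-ID vectors (disjoint),
#'   or `NULL` to draw a seeded stratified split with `train_fraction`.
#' @param train_fraction training fraction when `split` is NULL
#'   (default 2/3).
#' @param disease label value treated as positive (default: first level).
#' @param p_threshold,abundance_threshold candidate-filter thresholds.
#' @param k,n_repeats,n_trees forest / CV settings.
#' @param seed integer seed covering the split, CV and forests.
#' @return list of class `marker_evaluation`: `candidates`, `selection`,
#'   `model`, `train_pod`, `test_pod`, `train_roc`, `test_roc`, `split`,
#'   `manifest` (thresholds, seeds, marker list, sample usage audit).
#' @export
train_test_evaluate <- function(counts, groups, split = NULL,
                                train_fraction = 2 / 3, disease = NULL,
                                p_threshold = 0.05, abundance_threshold = 0.001,
                                k = 5, n_repeats = 5, n_trees = 500, seed = 1L) {
  groups <- as.character(groups)
  names(groups) <- colnames(counts)
  if (is.null(split))
    split <- stratified_split(colnames(counts), groups, train_fraction, seed)
  if (length(intersect(split$train, split$test)))
    stop("train and test sample sets overlap")
  bad <- setdiff(c(split$train, split$test), colnames(counts))
  if (length(bad)) stop("unknown sample IDs in split: ", paste(bad, collapse = ", "))
  if (length(unique(groups[split$test])) < 2)
    stop("test set must contain both classes")
  if (is.null(disease)) disease <- unique(groups)[1]

  tr_counts <- count_table(counts[, split$train, drop = FALSE])
  tr_groups <- groups[split$train]

  candidates <- candidate_filter(tr_counts, tr_groups, p_threshold,
                                 abundance_threshold)
  rel_tr <- relative_abundance(tr_counts)[candidates$feature_id, , drop = FALSE]
  selection <- if (nrow(candidates) >= 2) {
    cv_marker_selection(rel_tr, tr_groups, k = k, n_repeats = n_repeats,
                        n_trees = n_trees, seed = seed)
  } else {
    list(cv_curve = NULL, optimal_count = 1L,
         markers = candidates$feature_id, importance = NULL)
  }
  markers <- selection$markers

  model <- fit_forest(rel_tr[markers, , drop = FALSE], tr_groups,
                      disease = disease, n_trees = n_trees, seed = seed)

  train_pod <- pod_index(model)
  te_counts <- counts[, split$test, drop = FALSE]
  rel_te <- relative_abundance(te_counts)[markers, , drop = FALSE]
  test_pod <- pod_index(model, newdata = rel_te)

  train_roc <- roc_auc(train_pod$pod_fraction, tr_groups, disease = disease)
  test_roc <- roc_auc(test_pod$pod_fraction, groups[split$test],
                      disease = disease)

  manifest <- list(
    p_threshold = p_threshold, abundance_threshold = abundance_threshold,
    k = k, n_repeats = n_repeats, n_trees = n_trees, seed = seed,
    disease = disease, markers = markers,
    n_candidates = nrow(candidates),
    train_samples = split$train, test_samples = split$test)
  res <- list(candidates = candidates, selection = selection, model = model,
              train_pod = train_pod, test_pod = test_pod,
              train_roc = train_roc, test_roc = test_roc,
              split = split, manifest = manifest)
  class(res) <- "marker_evaluation"
  res
}
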