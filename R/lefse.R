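#' LDA effect size (LEfSe) biomarker discovery
#'
#' From-scratch implementation of the LEfSe procedure for class-labelled
#' feature tables (taxon tables at one or several ranks concatenated, or any
#' nonnegative feature table such as predicted pathway abundances):
#' \enumerate{
#'   \item each sample is normalised to a total of 1e6;
#'   \item per feature, a Kruskal-Wallis test across classes (equivalent to
#'     the Wilcoxon rank-sum test for two classes); features with
#'     p >= `alpha` are excluded;
#'   \item for the surviving features, over `n_boot` bootstrap subsamples
#'     (a fraction `boot_fraction` of each class, drawn with replacement),
#'     a one-component regularised linear discriminant is fitted; a
#'     feature's per-bootstrap effect size is the average of its share of
#'     the class-mean difference projected on the discriminant axis and its
#'     raw class-mean difference;
#'   \item the LDA score is log10 of the bootstrap-mean effect, floored at
#'     log10(1) = 0;
#'   \item a feature passes when KW p < `alpha` and score >= `lda_threshold`;
#'     its enriched class is the class with the larger mean normalised
#'     abundance. With more than two classes each class is contrasted
#'     one-against-all.
#' }
#' Zero within-class variance is handled by ridge regularisation of the
#' pooled covariance (epsilon = 1e-6 x trace), so sparse taxa that pass the
#' Kruskal-Wallis screen cannot crash the discriminant fit.
#'
#' @param features feature x sample matrix of non-negative abundances.
#' @param classes class label per sample (>= 2 classes, >= 3 samples each).
#' @param alpha Kruskal-Wallis screening level (default 0.05).
#' @param lda_threshold minimum log10 LDA score to pass (default 2.5).
#' @param n_boot bootstrap rounds for the effect size (default 30).
#' @param boot_fraction per-class subsample fraction (default 2/3).
#' @param seed integer seed.
#' @return data frame of class `lefse_result`: `feature_id`, `class`
#'   (enriched), `kw_p`, `lda_score`, `pass`, `note` (exclusion reason).
#' @export
lefse <- function(features, classes, alpha = 0.05, lda_threshold = 2.5,
                  n_boot = 30, boot_fraction = 2 / 3, seed = 1L) {
  m <- as.matrix(features) + 0
  classes <- as.character(classes)
  if (length(classes) != ncol(m)) stop("classes length must match samples")
  tab <- table(classes)
  if (length(tab) < 2) stop("lefse needs >= 2 classes")
  if (any(tab < 3)) stop("every class needs >= 3 samples (",
                         paste(names(tab)[tab < 3], collapse = ", "), ")")
  if (any(m < 0)) stop("feature table must be non-negative")

  # (1) per-sample normalisation to 1e6
  m <- sweep(m, 2, colSums(m), "/") * 1e6
  lev <- names(tab)
  cls <- factor(classes, levels = lev)

  class_means <- sapply(lev, function(g) rowMeans(m[, cls == g, drop = FALSE]))
  if (is.null(dim(class_means)))
    class_means <- matrix(class_means, nrow = 1,
                          dimnames = list(rownames(m), lev))
  enriched <- lev[max.col(class_means, ties.method = "first")]

  # (2) Kruskal-Wallis screen
  kw_p <- apply(m, 1, function(x) {
    if (length(unique(x)) == 1) return(1)
    stats::kruskal.test(x, cls)$p.value
  })
  constant <- apply(m, 1, function(x) length(unique(x)) == 1)
  survivors <- which(kw_p < alpha & !constant)

  scores <- rep(NA_real_, nrow(m))
  if (length(survivors)) {
    set.seed(seed)
    X <- t(m[survivors, , drop = FALSE])  # samples x features
    contrasts <- if (length(lev) == 2) list(lev[1]) else as.list(lev)
    eff_by_contrast <- matrix(0, length(survivors), length(contrasts))
    for (ci in seq_along(contrasts)) {
      y <- ifelse(cls == contrasts[[ci]], "one", "rest")
      eff <- matrix(NA_real_, length(survivors), n_boot)
      for (b in seq_len(n_boot)) {
        idx <- unlist(lapply(unique(y), function(g) {
          ig <- which(y == g)
          sample(ig, max(2, ceiling(boot_fraction * length(ig))),
                 replace = TRUE)
        }))
        eff[, b] <- lda_effect_sizes(X[idx, , drop = FALSE], y[idx])
      }
      eff_by_contrast[, ci] <- rowMeans(eff, na.rm = TRUE)
    }
    # score each feature by the contrast of its enriched class
    for (k in seq_along(survivors)) {
      f <- survivors[k]
      ci <- if (length(lev) == 2) 1L else match(enriched[f], lev)
      scores[f] <- log10(max(eff_by_contrast[k, ci], 1))
    }
  }

  out <- data.frame(
    feature_id = rownames(m),
    class = enriched,
    kw_p = kw_p,
    lda_score = scores,
    pass = !is.na(scores) & kw_p < alpha & scores >= lda_threshold,
    note = ifelse(constant, "constant feature",
                  ifelse(kw_p >= alpha, "kw_p >= alpha", "")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "params") <- list(alpha = alpha, lda_threshold = lda_threshold,
                              n_boot = n_boot, boot_fraction = boot_fraction,
                              seed = seed)
  class(out) <- c("lefse_result", "data.frame")
  out
}

# Per-feature effect sizes from a one-component Fisher discriminant between
# two classes: w solves (Sw + ridge) w = mu1 - mu2; each feature's effect is
# (|w_unit_i| * |projected class-mean difference| + |raw mean difference|)/2.
lda_effect_sizes <- function(X, y) {
  g1 <- y == y[1]
  if (all(g1) || !any(g1)) return(rep(NA_real_, ncol(X)))
  mu1 <- colMeans(X[g1, , drop = FALSE])
  mu2 <- colMeans(X[!g1, , drop = FALSE])
  center <- function(A) sweep(A, 2, colMeans(A))
  S1 <- crossprod(center(X[g1, , drop = FALSE]))
  S2 <- crossprod(center(X[!g1, , drop = FALSE]))
  Sw <- (S1 + S2) / max(1, nrow(X) - 2)
  tr <- sum(diag(Sw))
  ridge <- if (tr > 0) 1e-6 * tr else 1e-6
  diag(Sw) <- diag(Sw) + ridge
  w <- solve(Sw, mu1 - mu2)
  wn <- sqrt(sum(w^2))
  if (wn == 0) return(abs(mu1 - mu2))
  w_unit <- w / wn
  ld_gap <- abs(sum(w_unit * (mu1 - mu2)))  # class-mean gap on the axis
  (abs(w_unit) * ld_gap + abs(mu1 - mu2)) / 2
}

#' Ranked LEfSe report table
#'
#' Passing features sorted by enriched class, then by descending LDA score,
#' ties broken lexicographically by feature ID (deterministic ordering).
#'
#' @param result a `lefse_result` from [lefse()].
#' @return data frame: `feature_id`, `class`, `lda_score`, `kw_p`.
#' @export
lefse_report <- function(result) {
  stopifnot(inherits(result, "lefse_result"))
  hits <- result[result$pass, c("feature_id", "class", "lda_score", "kw_p")]
  hits <- hits[order(hits$class, -hits$lda_score, hits$feature_id), ]
  rownames(hits) <- NULL
  hits
}
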