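#' Aggregate a feature table to a taxonomic rank
#'
#' Features sharing the same lineage down to `rank` are summed. The grouping
#' key is the full upstream lineage, so features unclassified at `rank` are
#' pooled under their parent lineage plus the unclassified sentinel rather
#' than into one global bin. Total counts are conserved at every rank.
#'
#' @param counts a [count_table()].
#' @param taxonomy a `taxonomy_table` covering every feature.
#' @param rank one of the seven ranks (`"kingdom"` ... `"species"`).
#' @return A [count_table()] whose rownames are semicolon-joined lineages.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank) {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  missing <- setdiff(rownames(counts), taxonomy$feature_id)
  if (length(missing))
    stop("taxonomy missing feature(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  tax <- taxonomy[match(rownames(counts), taxonomy$feature_id), , drop = FALSE]
  upto <- TAXONOMIC_RANKS[seq_len(match(rank, TAXONOMIC_RANKS))]
  key <- apply(as.matrix(tax[, upto, drop = FALSE]), 1, paste, collapse = ";")
  agg <- rowsum(as.matrix(counts) + 0, group = key)
  count_table(agg[order(rownames(agg)), , drop = FALSE])
}

#' Convert counts to per-sample relative abundances
#'
#' @param counts a [count_table()] (or plain matrix) with positive column
#'   sums.
#' @return matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(counts) {
  m <- as.matrix(counts) + 0
  tot <- colSums(m)
  if (any(tot == 0))
    stop("zero-total sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "))
  sweep(m, 2, tot, "/")
}

#' Mann-Whitney U test (exact-with-ties enumeration for small groups)
#'
#' U is computed from midranks. When `max(n1, n2) <= exact_limit` the exact
#' two-sided p-value is obtained by enumerating all
#' `choose(n1 + n2, n1)` label assignments (valid under ties); otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples from the two groups.
#' @param exact_limit switch from enumeration to the normal approximation
#'   when either group exceeds this size (default 8).
#' @return list: `statistic` (U for the first group), `p_value`, `exact`.
#' @export
mann_whitney <- function(x, y, exact_limit = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups need at least one observation")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= exact_limit) {
    sel <- utils::combn(n1 + n2, n1, simplify = FALSE)
    Us <- vapply(sel, function(s) sum(r[s]) - n1 * (n1 + 1) / 2, numeric(1))
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    list(statistic = U, p_value = p, exact = TRUE)
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) return(list(statistic = U, p_value = 1, exact = FALSE))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    list(statistic = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         exact = FALSE)
  }
}

#' Per-taxon nonparametric group comparison
#'
#' Two groups: Mann-Whitney U (exact enumeration for small groups, see
#' [mann_whitney()]). More than two: Kruskal-Wallis with tie correction.
#' By default the test runs on per-sample relative abundances, matching the
#' percentage scale on which microbiome composition is usually reported;
#' raw p-values are reported and a Benjamini-Hochberg column is optional.
#'
#' @param features feature x sample matrix (counts or proportions).
#' @param groups group label per sample.
#' @param relative convert to per-sample proportions first (default TRUE).
#' @param adjust add a BH-adjusted `q_value` column (default FALSE).
#' @return data frame: `feature_id`, one `mean_<group>` column per group
#'   (mean relative abundance), `statistic`, `p_value`, `test`, and
#'   optionally `q_value`.
#' @export
group_compare <- function(features, groups, relative = TRUE, adjust = FALSE) {
  m <- as.matrix(features) + 0
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) stop("groups length must match sample count")
  tab <- table(groups)
  if (any(tab == 0) || length(tab) < 2) stop("need >= 2 non-empty groups")
  if (relative) m <- relative_abundance(m)
  lev <- names(tab)
  means <- sapply(lev, function(g) rowMeans(m[, groups == g, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1, dimnames = list(rownames(m), lev))
  two <- length(lev) == 2
  res <- lapply(seq_len(nrow(m)), function(i) {
    if (two) {
      mw <- mann_whitney(m[i, groups == lev[1]], m[i, groups == lev[2]])
      c(stat = mw$statistic, p = mw$p_value)
    } else {
      kw <- stats::kruskal.test(m[i, ], factor(groups))
      c(stat = unname(kw$statistic), p = kw$p.value)
    }
  })
  res <- do.call(rbind, res)
  out <- data.frame(feature_id = rownames(m), means,
                    statistic = res[, "stat"], p_value = res[, "p"],
                    test = if (two) "mann_whitney" else "kruskal_wallis",
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out)[1 + seq_along(lev)] <- paste0("mean_", lev)
  if (adjust) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Venn partition of detected features between two groups
#'
#' A feature is "present in a group" iff it has a nonzero count in at least
#' one sample of that group. Shared + unique counts sum to the number of
#' features detected anywhere.
#'
#' @param counts a [count_table()].
#' @param groups group label per sample (exactly 2 groups).
#' @return list: `shared`, `unique` (named by group), `total_detected`,
#'   `features` (list of feature-ID vectors per compartment).
#' @export
venn_partition <- function(counts, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("venn_partition needs exactly two groups")
  m <- as.matrix(counts)
  in_g <- sapply(lev, function(g) rowSums(m[, groups == g, drop = FALSE]) > 0)
  detected <- in_g[, 1] | in_g[, 2]
  shared <- in_g[, 1] & in_g[, 2]
  u1 <- in_g[, 1] & !in_g[, 2]
  u2 <- in_g[, 2] & !in_g[, 1]
  list(shared = sum(shared),
       unique = stats::setNames(c(sum(u1), sum(u2)), lev),
       total_detected = sum(detected),
       features = list(
         shared = rownames(m)[shared],
         unique = stats::setNames(list(rownames(m)[u1], rownames(m)[u2]), lev)))
}

#' Spearman correlation map between taxa and clinical covariates
#'
#' Midrank Spearman rho with a two-sided p from the t approximation
#' (`cor.test(..., exact = FALSE)`), on pairwise-complete observations.
#' Pairs are tiered by significance: `strong` (p <= 0.01), `moderate`
#' (0.01 < p <= 0.05), `none` — the convention used for solid/dotted edges
#' in correlation heatmap figures.
#'
#' @param features taxon x sample matrix (relative abundances or counts).
#' @param covariates data frame of numeric covariates, rows aligned with
#'   the samples (columns of `features`).
#' @param taxon_taxon also include all taxon-taxon pairs (default FALSE).
#' @param min_n minimum paired non-missing observations (default 3).
#' @return data frame: `var1`, `var2`, `rho`, `p_value`, `tier`, `n`,
#'   `note` (reason when rho is undefined).
#' @export
spearman_map <- function(features, covariates, taxon_taxon = FALSE, min_n = 3) {
  m <- as.matrix(features) + 0
  cov <- as.data.frame(covariates)
  num <- vapply(cov, is.numeric, logical(1))
  cov <- cov[, num, drop = FALSE]
  if (nrow(cov) != ncol(m)) stop("covariate rows must match samples")
  pairs <- list()
  for (i in rownames(m)) for (j in colnames(cov))
    pairs[[length(pairs) + 1]] <- list(x = m[i, ], y = cov[[j]], a = i, b = j)
  if (taxon_taxon && nrow(m) > 1) {
    idx <- utils::combn(rownames(m), 2, simplify = FALSE)
    for (ij in idx)
      pairs[[length(pairs) + 1]] <- list(x = m[ij[1], ], y = m[ij[2], ],
                                         a = ij[1], b = ij[2])
  }
  rows <- lapply(pairs, function(pr) {
    ok <- !is.na(pr$x) & !is.na(pr$y)
    n <- sum(ok)
    if (n < min_n)
      return(data.frame(var1 = pr$a, var2 = pr$b, rho = NA_real_,
                        p_value = NA_real_, tier = "none", n = n,
                        note = "fewer than min_n paired observations"))
    x <- pr$x[ok]; y <- pr$y[ok]
    if (length(unique(x)) == 1 || length(unique(y)) == 1)
      return(data.frame(var1 = pr$a, var2 = pr$b, rho = NA_real_,
                        p_value = NA_real_, tier = "none", n = n,
                        note = "constant vector"))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    p <- ct$p.value
    tier <- if (p <= 0.01) "strong" else if (p <= 0.05) "moderate" else "none"
    data.frame(var1 = pr$a, var2 = pr$b, rho = unname(ct$estimate),
               p_value = p, tier = tier, n = n, note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
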