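#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared distances into within- and
#' between-group components and tests the pseudo-F ratio
#' F = ((SS_total - SS_within) / (g - 1)) / (SS_within / (n - g))
#' by permuting group labels. The permutation p-value uses the
#' (1 + b) / (1 + m) estimator so it can never be 0; when the number of
#' distinct label assignments is at most `exhaustive_limit` the full
#' enumeration is used instead and the p-value is the exact proportion of
#' assignments with F at least as large as observed.
#'
#' @param d symmetric distance matrix with sample dimnames.
#' @param groups group label per sample (>= 2 groups, each non-empty).
#' @param n_permutations Monte-Carlo permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive_limit switch to exhaustive enumeration when the number
#'   of distinct assignments does not exceed this (default 20000).
#' @return list of class `permutation_test`: `statistic` (pseudo-F),
#'   `p_value`, `n_permutations` (actual count or number of assignments),
#'   `exhaustive`, `seed`, `method`.
#' @export
permanova <- function(d, groups, n_permutations = 10000, seed = 1L,
                      exhaustive_limit = 20000) {
  permutation_test_engine(d, groups, n_permutations, seed, exhaustive_limit,
                          statistic = permanova_stat, method = "PERMANOVA")
}

#' ANOSIM: analysis of similarities
#'
#' R = (mean between-group rank - mean within-group rank) / (M / 4), where
#' ranks (midranks on ties) are taken over all M = n (n - 1) / 2 pairwise
#' distances. R is in `[-1, 1]`; the permutation machinery is shared with
#' [permanova()].
#'
#' @inheritParams permanova
#' @return list of class `permutation_test` with `statistic` = R.
#' @export
anosim <- function(d, groups, n_permutations = 10000, seed = 1L,
                   exhaustive_limit = 20000) {
  permutation_test_engine(d, groups, n_permutations, seed, exhaustive_limit,
                          statistic = anosim_stat, method = "ANOSIM")
}

permutation_test_engine <- function(d, groups, n_permutations, seed,
                                    exhaustive_limit, statistic, method) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must match distance matrix")
  tab <- table(groups)
  if (length(tab) < 2) stop(method, " needs at least two groups")
  if (any(tab < 1)) stop("every group needs at least one sample")

  prep <- statistic(d, prepare = TRUE)
  obs <- statistic(prep, groups)

  n_assign <- exp(lgamma(n + 1) - sum(lgamma(tab + 1)))
  if (is.finite(n_assign) && n_assign <= exhaustive_limit) {
    assigns <- multiset_assignments(groups)
    stats <- vapply(assigns, function(g) statistic(prep, g), numeric(1))
    p <- mean(stats >= obs - 1e-12)
    res <- list(statistic = obs, p_value = p,
                n_permutations = length(assigns), exhaustive = TRUE,
                seed = seed, method = method)
  } else {
    set.seed(seed)
    b <- 0L
    for (i in seq_len(n_permutations)) {
      if (statistic(prep, sample(groups)) >= obs - 1e-12) b <- b + 1L
    }
    p <- (1 + b) / (1 + n_permutations)
    res <- list(statistic = obs, p_value = p,
                n_permutations = n_permutations, exhaustive = FALSE,
                seed = seed, method = method)
  }
  class(res) <- "permutation_test"
  res
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 5),
      ", p = ", signif(x$p_value, 5),
      if (x$exhaustive) " (exhaustive, " else " (",
      x$n_permutations, if (x$exhaustive) " assignments)" else " permutations)",
      "\n", sep = "")
  invisible(x)
}

# pseudo-F from squared distances; `prepare = TRUE` precomputes D^2
permanova_stat <- function(d, groups = NULL, prepare = FALSE) {
  if (prepare) return(list(D2 = d^2, n = nrow(d)))
  D2 <- d$D2; n <- d$n
  ss_total <- sum(D2) / (2 * n)
  lev <- unique(groups)
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  g <- length(lev)
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

# ANOSIM R from midranks of the pairwise distances
anosim_stat <- function(d, groups = NULL, prepare = FALSE) {
  if (prepare) {
    n <- nrow(d)
    lower <- which(lower.tri(d))
    r <- matrix(0, n, n)
    r[lower] <- rank(d[lower])
    r <- r + t(r)
    return(list(R = r, n = n, M = n * (n - 1) / 2))
  }
  r <- d$R; n <- d$n
  same <- outer(groups, groups, "==")
  lower <- lower.tri(r)
  within <- mean(r[lower & same])
  between <- mean(r[lower & !same])
  (between - within) / (d$M / 2)
}

# All distinct assignments of a multiset of labels to positions.
multiset_assignments <- function(groups) {
  lev <- unique(groups)
  counts <- as.integer(table(factor(groups, levels = lev)))
  n <- length(groups)
  out <- list()
  rec <- function(positions, li, current) {
    if (li == length(lev)) {
      current[positions] <- lev[li]
      out[[length(out) + 1L]] <<- current
      return(invisible(NULL))
    }
    sel <- utils::combn(positions, counts[li], simplify = FALSE)
    for (s in sel) {
      nxt <- current
      nxt[s] <- lev[li]
      rec(setdiff(positions, s), li + 1L, nxt)
    }
  }
  rec(seq_len(n), 1L, character(n))
  out
}
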