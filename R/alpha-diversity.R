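#' Alpha diversity estimators for one or more samples
#'
#' Computes, per sample: observed features, bias-corrected Chao1, ACE (rare
#' cutoff 10), Shannon-Wiener (natural log) and the Simpson dominance index,
#' following the Mothur conventions:
#' \itemize{
#'   \item Chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1)), Fk the number of
#'     features seen exactly k times (bias-corrected form);
#'   \item ACE = S_abund + S_rare / C + (F1 / C) gamma^2 with rare class
#'     counts <= 10, sample coverage C = 1 - F1 / N_rare and squared
#'     coefficient of variation gamma^2 = max(0, (S_rare / C)
#'     sum(i (i-1) Fi) / (N_rare (N_rare - 1)) - 1);
#'   \item Shannon H = -sum p_i ln p_i;
#'   \item Simpson D = sum n_i (n_i - 1) / (N (N - 1)) (dominance form;
#'     the complement is exposed as `simpson_complement`).
#' }
#'
#' @param counts a [count_table()] or a single sample's count vector.
#' @return data frame with one row per sample: `sample_id`,
#'   `observed_features`, `chao1`, `ace`, `shannon`, `simpson`,
#'   `simpson_complement`.
#' @export
alpha_diversity <- function(counts) {
  if (is.null(dim(counts))) {
    counts <- matrix(as.integer(counts), ncol = 1,
                     dimnames = list(NULL, "sample"))
  }
  res <- lapply(seq_len(ncol(counts)), function(j)
    alpha_one(counts[, j], colnames(counts)[j]))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

alpha_one <- function(x, id) {
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  N <- sum(x)
  if (N == 0) stop("all-zero count vector (sample '", id, "')")
  x <- x[x > 0]
  s_obs <- length(x)

  f1 <- sum(x == 1); f2 <- sum(x == 2)
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))

  rare <- x[x <= 10]
  s_rare <- length(rare); s_abund <- s_obs - s_rare
  n_rare <- sum(rare)
  if (s_rare == 0) {
    ace <- s_abund
  } else if (n_rare == f1) {
    # no coverage information (all rare features are singletons)
    ace <- NA_real_
  } else {
    C <- 1 - f1 / n_rare
    fi <- tabulate(rare, nbins = 10)
    g2 <- max(0, (s_rare / C) * sum(seq_len(10) * (seq_len(10) - 1) * fi) /
                (n_rare * (n_rare - 1)) - 1)
    ace <- s_abund + s_rare / C + (f1 / C) * g2
  }

  p <- x / N
  shannon <- -sum(p * log(p))
  simpson <- if (N > 1) sum(x * (x - 1)) / (N * (N - 1)) else 1

  data.frame(sample_id = if (is.null(id)) NA_character_ else id,
             observed_features = s_obs, chao1 = chao1, ace = ace,
             shannon = shannon, simpson = simpson,
             simpson_complement = 1 - simpson,
             stringsAsFactors = FALSE)
}

#' Rarefy a count table to an even depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads.
#' Samples with fewer reads than `depth` are dropped with a message.
#'
#' @param counts a [count_table()].
#' @param depth target depth (> 0).
#' @param seed integer seed for reproducibility.
#' @return A rarefied [count_table()]; every column sums to `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  if (depth <= 0) stop("rarefaction depth must be positive")
  tot <- colSums(counts)
  drop <- tot < depth
  if (all(drop)) stop("no sample reaches depth ", depth)
  if (any(drop))
    message("rarefy: dropping ", sum(drop), " sample(s) below depth ", depth,
            ": ", paste(colnames(counts)[drop], collapse = ", "))
  kept <- counts[, !drop, drop = FALSE]
  set.seed(seed)
  out <- apply(kept, 2, function(x) rarefy_vector(x, depth))
  rownames(out) <- rownames(kept)
  count_table(out)
}

rarefy_vector <- function(x, depth) {
  N <- sum(x)
  if (N == depth) return(as.integer(x))
  pool <- rep.int(seq_along(x), x)
  tabulate(sample(pool, depth), nbins = length(x))
}

#' Rarefaction curve: mean observed richness versus subsampling depth
#'
#' @param counts a [count_table()].
#' @param depths increasing grid of depths; entries exceeding a sample's
#'   total are truncated for that sample (with a warning).
#' @param replicates random subsamples averaged per depth.
#' @param seed integer seed.
#' @return data frame `sample_id`, `depth`, `mean_observed`; per sample the
#'   curve is monotone non-decreasing in depth.
#' @export
rarefaction_curve <- function(counts, depths, replicates = 10, seed = 1L) {
  if (is.unsorted(depths, strictly = FALSE)) stop("depth grid must be increasing")
  if (any(depths <= 0)) stop("depths must be positive")
  set.seed(seed)
  out <- list()
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]; N <- sum(x)
    dj <- depths[depths <= N]
    if (length(dj) < length(depths))
      warning("depth grid truncated at sample total (", colnames(counts)[j],
              ": ", N, " reads)")
    mo <- vapply(dj, function(d) {
      if (d == N) return(as.numeric(sum(x > 0)))
      mean(vapply(seq_len(replicates),
                  function(i) sum(rarefy_vector(x, d) > 0), numeric(1)))
    }, numeric(1))
    out[[j]] <- data.frame(sample_id = colnames(counts)[j], depth = dj,
                           mean_observed = mo, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expected rarefied richness (hypergeometric closed form)
#'
#' E[S] = sum_i (1 - choose(N - n_i, d) / choose(N, d)): the expected number
#' of features observed when subsampling d of N reads without replacement.
#'
#' @param x count vector.
#' @param depth subsample size d.
#' @return expected richness (real).
#' @export
expected_rarefied_richness <- function(x, depth) {
  x <- x[x > 0]; N <- sum(x)
  if (depth > N) stop("depth exceeds sample total")
  # lchoose for numeric stability at sequencing-scale N
  sum(1 - exp(lchoose(N - x, depth) - lchoose(N, depth)))
}
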