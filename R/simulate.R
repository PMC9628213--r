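#' Configuration for the synthetic ASV-data generator
#'
#' Defaults emulate the shape of a two-arm 16S case-control cohort: 27
#' samples per group, 976 ASVs, per-sample sequencing depths uniform on
#' 35,925-120,795 reads, a small minority of ASVs carrying planted
#' case-vs-control fold changes, and clinical covariates rank-correlated
#' with chosen ASVs.
#'
#' @param n_per_group samples per group (two groups: `"case"`, `"control"`).
#' @param n_features number of ASVs.
#' @param depth_range integer `(min, max)`; per-sample read depth is drawn
#'   uniformly on this range.
#' @param n_differential number of ASVs with a planted group effect.
#' @param fold_changes positive fold changes applied to the differential
#'   ASVs in the case group (recycled to `n_differential`).
#' @param overdispersion Dirichlet concentration scale `theta`; per-sample
#'   compositions are Dirichlet(`theta` x composition), so smaller values
#'   mean noisier samples. The default 200 gives the moderate biological
#'   overdispersion typical of stool 16S profiles.
#' @param baseline_sdlog log-normal sd of the baseline composition; 2 gives
#'   the strongly skewed rank-abundance curve of real gut communities.
#' @param differential_quantile differential ASVs are drawn from features
#'   whose baseline relative abundance is at or above this quantile, so the
#'   planted markers are detectable taxa rather than singletons.
#' @param covariate_links list of `list(feature =, covariate =, rho =)`
#'   entries; each adds a numeric covariate whose Spearman correlation with
#'   the feature's relative abundance targets `rho` (|rho| < 1), generated
#'   through a Gaussian copula. `feature` may be an index (resolved among
#'   the differential features first) or a feature ID.
#' @param seed integer seed; the same config and seed give bit-identical
#'   output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = 27L,
                             n_features = 976L,
                             depth_range = c(35925L, 120795L),
                             n_differential = 5L,
                             fold_changes = 4,
                             overdispersion = 200,
                             baseline_sdlog = 2,
                             differential_quantile = 0.75,
                             covariate_links = NULL,
                             seed = 1L) {
  stopifnot(n_per_group >= 1, n_features >= 1,
            length(depth_range) == 2, depth_range[1] <= depth_range[2],
            n_differential >= 0, n_differential <= n_features,
            all(fold_changes > 0), overdispersion > 0)
  if (n_differential > 0)
    fold_changes <- rep_len(fold_changes, n_differential)
  else fold_changes <- numeric(0)
  for (lk in covariate_links) {
    if (is.null(lk$rho) || abs(lk$rho) >= 1)
      stop("covariate link strength must satisfy |rho| < 1")
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    n_features = as.integer(n_features),
    depth_range = as.integer(depth_range),
    n_differential = as.integer(n_differential),
    fold_changes = fold_changes,
    overdispersion = overdispersion,
    baseline_sdlog = baseline_sdlog,
    differential_quantile = differential_quantile,
    covariate_links = covariate_links,
    seed = as.integer(seed)), class = "synthetic_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Simulate a complete synthetic ASV dataset with ground truth
#'
#' Baseline composition is drawn log-normally and normalised; the case-group
#' composition multiplies the differential features by their fold changes and
#' renormalises (so other features shift only through renormalisation).
#' Per-sample counts are Dirichlet-multinomial: composition ~
#' Dirichlet(theta x group composition), counts ~ Multinomial(depth,
#' composition) with depth uniform on `depth_range`. A random bifurcating
#' tree with exponential branch lengths and a nested random taxonomy
#' (geometric genus sizes) are attached. Numeric covariates are generated
#' via a Gaussian copula on the normal scores of the linked feature's
#' relative abundance, using the classical calibration
#' r = 2 sin(pi rho_S / 6) to hit the requested Spearman strength.
#'
#' @param config a [synthetic_config()].
#' @return list with `counts` ([count_table()]), `taxonomy`
#'   (`taxonomy_table`), `metadata` (data frame: `sample_id`, `group`,
#'   covariates), `tree` (`phylo`), `truth` (list: `differential` data frame
#'   of feature/fold change/baseline, `baseline` named vector,
#'   `covariate_links`, `seed`).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  p <- config$n_features
  feature_ids <- sprintf("ASV%04d", seq_len(p))

  base <- stats::rlnorm(p, meanlog = 0, sdlog = config$baseline_sdlog)
  base <- base / sum(base)
  names(base) <- feature_ids

  if (config$n_differential > 0) {
    eligible <- which(base >= stats::quantile(base, config$differential_quantile))
    if (length(eligible) < config$n_differential)
      eligible <- order(base, decreasing = TRUE)[seq_len(config$n_differential)]
    diff_idx <- sort(sample(eligible, config$n_differential))
  } else diff_idx <- integer(0)

  case <- base
  case[diff_idx] <- case[diff_idx] * config$fold_changes
  case <- case / sum(case)

  n <- config$n_per_group
  sample_ids <- c(sprintf("CASE%02d", seq_len(n)), sprintf("CTRL%02d", seq_len(n)))
  group <- rep(c("case", "control"), each = n)
  comps <- list(case = case, control = base)

  depths <- sample(seq(config$depth_range[1], config$depth_range[2]), 2 * n,
                   replace = TRUE)
  counts <- matrix(0L, nrow = p, ncol = 2 * n,
                   dimnames = list(feature_ids, sample_ids))
  for (j in seq_len(2 * n)) {
    pi_j <- rdirichlet1(config$overdispersion * comps[[group[j]]])
    counts[, j] <- stats::rmultinom(1, size = depths[j], prob = pi_j)[, 1]
  }
  # guard the count_table invariant of positive per-sample totals
  counts <- count_table(counts)

  tree <- ape::rtree(p, tip.label = sample(feature_ids),
                     br = function(k) stats::rexp(k, rate = 10))

  taxonomy <- random_taxonomy(feature_ids)

  rel <- sweep(counts, 2, colSums(counts), "/")
  metadata <- data.frame(sample_id = sample_ids, group = group,
                         stringsAsFactors = FALSE)
  links <- config$covariate_links
  link_rows <- list()
  for (lk in links) {
    fid <- lk$feature
    if (is.numeric(fid)) {
      fid <- if (fid <= length(diff_idx)) feature_ids[diff_idx[fid]] else feature_ids[fid]
    }
    if (!fid %in% feature_ids) stop("covariate link references unknown feature ", fid)
    r_pearson <- 2 * sin(pi * lk$rho / 6)
    z <- stats::qnorm(rank(rel[fid, ], ties.method = "average") / (2 * n + 1))
    cov_val <- r_pearson * z + sqrt(1 - r_pearson^2) * stats::rnorm(2 * n)
    metadata[[lk$covariate]] <- cov_val
    link_rows[[length(link_rows) + 1]] <-
      data.frame(feature_id = fid, covariate = lk$covariate,
                 target_spearman = lk$rho, stringsAsFactors = FALSE)
  }
  link_tab <- if (length(link_rows)) do.call(rbind, link_rows) else
    data.frame(feature_id = character(0), covariate = character(0),
               target_spearman = numeric(0))

  truth <- list(
    differential = data.frame(
      feature_id = feature_ids[diff_idx],
      fold_change = config$fold_changes,
      baseline = unname(base[diff_idx]),
      stringsAsFactors = FALSE),
    baseline = base,
    covariate_links = link_tab,
    seed = config$seed)

  list(counts = counts, taxonomy = taxonomy, metadata = metadata,
       tree = tree, truth = truth)
}

#' Simulate a null dataset (no group effect)
#'
#' Both groups are drawn from the identical composition; the truth table is
#' empty. Used to verify false-positive control of the downstream tests.
#'
#' @param config a [synthetic_config()]; its `n_differential` is forced to 0.
#' @return As [simulate_dataset()].
#' @export
simulate_null <- function(config = synthetic_config()) {
  config$n_differential <- 0L
  config$fold_changes <- numeric(0)
  simulate_dataset(config)
}

# Nested random taxonomy: features partitioned into genera with geometric
# sizes, genera into families, families into orders, orders into classes,
# classes into phyla; species left unclassified (typical of 16S V3-V4).
random_taxonomy <- function(feature_ids) {
  p <- length(feature_ids)
  geom_partition <- function(n_items, mean_size) {
    sizes <- integer(0)
    while (sum(sizes) < n_items)
      sizes <- c(sizes, 1L + stats::rgeom(1, prob = 1 / mean_size))
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_items)
    rep(seq_along(sizes), times = sizes)
  }
  genus  <- geom_partition(p, mean_size = 4)
  family <- geom_partition(max(genus), mean_size = 3)[genus]
  ord    <- geom_partition(max(family), mean_size = 3)[family]
  klass  <- geom_partition(max(ord), mean_size = 2)[ord]
  phylum <- geom_partition(max(klass), mean_size = 3)[klass]
  taxonomy_table(data.frame(
    feature_id = feature_ids,
    kingdom = "k__Bacteria",
    phylum = sprintf("p__Phylum_%03d", phylum),
    class = sprintf("c__Class_%03d", klass),
    order = sprintf("o__Order_%03d", ord),
    family = sprintf("f__Family_%03d", family),
    genus = sprintf("g__Genus_%03d", genus),
    species = NA_character_,
    stringsAsFactors = FALSE))
}

#' Write a simulated dataset to a directory
#'
#' Emits `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `tree.nwk` and
#' `truth.json`.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  truth <- dataset$truth
  truth$baseline <- as.list(truth$baseline)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
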