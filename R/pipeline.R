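#' Default pipeline configuration
#'
#' @param counts,taxonomy,metadata,tree input file paths (tree optional).
#' @param group_column metadata column holding the case/control label.
#' @param disease label value treated as the disease class (default: first
#'   observed).
#' @param out_dir output directory.
#' @param stages subset of
#'   `c("alpha", "beta", "compare", "venn", "lefse", "correlate", "markers")`
#'   to run (default all).
#' @param beta_metric distance for ordination and permutation tests.
#' @param rank taxonomic rank for the comparison and LEfSe stages (`"asv"`
#'   for no aggregation).
#' @param covariates metadata columns used in the Spearman stage (default:
#'   all numeric columns).
#' @param subgroups list of `list(column =, levels = NULL)` metadata
#'   filters; each subgroup re-runs the comparison + LEfSe (and optionally
#'   marker) stages on that sample subset.
#' @param alpha,lda_threshold,p_threshold,abundance_threshold thresholds.
#' @param n_permutations permutation count for PERMANOVA/ANOSIM.
#' @param n_trees,k,n_repeats forest and CV settings.
#' @param rarefy_depth optional even depth applied before the diversity
#'   stages (default `NULL`: no rarefaction).
#' @param subgroup_markers also fit the marker model within each subgroup.
#' @param seed integer seed covering every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(counts, metadata, group_column,
                       taxonomy = NULL, tree = NULL,
                       disease = NULL, out_dir = "gutmarker_out",
                       stages = c("alpha", "beta", "compare", "venn",
                                  "lefse", "correlate", "markers"),
                       beta_metric = "jaccard_binary", rank = "genus",
                       covariates = NULL, subgroups = list(),
                       alpha = 0.05, lda_threshold = 2.5,
                       p_threshold = 0.05, abundance_threshold = 0.001,
                       n_permutations = 10000, n_trees = 500, k = 5,
                       n_repeats = 5, rarefy_depth = NULL,
                       subgroup_markers = FALSE, seed = 1L) {
  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy,
                 tree = tree, group_column = group_column, disease = disease,
                 out_dir = out_dir, stages = stages,
                 beta_metric = beta_metric, rank = rank,
                 covariates = covariates, subgroups = subgroups,
                 alpha = alpha, lda_threshold = lda_threshold,
                 p_threshold = p_threshold,
                 abundance_threshold = abundance_threshold,
                 n_permutations = n_permutations, n_trees = n_trees,
                 k = k, n_repeats = n_repeats, rarefy_depth = rarefy_depth,
                 subgroup_markers = subgroup_markers,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full case-control analysis pipeline
#'
#' Executes the enabled stages in order — alpha diversity, beta
#' diversity/ordination with PERMANOVA and ANOSIM, Venn partition,
#' rank-level group comparison, LEfSe, Spearman correlation map, and the
#' random-forest marker model — then repeats the comparison/LEfSe (and
#' optionally marker) stages inside each configured metadata subgroup.
#' Subgroup levels with fewer than 3 samples are skipped with a warning.
#' Every output file is a TSV under `out_dir`; `manifest.json` records the
#' configuration, seeds, input hashes and per-file MD5 hashes, so a run is
#' reproducible hash-for-hash from its manifest.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @return list with the in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  counts <- if (is.character(config$counts)) read_count_table(config$counts)
            else config$counts
  metadata <- if (is.character(config$metadata))
    read_sample_metadata(config$metadata, config$group_column)
  else config$metadata
  taxonomy <- if (is.character(config$taxonomy)) read_taxonomy(config$taxonomy)
              else config$taxonomy
  tree <- if (is.character(config$tree)) read_tree(config$tree)
          else config$tree

  al <- align_tables(counts, metadata, taxonomy, tree)
  counts <- al$counts; metadata <- al$metadata
  taxonomy <- al$taxonomy; tree <- al$tree
  groups <- as.character(metadata[[config$group_column]])
  disease <- if (is.null(config$disease)) unique(groups)[1] else config$disease

  if (!is.null(config$rarefy_depth))
    counts <- rarefy(counts, config$rarefy_depth, seed = config$seed)

  results <- list()
  outputs <- character(0)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  stage_table <- function(obj, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_tsv(obj, path)
    outputs <<- c(outputs, path)
  }

  if ("alpha" %in% config$stages) {
    results$alpha <- alpha_diversity(counts)
    stage_table(results$alpha, "alpha_diversity")
    say("alpha: ", ncol(counts), " samples")
  }

  if ("beta" %in% config$stages) {
    d <- beta_distance(counts, config$beta_metric, tree = tree)
    ord <- pcoa(d)
    results$beta <- list(
      distance = d, ordination = ord,
      permanova = permanova(d, groups, config$n_permutations,
                            seed = config$seed),
      anosim = anosim(d, groups, config$n_permutations, seed = config$seed))
    coords <- data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates[, seq_len(min(2, ncol(ord$coordinates))),
                                         drop = FALSE])
    stage_table(coords, "pcoa_coordinates")
    stage_table(data.frame(
      test = c("permanova", "anosim"),
      statistic = c(results$beta$permanova$statistic,
                    results$beta$anosim$statistic),
      p_value = c(results$beta$permanova$p_value,
                  results$beta$anosim$p_value),
      n_permutations = c(results$beta$permanova$n_permutations,
                         results$beta$anosim$n_permutations)),
      "permutation_tests")
    say("beta: ", config$beta_metric, ", PERMANOVA p = ",
        signif(results$beta$permanova$p_value, 4))
  }

  if ("venn" %in% config$stages) {
    v <- venn_partition(counts, groups)
    results$venn <- v
    stage_table(data.frame(compartment = c("shared", names(v$unique), "total"),
                           n_features = c(v$shared, unname(v$unique),
                                          v$total_detected)),
                "venn_partition")
  }

  rank_table <- function() {
    if (identical(config$rank, "asv") || is.null(taxonomy)) counts
    else aggregate_taxa(counts, taxonomy, config$rank)
  }

  if ("compare" %in% config$stages) {
    tab <- rank_table()
    results$compare <- group_compare(tab, groups)
    stage_table(results$compare, "group_comparison")
    say("compare: ", sum(results$compare$p_value < 0.05), " taxa at p < 0.05")
  }

  if ("lefse" %in% config$stages) {
    tab <- rank_table()
    results$lefse <- lefse(tab, groups, alpha = config$alpha,
                           lda_threshold = config$lda_threshold,
                           seed = config$seed)
    stage_table(lefse_report(results$lefse), "lefse_hits")
    say("lefse: ", sum(results$lefse$pass), " passing taxa")
  }

  if ("correlate" %in% config$stages) {
    covs <- config$covariates
    if (is.null(covs)) {
      covs <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
    }
    if (length(covs)) {
      sig <- results$compare
      feats <- if (!is.null(sig)) sig$feature_id[sig$p_value < 0.05] else character(0)
      tab <- rank_table()
      if (length(feats) < 2) feats <- rownames(tab)
      rel <- relative_abundance(tab)[feats, , drop = FALSE]
      results$correlation <- spearman_map(rel, metadata[, covs, drop = FALSE])
      stage_table(results$correlation, "spearman_correlations")
    } else say("correlate: no numeric covariates; skipped")
  }

  if ("markers" %in% config$stages) {
    results$markers <- train_test_evaluate(
      counts, groups, disease = disease,
      p_threshold = config$p_threshold,
      abundance_threshold = config$abundance_threshold,
      k = config$k, n_repeats = config$n_repeats,
      n_trees = config$n_trees, seed = config$seed)
    mk <- results$markers
    stage_table(mk$candidates, "candidates")
    if (!is.null(mk$selection$cv_curve))
      stage_table(mk$selection$cv_curve, "cv_curve")
    stage_table(data.frame(rank = seq_along(mk$manifest$markers),
                           feature_id = mk$manifest$markers), "markers")
    stage_table(rbind(cbind(set = "train", mk$train_pod),
                      cbind(set = "test", mk$test_pod)), "pod")
    stage_table(data.frame(
      set = c("train", "test"),
      auc = c(mk$train_roc$auc, mk$test_roc$auc),
      ci_low = c(mk$train_roc$ci_low, mk$test_roc$ci_low),
      ci_high = c(mk$train_roc$ci_high, mk$test_roc$ci_high),
      p_value = c(mk$train_roc$p_value, mk$test_roc$p_value)), "roc")
    say("markers: ", length(mk$manifest$markers), " selected, test AUC = ",
        signif(mk$test_roc$auc, 4))
  }

  # subgroup analyses: pure metadata filters re-using the main operations
  results$subgroups <- list()
  for (sg in config$subgroups) {
    col <- sg$column
    if (!col %in% names(metadata)) {
      warning("subgroup column '", col, "' not in metadata; skipped")
      next
    }
    labels <- as.character(metadata[[col]])
    keep <- !is.na(labels)
    if (!is.null(sg$levels)) keep <- keep & labels %in% sg$levels
    lev_tab <- table(labels[keep])
    if (length(lev_tab) < 2 || any(lev_tab < 3)) {
      warning("subgroup '", col, "': a level has < 3 samples; skipped")
      say("subgroup ", col, ": skipped (level with < 3 samples)")
      next
    }
    sub_counts <- count_table(counts[, keep, drop = FALSE])
    sub_labels <- labels[keep]
    tab <- if (identical(config$rank, "asv") || is.null(taxonomy)) sub_counts
           else aggregate_taxa(sub_counts, taxonomy, config$rank)
    sub <- list(
      compare = group_compare(tab, sub_labels),
      lefse = lefse(tab, sub_labels, alpha = config$alpha,
                    lda_threshold = config$lda_threshold, seed = config$seed))
    stage_table(sub$compare, paste0("subgroup_", col, "_comparison"))
    stage_table(lefse_report(sub$lefse), paste0("subgroup_", col, "_lefse"))
    if (isTRUE(config$subgroup_markers) && length(lev_tab) == 2) {
      sub$markers <- tryCatch(
        train_test_evaluate(sub_counts, sub_labels,
                            p_threshold = config$p_threshold,
                            abundance_threshold = config$abundance_threshold,
                            k = min(config$k, min(lev_tab)),
                            n_repeats = config$n_repeats,
                            n_trees = config$n_trees, seed = config$seed),
        error = function(e) {
          say("subgroup ", col, " markers: skipped (", conditionMessage(e), ")")
          NULL
        })
      if (!is.null(sub$markers))
        stage_table(data.frame(rank = seq_along(sub$markers$manifest$markers),
                               feature_id = sub$markers$manifest$markers),
                    paste0("subgroup_", col, "_markers"))
    }
    results$subgroups[[col]] <- sub
    say("subgroup ", col, ": ", sum(sub$lefse$pass), " LEfSe hits")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gutmarker")),
    config = config[setdiff(names(config), c("counts", "metadata",
                                             "taxonomy", "tree"))],
    inputs = list(
      counts = if (is.character(config$counts))
        unname(tools::md5sum(config$counts)) else "in-memory",
      n_features = nrow(counts), n_samples = ncol(counts)),
    log = log,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Human-readable summary of a pipeline run directory
#'
#' @param dir a completed [run_pipeline()] output directory.
#' @return character vector of markdown lines (also returned invisibly by
#'   writing `report.md` into `dir`).
#' @export
pipeline_report <- function(dir) {
  lines <- c("# gutmarker run report", "")
  grab <- function(name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    if (file.exists(p)) utils::read.delim(p, check.names = FALSE) else NULL
  }
  fmt <- function(df, max_rows = 10) {
    df <- utils::head(df, max_rows)
    c(paste(colnames(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(trimws(format(r, digits = 4)),
                                     collapse = " | ")))
  }
  section <- function(title, name, max_rows = 10) {
    df <- grab(name)
    if (is.null(df)) c(paste0("## ", title), "", "_absent_", "")
    else c(paste0("## ", title), "", fmt(df, max_rows), "")
  }
  lines <- c(lines,
             section("Alpha diversity", "alpha_diversity"),
             section("Community-level tests", "permutation_tests"),
             section("Venn partition", "venn_partition"),
             section("Top differential taxa", "group_comparison"),
             section("LEfSe hits", "lefse_hits"),
             section("Selected markers", "markers"),
             section("ROC / AUC", "roc"))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(lines)
}
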