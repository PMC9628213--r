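#' Construct a count table
#'
#' The central data object of the package: an integer matrix of ASV (or
#' taxon) counts with features as rows and samples as columns.
#'
#' @param counts numeric matrix of non-negative integers, features x samples,
#'   with unique rownames (feature IDs) and colnames (sample IDs).
#' @return An integer matrix of class `count_table`.
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs feature rownames and sample colnames")
  validate_count_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(counts))
  counts
}

#' @export
as.matrix.count_table <- function(x, ...) {
  class(x) <- setdiff(class(x), "count_table")
  x
}

validate_count_table <- function(counts) {
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("count table contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at feature '", rownames(counts)[bad[1]],
         "', sample '", colnames(counts)[bad[2]], "'")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count at feature '", rownames(counts)[bad[1]],
         "', sample '", colnames(counts)[bad[2]], "'")
  }
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  invisible(counts)
}

#' Read a feature-by-sample count table from TSV
#'
#' Expects the common ASV-table export layout: first column feature IDs,
#' header row sample IDs, integer cells.
#'
#' @param path path to a tab-separated file.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a feature-ID column and >=1 sample column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(df[, -1, drop = FALSE], is.numeric, logical(1))]
    stop("non-numeric cells in sample column(s): ", paste(bad, collapse = ", "))
  }
  rownames(m) <- ids
  count_table(m)
}

#' Write a count table to TSV
#'
#' @param counts a [count_table()].
#' @param path output path.
#' @param id_column header name for the feature-ID column.
#' @export
write_count_table <- function(counts, path, id_column = "feature_id") {
  df <- data.frame(rownames(counts), as.matrix(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Canonical rank order, coarse to fine.
TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")
RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Sentinel label for a feature unclassified at a rank
#'
#' Uses the rank-prefixed literal (e.g. `"g__unclassified"`) so that
#' aggregation at genus level groups all unassigned features of the same
#' parent lineage together, mirroring the `Enterobacteriaceae_unclassified`
#' style of SILVA-annotated tables.
#'
#' @param rank one of the seven taxonomic ranks.
#' @return character sentinel.
#' @export
unclassified_label <- function(rank) {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  paste0(RANK_PREFIXES[[rank]], "unclassified")
}

#' Read per-feature taxonomy assignments from TSV
#'
#' Accepts either the two-column layout `feature_id <tab> k__...;p__...;...`
#' (semicolon-joined lineage) or an eight-column layout with one column per
#' rank. Missing or empty ranks become the [unclassified_label()] sentinel.
#'
#' @param path path to a tab-separated file.
#' @return A `taxonomy_table` data frame: `feature_id` plus the 7 rank
#'   columns, ordered coarse to fine.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 2) {
    lin <- strsplit(as.character(df[[2]]), ";", fixed = TRUE)
    m <- t(vapply(lin, function(x) {
      x <- trimws(x)
      length(x) <- 7L
      x
    }, character(7)))
    colnames(m) <- TAXONOMIC_RANKS
    tax <- data.frame(feature_id = as.character(df[[1]]), m,
                      stringsAsFactors = FALSE)
  } else if (ncol(df) == 8) {
    colnames(df) <- c("feature_id", TAXONOMIC_RANKS)
    df$feature_id <- as.character(df$feature_id)
    tax <- df
  } else {
    stop("taxonomy file must have 2 columns (id + lineage string) or 8 columns")
  }
  taxonomy_table(tax)
}

#' Construct a taxonomy table
#'
#' @param tax data frame with a `feature_id` column and the 7 rank columns
#'   (missing ranks allowed; filled with the unclassified sentinel).
#' @return A `taxonomy_table` data frame.
#' @export
taxonomy_table <- function(tax) {
  if (!"feature_id" %in% colnames(tax)) stop("taxonomy needs a feature_id column")
  if (anyDuplicated(tax$feature_id))
    stop("duplicate feature IDs in taxonomy: ",
         paste(unique(tax$feature_id[duplicated(tax$feature_id)]), collapse = ", "))
  for (r in TAXONOMIC_RANKS) {
    if (!r %in% colnames(tax)) tax[[r]] <- NA_character_
    v <- trimws(as.character(tax[[r]]))
    empty <- is.na(v) | v == "" | v == RANK_PREFIXES[[r]]
    v[empty] <- unclassified_label(r)
    tax[[r]] <- v
  }
  tax <- tax[, c("feature_id", TAXONOMIC_RANKS)]
  rownames(tax) <- NULL
  class(tax) <- c("taxonomy_table", "data.frame")
  tax
}

#' Write a taxonomy table to TSV (semicolon-joined lineage layout)
#'
#' @param tax a `taxonomy_table`.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  lineage <- apply(as.matrix(tax[, TAXONOMIC_RANKS]), 1, paste, collapse = ";")
  utils::write.table(
    data.frame(feature_id = tax$feature_id, lineage = lineage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path path to a tab-separated file; first column sample IDs.
#' @param group_column name of the categorical group-label column (checked
#'   to exist when given).
#' @return A data frame with a `sample_id` column; remaining columns are
#'   clinical covariates and group labels. Missing values allowed.
#' @export
read_sample_metadata <- function(path, group_column = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  colnames(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.null(group_column) && !group_column %in% colnames(df))
    stop("group column '", group_column, "' not found in metadata")
  df
}

#' Read a phylogenetic tree from Newick
#'
#' UniFrac needs a rooted tree; unrooted input is midpoint-rooted.
#' Negative branch lengths are rejected.
#'
#' @param path path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object, rooted.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree from ", path)
  prepare_tree(tree)
}

prepare_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree
}

check_tree_covers <- function(tree, feature_ids) {
  missing <- setdiff(feature_ids, tree$tip.label)
  if (length(missing))
    stop("tree is missing ", length(missing), " feature(s): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ..." else "")
  invisible(TRUE)
}

#' Align counts, metadata, taxonomy and tree to a consistent sample/feature set
#'
#' Restricts the count table and metadata to their shared sample IDs (in
#' count-table order) and checks that taxonomy and tree cover every feature.
#' Drops are reported via `message()`.
#'
#' @param counts a [count_table()].
#' @param metadata sample metadata data frame with a `sample_id` column.
#' @param taxonomy optional `taxonomy_table`.
#' @param tree optional rooted `phylo` covering all features.
#' @return list with elements `counts`, `metadata`, `taxonomy`, `tree`,
#'   `dropped` (list of dropped sample IDs per input).
#' @export
align_tables <- function(counts, metadata, taxonomy = NULL, tree = NULL) {
  shared <- intersect(colnames(counts), metadata$sample_id)
  if (length(shared) == 0)
    stop("no shared sample IDs between counts and metadata")
  dropped <- list(
    counts_samples  = setdiff(colnames(counts), shared),
    metadata_samples = setdiff(metadata$sample_id, shared))
  if (length(dropped$counts_samples))
    message("align: dropping ", length(dropped$counts_samples),
            " count-table sample(s) absent from metadata")
  if (length(dropped$metadata_samples))
    message("align: dropping ", length(dropped$metadata_samples),
            " metadata sample(s) absent from counts")
  counts <- counts[, shared, drop = FALSE]
  keep <- rowSums(counts) >= 0  # features kept; order preserved
  counts <- count_table(counts[keep, , drop = FALSE])
  metadata <- metadata[match(shared, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!is.null(taxonomy)) {
    missing <- setdiff(rownames(counts), taxonomy$feature_id)
    if (length(missing))
      stop("taxonomy missing ", length(missing), " feature(s): ",
           paste(utils::head(missing, 10), collapse = ", "))
    taxonomy <- taxonomy[taxonomy$feature_id %in% rownames(counts), , drop = FALSE]
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$feature_id), , drop = FALSE]
    rownames(taxonomy) <- NULL
    class(taxonomy) <- c("taxonomy_table", "data.frame")
  }
  if (!is.null(tree)) check_tree_covers(tree, rownames(counts))
  list(counts = counts, metadata = metadata, taxonomy = taxonomy,
       tree = tree, dropped = dropped)
}
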