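#' Beta-diversity distance matrix between samples
#'
#' Implements the four dissimilarities used throughout the package:
#' \itemize{
#'   \item `bray_curtis`: 1 - 2 sum min(x_i, y_i) / (sum x_i + sum y_i);
#'   \item `jaccard_binary`: 1 - |A intersect B| / |A union B| on presence
#'     sets;
#'   \item `unweighted_unifrac`: unshared branch length divided by the total
#'     branch length spanned by either sample;
#'   \item `weighted_unifrac`: sum b_e |p_e^A - p_e^B| over branches, with
#'     p_e the proportion of a sample's reads descending from branch e;
#'     normalised by sum b_e (p_e^A + p_e^B) by default (`normalized =
#'     FALSE` gives the raw variant).
#' }
#' All four lie in `[0, 1]` (raw weighted UniFrac is unbounded), vanish on
#' identical samples, and are symmetric.
#'
#' @param counts a [count_table()].
#' @param metric one of `"bray_curtis"`, `"jaccard_binary"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`.
#' @param tree rooted `phylo` covering every feature with a nonzero count;
#'   required for the UniFrac metrics.
#' @param normalized for `weighted_unifrac`: divide by the total
#'   abundance-weighted branch length (default TRUE).
#' @return A symmetric, zero-diagonal `dist`-like matrix (plain matrix with
#'   sample IDs as dimnames).
#' @export
beta_distance <- function(counts,
                          metric = c("bray_curtis", "jaccard_binary",
                                     "unweighted_unifrac", "weighted_unifrac"),
                          tree = NULL, normalized = TRUE) {
  metric <- match.arg(metric)
  m <- as.matrix(counts)
  n <- ncol(m)
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac")) {
    if (is.null(tree)) stop("UniFrac metrics require a phylogenetic tree")
    return(unifrac_distance(m, tree, weighted = metric == "weighted_unifrac",
                            normalized = normalized))
  }
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  if (metric == "bray_curtis") {
    tot <- colSums(m)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        1 - 2 * sum(pmin(m[, i], m[, j])) / (tot[i] + tot[j])
    }
  } else {
    pres <- m > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- sum(pres[, i] & pres[, j])
      u <- sum(pres[, i] | pres[, j])
      d[i, j] <- d[j, i] <- if (u == 0) 0 else 1 - a / u
    }
  }
  d
}

# Per-edge descendant-tip mass for every sample, by postorder accumulation.
# Returns list(branch lengths, edges x samples matrix of subtended totals).
edge_sample_mass <- function(m, tree) {
  check_tree_covers(tree, rownames(m)[rowSums(m) > 0])
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  node_mass <- matrix(0, n_node, ncol(m))
  present <- intersect(tree$tip.label, rownames(m))
  node_mass[match(present, tree$tip.label), ] <- m[present, , drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    node_mass[parent, ] <- node_mass[parent, ] + node_mass[child, ]
  }
  list(b = tree$edge.length, mass = node_mass[tree$edge[, 2], , drop = FALSE])
}

unifrac_distance <- function(m, tree, weighted, normalized = TRUE) {
  es <- edge_sample_mass(m, tree)
  b <- es$b
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  if (weighted) {
    p <- sweep(es$mass, 2, colSums(m), "/")
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(b * abs(p[, i] - p[, j]))
      if (normalized) {
        den <- sum(b * (p[, i] + p[, j]))
        d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
      } else d[i, j] <- d[j, i] <- num
    }
  } else {
    pres <- es$mass > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      either <- pres[, i] | pres[, j]
      both <- pres[, i] & pres[, j]
      den <- sum(b[either])
      d[i, j] <- d[j, i] <- if (den == 0) 0 else sum(b[either & !both]) / den
    }
  }
  d
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: eigendecomposition of the double-centred matrix
#' -1/2 J D^2 J. Coordinates are eigenvectors scaled by the square root of
#' their (positive) eigenvalues; negative eigenvalues are reported but carry
#' no coordinates. Variance explained is taken over the positive eigenvalues.
#'
#' @param d symmetric, zero-diagonal distance matrix.
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (non-increasing, full spectrum) and `explained` (proportion per
#'   positive axis).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  G <- -0.5 * (d^2)
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  pos <- which(ev > max(ev, 0) * 1e-10 & ev > 0)
  coords <- matrix(0, n, length(pos),
                   dimnames = list(rownames(d),
                                   if (length(pos)) paste0("PCo", seq_along(pos))))
  if (length(pos))
    coords[] <- eg$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(ev[pos]), length(pos))
  explained <- if (length(pos)) ev[pos] / sum(ev[pos]) else numeric(0)
  list(coordinates = coords, eigenvalues = ev, explained = explained)
}
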