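# Small in-code fixtures shared across tests.

toy_counts <- function() {
  count_table(matrix(
    c(3L, 0L, 5L,
      1L, 2L, 0L,
      4L, 4L, 4L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("ASV1", "ASV2", "ASV3"), c("S1", "S2", "S3"))))
}

toy_taxonomy <- function() {
  taxonomy_table(data.frame(
    feature_id = c("ASV1", "ASV2", "ASV3"),
    kingdom = "k__Bacteria",
    phylum = c("p__Firmicutes", "p__Firmicutes", "p__Bacteroidota"),
    class = c("c__Bacilli", "c__Bacilli", "c__Bacteroidia"),
    order = c("o__Lactobacillales", "o__Lactobacillales", "o__Bacteroidales"),
    family = c("f__Streptococcaceae", "f__Streptococcaceae", "f__Bacteroidaceae"),
    genus = c("g__Streptococcus", "g__Streptococcus", "g__Bacteroides"),
    species = NA_character_,
    stringsAsFactors = FALSE))
}

star_tree <- function(tips, brlen = 1) {
  ape::read.tree(text = paste0(
    "(", paste0(tips, ":", brlen, collapse = ","), "):0;"))
}

# tiny two-group dataset for fast end-to-end runs
small_config <- function(seed = 1L, n_differential = 3L, fold_changes = 6,
                         n_per_group = 10L) {
  synthetic_config(n_per_group = n_per_group, n_features = 80L,
                   depth_range = c(3000L, 6000L),
                   n_differential = n_differential,
                   fold_changes = fold_changes, seed = seed)
}

# exhaustive two-sided Mann-Whitney oracle by concordant-pair counting over
# every label assignment (independent of the implementation's rank route)
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  sel <- utils::combn(length(pooled), n1, simplify = FALSE)
  us <- vapply(sel, function(s) u_of(pooled[s], pooled[-s]), numeric(1))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
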