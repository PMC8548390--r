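#' Three-set Venn partition
#'
#' Exact counts of the seven regions of three DEP id sets, conventionally
#' A = parent-vs-parent, B = hybrid-vs-female, C = hybrid-vs-male.
#'
#' @param set_a,set_b,set_c character vectors of ids (duplicates ignored).
#' @return one-row tibble of class `venn_partition` with columns `only_a`,
#'   `only_b`, `only_c`, `ab`, `ac`, `bc`, `abc`.
#' @export
venn_partition <- function(set_a, set_b, set_c) {
  set_a <- unique(set_a); set_b <- unique(set_b); set_c <- unique(set_c)
  ids <- unique(c(set_a, set_b, set_c))
  in_a <- ids %in% set_a
  in_b <- ids %in% set_b
  in_c <- ids %in% set_c
  out <- tibble::tibble(
    only_a = sum(in_a & !in_b & !in_c),
    only_b = sum(!in_a & in_b & !in_c),
    only_c = sum(!in_a & !in_b & in_c),
    ab = sum(in_a & in_b & !in_c),
    ac = sum(in_a & !in_b & in_c),
    bc = sum(!in_a & in_b & in_c),
    abc = sum(in_a & in_b & in_c)
  )
  class(out) <- c("venn_partition", class(out))
  out
}

#' Shared fraction of two sets in a Venn partition
#'
#' Percentage of a denominator set occupied by a pairwise overlap
#' (pair-exclusive region plus the triple region), rounded half away from
#' zero to two decimals.
#'
#' @param region_counts a [venn_partition()] tibble.
#' @param pair two of `"a"`, `"b"`, `"c"` naming the overlapping sets.
#' @param denominator_set one of `"a"`, `"b"`, `"c"`.
#' @return numeric percentage.
#' @examples
#' vp <- tibble::tibble(only_a = 164, only_b = 0, only_c = 0,
#'                      ab = 63, ac = 23, bc = 0, abc = 4)
#' shared_fraction(vp, c("a", "c"), "a")  # (23 + 4) / 254 -> 10.63
#' @export
shared_fraction <- function(region_counts, pair, denominator_set) {
  stopifnot(length(pair) == 2, all(pair %in% c("a", "b", "c")),
            denominator_set %in% c("a", "b", "c"))
  rc <- region_counts
  pair_region <- paste(sort(pair), collapse = "")
  size_of <- function(s) {
    regions <- c(paste0("only_", s),
                 paste(sort(c(s, setdiff(c("a", "b", "c"), s)[1])), collapse = ""),
                 paste(sort(c(s, setdiff(c("a", "b", "c"), s)[2])), collapse = ""),
                 "abc")
    sum(unlist(rc[regions]))
  }
  denom <- size_of(denominator_set)
  if (denom == 0) .abort_value("denominator set is empty")
  percentage(rc[[pair_region]] + rc[["abc"]], denom, 2)
}

#' Term over-representation test
#'
#' One-sided hypergeometric over-representation test of each annotation
#' term in a DE protein set against a background set (the Fisher
#' construction used for GO enrichment), with Benjamini-Hochberg
#' adjustment across terms.
#'
#' @param term_map tibble with columns `protein_id`, `term_id` (one row
#'   per annotation).
#' @param de_ids differentially expressed protein ids; must be a subset of
#'   `background_ids`.
#' @param background_ids the background (typically all quantified
#'   proteins).
#' @return tibble sorted by `p_raw`: `term_id`, `k` (DE with term),
#'   `K` (background with term), `n` (DE size), `N` (background size),
#'   `p_raw`, `p_adj`.
#' @export
enrich_terms <- function(term_map, de_ids, background_ids) {
  de_ids <- unique(de_ids)
  background_ids <- unique(background_ids)
  stray <- setdiff(de_ids, background_ids)
  if (length(stray) > 0) {
    .abort_value(paste0("DE id(s) absent from background: ",
                        paste(stray, collapse = ", ")))
  }
  tm <- dplyr::distinct(
    dplyr::filter(term_map, .data$protein_id %in% background_ids))
  n <- length(de_ids)
  N <- length(background_ids)
  counts <- dplyr::summarise(
    dplyr::group_by(tm, .data$term_id),
    K = dplyr::n(),
    k = sum(.data$protein_id %in% de_ids),
    .groups = "drop")
  out <- dplyr::mutate(
    counts,
    n = n, N = N,
    p_raw = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                          lower.tail = FALSE),
    p_adj = bh_adjust(.data$p_raw)
  )
  dplyr::arrange(dplyr::select(out, "term_id", "k", "K", "n", "N",
                               "p_raw", "p_adj"),
                 .data$p_raw, .data$term_id)
}

#' Average-linkage hierarchical clustering of expression profiles
#'
#' UPGMA (unweighted average linkage) clustering on Euclidean distances
#' between protein rows, the standard configuration for DEP heat-map
#' dendrograms. Rows may optionally be z-scored first. Missing values are
#' rejected; filter with [filter_complete_cases()] beforehand.
#'
#' @param quant wide quantification tibble (`protein_id` + numeric sample
#'   columns), at least two rows.
#' @param standardize z-score each row before computing distances
#'   (default `FALSE`).
#' @return object of class `protein_dendrogram` wrapping the
#'   [stats::hclust()] fit; see [generics::tidy()] for the merge table and
#'   [dendrogram_newick()] for Newick export.
#' @export
cluster_rows <- function(quant, standardize = FALSE) {
  mat <- as.matrix(quant[-1])
  rownames(mat) <- quant$protein_id
  if (nrow(mat) < 2) .abort_value("need at least 2 rows to cluster")
  if (any(!is.finite(mat))) {
    .abort_value("missing values present; filter rows first (filter_complete_cases)")
  }
  if (standardize) {
    mat <- t(apply(mat, 1, function(x) {
      s <- sd(x)
      if (s == 0) x - mean(x) else (x - mean(x)) / s
    }))
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "average")
  structure(list(hclust = hc, ids = quant$protein_id),
            class = "protein_dendrogram")
}

#' @export
print.protein_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram over", length(x$ids), "rows;",
      length(x$hclust$height), "merges, max height",
      format(max(x$hclust$height), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.protein_dendrogram <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Merge table of a protein dendrogram
#'
#' @param x a `protein_dendrogram` from [cluster_rows()].
#' @param ... unused.
#' @return tibble with one row per merge: `merge1`, `merge2` (negative
#'   values are leaves, positive values earlier merges, as in
#'   [stats::hclust()]) and `height` (Euclidean distance units).
#' @method tidy protein_dendrogram
#' @export
tidy.protein_dendrogram <- function(x, ...) {
  tibble::tibble(
    merge1 = x$hclust$merge[, 1],
    merge2 = x$hclust$merge[, 2],
    height = x$hclust$height
  )
}

#' Export a dendrogram as a Newick string
#'
#' Converts the UPGMA tree to Newick with branch lengths derived from the
#' merge heights (ultrametric: each leaf sits at depth height/2 below its
#' merge). Requires the `ape` package.
#'
#' @param x a `protein_dendrogram` from [cluster_rows()].
#' @return a single Newick string.
#' @export
dendrogram_newick <- function(x) {
  stopifnot(inherits(x, "protein_dendrogram"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    .abort_value("Newick export requires the 'ape' package")
  }
  phy <- ape::as.phylo(x$hclust)
  ape::write.tree(phy)
}
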