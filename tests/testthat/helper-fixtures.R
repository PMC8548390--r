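# deterministic miniature trio fixtures and brute-force reference
# implementations used as independent oracles

make_trio_design <- function(n_rep = 3) {
  tibble::tibble(
    sample_id = paste0(rep(c("P1", "P2", "F1"), each = n_rep), "_r",
                       rep(seq_len(n_rep), 3)),
    genotype = rep(c("P1", "P2", "F1"), each = n_rep),
    role = rep(c("female_parent", "male_parent", "hybrid"), each = n_rep),
    replicate = rep(seq_len(n_rep), 3)
  )
}

# quant table with per-genotype means given as a named list of
# protein_id -> c(female, male, hybrid); exact values, no noise
make_trio_quant <- function(means, n_rep = 3) {
  design <- make_trio_design(n_rep)
  rows <- lapply(names(means), function(id) {
    v <- rep(means[[id]], each = n_rep)
    stats::setNames(as.list(c(id, v)), c("protein_id", design$sample_id))
  })
  quant <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  quant[-1] <- lapply(quant[-1], as.numeric)
  list(quant = quant, design = design)
}

# step-up BH written from the definition (sorted scale, tail cummin)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# O(n^3) UPGMA: cluster distance = mean of all inter-cluster pairwise
# original Euclidean distances
brute_upgma_heights <- function(mat) {
  d <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters <- c(clusters, list(merged))
  }
  heights
}

# exact upper-tail hypergeometric by enumeration of the support
hyper_tail_enum <- function(k, K, n, N) {
  support <- max(0, n - (N - K)):min(K, n)
  sum(vapply(support[support >= k], function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}
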