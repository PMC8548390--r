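test_that("venn partition performs exact set algebra", {
  vp <- venn_partition("x", "x", "x")
  expect_equal(vp$abc, 1)
  expect_equal(sum(unlist(vp)), 1)

  vp2 <- venn_partition(c("a1", "a2"), c("b1", "b2", "b3"),
                        c("c1", "c2", "c3", "c4"))
  expect_equal(unlist(vp2[c("only_a", "only_b", "only_c")]),
               c(only_a = 2, only_b = 3, only_c = 4))
  expect_equal(vp2$abc + vp2$ab + vp2$ac + vp2$bc, 0)

  # region sums reconstruct each set against brute-force membership
  set.seed(71)
  ids <- sprintf("id%03d", 1:100)
  for (i in 1:10) {
    A <- sample(ids, sample(0:60, 1))
    B <- sample(ids, sample(0:60, 1))
    C <- sample(ids, sample(0:60, 1))
    vp <- venn_partition(A, B, C)
    expect_equal(vp$only_a + vp$ab + vp$ac + vp$abc, length(A))
    expect_equal(vp$only_b + vp$ab + vp$bc + vp$abc, length(B))
    expect_equal(vp$only_c + vp$ac + vp$bc + vp$abc, length(C))
    expect_equal(sum(unlist(vp)), length(unique(c(A, B, C))))
  }
})

test_that("shared fractions reproduce the published overlap percentage", {
  vp <- tibble::tibble(only_a = 164, only_b = 0, only_c = 0,
                       ab = 63, ac = 23, bc = 0, abc = 4)
  # |A| = 164 + 63 + 23 + 4 = 254; (23 + 4) / 254 -> 10.63
  expect_equal(shared_fraction(vp, c("a", "c"), "a"), 10.63)

  empty_pair <- tibble::tibble(only_a = 10, only_b = 5, only_c = 5,
                               ab = 0, ac = 0, bc = 0, abc = 0)
  expect_equal(shared_fraction(empty_pair, c("a", "b"), "a"), 0)

  all_triple <- tibble::tibble(only_a = 0, only_b = 0, only_c = 0,
                               ab = 0, ac = 0, bc = 0, abc = 12)
  expect_equal(shared_fraction(all_triple, c("a", "c"), "a"), 100)

  none <- tibble::tibble(only_a = 0, only_b = 1, only_c = 1,
                         ab = 0, ac = 0, bc = 1, abc = 0)
  expect_error(shared_fraction(none, c("a", "b"), "a"),
               class = "heteroprot_value_error")
})

test_that("over-representation p-values are exact hypergeometric tails", {
  tm <- tibble::tibble(
    protein_id = c(paste0("p", 1:8), paste0("p", 1:4)),
    term_id = c(rep("T_all", 8), rep("T_sel", 4))
  )
  bg <- paste0("p", 1:8)
  de <- paste0("p", 1:4)
  res <- enrich_terms(tm, de, bg)
  # a term on every background protein can never be enriched
  expect_equal(res$p_raw[res$term_id == "T_all"], 1)
  # k=3 of the DE set of 4 carry a term on K=4 of N=8: P(X>=3) = 17/70
  tm2 <- tibble::tibble(protein_id = c("p1", "p2", "p3", "p5"),
                        term_id = "T")
  res2 <- enrich_terms(tm2, de, bg)
  expect_equal(res2$p_raw, 17 / 70, tolerance = 1e-12)

  # absent from the DE set: one-sided tail is 1
  tm3 <- tibble::tibble(protein_id = c("p5", "p6"), term_id = "T")
  expect_equal(enrich_terms(tm3, de, bg)$p_raw, 1)

  expect_error(enrich_terms(tm, c("p1", "zz"), bg),
               class = "heteroprot_value_error")
})

test_that("enrichment matches enumeration and fisher.test on random tables", {
  set.seed(81)
  for (i in 1:15) {
    N <- sample(6:20, 1)
    bg <- sprintf("g%02d", seq_len(N))
    de <- sample(bg, sample(2:(N - 1), 1))
    with_term <- sample(bg, sample(1:N, 1))
    tm <- tibble::tibble(protein_id = with_term, term_id = "T")
    res <- enrich_terms(tm, de, bg)
    k <- length(intersect(with_term, de))
    expect_equal(res$p_raw, hyper_tail_enum(k, length(with_term),
                                            length(de), N),
                 tolerance = 1e-10)
    ft <- stats::fisher.test(
      matrix(c(k, length(de) - k,
               length(with_term) - k,
               N - length(with_term) - length(de) + k), 2),
      alternative = "greater")
    expect_equal(res$p_raw, ft$p.value, tolerance = 1e-10)
  }
})

test_that("UPGMA clustering reproduces hand and brute-force references", {
  # two identical rows: single merge at height 0
  q2 <- tibble::tibble(protein_id = c("a", "b"),
                       s1 = c(1, 1), s2 = c(2, 2))
  dg2 <- cluster_rows(q2)
  expect_equal(tidy(dg2)$height, 0)

  # 1-D points at 0, 1, 5: merges at 1 then (4 + 5)/2 = 4.5
  q3 <- tibble::tibble(protein_id = c("x", "y", "z"), s1 = c(0, 1, 5))
  expect_equal(tidy(cluster_rows(q3))$height, c(1, 4.5))

  # brute-force O(n^3) UPGMA on random matrices
  set.seed(91)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    mat <- matrix(stats::rnorm(n * 4), n)
    q <- dplyr::bind_cols(tibble::tibble(protein_id = paste0("r", seq_len(n))),
                          tibble::as_tibble(mat, .name_repair = "minimal"))
    names(q)[-1] <- paste0("s", 1:4)
    dg <- cluster_rows(q)
    expect_equal(tidy(dg)$height, brute_upgma_heights(mat), tolerance = 1e-10)
    # heights are monotone non-decreasing (average linkage on a metric)
    expect_true(all(diff(tidy(dg)$height) >= -1e-12))
    # permutation invariance of the height sequence
    qp <- q[sample(n), ]
    expect_equal(tidy(cluster_rows(qp))$height, tidy(dg)$height,
                 tolerance = 1e-10)
  }

  expect_error(cluster_rows(q3[1, ]), class = "heteroprot_value_error")
  q_na <- q3
  q_na$s1[2] <- NA
  expect_error(cluster_rows(q_na), class = "heteroprot_value_error")
})

test_that("dendrograms export as ultrametric Newick trees", {
  q <- tibble::tibble(protein_id = c("x", "y", "z"), s1 = c(0, 1, 5))
  nwk <- dendrogram_newick(cluster_rows(q))
  expect_match(nwk, "^\\(.*\\);$")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("x", "y", "z"))
  # root-to-tip depth equals half the final merge height for every tip
  depths <- ape::node.depth.edgelength(phy)[seq_len(3)]
  expect_equal(depths, rep(4.5 / 2, 3), tolerance = 1e-10)
})
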