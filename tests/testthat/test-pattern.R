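test_that("the rule table assigns the worked single-protein examples", {
  # f1 at the mid-parent value is additive (ratio 1 inside the window)
  expect_equal(classify_protein(150, 100, 200)$label, "additive")

  # f1/HP = 2.0 clears the 1.65 cut: over-dominant up
  expect_equal(classify_protein(400, 100, 200)$label, "over_dominant_up")

  # f1/HP = 1.55 lands in [1.5, 1.65): dominant high-parent
  call_hp <- classify_protein(310, 100, 200)
  expect_equal(call_hp$label, "high_parent")
  expect_equal(call_hp$direction, "up")

  # literal reading, f1/HP = 0.58 with near-equal parents (f1/MP ~ 0.61):
  # under-dominant via the 0.603 cut
  p <- pattern_params(mode = "literal")
  call_ud <- classify_protein(0.58 * 1.10, 1, 1.10, p)
  expect_equal(call_ud$r_hp, 0.58, tolerance = 1e-12)
  expect_lt(call_ud$r_mp, 0.67)
  expect_equal(call_ud$label, "under_dominant")
  expect_equal(call_ud$direction, "down")

  # boundary: f1/HP exactly at the upper cut is over-dominant (closed on
  # that side). HP is a power of two so f1 = HP * cut and f1/HP = cut are
  # exact in floating point.
  cut <- 1.5 * (1 + 0.10)
  expect_equal(classify_protein(128 * cut, 64, 128)$label,
               "over_dominant_up")
  # with band = 0 the cut is exactly 1.5 and the dominant band vanishes
  expect_equal(classify_protein(300, 100, 200,
                                pattern_params(band = 0))$label,
               "over_dominant_up")
  # boundary: f1/MP exactly 1.5 leaves the additive window (open interval)
  expect_false(classify_protein(1.5 * 150, 100, 200)$label == "additive")

  expect_error(classify_protein(-1, 1, 1), class = "heteroprot_value_error")
})

test_that("rules are exhaustive, scale-invariant and parent-symmetric", {
  set.seed(61)
  n <- 20000
  f1 <- exp(stats::runif(n, -3, 3))
  p1 <- exp(stats::runif(n, -3, 3))
  p2 <- exp(stats::runif(n, -3, 3))
  for (mode in c("literal", "reconstructed")) {
    prm <- pattern_params(mode = mode)
    calls <- heteroprot:::.classify_vec(f1, p1, p2, prm)
    # exhaustive: every triple gets exactly one known label
    expect_false(anyNA(calls$label))
    expect_true(all(calls$label %in% c("additive", "over_dominant_up",
                                       "high_parent", "under_dominant",
                                       "low_parent", "partial_nonadditive")))
    # independent re-derivation of the ordered rule table
    hp <- pmax(p1, p2); lp <- pmin(p1, p2); mp <- (p1 + p2) / 2
    r_dn <- if (mode == "literal") f1 / hp else f1 / lp
    expected <- ifelse(f1 / mp > 0.67 & f1 / mp < 1.5, "additive",
                ifelse(f1 / hp >= 1.65, "over_dominant_up",
                ifelse(f1 / hp >= 1.5, "high_parent",
                ifelse(r_dn <= 0.603, "under_dominant",
                ifelse(r_dn <= 0.67, "low_parent", "partial_nonadditive")))))
    expect_identical(calls$label, expected)
    # scale invariance and parent symmetry
    scl <- heteroprot:::.classify_vec(3.7 * f1, 3.7 * p1, 3.7 * p2, prm)
    expect_identical(scl$label, calls$label)
    swp <- heteroprot:::.classify_vec(f1, p2, p1, prm)
    expect_identical(swp$label, calls$label)
    # direction is tied to the label
    expect_identical(calls$direction,
                     unname(c(additive = "none", over_dominant_up = "up",
                              high_parent = "up", under_dominant = "down",
                              low_parent = "down",
                              partial_nonadditive = "none")[calls$label]))
  }
})

test_that("increasing f1 never moves the label down the dominance order", {
  rank_of <- c(under_dominant = 1, low_parent = 2, partial_nonadditive = 3,
               additive = 3, high_parent = 4, over_dominant_up = 5)
  f1_grid <- exp(seq(log(0.01), log(100), length.out = 4000))
  for (mode in c("literal", "reconstructed")) {
    prm <- pattern_params(mode = mode)
    for (parents in list(c(1, 1.05), c(1, 2), c(1, 4))) {
      labels <- heteroprot:::.classify_vec(f1_grid, parents[1], parents[2],
                                           prm)$label
      expect_true(all(diff(rank_of[labels]) >= 0))
    }
  }
})

test_that("band = 0 empties the dominant (band) classes", {
  set.seed(62)
  prm <- pattern_params(band = 0)
  f1 <- exp(stats::runif(5000, -3, 3))
  p1 <- exp(stats::runif(5000, -3, 3))
  p2 <- exp(stats::runif(5000, -3, 3))
  calls <- heteroprot:::.classify_vec(f1, p1, p2, prm)
  expect_false(any(calls$label %in% c("high_parent", "low_parent")))
})

test_that("classify_all works from replicate means and validates ids", {
  fx <- make_trio_quant(list(add = c(100, 200, 150),
                             od = c(100, 200, 400),
                             dom = c(100, 200, 310)))
  calls <- classify_all(fx$quant, fx$design, c("add", "od", "dom"))
  expect_equal(calls$label[match(c("add", "od", "dom"), calls$protein_id)],
               c("additive", "over_dominant_up", "high_parent"))

  expect_equal(nrow(classify_all(fx$quant, fx$design, character(0))), 0)
  expect_error(classify_all(fx$quant, fx$design, c("add", "ghost")),
               "ghost")
})

test_that("planted patterns are recovered perfectly without noise", {
  for (mode in c("reconstructed", "literal")) {
    mix <- if (mode == "literal") {
      c(additive = 0.2, high_parent = 0.2, low_parent = 0,
        over_dominant = 0.3, under_dominant = 0.2, null = 0.1)
    } else {
      c(additive = 0.2, high_parent = 0.15, low_parent = 0.15,
        over_dominant = 0.2, under_dominant = 0.2, null = 0.1)
    }
    sim <- simulate_quant(sim_config(n_proteins = 400, cv = 0, seed = 13,
                                     pattern_mix = mix, mode = mode))
    tr <- sim$truth[sim$truth$true_pattern != "null", ]
    calls <- classify_all(sim$quant, sim$design, tr$protein_id,
                          pattern_params(mode = mode))
    expect_identical(calls$label[match(tr$protein_id, calls$protein_id)],
                     tr$true_pattern)
  }
})

test_that("pattern summaries reproduce the published worked example", {
  calls <- tibble::tibble(label = rep(
    c("additive", "over_dominant_up", "under_dominant",
      "high_parent", "low_parent"),
    c(29, 150, 45, 51, 24)))
  s <- summarize_patterns(calls)
  expect_equal(s$n_additive, 29)
  expect_equal(s$n_nonadditive, 270)
  expect_equal(s$pct_nonadditive_of_classified, 90.3)
  expect_equal(s$pct_overdominant_of_nonadditive, 72.2)
  expect_equal(s$pct_dominant_of_nonadditive, 27.8)
  expect_equal(s$pct_overdominant_of_classified, 65.2)
  expect_equal(s$pct_up_of_overdominant, 76.9)

  all_add <- summarize_patterns(tibble::tibble(label = rep("additive", 7)))
  expect_equal(all_add$pct_nonadditive_of_classified, 0)
  expect_true(is.na(all_add$pct_up_of_overdominant))

  one_od <- summarize_patterns(tibble::tibble(label = "over_dominant_up"))
  expect_equal(one_od$pct_overdominant_of_classified, 100)

  expect_error(summarize_patterns(tibble::tibble(label = character())),
               class = "heteroprot_value_error")
})

test_that("percentage rounds half away from zero at the requested scale", {
  expect_equal(percentage(697, 4395, 2), 15.86)
  expect_equal(percentage(195, 299, 1), 65.2)
  expect_equal(percentage(0, 100, 2), 0)
  expect_equal(percentage(1, 16, 2), 6.25)
  expect_equal(percentage(1, 8, 1), 12.5)
  # explicit half-way case: 0.125 -> 0.13, not banker's 0.12
  expect_equal(heteroprot:::round_half_away(0.125, 2), 0.13)
  expect_equal(heteroprot:::round_half_away(-0.125, 2), -0.13)
  expect_error(percentage(5, 0), class = "heteroprot_value_error")
  expect_error(percentage(7, 5), class = "heteroprot_value_error")
})
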