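#' Mid-parent value
#'
#' Arithmetic mean of the two parents' trait means.
#'
#' @param p1_mean,p2_mean finite parent trait means.
#' @return `(p1_mean + p2_mean) / 2`.
#' @export
mid_parent <- function(p1_mean, p2_mean) {
  if (any(!is.finite(c(p1_mean, p2_mean)))) .abort_value("means must be finite")
  (p1_mean + p2_mean) / 2
}

#' Heterosis indices for a trait
#'
#' Computes the three classical heterosis percentages of an F1 hybrid
#' relative to its parents: over-high-parent heterosis
#' `OPH = (F1 - HP)/HP * 100`, mid-parent heterosis
#' `MPH = (F1 - MP)/MP * 100` and below-low-parent heterosis
#' `BPH = (F1 - LP)/LP * 100`, with `HP = max(p1, p2)`,
#' `LP = min(p1, p2)` and `MP` the parental mean. The result is
#' scale-invariant and symmetric in the two parents.
#'
#' @param f1_mean hybrid trait mean.
#' @param p1_mean,p2_mean parent trait means (order irrelevant).
#' @return one-row tibble: `f1_mean`, `hp`, `lp`, `mp`, `oph_pct`,
#'   `mph_pct`, `bph_pct`.
#' @examples
#' heterosis_indices(1.5, 1.2, 0.8)  # OPH 25, MPH 50, BPH 87.5
#' @export
heterosis_indices <- function(f1_mean, p1_mean, p2_mean) {
  if (any(!is.finite(c(f1_mean, p1_mean, p2_mean)))) {
    .abort_value("means must be finite")
  }
  hp <- max(p1_mean, p2_mean)
  lp <- min(p1_mean, p2_mean)
  mp <- mid_parent(p1_mean, p2_mean)
  for (ix in c(hp = "OPH", mp = "MPH", lp = "BPH")[c(hp, mp, lp) == 0]) {
    .abort_value(paste0(ix, " is undefined: its parent reference value is zero"))
  }
  tibble::tibble(
    f1_mean = f1_mean, hp = hp, lp = lp, mp = mp,
    oph_pct = (f1_mean - hp) / hp * 100,
    mph_pct = (f1_mean - mp) / mp * 100,
    bph_pct = (f1_mean - lp) / lp * 100
  )
}

#' Heterosis indices from a replicate trait table
#'
#' Aggregates replicate measurements to per-genotype arithmetic means and
#' evaluates [heterosis_indices()] for the hybrid against the other two
#' genotypes.
#'
#' @param traits tibble with columns `genotype`, `replicate`, `value`.
#' @param hybrid genotype label of the F1 hybrid (default `"hybrid"`).
#' @return one-row tibble as from [heterosis_indices()].
#' @export
trait_heterosis <- function(traits, hybrid = "hybrid") {
  means <- dplyr::summarise(dplyr::group_by(traits, .data$genotype),
                            mean = mean(.data$value), .groups = "drop")
  if (!hybrid %in% means$genotype) {
    .abort_design(paste0("hybrid genotype '", hybrid, "' not in trait table"))
  }
  parents <- means$mean[means$genotype != hybrid]
  if (length(parents) != 2) {
    .abort_design("trait table must contain exactly two parent genotypes")
  }
  heterosis_indices(means$mean[means$genotype == hybrid],
                    parents[1], parents[2])
}

#' Pairwise trait significance tests
#'
#' Two-sided pooled-variance two-sample t-tests between every pair of
#' genotypes in a replicate trait table (the hybrid against each parent and
#' parent against parent in a trio).
#'
#' @param traits tibble with columns `genotype`, `replicate`, `value`;
#'   every genotype needs at least two replicates.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return tibble with one row per genotype pair: `genotype_a`,
#'   `genotype_b`, `t_stat`, `df`, `p_value`, `significant`.
#' @export
trait_significance <- function(traits, alpha = 0.05) {
  split_vals <- split(traits$value, traits$genotype)
  too_few <- names(split_vals)[vapply(split_vals, length, 1L) < 2]
  if (length(too_few) > 0) {
    .abort_design(paste0("genotype(s) with < 2 replicates: ",
                         paste(too_few, collapse = ", ")))
  }
  pairs <- utils::combn(names(split_vals), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tt <- two_sample_test(split_vals[[a]], split_vals[[b]])
    tt <- dplyr::mutate(tt, genotype_a = a, genotype_b = b, .before = 1)
    dplyr::mutate(tt, significant = .data$p_value <= alpha)
  })
}
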