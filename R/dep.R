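#' Pooled-variance two-sample t-test
#'
#' Two-sided Student t-test with pooled variance and
#' `df = n_a + n_b - 2`. Unlike [stats::t.test()] it handles degenerate
#' data gracefully: two identical constant groups give `t = 0`, `p = 1`.
#'
#' @param a,b numeric vectors of replicate values, each with at least two
#'   finite values.
#' @return one-row tibble: `t_stat`, `df`, `p_value`.
#' @examples
#' two_sample_test(c(1, 2, 3), c(2, 3, 4))
#' @export
two_sample_test <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    .abort_value("each group needs at least 2 finite values")
  }
  res <- .pooled_t_vec(mean(a), mean(b), var(a), var(b),
                       length(a), length(b))
  tibble::tibble(t_stat = res$t_stat, df = res$df, p_value = res$p_value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values (a thin
#' validated wrapper over [stats::p.adjust()] with `method = "BH"`);
#' output order matches input order.
#'
#' @param p_values numeric vector of probabilities in \[0, 1\].
#' @return adjusted p-values, clipped to at most 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    .abort_value("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed proteins for one genotype comparison
#'
#' Tests every protein for a mean difference between two genotype roles
#' with a pooled-variance t-test (on log2 abundances by default), adjusts
#' p-values with Benjamini-Hochberg across the testable proteins, and
#' reports the fold change on the original intensity scale. Proteins with
#' fewer than two observed replicates in either group are excluded from
#' the comparison and listed in the `skipped` attribute (with a message).
#'
#' @param quant wide quantification tibble (`protein_id` + sample columns).
#' @param design trio design tibble.
#' @param comparison length-2 character vector of roles
#'   `(test, reference)`, e.g. `c("hybrid", "female_parent")`. "Up" means
#'   higher in the test genotype.
#' @param alpha significance level (default 0.05).
#' @param use_fdr if `TRUE` (default) significance is judged on the
#'   BH-adjusted p-value, otherwise on the raw p-value.
#' @param log_transform if `TRUE` (default) the t-test runs on log2
#'   abundances; the fold change is always the raw-scale mean ratio.
#' @return tibble with one row per testable protein: `protein_id`,
#'   `comparison`, `fc`, `log2fc`, `t_stat`, `df`, `p_raw`, `p_adj`,
#'   `direction`, `significant`.
#' @seealso [summarize_comparison()]
#' @export
call_deps <- function(quant, design, comparison = c("hybrid", "female_parent"),
                      alpha = 0.05, use_fdr = TRUE, log_transform = TRUE) {
  design <- validate_design(design)
  if (length(comparison) != 2 || !all(comparison %in% .roles)) {
    .abort_design(paste0("comparison must be two of: ",
                         paste(.roles, collapse = ", ")))
  }
  label <- paste(comparison, collapse = "_vs_")
  cols_a <- design$sample_id[design$role == comparison[1]]
  cols_b <- design$sample_id[design$role == comparison[2]]
  mat_a <- as.matrix(quant[cols_a])
  mat_b <- as.matrix(quant[cols_b])

  n_a <- rowSums(is.finite(mat_a))
  n_b <- rowSums(is.finite(mat_b))
  testable <- n_a >= 2 & n_b >= 2
  skipped <- quant$protein_id[!testable]
  if (length(skipped) > 0) {
    message(length(skipped),
            " protein(s) skipped (<2 observed replicates in a group)")
  }
  mat_a <- mat_a[testable, , drop = FALSE]
  mat_b <- mat_b[testable, , drop = FALSE]
  n_a <- n_a[testable]
  n_b <- n_b[testable]

  mean_a_raw <- rowMeans(mat_a, na.rm = TRUE)
  mean_b_raw <- rowMeans(mat_b, na.rm = TRUE)
  ta <- if (log_transform) log2(mat_a) else mat_a
  tb <- if (log_transform) log2(mat_b) else mat_b
  row_var <- function(m, n) {
    mu <- rowMeans(m, na.rm = TRUE)
    rowSums((m - mu)^2, na.rm = TRUE) / (n - 1)
  }
  tt <- .pooled_t_vec(rowMeans(ta, na.rm = TRUE), rowMeans(tb, na.rm = TRUE),
                      row_var(ta, n_a), row_var(tb, n_b), n_a, n_b)
  fc <- mean_a_raw / mean_b_raw
  p_adj <- bh_adjust(tt$p_value)
  out <- tibble::tibble(
    protein_id = quant$protein_id[testable],
    comparison = label,
    fc = fc,
    log2fc = log2(fc),
    t_stat = tt$t_stat,
    df = tt$df,
    p_raw = tt$p_value,
    p_adj = p_adj,
    direction = ifelse(fc > 1, "up", "down"),
    significant = (if (use_fdr) p_adj else tt$p_value) <= alpha
  )
  attr(out, "skipped") <- skipped
  out
}

#' Summarise a DEP comparison as up/down counts and percentages
#'
#' Counts significant up- and down-regulated proteins in one comparison's
#' records and expresses them as percentages of the jointly quantified
#' protein set, rounded half away from zero to two decimals.
#'
#' @param records DEP tibble from [call_deps()] (a single comparison).
#' @param n_quantified size of the quantified background set.
#' @return one-row tibble: `comparison`, `n_up`, `pct_up`, `n_down`,
#'   `pct_down`, `n_total`, `pct_total`.
#' @export
summarize_comparison <- function(records, n_quantified) {
  if (n_quantified <= 0) .abort_value("n_quantified must be > 0")
  cmp <- unique(records$comparison)
  if (length(cmp) > 1) {
    .abort_value("records must come from a single comparison")
  }
  sig <- records[records$significant, , drop = FALSE]
  n_up <- sum(sig$direction == "up")
  n_down <- sum(sig$direction == "down")
  tibble::tibble(
    comparison = if (length(cmp) == 1) cmp else NA_character_,
    n_up = n_up, pct_up = percentage(n_up, n_quantified, 2),
    n_down = n_down, pct_down = percentage(n_down, n_quantified, 2),
    n_total = n_up + n_down,
    pct_total = percentage(n_up + n_down, n_quantified, 2)
  )
}
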