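#' Run the full trio heterosis analysis
#'
#' Orchestrates the whole pipeline on a quantification matrix: filters to
#' the jointly quantified (complete-case) protein set, calls DEPs for the
#' three pairwise comparisons (parent vs parent, hybrid vs each parent),
#' summarises each as up/down counts and percentages, partitions the three
#' DEP sets into Venn regions, classifies the inheritance pattern of every
#' protein differential between the hybrid and at least one parent, and —
#' when a trait table or term map is supplied — adds heterosis indices,
#' pairwise trait tests and term enrichment. All settings in effect are
#' recorded in the result.
#'
#' @param quant wide quantification tibble (`protein_id` + sample
#'   columns), e.g. `read_quant_table(...)$quant` or
#'   `simulate_quant(...)$quant`.
#' @param design trio design tibble.
#' @param traits optional trait tibble (`genotype`, `replicate`, `value`).
#' @param hybrid_genotype genotype label of the hybrid in `traits`
#'   (default `"hybrid"`).
#' @param term_map optional annotation tibble (`protein_id`, `term_id`).
#' @param alpha significance level for DEP calling and trait tests.
#' @param use_fdr judge DEP significance on BH-adjusted p-values
#'   (default `TRUE`).
#' @param log_transform t-test on log2 abundances (default `TRUE`).
#' @param params [pattern_params()] for the inheritance classifier.
#' @return a list of class `trio_report`: `n_quantified`, `deps` (one
#'   tibble, all three comparisons), `comparison_summary`, `venn`,
#'   `pattern_calls`, `pattern_summary`, and optionally `heterosis`,
#'   `trait_tests`, `enrichment`; plus `settings`.
#' @examples
#' sim <- simulate_quant(sim_config(n_proteins = 200, cv = 0.1, seed = 2))
#' rep <- run_trio_analysis(sim$quant, sim$design)
#' glance(rep)
#' @export
run_trio_analysis <- function(quant, design, traits = NULL,
                              hybrid_genotype = "hybrid",
                              term_map = NULL, alpha = 0.05, use_fdr = TRUE,
                              log_transform = TRUE,
                              params = pattern_params()) {
  design <- validate_design(design)
  quant <- filter_complete_cases(validate_quant(quant))
  n_quantified <- nrow(quant)
  comparisons <- list(
    c("female_parent", "male_parent"),
    c("hybrid", "female_parent"),
    c("hybrid", "male_parent")
  )
  deps <- purrr::map(comparisons, function(cmp) {
    call_deps(quant, design, cmp, alpha = alpha, use_fdr = use_fdr,
              log_transform = log_transform)
  })
  summary <- purrr::map_dfr(deps, summarize_comparison,
                            n_quantified = n_quantified)
  sig_ids <- purrr::map(deps, ~ .x$protein_id[.x$significant])
  venn <- venn_partition(sig_ids[[1]], sig_ids[[2]], sig_ids[[3]])
  # classified set: proteins differential between the hybrid and either parent
  dep_union <- union(sig_ids[[2]], sig_ids[[3]])
  pattern_calls <- classify_all(quant, design, dep_union, params)
  pattern_summary <- if (nrow(pattern_calls) > 0) {
    summarize_patterns(pattern_calls)
  } else NULL

  out <- list(
    n_quantified = n_quantified,
    deps = dplyr::bind_rows(deps),
    comparison_summary = summary,
    venn = venn,
    pattern_calls = pattern_calls,
    pattern_summary = pattern_summary,
    settings = list(alpha = alpha, use_fdr = use_fdr,
                    log_transform = log_transform,
                    pattern_mode = params$mode,
                    upper = params$upper, lower = params$lower,
                    band = params$band)
  )
  if (!is.null(traits)) {
    out$heterosis <- trait_heterosis(traits, hybrid = hybrid_genotype)
    out$trait_tests <- trait_significance(traits, alpha = alpha)
  }
  if (!is.null(term_map) && length(dep_union) > 0) {
    out$enrichment <- enrich_terms(term_map, dep_union, quant$protein_id)
  }
  structure(out, class = "trio_report")
}

#' @export
print.trio_report <- function(x, ...) {
  cat("Trio heterosis analysis:", x$n_quantified, "quantified proteins\n\n")
  print(x$comparison_summary)
  if (!is.null(x$pattern_summary)) {
    cat("\nInheritance patterns (", nrow(x$pattern_calls),
        " hybrid-vs-parent DEPs):\n", sep = "")
    print(x$pattern_summary)
  }
  if (!is.null(x$heterosis)) {
    cat("\nTrait heterosis:\n")
    print(x$heterosis)
  }
  invisible(x)
}

#' Per-comparison summary of a trio report
#'
#' @param x a `trio_report` from [run_trio_analysis()].
#' @param ... unused.
#' @return the comparison-summary tibble (one row per pairwise
#'   comparison).
#' @method tidy trio_report
#' @export
tidy.trio_report <- function(x, ...) {
  x$comparison_summary
}

#' One-row overview of a trio report
#'
#' @param x a `trio_report` from [run_trio_analysis()].
#' @param ... unused.
#' @return one-row tibble: quantified protein count, DEP counts per
#'   comparison, and the headline pattern percentages (plus mid-parent
#'   heterosis when a trait table was analysed).
#' @method glance trio_report
#' @export
glance.trio_report <- function(x, ...) {
  cs <- x$comparison_summary
  out <- tibble::tibble(
    n_quantified = x$n_quantified,
    n_dep_parent_vs_parent = cs$n_total[1],
    n_dep_hybrid_vs_female = cs$n_total[2],
    n_dep_hybrid_vs_male = cs$n_total[3],
    n_classified = nrow(x$pattern_calls),
    pct_nonadditive = if (!is.null(x$pattern_summary))
      x$pattern_summary$pct_nonadditive_of_classified else NA_real_,
    pct_overdominant_of_classified = if (!is.null(x$pattern_summary))
      x$pattern_summary$pct_overdominant_of_classified else NA_real_
  )
  if (!is.null(x$heterosis)) {
    out$mph_pct <- x$heterosis$mph_pct
    out$bph_pct <- x$heterosis$bph_pct
  }
  out
}

#' Write a trio report as JSON
#'
#' Serialises every table of the report (plus the settings in effect) to a
#' single JSON file; all numbers are written at full precision so the
#' report is recomputable-from and comparable-with the stage outputs.
#'
#' @param report a `trio_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "trio_report"))
  payload <- lapply(unclass(report), function(el) {
    if (inherits(el, "tbl_df")) as.data.frame(el) else el
  })
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}
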