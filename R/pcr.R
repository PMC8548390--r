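#' Relative expression by the Livak 2^-ddCt method
#'
#' Converts qPCR cycle-threshold values to fold expression relative to a
#' calibrator. Per genotype, replicate Ct values are first averaged on the
#' Ct scale, then `dCt = mean(ct_target) - mean(ct_reference)`,
#' `ddCt = dCt(genotype) - dCt(calibrator)` and the relative expression is
#' `2^-ddCt`. With `calibrator = "mid_parent"` the calibrator dCt is the
#' mean of the two parents' dCt values, so hybrid expression is read
#' relative to the mid-parent level.
#'
#' @param ct tibble with columns `gene`, `genotype`, `organ`, `replicate`,
#'   `ct_target`, `ct_reference` (see [read_ct_table()]).
#' @param gene gene to evaluate.
#' @param organ organ to evaluate; `NULL` (default) if the table has a
#'   single organ.
#' @param calibrator `"mid_parent"` (default) or the name of a genotype in
#'   the table.
#' @param parents length-2 character vector naming the parent genotypes;
#'   required when `calibrator = "mid_parent"`.
#' @return tibble with one row per genotype: `gene`, `organ`, `genotype`,
#'   `delta_ct`, `delta_delta_ct`, `rel_expr`.
#' @examples
#' ct <- tibble::tibble(
#'   gene = "QS", genotype = rep(c("P1", "P2", "F1"), each = 2),
#'   organ = "root", replicate = rep(1:2, 3),
#'   ct_target = c(25, 25, 27, 27, 24, 24), ct_reference = c(20, 20, 20, 20, 20, 20))
#' ddct_relative_expression(ct, "QS", parents = c("P1", "P2"))
#' @export
ddct_relative_expression <- function(ct, gene, organ = NULL,
                                     calibrator = "mid_parent",
                                     parents = NULL) {
  sub <- ct[ct$gene == gene, , drop = FALSE]
  if (!is.null(organ)) sub <- sub[sub$organ == organ, , drop = FALSE]
  if (nrow(sub) == 0) .abort_value("no Ct rows for this gene/organ")
  if (length(unique(sub$organ)) > 1) {
    .abort_value("multiple organs present; pass `organ`")
  }
  dct <- dplyr::summarise(
    dplyr::group_by(sub, .data$genotype),
    delta_ct = mean(.data$ct_target) - mean(.data$ct_reference),
    .groups = "drop")
  if (identical(calibrator, "mid_parent")) {
    if (is.null(parents) || length(parents) != 2) {
      .abort_value("calibrator = 'mid_parent' needs `parents` (length 2)")
    }
    missing_p <- setdiff(parents, dct$genotype)
    if (length(missing_p) > 0) {
      .abort_value(paste0("parent genotype(s) missing: ",
                          paste(missing_p, collapse = ", ")))
    }
    cal_dct <- mean(dct$delta_ct[match(parents, dct$genotype)])
  } else {
    if (!calibrator %in% dct$genotype) {
      .abort_value(paste0("calibrator genotype '", calibrator, "' missing"))
    }
    cal_dct <- dct$delta_ct[dct$genotype == calibrator]
  }
  out <- dplyr::mutate(
    dct,
    gene = gene,
    organ = unique(sub$organ),
    delta_delta_ct = .data$delta_ct - cal_dct,
    rel_expr = 2^(-.data$delta_delta_ct)
  )
  dplyr::select(out, "gene", "organ", "genotype", "delta_ct",
                "delta_delta_ct", "rel_expr")
}
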