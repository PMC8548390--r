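#' Parameters of the inheritance-pattern rule table
#'
#' The classifier compares the hybrid mean against the mid-parent (MP),
#' high-parent (HP) and low-parent (LP) means using a fold-change threshold
#' pair with a 10% band around the upper and lower cuts. With the defaults
#' (`upper = 1.5`, `lower = 0.67`, `band = 0.10`) the four cut points are
#' 1.65, 1.5, 0.67 and 0.603.
#'
#' Two readings of the down-regulated bands are provided. In
#' `mode = "literal"` every ratio is taken against the high parent,
#' following the rule text verbatim. In `mode = "reconstructed"` the
#' down-regulated bands (under-dominant, low-parent) are taken against the
#' low parent, the biologically conventional reading under which
#' "low-parent expression" actually means "near the low parent".
#'
#' @param upper upper fold-change threshold (> 1; default 1.5).
#' @param lower lower fold-change threshold (in (0, 1); default 0.67).
#' @param band proportional band width around the thresholds (default 0.10).
#' @param mode `"literal"` (default) or `"reconstructed"`.
#' @return a list of class `pattern_params`.
#' @seealso [classify_protein()] for the rule table itself.
#' @export
pattern_params <- function(upper = 1.5, lower = 0.67, band = 0.10,
                           mode = c("literal", "reconstructed")) {
  mode <- match.arg(mode)
  if (!(lower > 0 && lower < 1 && upper > 1)) {
    .abort_config("need 0 < lower < 1 < upper")
  }
  if (band < 0 || band >= 1) .abort_config("need 0 <= band < 1")
  structure(list(upper = upper, lower = lower, band = band, mode = mode),
            class = "pattern_params")
}

# ordered label vocabulary; direction follows the label
.pattern_labels <- c("additive", "over_dominant_up", "high_parent",
                     "under_dominant", "low_parent", "partial_nonadditive")
.pattern_direction <- c(
  additive = "none", over_dominant_up = "up", high_parent = "up",
  under_dominant = "down", low_parent = "down", partial_nonadditive = "none"
)

# Vectorised rule table. HP = max(p1,p2), LP = min, MP = mean;
# U = upper, L = lower, b = band. Evaluated in order:
#   (1) L < f1/MP < U                 -> additive
#   (2) f1/R_up >= U(1+b)             -> over_dominant_up
#   (3) U <= f1/R_up < U(1+b)         -> high_parent
#   (4) f1/R_dn <= L(1-b)             -> under_dominant
#   (5) L(1-b) < f1/R_dn <= L         -> low_parent
#   (6) otherwise                     -> partial_nonadditive
# R_up is always HP; R_dn is HP (literal) or LP (reconstructed).
.classify_vec <- function(f1, p1, p2, params) {
  hp <- pmax(p1, p2)
  lp <- pmin(p1, p2)
  mp <- (p1 + p2) / 2
  r_mp <- f1 / mp
  r_hp <- f1 / hp
  r_lp <- f1 / lp
  r_dn <- if (params$mode == "literal") r_hp else r_lp
  u <- params$upper
  l <- params$lower
  hi_cut <- u * (1 + params$band)
  lo_cut <- l * (1 - params$band)
  label <- dplyr::case_when(
    r_mp > l & r_mp < u      ~ "additive",
    r_hp >= hi_cut           ~ "over_dominant_up",
    r_hp >= u                ~ "high_parent",
    r_dn <= lo_cut           ~ "under_dominant",
    r_dn <= l                ~ "low_parent",
    TRUE                     ~ "partial_nonadditive"
  )
  tibble::tibble(
    r_mp = r_mp, r_hp = r_hp, r_lp = r_lp,
    label = label,
    direction = unname(.pattern_direction[label])
  )
}

#' Classify one protein's inheritance pattern
#'
#' Assigns an expression-inheritance label to a protein from its hybrid and
#' parent mean abundances. A hybrid/mid-parent fold change inside
#' (`lower`, `upper`) is additive; outside it the protein is non-additive
#' and falls into over-dominant, high-parent (dominant), under-dominant or
#' low-parent bands around the thresholds (see [pattern_params()] for the
#' cut points and the two rule-reading modes). A non-additive protein
#' landing in none of the four bands is labelled `partial_nonadditive`.
#'
#' @param f1_mean,p1_mean,p2_mean positive mean abundances of the hybrid
#'   and the two parents. Parent order is irrelevant.
#' @param params a [pattern_params()] object.
#' @return one-row tibble with the ratios `r_mp`, `r_hp`, `r_lp`, the
#'   `label` and its `direction` (`up`, `down` or `none`).
#' @examples
#' classify_protein(150, 100, 200)             # mid-parent value: additive
#' classify_protein(400, 100, 200)             # F1/HP = 2: over-dominant
#' @export
classify_protein <- function(f1_mean, p1_mean, p2_mean,
                             params = pattern_params()) {
  stopifnot(inherits(params, "pattern_params"))
  if (any(c(f1_mean, p1_mean, p2_mean) <= 0) ||
      any(!is.finite(c(f1_mean, p1_mean, p2_mean)))) {
    .abort_value("means must be positive and finite")
  }
  .classify_vec(f1_mean, p1_mean, p2_mean, params)
}

#' Classify the inheritance pattern of a set of proteins
#'
#' Computes per-genotype replicate means from the quantification table and
#' applies [classify_protein()]'s rule table to every requested protein
#' (typically the DEPs from the hybrid-vs-parent comparisons).
#'
#' @param quant wide quantification tibble (`protein_id` + sample columns).
#' @param design trio design tibble (see [validate_design()]).
#' @param dep_ids character vector of protein ids to classify; must all be
#'   present in `quant`.
#' @param params a [pattern_params()] object.
#' @return tibble with one row per id: `protein_id`, `r_mp`, `r_hp`,
#'   `r_lp`, `label`, `direction`.
#' @export
classify_all <- function(quant, design, dep_ids, params = pattern_params()) {
  stopifnot(inherits(params, "pattern_params"))
  design <- validate_design(design)
  dep_ids <- unique(as.character(dep_ids))
  if (length(dep_ids) == 0) {
    return(tibble::tibble(protein_id = character(), r_mp = double(),
                          r_hp = double(), r_lp = double(),
                          label = character(), direction = character()))
  }
  missing_ids <- setdiff(dep_ids, quant$protein_id)
  if (length(missing_ids) > 0) {
    .abort_value(paste0("protein id(s) not in matrix: ",
                        paste(missing_ids, collapse = ", ")))
  }
  sub <- quant[match(dep_ids, quant$protein_id), ]
  means <- purrr::map(setNames(.roles, .roles), function(r) {
    cols <- design$sample_id[design$role == r]
    rowMeans(as.matrix(sub[cols]), na.rm = TRUE)
  })
  calls <- .classify_vec(means$hybrid, means$female_parent,
                         means$male_parent, params)
  dplyr::bind_cols(tibble::tibble(protein_id = dep_ids), calls)
}

#' Summarise inheritance-pattern frequencies
#'
#' Aggregates per-protein pattern calls into the class counts and the five
#' headline percentages: non-additive among classified, over-dominant and
#' dominant among non-additive, over-dominant among classified, and
#' up-regulated among over-dominant. Over-dominant pools the up band with
#' the under-dominant (down) band; dominant pools the high-parent and
#' low-parent bands. Percentages are rounded half away from zero to one
#' decimal; a percentage with an empty denominator is `NA`.
#'
#' @param calls tibble of pattern calls with a `label` column (as returned
#'   by [classify_all()]), or any data frame with such a column.
#' @return one-row tibble of counts (`n_additive`, `n_nonadditive`,
#'   `n_overdominant_up`, `n_overdominant_down`, `n_dominant_high`,
#'   `n_dominant_low`, `n_partial`) and percentages
#'   (`pct_nonadditive_of_classified`, `pct_overdominant_of_nonadditive`,
#'   `pct_dominant_of_nonadditive`, `pct_overdominant_of_classified`,
#'   `pct_up_of_overdominant`).
#' @export
summarize_patterns <- function(calls) {
  if (nrow(calls) == 0) .abort_value("no pattern calls to summarise")
  bad <- setdiff(unique(calls$label), .pattern_labels)
  if (length(bad) > 0) {
    .abort_value(paste0("unknown pattern label(s): ", paste(bad, collapse = ", ")))
  }
  n_of <- function(lbl) sum(calls$label == lbl)
  n_additive <- n_of("additive")
  n_od_up <- n_of("over_dominant_up")
  n_od_dn <- n_of("under_dominant")
  n_dom_hi <- n_of("high_parent")
  n_dom_lo <- n_of("low_parent")
  n_partial <- n_of("partial_nonadditive")
  n_nonadd <- n_od_up + n_od_dn + n_dom_hi + n_dom_lo + n_partial
  n_classified <- n_additive + n_nonadd
  n_od <- n_od_up + n_od_dn
  n_dom <- n_dom_hi + n_dom_lo
  pct <- function(k, n) if (n > 0) percentage(k, n, 1) else NA_real_
  tibble::tibble(
    n_additive = n_additive, n_nonadditive = n_nonadd,
    n_overdominant_up = n_od_up, n_overdominant_down = n_od_dn,
    n_dominant_high = n_dom_hi, n_dominant_low = n_dom_lo,
    n_partial = n_partial,
    pct_nonadditive_of_classified = pct(n_nonadd, n_classified),
    pct_overdominant_of_nonadditive = pct(n_od, n_nonadd),
    pct_dominant_of_nonadditive = pct(n_dom, n_nonadd),
    pct_overdominant_of_classified = pct(n_od, n_classified),
    pct_up_of_overdominant = pct(n_od_up, n_od)
  )
}
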