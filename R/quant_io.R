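#' Read a sample-design table
#'
#' The design table assigns each quantified sample to one genotype of the
#' trio (female parent, male parent, F1 hybrid) and a biological replicate.
#' Expected columns: `sample_id`, `genotype`, `role`, `replicate`; TSV or
#' CSV by file extension.
#'
#' @param path path to the design file.
#' @return a validated tibble with columns `sample_id`, `genotype`, `role`,
#'   `replicate`.
#' @seealso [read_quant_table()], [validate_design()]
#' @export
read_sample_design <- function(path) {
  design <- .read_delim_auto(path)
  need <- c("sample_id", "genotype", "role", "replicate")
  if (!all(need %in% names(design))) {
    .abort_format(paste0("design file must have columns: ",
                         paste(need, collapse = ", ")))
  }
  design <- dplyr::mutate(
    design,
    sample_id = as.character(.data$sample_id),
    genotype  = as.character(.data$genotype),
    role      = as.character(.data$role),
    replicate = as.integer(.data$replicate)
  )
  validate_design(design)
}

#' Validate a trio sample design
#'
#' Checks the invariants of the trio design: all three roles
#' (`female_parent`, `male_parent`, `hybrid`) present, each role mapped to
#' exactly one genotype label, unique sample ids, unique (genotype,
#' replicate) pairs, positive replicate indices.
#'
#' @param design a data frame with columns `sample_id`, `genotype`, `role`,
#'   `replicate`.
#' @return the design as a tibble, sorted by role then replicate.
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  missing_roles <- setdiff(.roles, design$role)
  if (length(missing_roles) > 0) {
    .abort_design(paste0("design lacks required role(s): ",
                         paste(missing_roles, collapse = ", ")))
  }
  bad_roles <- setdiff(design$role, .roles)
  if (length(bad_roles) > 0) {
    .abort_design(paste0("unknown role(s): ", paste(bad_roles, collapse = ", ")))
  }
  role_map <- dplyr::distinct(design, .data$role, .data$genotype)
  if (anyDuplicated(role_map$role)) {
    .abort_design("each role must map to exactly one genotype label")
  }
  if (anyDuplicated(design$sample_id)) .abort_design("duplicate sample_id")
  if (anyDuplicated(design[c("genotype", "replicate")])) {
    .abort_design("(genotype, replicate) pairs must be unique")
  }
  if (any(!is.finite(design$replicate)) || any(design$replicate < 1)) {
    .abort_design("replicate must be a positive integer")
  }
  dplyr::arrange(design, match(.data$role, .roles), .data$replicate)
}

#' Read a protein quantification matrix with its design
#'
#' Reads a delimited protein-by-sample abundance table (first column
#' `protein_id`, remaining columns one per sample) together with its sample
#' design, validates both, and returns them in canonical order (rows sorted
#' by protein id, sample columns sorted by sample id). Abundances must be
#' strictly positive where observed; empty cells or `NA` are kept as
#' missing. Sample columns not present in the design are rejected.
#'
#' @param path path to the quantification table (TSV or CSV by extension).
#' @param design_path path to the sample-design table.
#' @return a list of class `quant_matrix` with elements `quant` (wide
#'   tibble, `protein_id` + one numeric column per sample) and `design`.
#' @examples
#' sim <- simulate_quant(sim_config(n_proteins = 5, seed = 1))
#' tmp <- tempfile(fileext = ".tsv"); dtmp <- tempfile(fileext = ".tsv")
#' write_records(sim$quant, tmp)
#' write_records(sim$design, dtmp)
#' qm <- read_quant_table(tmp, dtmp)
#' dim(qm$quant)
#' @export
read_quant_table <- function(path, design_path) {
  design <- read_sample_design(design_path)
  quant <- .read_delim_auto(path)
  if (names(quant)[1] != "protein_id") {
    .abort_format("first column of the quant table must be 'protein_id'")
  }
  quant$protein_id <- as.character(quant$protein_id)
  extra <- setdiff(names(quant)[-1], design$sample_id)
  if (length(extra) > 0) {
    .abort_design(paste0("sample column(s) absent from design: ",
                         paste(extra, collapse = ", ")))
  }
  absent <- setdiff(design$sample_id, names(quant)[-1])
  if (length(absent) > 0) {
    .abort_design(paste0("design sample(s) missing from quant table: ",
                         paste(absent, collapse = ", ")))
  }
  quant <- validate_quant(quant)
  quant <- quant[c("protein_id", sort(design$sample_id))]
  structure(list(quant = quant, design = design), class = "quant_matrix")
}

#' Validate a quantification table
#'
#' Checks protein-id uniqueness and strict positivity of observed
#' abundances; returns the table sorted by protein id.
#'
#' @param quant wide tibble, `protein_id` first then numeric sample columns.
#' @return the validated tibble, rows sorted by `protein_id`.
#' @export
validate_quant <- function(quant) {
  quant <- tibble::as_tibble(quant)
  dup <- quant$protein_id[duplicated(quant$protein_id)]
  if (length(dup) > 0) {
    .abort_format(paste0("duplicate protein id(s): ",
                         paste(unique(dup), collapse = ", ")))
  }
  vals <- as.matrix(quant[-1])
  if (!is.numeric(vals)) .abort_format("abundance columns must be numeric")
  if (any(vals <= 0, na.rm = TRUE)) {
    .abort_value("observed abundances must be strictly positive")
  }
  dplyr::arrange(quant, .data$protein_id)
}

#' Keep proteins quantified in every sample
#'
#' Complete-case filter: drops proteins with any missing abundance, the
#' step that reduces an identified-protein table to the jointly quantified
#' set used by all downstream comparisons.
#'
#' @param quant wide quantification tibble.
#' @return the filtered tibble.
#' @export
filter_complete_cases <- function(quant) {
  keep <- stats::complete.cases(quant[-1])
  quant[keep, ]
}

#' Read a trait-measurement table
#'
#' CSV with columns `genotype`, `replicate`, `value` (one row per
#' biological replicate of a measured trait, e.g. % nicotine).
#'
#' @param path path to the CSV file.
#' @return tibble with those three columns.
#' @export
read_trait_table <- function(path) {
  traits <- .read_delim_auto(path)
  need <- c("genotype", "replicate", "value")
  if (!all(need %in% names(traits))) {
    .abort_format("trait table must have columns genotype, replicate, value")
  }
  if (any(!is.finite(traits$value))) .abort_value("trait values must be finite")
  tibble::as_tibble(traits[need])
}

#' Read a protein-to-term annotation map
#'
#' Two-column TSV (`protein_id`, `term_id`), one row per annotation, as
#' consumed by [enrich_terms()].
#'
#' @param path path to the TSV file.
#' @return tibble with columns `protein_id`, `term_id`.
#' @export
read_term_map <- function(path) {
  tm <- .read_delim_auto(path)
  if (!all(c("protein_id", "term_id") %in% names(tm))) {
    .abort_format("term map must have columns protein_id, term_id")
  }
  tibble::as_tibble(tm[c("protein_id", "term_id")])
}

#' Read a qPCR Ct table
#'
#' CSV with columns `gene`, `genotype`, `organ`, `replicate`, `ct_target`,
#' `ct_reference`, as consumed by [ddct_relative_expression()].
#'
#' @param path path to the CSV file.
#' @return tibble with those six columns.
#' @export
read_ct_table <- function(path) {
  ct <- .read_delim_auto(path)
  need <- c("gene", "genotype", "organ", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    .abort_format(paste0("Ct table must have columns: ",
                         paste(need, collapse = ", ")))
  }
  if (any(!is.finite(ct$ct_target)) || any(ct$ct_target <= 0) ||
      any(!is.finite(ct$ct_reference)) || any(ct$ct_reference <= 0)) {
    .abort_value("Ct values must be positive and finite")
  }
  tibble::as_tibble(ct[need])
}

#' Write a tabular result to disk
#'
#' Writes any result tibble as TSV or JSON. Numeric fields survive a
#' read-back to at least 12 significant digits; an empty table yields a
#' header-only file.
#'
#' @param records a data frame (possibly empty, but with columns).
#' @param path output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- tibble::as_tibble(records)
  if (format == "tsv") {
    out <- dplyr::mutate(records, dplyr::across(
      dplyr::where(is.numeric),
      ~ ifelse(is.na(.x), NA_character_, sprintf("%.15g", .x))
    ))
    readr::write_tsv(out, path, na = "NA")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("quant_matrix:", nrow(x$quant), "proteins x",
      ncol(x$quant) - 1, "samples\n")
  roles <- table(x$design$role)
  cat("design:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# delimiter by extension: .csv -> comma, anything else -> tab
.read_delim_auto <- function(path) {
  if (!file.exists(path)) .abort_value(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    na = c("", "NA"), progress = FALSE)
}
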