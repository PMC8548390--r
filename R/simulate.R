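#' Configuration for the trio simulator
#'
#' Describes a synthetic parent/parent/F1 quantification experiment with
#' planted inheritance patterns. Each protein is assigned a pattern from
#' `pattern_mix`; for non-null proteins the two parent medians differ by
#' `parent_fold` and the hybrid median is a pattern-specific multiple of
#' the reference parent (mid-parent for additive; high or low parent for
#' the dominant/over-dominant bands). Replicate values are the planted
#' median times lognormal multiplicative noise with coefficient of
#' variation `cv`.
#'
#' The default multipliers sit at the midpoint of each bounded rule band
#' (high-parent 1.575, low-parent 0.6365) and well inside the open bands
#' (over-dominant 2.0, under-dominant 0.45), so classification is
#' unambiguous at low noise. Planting follows the rule-table reading in
#' `mode`; the configuration is rejected if any requested pattern cannot be
#' realised under that mode with the given `parent_fold` (in particular,
#' a literal-mode low-parent class requires nearly equal parents).
#'
#' @param n_proteins number of proteins (default 2000).
#' @param n_replicates biological replicates per genotype (default 3).
#' @param parent_fold fold difference between parent medians for
#'   parent-divergent proteins (> 1; default 2).
#' @param pattern_mix named proportions over `additive`, `high_parent`,
#'   `low_parent`, `over_dominant`, `under_dominant`, `null`; must sum to 1.
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.2, a typical between-replicate spread for label-free
#'   protein quantification).
#' @param seed integer seed; one seed drives per-protein substreams, so
#'   enlarging `n_proteins` leaves earlier proteins unchanged.
#' @param mode rule-table reading used for planting, `"reconstructed"`
#'   (default; all six classes realisable) or `"literal"`.
#' @param multipliers optional named list overriding the planted
#'   hybrid/reference ratios for `over_dominant`, `high_parent`,
#'   `low_parent`, `under_dominant`.
#' @param base_log_mean,base_log_sd location and spread (natural-log scale)
#'   of the baseline protein medians (defaults log(1e6) and 1, spanning the
#'   orders of magnitude typical of protein intensity data).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2000, n_replicates = 3, parent_fold = 2,
                       pattern_mix = c(additive = 0.03, high_parent = 0.02,
                                       low_parent = 0.01, over_dominant = 0.05,
                                       under_dominant = 0.02, null = 0.87),
                       cv = 0.2, seed = 1,
                       mode = c("reconstructed", "literal"),
                       multipliers = NULL,
                       base_log_mean = log(1e6), base_log_sd = 1) {
  mode <- match.arg(mode)
  mix_names <- c("additive", "high_parent", "low_parent", "over_dominant",
                 "under_dominant", "null")
  if (!setequal(names(pattern_mix), mix_names)) {
    .abort_config(paste0("pattern_mix must be named over: ",
                         paste(mix_names, collapse = ", ")))
  }
  pattern_mix <- pattern_mix[mix_names]
  if (abs(sum(pattern_mix) - 1) > 1e-9 || any(pattern_mix < 0)) {
    .abort_config("pattern_mix proportions must be >= 0 and sum to 1")
  }
  if (cv < 0) .abort_config("cv must be >= 0")
  if (parent_fold <= 1) .abort_config("parent_fold must be > 1")
  if (n_replicates < 1 || n_proteins < 1) {
    .abort_config("n_proteins and n_replicates must be positive")
  }
  params <- pattern_params(mode = mode)
  mult <- list(
    over_dominant = 2.0,
    high_parent = params$upper * (1 + params$band / 2),
    low_parent = params$lower * (1 - params$band / 2),
    under_dominant = 0.45
  )
  if (!is.null(multipliers)) mult[names(multipliers)] <- multipliers
  cfg <- structure(
    list(n_proteins = as.integer(n_proteins),
         n_replicates = as.integer(n_replicates),
         parent_fold = parent_fold, pattern_mix = pattern_mix,
         cv = cv, seed = as.integer(seed), mode = mode,
         multipliers = mult, params = params,
         base_log_mean = base_log_mean, base_log_sd = base_log_sd),
    class = "sim_config")
  .check_plant_feasibility(cfg)
  cfg
}

# noise-free medians (p_lo, p_hi, f1) for one pattern under a config
.planted_medians <- function(pattern, baseline, cfg) {
  if (pattern == "null") {
    return(c(p_lo = baseline, p_hi = baseline, f1 = baseline))
  }
  p_lo <- baseline
  p_hi <- baseline * cfg$parent_fold
  mp <- (p_lo + p_hi) / 2
  f1 <- switch(pattern,
    additive = mp,
    high_parent = cfg$multipliers$high_parent * p_hi,
    over_dominant = cfg$multipliers$over_dominant * p_hi,
    under_dominant = cfg$multipliers$under_dominant *
      (if (cfg$mode == "literal") p_hi else p_lo),
    low_parent = cfg$multipliers$low_parent *
      (if (cfg$mode == "literal") p_hi else p_lo)
  )
  c(p_lo = p_lo, p_hi = p_hi, f1 = f1)
}

# planted label in the classifier's vocabulary
.truth_label <- c(additive = "additive", high_parent = "high_parent",
                  low_parent = "low_parent", over_dominant = "over_dominant_up",
                  under_dominant = "under_dominant", null = "null")

.check_plant_feasibility <- function(cfg) {
  active <- names(cfg$pattern_mix)[cfg$pattern_mix > 0 &
                                     names(cfg$pattern_mix) != "null"]
  for (pat in active) {
    m <- .planted_medians(pat, 1, cfg)
    got <- .classify_vec(m["f1"], m["p_lo"], m["p_hi"], cfg$params)$label
    want <- .truth_label[[pat]]
    if (got != want) {
      .abort_config(paste0(
        "pattern '", pat, "' is not realisable in mode '", cfg$mode,
        "' with parent_fold = ", cfg$parent_fold,
        " (planted medians classify as '", got, "')"))
    }
  }
  invisible(cfg)
}

# per-protein substream seed from the run seed and a protein counter
.substream_seed <- function(seed, i) {
  base <- (as.numeric(seed) * 48271) %% 2147483647
  as.integer((base + i * 2654435761) %% 2147483647)
}

#' Simulate a trio quantification matrix with planted patterns
#'
#' Generates a protein-by-sample abundance table for a female parent, male
#' parent and F1 hybrid with `n_replicates` biological replicates each,
#' together with the design table and a truth table recording every
#' protein's planted pattern and hybrid/parent ratios. Deterministic given
#' `config$seed`; the planted value is the log-scale median, so replicate
#' values are `median * exp(N(0, sigma))` with
#' `sigma = sqrt(log(1 + cv^2))`.
#'
#' @param config a [sim_config()] object.
#' @return list of class `quant_matrix` with elements `quant`, `design`
#'   and `truth` (tibble: `protein_id`, `true_pattern`, `f1_over_mp`,
#'   `f1_over_hp`, `f1_over_lp`).
#' @examples
#' sim <- simulate_quant(sim_config(n_proteins = 10, cv = 0, seed = 7))
#' sim$truth
#' @export
simulate_quant <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- .hold_rng()
  on.exit(.release_rng(old_seed), add = TRUE)

  n_rep <- config$n_replicates
  genotypes <- c(female_parent = "P1", male_parent = "P2", hybrid = "F1")
  design <- tibble::tibble(
    sample_id = as.vector(vapply(genotypes, function(g)
      paste0(g, "_r", seq_len(n_rep)), character(n_rep))),
    genotype = rep(unname(genotypes), each = n_rep),
    role = rep(names(genotypes), each = n_rep),
    replicate = rep(seq_len(n_rep), times = 3)
  )
  sigma <- sqrt(log(1 + config$cv^2))
  cum_mix <- cumsum(config$pattern_mix)
  n <- config$n_proteins
  width <- nchar(as.character(n))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(n))

  values <- matrix(NA_real_, nrow = n, ncol = 3 * n_rep)
  truth_pattern <- character(n)
  r_mp <- r_hp <- r_lp <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.substream_seed(config$seed, i))
    pattern <- names(cum_mix)[which(stats::runif(1) <= cum_mix + 1e-12)[1]]
    hi_is_female <- stats::runif(1) < 0.5
    baseline <- exp(stats::rnorm(1, config$base_log_mean, config$base_log_sd))
    med <- .planted_medians(pattern, baseline, config)
    female <- if (hi_is_female) med[["p_hi"]] else med[["p_lo"]]
    male <- if (hi_is_female) med[["p_lo"]] else med[["p_hi"]]
    medians <- rep(c(female, male, med[["f1"]]), each = n_rep)
    noise <- exp(stats::rnorm(3 * n_rep, 0, sigma))
    values[i, ] <- medians * noise
    truth_pattern[i] <- .truth_label[[pattern]]
    mp <- (female + male) / 2
    r_mp[i] <- med[["f1"]] / mp
    r_hp[i] <- med[["f1"]] / med[["p_hi"]]
    r_lp[i] <- med[["f1"]] / med[["p_lo"]]
  }
  colnames(values) <- design$sample_id
  quant <- dplyr::bind_cols(tibble::tibble(protein_id = ids),
                            tibble::as_tibble(values))
  truth <- tibble::tibble(protein_id = ids, true_pattern = truth_pattern,
                          f1_over_mp = r_mp, f1_over_hp = r_hp,
                          f1_over_lp = r_lp)
  structure(list(quant = quant, design = design, truth = truth),
            class = "quant_matrix")
}

#' Simulate trait replicates for the trio
#'
#' Draws replicate trait values per genotype as
#' `mean * exp(N(0, sigma))` with `sigma = sqrt(log(1 + cv^2))`.
#' The default means are a nicotine-content trio (percent dry weight) with
#' strong positive heterosis: parents near 0.47 and 0.52 and a hybrid at
#' 0.76, i.e. mid-parent heterosis around 53% and transgression past the
#' low parent of around 61%.
#'
#' @param genotype_means named positive numeric vector of trait means; the
#'   names become the `genotype` column.
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param n_replicates replicates per genotype (default 3).
#' @param seed integer seed.
#' @return tibble with columns `genotype`, `replicate`, `value`.
#' @export
simulate_trait <- function(genotype_means = c(female_parent = 0.47287,
                                              male_parent = 0.52157,
                                              hybrid = 0.76),
                           cv = 0.05, n_replicates = 3, seed = 1) {
  if (any(genotype_means <= 0) || any(!is.finite(genotype_means))) {
    .abort_config("genotype means must be positive and finite")
  }
  if (is.null(names(genotype_means)) || any(names(genotype_means) == "")) {
    .abort_config("genotype_means must be a named vector")
  }
  if (cv < 0) .abort_config("cv must be >= 0")
  if (n_replicates < 1) .abort_config("n_replicates must be >= 1")
  old_seed <- .hold_rng()
  on.exit(.release_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  sigma <- sqrt(log(1 + cv^2))
  n_g <- length(genotype_means)
  tibble::tibble(
    genotype = rep(names(genotype_means), each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = n_g),
    value = rep(unname(genotype_means), each = n_replicates) *
      exp(stats::rnorm(n_g * n_replicates, 0, sigma))
  )
}

.hold_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.release_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
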